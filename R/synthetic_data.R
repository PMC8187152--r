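# Synthetic multi-species developmental splicing data with ground truth.
#
# The generator emulates the study design the pipeline expects: seven
# species with their gestation times, seven organs, ordered developmental
# stages (dense prenatal, sparse postnatal), overdispersed
# binomial inclusion/exclusion counts (beta-binomial), canonical
# trajectory shapes, planted intronic hexamers and planted exon gain/
# loss/alternification events on the species tree. Every dataset is a
# pure function of its configuration and seed.

#' Default simulation configuration
#'
#' @param n_genes Number of cassette-exon segments to simulate.
#' @param species Named numeric vector of gestation days (default
#'   [gestation_table()]).
#' @param organs Organ names.
#' @param n_replicates Samples per organ-stage.
#' @param pattern_mix Named proportions of trajectory shapes (sum to 1).
#' @param depth Mean junction coverage (Poisson mean of `i + e`).
#' @param rho Beta-binomial overdispersion in `[0, 1)`.
#' @param lr Read length in nt.
#' @param amplitude_range Range of true dPSI for dynamic exons.
#' @param seed Mandatory integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 50,
                       species = gestation_table(),
                       organs = c("brain", "cerebellum", "heart", "kidney",
                                  "liver", "ovary", "testis"),
                       n_replicates = 2,
                       pattern_mix = c(up = 0.3, down = 0.3, `up-down` = 0.1,
                                       `down-up` = 0.1, flat = 0.2),
                       depth = 50, rho = 0.05, lr = 100,
                       amplitude_range = c(0.3, 0.8),
                       seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(abs(sum(pattern_mix) - 1) < 1e-8, rho >= 0, rho < 1)
  structure(list(n_genes = n_genes, species = species, organs = organs,
                 n_replicates = n_replicates, pattern_mix = pattern_mix,
                 depth = depth, rho = rho, lr = lr,
                 amplitude_range = amplitude_range, seed = as.integer(seed)),
            class = "sim_config")
}

#' Developmental stage grid for one species
#'
#' Four prenatal stages at 30/50/70/95% of gestation and three postnatal
#' stages at 3, 30 and 300 days after birth, mirroring a dense prenatal /
#' sparse postnatal design.
#'
#' @param gestation Gestation time in days.
#' @return `data.frame` with `stage` and `days_post_conception`.
#' @export
stage_grid <- function(gestation) {
  data.frame(
    stage = c("e30", "e50", "e70", "e95", "p3", "p30", "p300"),
    days_post_conception = c(gestation * c(0.30, 0.50, 0.70, 0.95),
                             gestation + c(3, 30, 300)))
}

#' True PSI trajectory of a canonical shape
#'
#' Logistic curves for monotone shapes, Gaussian bumps for transient
#' shapes, rescaled so the range over the sampled ages equals `amplitude`
#' above a baseline of `base`.
#'
#' @param pattern One of `"up"`, `"down"`, `"up-down"`, `"down-up"`,
#'   `"flat"`.
#' @param amplitude True dPSI in `(0, 1]` (ignored for `"flat"`).
#' @param ages Sorted log ages.
#' @param base Baseline PSI (default 0.1; flat exons sit at 0.5).
#' @return Numeric vector of true PSI in `[0, 1]`.
#' @export
simulate_trajectory <- function(pattern, amplitude, ages, base = 0.1) {
  stopifnot(!is.unsorted(ages))
  if (pattern == "flat") return(rep(0.5, length(ages)))
  stopifnot(amplitude > 0, amplitude <= 1, base + amplitude <= 1)
  mid <- (min(ages) + max(ages)) / 2
  span <- max(ages) - min(ages)
  shape <- switch(pattern,
    "up" = stats::plogis((ages - mid) / (span / 10)),
    "down" = stats::plogis(-(ages - mid) / (span / 10)),
    "up-down" = exp(-(ages - mid)^2 / (2 * (span / 5)^2)),
    "down-up" = 1 - exp(-(ages - mid)^2 / (2 * (span / 5)^2)),
    stop("unknown pattern: ", pattern, call. = FALSE))
  shape <- (shape - min(shape)) / (max(shape) - min(shape))
  base + amplitude * shape
}

#' Beta-binomial inclusion/exclusion counts
#'
#' Total coverage is Poisson with mean `depth`; inclusion counts are
#' beta-binomial with mean `psi` and intra-class correlation `rho`
#' (`rho = 0` reduces to the binomial). The implied quasi-binomial
#' dispersion is approximately `1 + (n - 1) * rho`.
#'
#' @param psi Vector of true PSI values.
#' @param depth Mean total coverage.
#' @param rho Overdispersion in `[0, 1)`.
#' @param seed Optional seed (set when given; otherwise the caller's RNG
#'   stream is used).
#' @return `data.frame` with columns `i` and `e`.
#' @export
simulate_counts <- function(psi, depth, rho = 0, seed = NULL) {
  stopifnot(all(psi >= 0 & psi <= 1), depth >= 0, rho >= 0, rho < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(length(psi), depth)
  if (rho == 0) {
    i <- stats::rbinom(length(psi), n, psi)
  } else {
    shape_sum <- (1 - rho) / rho
    pmix <- ifelse(psi %in% c(0, 1), psi,
                   stats::rbeta(length(psi), psi * shape_sum,
                                (1 - psi) * shape_sum))
    i <- stats::rbinom(length(psi), n, pmix)
  }
  data.frame(i = i, e = n - i)
}

#' Simulate a full developmental splicing dataset
#'
#' One cassette segment per gene; each gene draws a trajectory shape from
#' the configured mixture and an amplitude from `amplitude_range`, shared
#' across species and organs. Counts are beta-binomial around the true
#' trajectory at each sample's log age.
#'
#' @param config A [sim_config()].
#' @return List: `segments` (segment table), `meta` (sample metadata),
#'   `counts` (long counts), `truth` (per-gene true pattern/amplitude).
#' @export
simulate_devas_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  patterns <- sample(names(config$pattern_mix), n, replace = TRUE,
                     prob = config$pattern_mix)
  amps <- stats::runif(n, config$amplitude_range[1L],
                       config$amplitude_range[2L])
  amps[patterns == "flat"] <- 0
  lens <- sample(30:300, n, replace = TRUE)
  segments <- data.frame(
    segment_id = sprintf("seg%04d", seq_len(n)),
    gene_id = sprintf("g%04d", seq_len(n)),
    chrom = "chr1",
    start = cumsum(c(0, lens[-n] + 1000)),
    length = lens, as_class = "CE", stringsAsFactors = FALSE)
  segments$end <- segments$start + segments$length

  meta <- do.call(rbind, lapply(names(config$species), function(sp) {
    st <- stage_grid(config$species[[sp]])
    do.call(rbind, lapply(config$organs, function(org) {
      data.frame(sample_id = paste(sp, org, rep(st$stage,
                   each = config$n_replicates),
                   seq_len(config$n_replicates), sep = "."),
                 species = sp, organ = org,
                 stage = rep(st$stage, each = config$n_replicates),
                 days_post_conception = rep(st$days_post_conception,
                   each = config$n_replicates))
    }))
  }))
  rownames(meta) <- NULL
  meta$a <- log(meta$days_post_conception)

  counts <- do.call(rbind, lapply(seq_len(n), function(g) {
    true_psi <- numeric(nrow(meta))
    for (sp in names(config$species)) {
      idx <- which(meta$species == sp)
      ord <- order(meta$a[idx])
      true_psi[idx[ord]] <- simulate_trajectory(patterns[g], amps[g],
                                                meta$a[idx][ord])
    }
    cnt <- simulate_counts(true_psi, config$depth, config$rho)
    data.frame(segment_id = segments$segment_id[g],
               sample_id = meta$sample_id, i = cnt$i, e = cnt$e,
               true_psi = true_psi, stringsAsFactors = FALSE)
  }))
  rownames(counts) <- NULL

  truth <- data.frame(segment_id = segments$segment_id, pattern = patterns,
                      amplitude = amps, stringsAsFactors = FALSE)
  list(segments = segments, meta = meta,
       counts = counts[, c("segment_id", "sample_id", "i", "e")],
       truth = truth)
}

.random_seq <- function(n_char) {
  paste(sample(c("A", "C", "G", "T"), n_char, replace = TRUE), collapse = "")
}

#' Random flank sequences
#'
#' @param n Number of sequences.
#' @param len Sequence length (default 200 nt).
#' @param seed Optional seed.
#' @return Character vector.
#' @export
random_flanks <- function(n, len = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(k) .random_seq(len), "")
}

#' Plant a hexamer into a fraction of flank sequences
#'
#' Inserts (overwrites in place at a random position) the hexamer into a
#' random subset of the flanks.
#'
#' @param flanks Character vector of flank sequences.
#' @param hexamer Hexamer to plant.
#' @param fraction Fraction of flanks to receive the hexamer.
#' @param seed Optional seed.
#' @return List: `flanks` (modified sequences), `planted` (logical).
#' @export
plant_flank_motifs <- function(flanks, hexamer, fraction, seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(flanks)
  planted <- rep(FALSE, n)
  if (n > 0 && fraction > 0) {
    pick <- sample(n, round(n * fraction))
    for (k in pick) {
      pos <- sample(nchar(flanks[k]) - nchar(hexamer) + 1L, 1L)
      substr(flanks[k], pos, pos + nchar(hexamer) - 1L) <- hexamer
      planted[k] <- TRUE
    }
  }
  list(flanks = flanks, planted = planted)
}

# regenerate `len` nt until sharing no exact `word`-mer with any of `refs`
.seq_avoiding <- function(len, refs, word = 8, max_tries = 100) {
  words_of <- function(x) {
    if (nchar(x) < word) return(character(0))
    substring(x, seq_len(nchar(x) - word + 1L),
              seq_len(nchar(x) - word + 1L) + word - 1L)
  }
  ref_words <- unique(unlist(lapply(refs, words_of)))
  for (k in seq_len(max_tries)) {
    cand <- .random_seq(len)
    if (!any(words_of(cand) %in% ref_words)) return(cand)
  }
  stop("could not draw a sequence avoiding shared words", call. = FALSE)
}

#' Generate planted exon gain/loss and alternification scenarios
#'
#' For each event, emits a border-exon pair across all species with an
#' interspaced candidate exon in the species implied by the event (a gain
#' below an edge puts the exon in that clade; a loss puts it everywhere
#' else). Presence-species exon sequences share a common core with a few
#' point mutations; absence-species border and inter-border sequences are
#' drawn to share no 8-mer with the candidate, so the birth filters are
#' noiseless. Alternification events get per-species organ-stage PSI
#' tables with >= 4 pairs below 0.9 in cassette species.
#'
#' @param events List of `list(type, clade)` with `type` in
#'   `"gain"`/`"loss"`/`"alternification_gain"`/`"alternification_loss"`
#'   and `clade` a character vector of tip labels.
#' @param tree Species tree (default [default_species_tree()]).
#' @param exon_len Candidate exon length in nt.
#' @param n_mut Point mutations between presence-species copies.
#' @param seed Mandatory seed.
#' @return List of scenarios; structural events carry `borders` (input to
#'   [find_interspaced_candidates()]) and `truth`; alternification events
#'   carry `psi_tables` and `truth`.
#' @export
generate_evolution_scenario <- function(events, tree = default_species_tree(),
                                        exon_len = 60, n_mut = 2, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  species <- tree$tip.label
  lapply(seq_along(events), function(k) {
    ev <- events[[k]]
    stopifnot(all(ev$clade %in% species))
    pid <- sprintf("pair%03d", k)
    if (ev$type %in% c("gain", "loss")) {
      present <- if (ev$type == "gain") species %in% ev$clade
                 else !(species %in% ev$clade)
      names(present) <- species
      core <- .random_seq(exon_len)
      rows <- do.call(rbind, lapply(species, function(sp) {
        if (present[[sp]]) {
          seq_sp <- strsplit(core, "")[[1L]]
          mut <- sample(exon_len, n_mut)
          seq_sp[mut] <- sample(c("A", "C", "G", "T"), n_mut, replace = TRUE)
          exon_seq <- paste0(.random_seq(4), paste(seq_sp, collapse = ""),
                             .random_seq(4))
          data.frame(pair_id = pid, species = sp, n_between = 1L,
                     exon_id = paste(pid, sp, sep = "."),
                     exon_seq = exon_seq, exon_len = exon_len,
                     up_seq = NA_character_, down_seq = NA_character_,
                     between_seq = NA_character_,
                     stringsAsFactors = FALSE)
        } else {
          data.frame(pair_id = pid, species = sp, n_between = 0L,
                     exon_id = NA_character_, exon_seq = NA_character_,
                     exon_len = NA_integer_,
                     up_seq = .seq_avoiding(120, core),
                     down_seq = .seq_avoiding(120, core),
                     between_seq = .seq_avoiding(150, core),
                     stringsAsFactors = FALSE)
        }
      }))
      list(pair_id = pid, type = ev$type, borders = rows,
           truth = list(event = ev$type, clade = sort(ev$clade),
                        presence = present))
    } else {
      cassette <- if (ev$type == "alternification_gain")
        species %in% ev$clade else !(species %in% ev$clade)
      names(cassette) <- species
      psi_tables <- lapply(stats::setNames(species, species), function(sp) {
        if (cassette[[sp]])
          c(stats::runif(6, 0.3, 0.8), stats::runif(8, 0.95, 1))
        else stats::runif(14, 0.95, 1)
      })
      list(pair_id = pid, type = ev$type, psi_tables = psi_tables,
           truth = list(event = ev$type, clade = sort(ev$clade),
                        cassette = cassette))
    }
  })
}
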