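# Evolution of cassette exons: gain/loss of exons between orthologous
# border exons, single-event parsimony dating on the species tree, and
# "alternification" (constitutive -> cassette transitions).

#' Default seven-species tree
#'
#' Rooted topology with chicken as outgroup:
#' `((((human,macaque),((mouse,rat),rabbit)),opossum),chicken)`.
#'
#' @return An `ape::phylo` tree.
#' @export
default_species_tree <- function() {
  ape::read.tree(text =
    "((((human,macaque),((mouse,rat),rabbit)),opossum),chicken);")
}

# leaf set below each edge's child node, as a list indexed by edge row
.edge_clades <- function(tree) {
  n_tip <- length(tree$tip.label)
  tips_below <- function(node) {
    if (node <= n_tip) return(node)
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    unlist(lapply(kids, tips_below), use.names = FALSE)
  }
  lapply(tree$edge[, 2L], function(child) tree$tip.label[tips_below(child)])
}

# human-readable age-class label for a clade of the default tree
.age_class_label <- function(clade) {
  clade <- sort(clade)
  known <- list(
    primate = c("human", "macaque"),
    rodent = c("mouse", "rat"),
    glires = c("mouse", "rabbit", "rat"),
    eutherian = c("human", "macaque", "mouse", "rabbit", "rat"),
    mammalian = c("human", "macaque", "mouse", "opossum", "rabbit", "rat"))
  if (length(clade) == 1L) return(paste0(clade, "-specific"))
  for (lab in names(known))
    if (identical(clade, known[[lab]])) return(lab)
  paste(clade, collapse = "+")
}

#' Date a presence/absence pattern by single-event parsimony
#'
#' Enumerates every scenario in which exactly one event (a gain on a
#' branch with ancestral absence, or a loss on a branch with ancestral
#' presence) explains the presence pattern. A gain on edge `e` predicts
#' presence exactly in the clade below `e`; a loss predicts absence
#' exactly there. If exactly one scenario matches, it is returned; if a
#' gain and a loss scenario both match (the root-split ambiguity) or none
#' does, the pattern is discarded.
#'
#' @param presence Named logical vector over the tree's tip labels.
#' @param tree Rooted `phylo` tree (default [default_species_tree()]).
#' @return List `event` (`"gain"` or `"loss"`), `clade` (tips below the
#'   event branch), `age_class`; or `NULL` when the pattern is constant,
#'   ambiguous, or not explainable by a single event.
#' @export
parsimony_age <- function(presence, tree = default_species_tree()) {
  stopifnot(setequal(names(presence), tree$tip.label), !anyNA(presence))
  presence <- presence[tree$tip.label]
  if (all(presence) || all(!presence)) return(NULL)
  clades <- .edge_clades(tree)
  present_set <- sort(names(presence)[presence])
  absent_set <- sort(names(presence)[!presence])
  gain_hit <- which(vapply(clades, function(cl)
    identical(sort(cl), present_set), TRUE))
  loss_hit <- which(vapply(clades, function(cl)
    identical(sort(cl), absent_set), TRUE))
  n_hits <- length(gain_hit) + length(loss_hit)
  if (n_hits != 1L) return(NULL)  # none, or root-split ambiguous
  if (length(gain_hit) == 1L) {
    clade <- clades[[gain_hit]]
    list(event = "gain", clade = clade, age_class = .age_class_label(clade))
  } else {
    clade <- clades[[loss_hit]]
    list(event = "loss", clade = clade, age_class = .age_class_label(clade))
  }
}

#' Seeded local similarity between two sequences
#'
#' Seed-and-extend check standing in for a permissive local aligner:
#' every exact shared `word_size`-mer seed is extended in both directions
#' without gaps (match +1, mismatch `mismatch`), dropping the extension
#' when the running score falls `xdrop` below its maximum. Returns `TRUE`
#' when any extended segment reaches `min_score`. With the defaults any
#' exact shared block of 12+ nt (in particular 16 nt) is detected.
#'
#' @param query,target Sequences over ACGTN.
#' @param word_size Seed length (default 8).
#' @param min_score Acceptance threshold on the extended segment score.
#' @param mismatch Mismatch penalty (negative).
#' @param xdrop Extension drop-off.
#' @return Logical scalar.
#' @export
seq_similar <- function(query, target, word_size = 8, min_score = 12,
                        mismatch = -2, xdrop = 6) {
  if (is.na(query) || is.na(target) || nchar(target) == 0L ||
      nchar(query) < word_size)
    return(FALSE)
  q <- strsplit(toupper(query), "")[[1L]]
  t <- strsplit(toupper(target), "")[[1L]]
  nq <- length(q); nt <- length(t)
  if (nt < word_size) return(FALSE)
  words_at <- function(x, n) {
    substring(paste0(x, collapse = ""), seq_len(n - word_size + 1L),
              seq_len(n - word_size + 1L) + word_size - 1L)
  }
  tw <- words_at(t, nt)
  qw <- words_at(q, nq)
  hits <- which(qw %in% tw[!grepl("N", tw, fixed = TRUE)] &
                !grepl("N", qw, fixed = TRUE))
  extend <- function(qi, ti) {
    score <- word_size
    # right extension
    best <- score; cur <- score
    qk <- qi + word_size; tk <- ti + word_size
    while (qk <= nq && tk <= nt) {
      cur <- cur + if (q[qk] == t[tk] && q[qk] != "N") 1 else mismatch
      if (cur > best) best <- cur
      if (best - cur > xdrop) break
      qk <- qk + 1L; tk <- tk + 1L
    }
    score <- best
    # left extension
    best <- score; cur <- score
    qk <- qi - 1L; tk <- ti - 1L
    while (qk >= 1L && tk >= 1L) {
      cur <- cur + if (q[qk] == t[tk] && q[qk] != "N") 1 else mismatch
      if (cur > best) best <- cur
      if (best - cur > xdrop) break
      qk <- qk - 1L; tk <- tk - 1L
    }
    best
  }
  for (qi in hits) {
    for (ti in which(tw == qw[qi])) {
      if (extend(qi, ti) >= min_score) return(TRUE)
    }
  }
  FALSE
}

#' Find candidate gained/lost exons between orthologous border exons
#'
#' For each pair of 1:1 orthologous border exons, lists the species
#' carrying exactly one additional exon between the borders. Pairs where
#' any species has more than one interspaced exon are excluded (flagged
#' `multi_exon`); pairs with no interspaced exon anywhere yield no
#' candidate.
#'
#' @param borders `data.frame`, one row per (pair, species):
#'   `pair_id`, `species`, `n_between` (number of exons between the
#'   borders), plus optional columns `exon_id`, `exon_seq`, `exon_len`,
#'   `up_seq`, `down_seq`, `between_seq` describing the interspaced exon
#'   and the target region.
#' @return List of candidates; each has `pair_id`, `presence` (named
#'   logical over species), and the per-species rows. Pairs flagged
#'   multi-exon are dropped with a message.
#' @export
find_interspaced_candidates <- function(borders) {
  stopifnot(all(c("pair_id", "species", "n_between") %in% names(borders)))
  out <- lapply(split(borders, borders$pair_id), function(b) {
    if (any(b$n_between > 1L)) {
      message("pair ", b$pair_id[1L], ": multi-exon interspacing, excluded")
      return(NULL)
    }
    if (all(b$n_between == 0L)) return(NULL)
    presence <- stats::setNames(b$n_between == 1L, b$species)
    list(pair_id = b$pair_id[1L], presence = presence, rows = b)
  })
  out[!vapply(out, is.null, TRUE)]
}

#' Apply the three exon-birth filters to a candidate
#'
#' 1. the candidate exon (plus 4 flanking nt) must not align to the border
#'    exons or the inter-border sequence of any species lacking the exon;
#' 2. candidate exons observed in multiple species must all align to each
#'    other; 3. only exons shorter than `max_len` nt are kept.
#'
#' @param candidate A candidate from [find_interspaced_candidates()]; its
#'   `rows` must carry `exon_seq` (with flanks), `exon_len`, and for
#'   absence species `up_seq`, `down_seq`, `between_seq`.
#' @param max_len Strict upper bound on exon length (default 500).
#' @param ... Passed to [seq_similar()].
#' @return Logical: candidate retained?
#' @export
apply_birth_filters <- function(candidate, max_len = 500, ...) {
  rows <- candidate$rows
  pres <- rows[candidate$presence[rows$species], , drop = FALSE]
  abs_ <- rows[!candidate$presence[rows$species], , drop = FALSE]
  # filter 3: length
  if (any(pres$exon_len >= max_len)) return(FALSE)
  # filter 1: no similarity to absence-species target regions
  for (k in seq_len(nrow(pres))) {
    for (j in seq_len(nrow(abs_))) {
      targets <- c(abs_$up_seq[j], abs_$down_seq[j], abs_$between_seq[j])
      targets <- targets[!is.na(targets) & nzchar(targets)]
      if (any(vapply(targets, function(tg)
        seq_similar(pres$exon_seq[k], tg, ...), TRUE)))
        return(FALSE)
    }
  }
  # filter 2: presence-species exons all similar to each other
  if (nrow(pres) > 1L) {
    for (k in seq_len(nrow(pres) - 1L)) for (j in seq((k + 1L), nrow(pres))) {
      if (!seq_similar(pres$exon_seq[k], pres$exon_seq[j], ...))
        return(FALSE)
    }
  }
  TRUE
}

#' Detect alternification from per-species organ-stage PSI tables
#'
#' An orthologous exon is a cassette exon in a species when at least
#' `min_pairs` organ-stage mean PSI values fall strictly below
#' `psi_cutoff`; otherwise it is constitutive. A species with no defined
#' PSI is unknown, and exons with unknown species are discarded. The
#' cassette/constitutive vector is dated by [parsimony_age()] (single
#' event only); a gain of cassette status is an alternification gain.
#'
#' @param psi_tables Named list (per species) of numeric vectors/matrices
#'   of organ-stage mean PSI (`NA` = undefined).
#' @param tree Species tree.
#' @param min_pairs Organ-stage pairs required below the cutoff.
#' @param psi_cutoff Strict PSI cutoff (default 0.9).
#' @return List with `status` (named: `"cassette"`/`"constitutive"`) and
#'   `event` (from [parsimony_age()], types prefixed `alternification_`);
#'   `NULL` when any species is unknown.
#' @export
detect_alternification <- function(psi_tables, tree = default_species_tree(),
                                   min_pairs = 4, psi_cutoff = 0.9) {
  status <- vapply(psi_tables, function(x) {
    x <- as.numeric(x)
    if (all(is.na(x))) return(NA)
    sum(x < psi_cutoff, na.rm = TRUE) >= min_pairs
  }, TRUE)
  if (anyNA(status)) return(NULL)
  ev <- parsimony_age(status, tree)
  if (!is.null(ev)) ev$event <- paste0("alternification_", ev$event)
  list(status = ifelse(status, "cassette", "constitutive"), event = ev)
}

#' Does an interval overlap a feature set?
#'
#' @param exon Numeric `c(start, end)` interval.
#' @param features Two-column matrix/data.frame of feature `start`, `end`
#'   on the same chromosome.
#' @param min_overlap Minimum overlap with any single feature in nt
#'   (10 for transposable elements, 1 for coding sequence).
#' @return Logical scalar.
#' @export
interval_overlap_flag <- function(exon, features, min_overlap = 1) {
  features <- as.matrix(features)
  if (nrow(features) == 0L) return(FALSE)
  ov <- pmax(0, pmin(exon[2L], features[, 2L]) - pmax(exon[1L], features[, 1L]))
  any(ov >= min_overlap)
}
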