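# Pipeline orchestration: synthetic generation -> PSI -> devAS -> patterns
# -> orthology -> motifs -> evolution -> summaries, with a manifest and
# the resolved configuration written next to the outputs.

#' Pipeline configuration
#'
#' All thresholds default to the analysis' published values and are
#' surfaced as named keys; no stage uses a hidden constant.
#'
#' @param seed Master seed; every stage derives its stream from it.
#' @param sim A [sim_config()] for the synthetic dataset (defaults to a
#'   small configuration using `seed`).
#' @param min_reads Minimum `i + e` for defined PSI (10).
#' @param min_cov_frac,min_mid_psi Eligibility thresholds (0.6, 4).
#' @param alpha,min_dpsi devAS call thresholds (0.05, 0.2).
#' @param ratio_lo,ratio_hi Pattern monotonicity thresholds (0.3, 0.7).
#' @param iou_keep,iou_edge Orthology thresholds (0.6, 0.6).
#' @param alt_min_pairs,alt_psi_cutoff Alternification rule (4, 0.9).
#' @param flank_len,score_window Flank lengths in nt (200, 50).
#' @param te_min_overlap TE overlap in nt (10).
#' @param stages Named logical vector toggling stages.
#' @param motif_hexamer,motif_target_frac,motif_bg_frac Planted-motif
#'   specification for the synthetic motif stage.
#' @param n_evo_events Number of planted evolution scenarios.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            sim = NULL,
                            min_reads = 10,
                            min_cov_frac = 0.6, min_mid_psi = 4,
                            alpha = 0.05, min_dpsi = 0.2,
                            ratio_lo = 0.3, ratio_hi = 0.7,
                            iou_keep = 0.6, iou_edge = 0.6,
                            alt_min_pairs = 4, alt_psi_cutoff = 0.9,
                            flank_len = 200, score_window = 50,
                            te_min_overlap = 10,
                            stages = c(simulate = TRUE, psi = TRUE,
                                       devas = TRUE, patterns = TRUE,
                                       ortho = TRUE, motifs = TRUE,
                                       evolve = TRUE, summarize = TRUE),
                            motif_hexamer = "ACTAAC",
                            motif_target_frac = 0.4,
                            motif_bg_frac = 0.1,
                            n_evo_events = 6) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.null(sim)) sim <- sim_config(seed = seed + 1L)
  structure(as.list(environment()), class = "pipeline_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Run the full pipeline on a synthetic dataset
#'
#' Executes the enabled stages in dependency order and writes one TSV per
#' stage plus `config.json` and `manifest.json` into `outdir`. Outputs are
#' a pure function of the configuration (including its seed).
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  res <- list()
  cfg_json <- config
  cfg_json$sim <- unclass(cfg_json$sim)
  jsonlite::write_json(unclass(cfg_json), file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)

  # --- simulate ------------------------------------------------------
  if (!config$stages[["simulate"]])
    stop("pipeline requires the simulate stage for synthetic input",
         call. = FALSE)
  dat <- simulate_devas_dataset(config$sim)
  res$data <- dat
  .write_tsv(dat$segments, file.path(outdir, "segments.tsv"))
  .write_tsv(dat$meta, file.path(outdir, "metadata.tsv"))
  .write_tsv(dat$counts, file.path(outdir, "counts.tsv"))
  .write_tsv(dat$truth, file.path(outdir, "truth.tsv"))
  manifest$stages$simulate <- list(n_segments = nrow(dat$segments),
                                   n_samples = nrow(dat$meta))

  # --- psi -----------------------------------------------------------
  if (config$stages[["psi"]]) {
    psi <- psi_matrix(dat$counts, dat$segments, lr = config$sim$lr,
                      min_reads = config$min_reads)
    res$psi <- psi
    write_psi_tsv(psi, file.path(outdir, "psi_matrix.tsv"))
    manifest$stages$psi <- list(n_defined = sum(!is.na(psi)),
                                n_cells = length(psi))
  }

  # --- devas + patterns ---------------------------------------------
  if (config$stages[["devas"]]) {
    combos <- unique(dat$meta[, c("species", "organ")])
    devas_all <- list(); traj_all <- list()
    for (k in seq_len(nrow(combos))) {
      sp <- combos$species[k]; org <- combos$organ[k]
      sm <- dat$meta[dat$meta$species == sp & dat$meta$organ == org, ]
      sc <- dat$counts[dat$counts$sample_id %in% sm$sample_id, ]
      dres <- devas_test(sc, sm, dat$segments, lr = config$sim$lr,
                         alpha = config$alpha)
      dres$species <- sp; dres$organ <- org
      devas_all[[k]] <- dres
      if (config$stages[["patterns"]]) {
        traj_all[[k]] <- .fit_patterns_one(sc, sm, dat$segments, dres, config)
      }
    }
    devas <- do.call(rbind, devas_all)
    res$devas <- devas
    .write_tsv(devas, file.path(outdir, "devas.tsv"))
    manifest$stages$devas <- list(n_tests = nrow(devas),
                                  n_eligible = sum(devas$eligible),
                                  n_significant = sum(devas$significant,
                                                      na.rm = TRUE))
    if (config$stages[["patterns"]]) {
      traj <- do.call(rbind, traj_all)
      res$trajectories <- traj
      .write_tsv(traj, file.path(outdir, "trajectories.tsv"))
      manifest$stages$patterns <- list(n_fits = nrow(traj),
                                       n_devas = sum(traj$devas,
                                                     na.rm = TRUE))
    }
  }

  # --- ortho ---------------------------------------------------------
  if (config$stages[["ortho"]]) {
    set.seed(config$seed + 101L)
    species <- names(config$sim$species)
    maps <- .simulate_ortho_mappings(min(config$sim$n_genes, 20L), species)
    groups <- build_ortho_groups(maps, species,
                                 keep_threshold = config$iou_keep,
                                 edge_threshold = config$iou_edge)
    res$ortho <- groups
    .write_tsv(groups, file.path(outdir, "ortho_groups.tsv"))
    manifest$stages$ortho <- list(n_groups = length(unique(groups$group_id)))
  }

  # --- motifs --------------------------------------------------------
  if (config$stages[["motifs"]]) {
    set.seed(config$seed + 202L)
    sp3 <- names(config$sim$species)[1:3]
    targets <- lapply(stats::setNames(sp3, sp3), function(sp)
      plant_flank_motifs(random_flanks(60, config$flank_len),
                         config$motif_hexamer,
                         config$motif_target_frac)$flanks)
    backgrounds <- lapply(stats::setNames(sp3, sp3), function(sp)
      plant_flank_motifs(random_flanks(120, config$flank_len),
                         config$motif_hexamer,
                         config$motif_bg_frac)$flanks)
    enr <- combine_species_enrichment(targets, backgrounds)
    res$motifs <- enr
    top <- enr[order(enr$p_combined), ][seq_len(50L), ]
    .write_tsv(top, file.path(outdir, "enrichment_top.tsv"))
    manifest$stages$motifs <- list(
      n_significant = sum(enr$padj < 0.05),
      planted_hexamer = config$motif_hexamer,
      planted_padj = enr$padj[enr$hexamer == config$motif_hexamer])
  }

  # --- evolve --------------------------------------------------------
  if (config$stages[["evolve"]]) {
    tree <- default_species_tree()
    edges <- list(c("mouse"), c("human", "macaque"),
                  c("mouse", "rat"), c("mouse", "rat", "rabbit"),
                  c("human", "macaque", "mouse", "rat", "rabbit"),
                  c("opossum"))
    types <- rep(c("gain", "alternification_gain"),
                 length.out = config$n_evo_events)
    events <- lapply(seq_len(config$n_evo_events), function(k)
      list(type = types[k], clade = edges[[(k - 1L) %% length(edges) + 1L]]))
    scen <- generate_evolution_scenario(events, tree,
                                        seed = config$seed + 303L)
    evo <- .run_evolution(scen, tree, config)
    res$evolution <- evo
    .write_tsv(evo, file.path(outdir, "evolution.tsv"))
    manifest$stages$evolve <- list(n_events = nrow(evo),
                                   n_recovered = sum(evo$recovered))
  }

  # --- summarize -----------------------------------------------------
  if (config$stages[["summarize"]] && config$stages[["psi"]]) {
    d <- psi_distance(res$psi)
    coords <- mds_embed(d, k = 2)
    mds <- data.frame(sample_id = rownames(coords), dim1 = coords[, 1L],
                      dim2 = coords[, 2L])
    res$mds <- mds
    .write_tsv(mds, file.path(outdir, "mds.tsv"))
    manifest$stages$summarize <- list(n_samples = nrow(mds))
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

# fit trajectories and classify patterns for one species-organ analysis
.fit_patterns_one <- function(counts, meta, segments, devas, config) {
  counts$a <- log_age(meta$days_post_conception[
    match(counts$sample_id, meta$sample_id)])
  counts$psi <- compute_psi(
    counts$i, counts$e,
    segments$length[match(counts$segment_id, segments$segment_id)],
    config$sim$lr, min_reads = config$min_reads)$value
  rows <- lapply(split(counts, counts$segment_id), function(sc) {
    base <- data.frame(segment_id = sc$segment_id[1L],
                       species = devas$species[1L], organ = devas$organ[1L],
                       dpsi = NA_real_, up = NA_real_, down = NA_real_,
                       up_timing = NA_real_, down_timing = NA_real_,
                       ratio = NA_real_, pattern = NA_character_,
                       devas = NA)
    if (sum(!is.na(sc$psi)) < 5L) return(base)
    fit <- fit_psi_spline(sc$psi, sc$a)
    cl <- classify_pattern(fit, ratio_lo = config$ratio_lo,
                           ratio_hi = config$ratio_hi)
    padj <- devas$padj_min[devas$segment_id == sc$segment_id[1L]]
    base$dpsi <- fit$dpsi
    base$up <- cl$up; base$down <- cl$down
    base$up_timing <- cl$up_timing; base$down_timing <- cl$down_timing
    base$ratio <- cl$ratio; base$pattern <- cl$pattern
    base$devas <- if (length(padj) == 1L)
      call_devas(padj, fit$dpsi, config$alpha, config$min_dpsi) else NA
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# simple 1:1 mappings: per group one exon per species at shared coordinates
.simulate_ortho_mappings <- function(n_groups, species) {
  do.call(rbind, lapply(seq_len(n_groups), function(g) {
    base <- g * 10000
    len <- sample(80:200, 1L)
    do.call(rbind, lapply(species, function(sp) {
      jitter <- sample(0:5, 1L)
      data.frame(exon_id = paste0("ex", g, ".", sp), species = sp,
                 target_species = species,
                 start = base + jitter, end = base + jitter + len,
                 stringsAsFactors = FALSE)
    }))
  }))
}

# run candidate detection, filters and parsimony over planted scenarios
.run_evolution <- function(scenarios, tree, config) {
  rows <- lapply(scenarios, function(sc) {
    if (sc$type %in% c("gain", "loss")) {
      cands <- find_interspaced_candidates(sc$borders)
      if (length(cands) != 1L)
        return(data.frame(pair_id = sc$pair_id, type = sc$type,
                          event = NA_character_, age_class = NA_character_,
                          recovered = FALSE))
      cand <- cands[[1L]]
      keep <- apply_birth_filters(cand)
      ev <- if (keep) parsimony_age(cand$presence, tree) else NULL
      data.frame(pair_id = sc$pair_id, type = sc$type,
                 event = if (is.null(ev)) NA_character_ else ev$event,
                 age_class = if (is.null(ev)) NA_character_ else ev$age_class,
                 recovered = !is.null(ev) &&
                   identical(sort(ev$clade), sc$truth$clade))
    } else {
      alt <- detect_alternification(sc$psi_tables, tree,
                                    min_pairs = config$alt_min_pairs,
                                    psi_cutoff = config$alt_psi_cutoff)
      ev <- if (is.null(alt)) NULL else alt$event
      data.frame(pair_id = sc$pair_id, type = sc$type,
                 event = if (is.null(ev)) NA_character_ else ev$event,
                 age_class = if (is.null(ev)) NA_character_ else ev$age_class,
                 recovered = !is.null(ev) &&
                   identical(sort(ev$clade), sc$truth$clade))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
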