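# Cross-species exon orthology from coordinate mappings.
#
# Exons lifted across species are matched by intersect:union (IoU) of
# their mapped intervals. Exons with a poor best match to the annotated
# exons of any species are discarded; surviving exons become nodes of a
# graph whose edges require IoU > threshold in every species, and
# connected components with exactly one exon per species are reported as
# 1:1 orthology groups.

#' Intersect-over-union of two intervals
#'
#' @param a,b Numeric length-2 vectors `c(start, end)`, 0-based half-open,
#'   assumed on the same chromosome and strand.
#' @return Ratio in `[0, 1]`; 0 when disjoint.
#' @export
iou <- function(a, b) {
  if (a[2L] <= a[1L] || b[2L] <= b[1L])
    stop("empty interval", call. = FALSE)
  inter <- max(0, min(a[2L], b[2L]) - max(a[1L], b[1L]))
  inter / ((a[2L] - a[1L]) + (b[2L] - b[1L]) - inter)
}

# vectorised IoU on start/end columns
.iou_vec <- function(s1, e1, s2, e2) {
  inter <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  inter / ((e1 - s1) + (e2 - s2) - inter)
}

#' Build 1:1 orthologous exon groups
#'
#' `mappings` gives, for every exon, its (lifted) interval in every target
#' species, including its native species. Exons are kept when, in every
#' species, their mapped interval has IoU at least `keep_threshold` with
#' the best-matching native exon of that species. Edges connect kept exons
#' from different species whose mapped intervals have IoU strictly greater
#' than `edge_threshold` in all species. Connected components with exactly
#' one exon from each species form orthology groups; every other component
#' is discarded.
#'
#' @param mappings `data.frame`: `exon_id`, `species` (source),
#'   `target_species`, `start`, `end`. Absent mappings are absent rows.
#' @param species Character vector of species to cover.
#' @param keep_threshold Per-species node filter (keep when IoU >= this).
#' @param edge_threshold Edge rule (edge when IoU > this in all species).
#' @return `data.frame` with `group_id`, `species`, `exon_id`.
#' @export
build_ortho_groups <- function(mappings, species, keep_threshold = 0.6,
                               edge_threshold = 0.6) {
  stopifnot(all(c("exon_id", "species", "target_species", "start", "end")
                %in% names(mappings)))
  if (any(mappings$end <= mappings$start))
    stop("mapping with non-positive length", call. = FALSE)
  exons <- unique(mappings[, c("exon_id", "species")])
  exons <- exons[order(exons$exon_id), , drop = FALSE]

  # mapped interval lookup: exon x target species -> interval
  key <- paste(mappings$exon_id, mappings$target_species, sep = "\r")
  get_map <- function(ex, sp) {
    idx <- match(paste(ex, sp, sep = "\r"), key)
    if (is.na(idx)) NULL else c(mappings$start[idx], mappings$end[idx])
  }

  # node filter: best IoU against native exons of each species
  natives <- mappings[mappings$species == mappings$target_species, ,
                      drop = FALSE]
  keep <- vapply(seq_len(nrow(exons)), function(k) {
    ex <- exons$exon_id[k]
    all(vapply(species, function(sp) {
      iv <- get_map(ex, sp)
      if (is.null(iv)) return(FALSE)
      nat <- natives[natives$target_species == sp, , drop = FALSE]
      if (nrow(nat) == 0L) return(FALSE)
      max(.iou_vec(iv[1L], iv[2L], nat$start, nat$end)) >= keep_threshold
    }, TRUE))
  }, TRUE)
  exons <- exons[keep, , drop = FALSE]
  if (nrow(exons) == 0L)
    return(data.frame(group_id = character(0), species = character(0),
                      exon_id = character(0)))

  # edges: IoU > edge_threshold in every species
  n <- nrow(exons)
  edge_from <- integer(0); edge_to <- integer(0)
  if (n > 1L) {
    for (p in seq_len(n - 1L)) for (q in seq((p + 1L), n)) {
      if (exons$species[p] == exons$species[q]) next
      ok <- all(vapply(species, function(sp) {
        ia <- get_map(exons$exon_id[p], sp)
        ib <- get_map(exons$exon_id[q], sp)
        !is.null(ia) && !is.null(ib) &&
          .iou_vec(ia[1L], ia[2L], ib[1L], ib[2L]) > edge_threshold
      }, TRUE))
      if (ok) { edge_from <- c(edge_from, p); edge_to <- c(edge_to, q) }
    }
  }
  g <- igraph::make_graph(c(rbind(edge_from, edge_to)), n = n,
                          directed = FALSE)
  comp <- igraph::components(g)$membership

  out <- lapply(split(seq_len(n), comp), function(idx) {
    sp <- exons$species[idx]
    if (length(idx) == length(species) && setequal(sp, species) &&
        !anyDuplicated(sp)) {
      data.frame(species = sp, exon_id = exons$exon_id[idx])
    } else NULL
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L)
    return(data.frame(group_id = character(0), species = character(0),
                      exon_id = character(0)))
  res <- do.call(rbind, Map(function(df, gid) {
    data.frame(group_id = gid, df)
  }, out, sprintf("og%04d", seq_along(out))))
  rownames(res) <- NULL
  res
}
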