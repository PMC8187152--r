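# Inclusion/exclusion read counting and length-corrected PSI.

#' Count inclusion and exclusion reads for a segment
#'
#' Inclusion reads overlap the segment interval by at least 1 nt; exclusion
#' reads carry an exon-exon junction whose intron fully spans the segment.
#' Only uniquely mapping reads are counted; a read contributes at most once
#' to each category.
#'
#' @param alignments `data.frame` with one row per aligned block:
#'   `read_id`, `chrom`, `start`, `end` (0-based half-open), `unique`
#'   (logical). Blocks of one read must be sorted by `start`; the gaps
#'   between consecutive blocks are the read's junction introns.
#' @param segment List or one-row data.frame with `chrom`, `start`, `end`.
#' @return Named integer vector `c(i = ..., e = ...)`.
#' @export
count_segment_reads <- function(alignments, segment) {
  al <- alignments[alignments$chrom == segment$chrom & alignments$unique, ,
                   drop = FALSE]
  if (nrow(al) == 0L) return(c(i = 0L, e = 0L))
  sp <- split(al, al$read_id)
  i <- 0L; e <- 0L
  for (blocks in sp) {
    if (is.unsorted(blocks$start))
      stop("alignment blocks not sorted by start", call. = FALSE)
    if (any(blocks$start < segment$end & blocks$end > segment$start))
      i <- i + 1L
    if (nrow(blocks) > 1L) {
      gs <- blocks$end[-nrow(blocks)]
      ge <- blocks$start[-1L]
      if (any(gs <= segment$start & ge >= segment$end))
        e <- e + 1L
    }
  }
  c(i = i, e = e)
}

#' Length-corrected percent spliced-in
#'
#' PSI weighs inclusion and exclusion read counts by the number of distinct
#' alignment start positions supporting each:
#' \deqn{PSI = \frac{i/(l_s + l_r - 1)}{i/(l_s + l_r - 1) + e/(l_r - 1)}}
#' where \eqn{i}, \eqn{e} are inclusion and exclusion read counts and
#' \eqn{l_s}, \eqn{l_r} the segment and read lengths. PSI is undefined when
#' \eqn{i + e < 10}.
#'
#' @param i,e Inclusion and exclusion read counts (vectorised, >= 0).
#' @param ls Segment length in nt (>= 1).
#' @param lr Read length in nt (>= 2).
#' @param min_reads Minimum `i + e` for PSI to be defined (default 10).
#' @return `data.frame` with columns `value` (`NA` where undefined) and
#'   `defined`.
#' @examples
#' compute_psi(20, 10, ls = 100, lr = 100)
#' @export
compute_psi <- function(i, e, ls, lr, min_reads = 10) {
  if (any(i < 0) || any(e < 0))
    stop("negative read counts", call. = FALSE)
  stopifnot(all(ls >= 1), all(lr >= 2))
  defined <- (i + e) >= min_reads
  num <- i / (ls + lr - 1)
  value <- num / (num + e / (lr - 1))
  value[i == 0 & e > 0] <- 0  # guard 0/0 when num = 0
  value[!defined] <- NA_real_
  data.frame(value = value, defined = defined)
}

#' Build a segments x samples PSI matrix from a long counts table
#'
#' @param counts `data.frame` with `segment_id`, `sample_id`, `i`, `e`.
#' @param segments Segment table carrying `segment_id` and `length`.
#' @param lr Read length (scalar or named per-sample vector).
#' @param min_reads Minimum coverage for defined PSI.
#' @return Numeric matrix (segments x samples) with `NA` for undefined PSI.
#' @export
psi_matrix <- function(counts, segments, lr, min_reads = 10) {
  segs <- unique(counts$segment_id)
  samps <- unique(counts$sample_id)
  ls <- segments$length[match(counts$segment_id, segments$segment_id)]
  if (anyNA(ls)) stop("counts refer to unknown segments", call. = FALSE)
  lr_vec <- if (length(lr) == 1L) rep(lr, nrow(counts))
            else unname(lr[counts$sample_id])
  psi <- compute_psi(counts$i, counts$e, ls, lr_vec, min_reads)$value
  m <- matrix(NA_real_, length(segs), length(samps),
              dimnames = list(segs, samps))
  m[cbind(match(counts$segment_id, segs), match(counts$sample_id, samps))] <- psi
  m
}

#' Write a PSI matrix to TSV (empty cell = undefined)
#'
#' @param m PSI matrix from [psi_matrix()].
#' @param path Output path.
#' @export
write_psi_tsv <- function(m, path) {
  df <- data.frame(segment_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
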