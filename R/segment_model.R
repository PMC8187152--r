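# Gene segmentation and AS-class assignment.
#
# A "segment" is the sequence unit between two adjacent splice sites of a
# gene; segments are the atomic unit of splicing quantification throughout
# the package. Coordinates are 0-based half-open internally, so
# length = end - start; GTF input (1-based inclusive) is converted at the
# I/O boundary.

#' Construct a gene model
#'
#' A gene model holds one or more transcripts of a gene as ordered exon
#' intervals in 0-based half-open genomic coordinates.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param transcripts Named list; each element is a two-column matrix (or
#'   data.frame) of exon `start`, `end` (0-based half-open), sorted by
#'   position, non-overlapping, with every intron at least 1 nt long.
#' @return An object of class `gene_model`.
#' @examples
#' gm <- gene_model("g1", "chr1", "+",
#'                  list(t1 = cbind(c(0, 200, 400), c(100, 300, 500)),
#'                       t2 = cbind(c(0, 400), c(100, 500))))
#' @export
gene_model <- function(gene_id, chrom, strand, transcripts) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            strand %in% c("+", "-"),
            is.list(transcripts), length(transcripts) >= 1L)
  transcripts <- lapply(transcripts, function(tx) {
    tx <- as.matrix(tx)
    storage.mode(tx) <- "double"
    colnames(tx) <- c("start", "end")
    if (any(tx[, "end"] <= tx[, "start"]))
      stop("malformed transcript: empty or negative-length exon",
           call. = FALSE)
    if (nrow(tx) > 1L) {
      if (is.unsorted(tx[, "start"], strictly = TRUE))
        stop("malformed transcript: exons not sorted", call. = FALSE)
      if (any(tx[-nrow(tx), "end"] > tx[-1L, "start"]))
        stop("malformed transcript: overlapping exons", call. = FALSE)
      if (any(tx[-1L, "start"] - tx[-nrow(tx), "end"] < 1))
        stop("malformed transcript: intron shorter than 1 nt", call. = FALSE)
    }
    tx
  })
  if (is.null(names(transcripts)))
    names(transcripts) <- paste0(gene_id, ".t", seq_along(transcripts))
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 transcripts = transcripts),
            class = "gene_model")
}

#' Classify an alternative segment by its bounding splice-site kinds
#'
#' Splice-site kinds are given in transcription orientation. A segment that
#' starts at an acceptor and ends at a donor is a cassette exon (CE); donor
#' to acceptor is a retained intron (RI); acceptor/acceptor and donor/donor
#' bound alternative acceptor (AA) and alternative donor (AD) segments.
#'
#' @param start_kind,end_kind `"acceptor"` or `"donor"`, in transcription
#'   orientation.
#' @return One of `"CE"`, `"AA"`, `"AD"`, `"RI"` (vectorised).
#' @export
classify_as_class <- function(start_kind, end_kind) {
  stopifnot(all(start_kind %in% c("donor", "acceptor")),
            all(end_kind %in% c("donor", "acceptor")))
  out <- character(length(start_kind))
  out[start_kind == "acceptor" & end_kind == "donor"] <- "CE"
  out[start_kind == "acceptor" & end_kind == "acceptor"] <- "AA"
  out[start_kind == "donor" & end_kind == "donor"] <- "AD"
  out[start_kind == "donor" & end_kind == "acceptor"] <- "RI"
  out
}

#' Is a segment a microexon?
#'
#' Microexons are very short cassette exons of 3-27 nt (length < 28 nt).
#'
#' @param ls Segment length(s) in nucleotides (>= 1).
#' @return Logical vector.
#' @export
is_microexon <- function(ls) {
  stopifnot(all(ls >= 1))
  ls >= 3 & ls <= 27
}

#' Is a segment frame-preserving?
#'
#' @param ls Segment length(s) in nucleotides (>= 1).
#' @return `TRUE` where length is divisible by three.
#' @export
is_frame_preserving <- function(ls) {
  stopifnot(all(ls >= 1))
  ls %% 3 == 0
}

# Splice sites of one transcript in genomic coordinates, with kinds in
# transcription orientation. Boundaries are half-open edge positions: an
# intron between exon i and i+1 occupies [end_i, start_{i+1}).
.transcript_sites <- function(tx, strand) {
  n <- nrow(tx)
  if (n < 2L)
    return(data.frame(pos = numeric(0), kind = character(0)))
  left <- tx[-n, "end"]    # genomic left edge of each intron
  right <- tx[-1L, "start"] # genomic right edge of each intron
  if (strand == "+") {
    data.frame(pos = c(left, right),
               kind = rep(c("donor", "acceptor"), each = n - 1L))
  } else {
    data.frame(pos = c(left, right),
               kind = rep(c("acceptor", "donor"), each = n - 1L))
  }
}

#' Split a gene into segments between adjacent splice sites
#'
#' The gene span is cut at every distinct splice site of any transcript.
#' Each resulting segment is scored against every transcript: a transcript
#' "includes" the segment if the segment lies within one of its exons and
#' "excludes" it if one of its introns spans the segment. Segments with at
#' least one including and one excluding transcript are `alternative` and
#' get an AS class from their bounding splice-site kinds; all others
#' (including terminal segments before the first / after the last splice
#' site) are `constitutive` with class `NA`.
#'
#' @param gene A [gene_model()].
#' @return `data.frame` with columns `segment_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `start_kind`, `end_kind`, `status`,
#'   `as_class`, `length`, ordered by position.
#' @export
segment_gene <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  txs <- gene$transcripts
  sites <- do.call(rbind, lapply(txs, .transcript_sites, strand = gene$strand))
  gene_start <- min(vapply(txs, function(tx) min(tx[, "start"]), 0))
  gene_end <- max(vapply(txs, function(tx) max(tx[, "end"]), 0))
  # kind lookup per distinct position; conflicting kinds (possible with
  # overlapping transcripts) are recorded as NA and leave as_class NA
  kind_of <- function(pos) {
    k <- unique(sites$kind[sites$pos == pos])
    if (length(k) == 1L) k else NA_character_
  }
  bounds <- sort(unique(c(gene_start, gene_end, sites$pos)))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L]
  n <- length(starts)

  includes <- matrix(FALSE, n, length(txs))
  excludes <- matrix(FALSE, n, length(txs))
  for (j in seq_along(txs)) {
    tx <- txs[[j]]
    for (k in seq_len(n)) {
      includes[k, j] <- any(tx[, "start"] <= starts[k] & tx[, "end"] >= ends[k])
      if (nrow(tx) > 1L) {
        istart <- tx[-nrow(tx), "end"]
        iend <- tx[-1L, "start"]
        excludes[k, j] <- any(istart <= starts[k] & iend >= ends[k])
      }
    }
  }
  status <- ifelse(rowSums(includes) > 0 & rowSums(excludes) > 0,
                   "alternative", "constitutive")

  # start/end kinds in transcription orientation; gene ends have kind NA
  is_site <- function(pos) pos %in% sites$pos
  left_kind <- vapply(starts, function(p)
    if (is_site(p)) kind_of(p) else NA_character_, "")
  right_kind <- vapply(ends, function(p)
    if (is_site(p)) kind_of(p) else NA_character_, "")
  if (gene$strand == "+") {
    start_kind <- left_kind; end_kind <- right_kind
  } else {
    start_kind <- right_kind; end_kind <- left_kind
  }

  as_class <- rep(NA_character_, n)
  cls_ok <- status == "alternative" & !is.na(start_kind) & !is.na(end_kind)
  as_class[cls_ok] <- classify_as_class(start_kind[cls_ok], end_kind[cls_ok])
  # alternative terminal segments (kind NA on one side) are not analysed
  status[status == "alternative" & !cls_ok] <- "constitutive"

  ord <- if (gene$strand == "+") seq_len(n) else rev(seq_len(n))
  data.frame(
    segment_id = paste0(gene$gene_id, ".s", match(seq_len(n), ord)),
    gene_id = gene$gene_id,
    chrom = gene$chrom,
    start = starts,
    end = ends,
    strand = gene$strand,
    start_kind = start_kind,
    end_kind = end_kind,
    status = status,
    as_class = as_class,
    length = ends - starts,
    stringsAsFactors = FALSE
  )
}

#' Read gene models from a GTF file
#'
#' Uses exon features with `gene_id` and `transcript_id` attributes;
#' 1-based inclusive GTF coordinates are converted to 0-based half-open.
#'
#' @param path Path to a GTF file.
#' @return Named list of [gene_model()] objects.
#' @export
read_gene_models_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,  # to 0-based
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   gene_id = gr$gene_id,
                   transcript_id = gr$transcript_id,
                   stringsAsFactors = FALSE)
  lapply(split(df, df$gene_id), function(g) {
    txs <- lapply(split(g, g$transcript_id), function(tx) {
      tx <- tx[order(tx$start), ]
      cbind(start = tx$start, end = tx$end)
    })
    gene_model(g$gene_id[1L], g$chrom[1L], g$strand[1L], txs)
  })
}

#' Write a segments table to TSV
#'
#' @param segments Segment `data.frame` from [segment_gene()].
#' @param path Output file path.
#' @export
write_segments_tsv <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
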