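# Hexamer enrichment in intronic flanks, Irwin-Hall p-value combination
# and PWM-based motif annotation.
#
# Candidate intronic splicing regulatory elements are found by testing all
# 4,096 hexamers for presence enrichment in the 200-nt intronic flanks of
# developmentally dynamic exons against the remaining alternative exons,
# per species, with one-sided Fisher's exact tests. Per-species p-values
# are combined with the Irwin-Hall distribution (sum of uniforms) and
# BH-adjusted across hexamers.

#' All 4,096 DNA hexamers
#' @return Character vector, lexicographic order over A,C,G,T.
#' @export
all_hexamers <- function() {
  nts <- c("A", "C", "G", "T")
  grid <- expand.grid(rep(list(nts), 6L), stringsAsFactors = FALSE)[, 6:1]
  apply(grid, 1L, paste0, collapse = "")
}

#' One-sided Fisher test for hexamer presence enrichment
#'
#' The 2x2 table counts flank sequences containing the hexamer at least
#' once (presence/absence, not occurrences) in target versus background
#' sets. One-sided p for enrichment in the target, computed from the
#' hypergeometric tail (identical to `fisher.test(alternative =
#' "greater")$p.value`).
#'
#' @param target,background Character vectors of flank sequences (the two
#'   sets must be disjoint by construction).
#' @param hexamer Hexamer string.
#' @return One-sided p-value, or `NA` if either set is empty.
#' @export
hexamer_fisher <- function(target, background, hexamer) {
  if (length(target) == 0L || length(background) == 0L) return(NA_real_)
  qt <- sum(grepl(hexamer, target, fixed = TRUE))
  qb <- sum(grepl(hexamer, background, fixed = TRUE))
  .hyper_tail_p(qt, qt + qb, length(target), length(background))
}

# P(X >= q) for X ~ Hypergeometric(drawn = n_target of n_target+n_bg,
# white = m positives)
.hyper_tail_p <- function(q, m, n_target, n_bg) {
  stats::phyper(q - 1, m, n_target + n_bg - m, n_target, lower.tail = FALSE)
}

#' Presence-enrichment p-values for all hexamers at once
#'
#' Vectorised over the full hexamer alphabet; equivalent to calling
#' [hexamer_fisher()] per hexamer but far faster.
#'
#' @param target,background Character vectors of flank sequences.
#' @param hexamers Hexamer set (default all 4,096).
#' @return Named vector of one-sided p-values.
#' @export
hexamer_enrichment <- function(target, background, hexamers = all_hexamers()) {
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(hexamers))
  cnt <- function(seqs) {
    if (length(seqs) == 0L) return(rep(0L, length(hexamers)))
    hits <- Biostrings::vcountPDict(pd, Biostrings::DNAStringSet(seqs))
    as.integer(rowSums(hits > 0))
  }
  qt <- cnt(target); qb <- cnt(background)
  p <- .hyper_tail_p(qt, qt + qb, length(target), length(background))
  names(p) <- hexamers
  p
}

#' Combine p-values with the Irwin-Hall distribution
#'
#' The combined p-value is the probability that a sum of `k` independent
#' Uniform(0,1) variables falls at or below the observed sum of the `k`
#' p-values, from the exact alternating-sum CDF
#' \deqn{F_k(s) = \frac{1}{k!}\sum_{j=0}^{\lfloor s\rfloor}(-1)^j
#'   \binom{k}{j}(s-j)^k.}
#' For sums above `k/2` the symmetric identity `F_k(s) = 1 - F_k(k - s)`
#' is used for numerical stability.
#'
#' @param p Vector of p-values in `[0, 1]` (one per species), length >= 1.
#' @return Combined p-value.
#' @export
irwin_hall_combine <- function(p) {
  k <- length(p)
  if (k == 0L) stop("need at least one p-value", call. = FALSE)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  irwin_hall_cdf(sum(p), k)
}

#' Irwin-Hall cumulative distribution function
#'
#' @param s Observed sum (vectorised).
#' @param k Number of uniforms.
#' @return `P(S <= s)` for `S` the sum of `k` iid Uniform(0,1).
#' @export
irwin_hall_cdf <- function(s, k) {
  stopifnot(k >= 1)
  lower <- function(x) {
    # exact alternating sum, x in [0, k/2]
    vapply(x, function(xi) {
      j <- 0:floor(xi)
      sum((-1)^j * exp(lchoose(k, j) + k * log(xi - j) - lfactorial(k)))
    }, 0)
  }
  out <- numeric(length(s))
  out[s <= 0] <- 0
  out[s >= k] <- 1
  mid <- s > 0 & s < k
  sm <- s[mid]
  flip <- sm > k / 2
  res <- numeric(length(sm))
  res[!flip] <- lower(sm[!flip])
  res[flip] <- 1 - lower(k - sm[flip])
  res[sm == k / 2] <- 0.5
  out[mid] <- pmin(1, pmax(0, res))
  out
}

#' Cross-species enrichment with Irwin-Hall combination and BH adjustment
#'
#' Runs [hexamer_enrichment()] per species, combines per-hexamer p-values
#' with [irwin_hall_combine()] and BH-adjusts across hexamers (one stratum,
#' e.g. one region x direction combination).
#'
#' @param targets,backgrounds Named lists (per species) of flank sequence
#'   vectors.
#' @param hexamers Hexamer set (default all 4,096).
#' @return `data.frame`: `hexamer`, one `p_<species>` column per species,
#'   `p_combined`, `padj`.
#' @export
combine_species_enrichment <- function(targets, backgrounds,
                                       hexamers = all_hexamers()) {
  stopifnot(length(targets) >= 1L,
            identical(names(targets), names(backgrounds)))
  pmat <- vapply(names(targets), function(sp)
    hexamer_enrichment(targets[[sp]], backgrounds[[sp]], hexamers),
    numeric(length(hexamers)))
  pmat <- matrix(pmat, nrow = length(hexamers),
                 dimnames = list(hexamers, names(targets)))
  comb <- apply(pmat, 1L, irwin_hall_combine)
  out <- data.frame(hexamer = hexamers, pmat, check.names = FALSE)
  names(out)[-1L] <- paste0("p_", names(targets))
  out$p_combined <- comb
  out$padj <- bh_adjust(comb)
  rownames(out) <- NULL
  out
}

#' Probability that a PWM motif generates a hexamer
#'
#' The motif is slid across the hexamer at every offset `o` from
#' `1 - lm` to `5` (`lm` = motif length). At each offset the generation
#' probability is the product of the motif's position frequencies over the
#' overlapping hexamer positions times `0.25^m` for the `m` non-overlapping
#' positions; offsets are combined as
#' `p = 1 - prod_o (1 - p_o)`.
#'
#' @param hexamer Hexamer string over ACGT (any `N` yields probability 0
#'   with a warning).
#' @param pwm Numeric matrix, `lm` rows x 4 columns named A, C, G, T (or
#'   U); each row sums to 1.
#' @return Probability in `[0, 1]`.
#' @export
pwm_hexamer_prob <- function(hexamer, pwm) {
  pwm <- .check_pwm(pwm)
  nts <- strsplit(hexamer, "")[[1L]]
  if (length(nts) != 6L) stop("hexamer must have length 6", call. = FALSE)
  if (any(!nts %in% c("A", "C", "G", "T"))) {
    warning("hexamer contains non-ACGT characters; probability 0")
    return(0)
  }
  lm <- nrow(pwm)
  ntcol <- match(nts, colnames(pwm))
  p_not <- 1
  for (o in (1 - lm):5) {
    j <- seq_len(6L)
    ov <- j[j - o >= 1 & j - o <= lm]
    m <- 6L - length(ov)
    po <- prod(pwm[cbind(ov - o, ntcol[ov])]) * 0.25^m
    p_not <- p_not * (1 - po)
  }
  1 - p_not
}

.check_pwm <- function(pwm) {
  pwm <- as.matrix(pwm)
  if (ncol(pwm) != 4L) stop("PWM needs 4 nucleotide columns", call. = FALSE)
  if (is.null(colnames(pwm))) colnames(pwm) <- c("A", "C", "G", "T")
  colnames(pwm) <- sub("U", "T", toupper(colnames(pwm)))
  if (any(abs(rowSums(pwm) - 1) > 1e-6))
    stop("PWM rows must sum to 1", call. = FALSE)
  pwm[, c("A", "C", "G", "T")]
}

#' Annotate hexamers with PWM motifs
#'
#' For each motif, hexamer generation probabilities are computed for the
#' whole hexamer set; every hexamer whose probability is at least half the
#' maximum probability for that motif is annotated with it.
#'
#' @param pwms Named list of PWM matrices.
#' @param hexamers Hexamer set (default all 4,096).
#' @return `data.frame`: `hexamer`, `motif_id`, `prob`, `max_prob`.
#' @export
annotate_hexamers <- function(pwms, hexamers = all_hexamers()) {
  out <- lapply(names(pwms), function(id) {
    pr <- vapply(hexamers, pwm_hexamer_prob, 0, pwm = pwms[[id]])
    mx <- max(pr)
    keep <- pr >= mx / 2
    data.frame(hexamer = hexamers[keep], motif_id = id, prob = pr[keep],
               max_prob = mx)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read CISBP-style PWM text files
#'
#' Expects a whitespace-delimited table per file with a position column
#' followed by four frequency columns (A, C, G, U/T).
#'
#' @param paths Named character vector of file paths; names become motif
#'   ids (basenames used when unnamed).
#' @return Named list of PWM matrices.
#' @export
read_pwms <- function(paths) {
  if (is.null(names(paths)))
    names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  lapply(paths, function(p) {
    tab <- utils::read.table(p, header = TRUE, check.names = FALSE)
    m <- as.matrix(tab[, -1L, drop = FALSE])
    .check_pwm(m)
  })
}

#' Positional occurrence profile of a hexamer in flank sequences
#'
#' Counts hexamer match starts per distance bin from the splice-site end
#' of each flank. Overlapping matches are counted at their start position.
#'
#' @param hexamer Hexamer string.
#' @param flanks Character vector of equal-length flank sequences.
#' @param bin_width Bin width in nt.
#' @return Integer vector of per-bin counts (bin 1 = positions
#'   `1..bin_width`).
#' @export
positional_profile <- function(hexamer, flanks, bin_width = 50) {
  if (length(flanks) == 0L) return(integer(0))
  flen <- unique(nchar(flanks))
  stopifnot(length(flen) == 1L, flen >= bin_width)
  n_bins <- ceiling((flen - nchar(hexamer) + 1L) / bin_width)
  counts <- integer(n_bins)
  hits <- Biostrings::vmatchPattern(hexamer,
                                    Biostrings::DNAStringSet(flanks))
  starts <- unlist(lapply(hits, Biostrings::start), use.names = FALSE)
  if (length(starts)) {
    tb <- table(factor(ceiling(starts / bin_width), levels = seq_len(n_bins)))
    counts <- as.integer(tb)
  }
  counts
}

#' Resampled enrichment p-values (robustness check)
#'
#' Repeats [hexamer_fisher()] on random subsamples of the target set.
#'
#' @param target,background Flank sequence vectors.
#' @param hexamer Hexamer string.
#' @param n_target Subsample size (without replacement).
#' @param n_rep Number of repetitions.
#' @param seed Seed for reproducibility.
#' @return Numeric vector of `n_rep` p-values.
#' @export
resample_enrichment <- function(target, background, hexamer, n_target,
                                n_rep = 100, seed = 1) {
  stopifnot(n_target <= length(target))
  set.seed(seed)
  vapply(seq_len(n_rep), function(r) {
    hexamer_fisher(sample(target, n_target), background, hexamer)
  }, 0)
}
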