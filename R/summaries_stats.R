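# Cross-sample and cross-species summary statistics.

#' Pearson correlation over pairwise-complete PSI entries
#'
#' @param x,y Numeric vectors of equal length; `NA` = undefined PSI.
#' @param min_pairs Minimum number of jointly defined entries (default 3).
#' @return Pearson r, or `NA` when fewer than `min_pairs` complete pairs
#'   are available.
#' @export
pairwise_correlation <- function(x, y, min_pairs = 3) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_pairs) return(NA_real_)
  stats::cor(x[ok], y[ok])
}

#' PSI distance matrix (1 - Pearson r) between samples
#'
#' @param m PSI matrix (segments x samples), `NA` = undefined.
#' @param complete_only If `TRUE`, restrict to segments defined in every
#'   sample before computing correlations.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
psi_distance <- function(m, complete_only = FALSE) {
  if (complete_only) m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (b > a) d[a, b] <- d[b, a] <- 1 - pairwise_correlation(m[, a], m[, b])
  }
  d
}

#' Classical multidimensional scaling (principal coordinates)
#'
#' Double-centres the squared distance matrix, takes the top `k`
#' eigenpairs and scales eigenvectors by the square roots of their
#' eigenvalues; negative eigenvalues are truncated at zero (standard for
#' non-Euclidean 1 - r distances).
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @param k Number of dimensions (default 2).
#' @return Matrix of coordinates (points x k).
#' @export
mds_embed <- function(d, k = 2) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8) || any(abs(diag(d)) > 1e-12))
    stop("distance matrix must be symmetric with zero diagonal",
         call. = FALSE)
  n <- nrow(d)
  j <- diag(n) - 1 / n
  b <- -0.5 * j %*% (d^2) %*% j
  eg <- eigen((b + t(b)) / 2, symmetric = TRUE)
  lam <- pmax(eg$values[seq_len(k)], 0)
  coords <- eg$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k)
  rownames(coords) <- rownames(d)
  coords
}

#' Organ-pair co-occurrence of devAS membership
#'
#' For every organ pair, a two-sided Fisher's exact test on the 2x2 table
#' of devAS membership (yes/no in organ A x yes/no in organ B) over all
#' exons that are devAS in at least one organ. The odds ratio is the
#' sample cross-product ratio.
#'
#' @param membership Logical matrix (exons x organs).
#' @return `data.frame`: `organ_a`, `organ_b`, `odds_ratio`, `p`.
#' @export
organ_pair_cooccurrence <- function(membership) {
  stopifnot(is.matrix(membership) || is.data.frame(membership))
  membership <- as.matrix(membership)
  membership <- membership[rowSums(membership) >= 1L, , drop = FALSE]
  organs <- colnames(membership)
  pairs <- utils::combn(seq_along(organs), 2L)
  out <- apply(pairs, 2L, function(pq) {
    a <- membership[, pq[1L]]; b <- membership[, pq[2L]]
    tab <- table(factor(a, c(TRUE, FALSE)), factor(b, c(TRUE, FALSE)))
    degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    or <- if (degenerate) NA_real_
          else (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    p <- if (degenerate) 1 else stats::fisher.test(tab)$p.value
    data.frame(organ_a = organs[pq[1L]], organ_b = organs[pq[2L]],
               odds_ratio = or, p = p)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Positionwise mean and standard error of flank score tracks
#'
#' @param tracks Numeric matrix (exons x positions), `NA` allowed.
#' @return `data.frame` with `position`, `mean`, `sem`, `lo`, `hi`
#'   (mean +/- 2 sem).
#' @export
mean_flank_score <- function(tracks) {
  tracks <- as.matrix(tracks)
  if (nrow(tracks) == 0L) stop("empty exon set", call. = FALSE)
  n_def <- colSums(!is.na(tracks))
  mu <- colMeans(tracks, na.rm = TRUE)
  sdv <- apply(tracks, 2L, stats::sd, na.rm = TRUE)
  sem <- ifelse(n_def > 0, sdv / sqrt(n_def), NA_real_)
  sem[n_def == 1L] <- 0
  data.frame(position = seq_len(ncol(tracks)), mean = mu, sem = sem,
             lo = mu - 2 * sem, hi = mu + 2 * sem)
}

#' Compare minor allele frequencies between two exon groups
#'
#' Drops singleton SNPs (minor allele count <= 1), computes the mean
#' log10 minor allele frequency per group and a two-sided
#' Mann-Whitney/Wilcoxon rank test.
#'
#' @param snps_a,snps_b `data.frame`s with `minor_count` and `total`
#'   (allele numbers).
#' @return List: `mean_log10_a`, `mean_log10_b`, `p`, `n_a`, `n_b`;
#'   `NULL` when either group is empty after filtering.
#' @export
maf_compare <- function(snps_a, snps_b) {
  maf <- function(s) {
    s <- s[s$minor_count > 1, , drop = FALSE]
    s$minor_count / s$total
  }
  ma <- maf(snps_a); mb <- maf(snps_b)
  if (length(ma) == 0L || length(mb) == 0L) return(NULL)
  p <- suppressWarnings(stats::wilcox.test(ma, mb)$p.value)
  list(mean_log10_a = mean(log10(ma)), mean_log10_b = mean(log10(mb)),
       p = p, n_a = length(ma), n_b = length(mb))
}

#' Clopper-Pearson 95% confidence interval for a proportion
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (>= 1).
#' @param conf Confidence level (default 0.95).
#' @return Named vector `c(lower, upper)`.
#' @export
binomial_ci <- function(k, n, conf = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  alpha <- 1 - conf
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}
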