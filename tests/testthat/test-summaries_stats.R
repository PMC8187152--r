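test_that("pairwise correlation uses pairwise-complete entries", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(pairwise_correlation(x, x), 1)
  expect_equal(pairwise_correlation(x, 1 - x), -1)
  expect_equal(pairwise_correlation(x, c(0.2, 0.4, 0.5, 0.9)),
               cor(x, c(0.2, 0.4, 0.5, 0.9)))
  # hand computation: sum xy = 0.11, sum x^2 = 0.05, sum y^2 = 0.26
  expect_equal(pairwise_correlation(x, c(0.2, 0.4, 0.5, 0.9)),
               0.11 / sqrt(0.05 * 0.26), tolerance = 1e-12)
  # NA entries dropped pairwise; fewer than 3 pairs -> NA
  expect_equal(pairwise_correlation(c(x, NA), c(0.2, 0.4, 0.5, 0.9, 0.1)),
               cor(x, c(0.2, 0.4, 0.5, 0.9)))
  expect_true(is.na(pairwise_correlation(c(0.1, 0.2, NA, NA),
                                         c(0.3, 0.1, 0.5, 0.6))))
  # affine invariance
  expect_equal(pairwise_correlation(2 * x + 1, c(0.2, 0.4, 0.5, 0.9)),
               pairwise_correlation(x, c(0.2, 0.4, 0.5, 0.9)))
})

test_that("classical MDS recovers planted configurations", {
  set.seed(44)
  pts <- matrix(rnorm(8), 4, 2)
  d <- as.matrix(dist(pts))
  emb <- mds_embed(d, 2)
  # distance reconstruction up to rotation/reflection
  expect_equal(as.matrix(dist(emb)), d, tolerance = 1e-8)
  # Procrustes alignment error against the planted points
  pc <- function(a, b) {
    a <- scale(a, scale = FALSE); b <- scale(b, scale = FALSE)
    sv <- svd(t(b) %*% a)
    sum((a - b %*% sv$u %*% t(sv$v))^2)
  }
  expect_lt(pc(emb, pts), 1e-6)
  # agrees with the reference implementation
  ref <- cmdscale(d, k = 2)
  expect_equal(abs(emb), abs(ref), tolerance = 1e-8)
  # all-equal distances among 3 points: equilateral triangle
  d3 <- matrix(1, 3, 3) - diag(3)
  e3 <- mds_embed(d3, 2)
  expect_equal(max(dist(e3)) - min(dist(e3)), 0, tolerance = 1e-10)
  # duplicate points collapse to identical coordinates
  d4 <- as.matrix(dist(rbind(c(0, 0), c(0, 0), c(3, 4))))
  e4 <- mds_embed(d4, 2)
  expect_lt(max(abs(e4[1, ] - e4[2, ])), 1e-6)
  expect_error(mds_embed(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("organ co-occurrence tables, ORs and Fisher p-values", {
  m <- matrix(FALSE, 50, 2, dimnames = list(NULL, c("brain", "heart")))
  m[1:20, 1] <- TRUE; m[1:20, 2] <- TRUE    # 20 in both
  m[21:25, 1] <- TRUE                       # 5 brain only
  m[26:30, 2] <- TRUE                       # 5 heart only
  m[31:50, ] <- FALSE                       # excluded (devAS nowhere)
  # exons devAS nowhere are excluded; add a third organ so the
  # brain/heart table keeps a both-negative cell
  m3 <- cbind(m, liver = c(rep(FALSE, 30), rep(TRUE, 20)))
  res3 <- organ_pair_cooccurrence(m3)
  row <- res3[res3$organ_a == "brain" & res3$organ_b == "heart", ]
  expect_equal(row$odds_ratio, (20 * 20) / (5 * 5))
  expect_equal(row$p,
               fisher.test(matrix(c(20, 5, 5, 20), 2))$p.value)
  # symmetry in pair order: OR of transposed membership identical
  resT <- organ_pair_cooccurrence(m3[, c(2, 1, 3)])
  rowT <- resT[resT$organ_a == "heart" & resT$organ_b == "brain", ]
  expect_equal(rowT$odds_ratio, row$odds_ratio)
  # degenerate margin: all included exons devAS in organ A
  mdeg <- cbind(a = rep(TRUE, 10), b = rep(c(TRUE, FALSE), 5))
  resd <- organ_pair_cooccurrence(mdeg)
  expect_true(is.na(resd$odds_ratio))
  expect_equal(resd$p, 1)
})

test_that("mean flank scores return mean +/- 2 sem", {
  tr <- matrix(0.8, 5, 50)
  ms <- mean_flank_score(tr)
  expect_equal(ms$mean, rep(0.8, 50))
  expect_equal(ms$sem, rep(0, 50))
  tr2 <- rbind(rep(0, 50), rep(1, 50))
  ms2 <- mean_flank_score(tr2)
  expect_equal(ms2$mean, rep(0.5, 50))
  expect_equal(ms2$lo, ms2$mean - 2 * ms2$sem)
  expect_error(mean_flank_score(matrix(0, 0, 50)), "empty")
})

test_that("MAF comparison filters singletons and runs the rank test", {
  a <- data.frame(minor_count = c(1, 5, 10, 20), total = 1000)
  b <- data.frame(minor_count = c(1, 5, 10, 20), total = 10000)
  res <- maf_compare(a, b)
  expect_equal(res$n_a, 3)  # singleton dropped
  expect_equal(res$mean_log10_a - res$mean_log10_b, 1)  # 10x MAF ratio
  same <- maf_compare(a, a)
  expect_equal(same$p, 1)
  empty <- data.frame(minor_count = c(1, 1), total = 100)
  expect_null(maf_compare(a, empty))
})

test_that("Clopper-Pearson intervals match exact beta quantiles", {
  expect_equal(unname(binomial_ci(0, 10)[1]), 0)
  expect_equal(unname(binomial_ci(10, 10)[2]), 1)
  ci <- binomial_ci(5, 10)
  expect_equal(unname(ci), c(qbeta(0.025, 5, 6), qbeta(0.975, 6, 5)),
               tolerance = 1e-12)
  expect_equal(unname(round(ci, 3)), c(0.187, 0.813))
})

test_that("psi_distance builds a symmetric 1 - r matrix", {
  set.seed(9)
  m <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("s1", "s2", "s3")))
  m[sample(60, 5)] <- NA
  d <- psi_distance(m)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), setNames(rep(0, 3), colnames(m)))
  expect_equal(d["s1", "s2"],
               1 - pairwise_correlation(m[, 1], m[, 2]))
})
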