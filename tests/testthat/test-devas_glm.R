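test_that("gestation defaults match the stated species values", {
  g <- gestation_table()
  expect_equal(unname(g[c("human", "macaque", "mouse", "rat", "rabbit",
                          "opossum", "chicken")]),
               c(280, 165, 20, 21, 30, 15, 21))
})

test_that("eligibility applies the 60% coverage and 4-in-range rules", {
  # all covered, all mid-range
  expect_true(devas_eligible(rep(10, 10), rep(10, 10), rep(0.5, 10)))
  # 50% covered < 60%
  i <- c(rep(10, 5), rep(2, 5)); e <- c(rep(10, 5), rep(3, 5))
  psi <- c(rep(0.5, 5), rep(NA, 5))
  expect_false(devas_eligible(i, e, psi))
  # coverage fine but only 3 mid-range PSI
  psi2 <- c(0.5, 0.5, 0.5, 0.95, 0.95, 0.95, 0.95, 0.95, 0.95, 0.95)
  expect_false(devas_eligible(rep(10, 10), rep(10, 10), psi2))
  # boundary: PSI exactly 0.1 and 0.9 count as in range
  psi3 <- c(0.1, 0.1, 0.9, 0.9, rep(0.95, 6))
  expect_true(devas_eligible(rep(10, 10), rep(10, 10), psi3))
})

test_that("a noiseless logistic trend yields a tiny linear-term p", {
  a <- seq(log(10), log(1000), length.out = 20)
  psi <- 0.1 + 0.8 * plogis((a - mean(a)) / 0.4)
  n <- 200
  i <- round(n * psi); e <- n - i
  fit <- fit_devas_glm(i, e, a)
  expect_true(fit$converged)
  expect_lt(fit$p[["a"]], 1e-6)
})

test_that("flat high-coverage profiles give non-significant terms", {
  a <- seq(log(10), log(1000), length.out = 20)
  i <- rep(500, 20); e <- rep(500, 20)
  fit <- fit_devas_glm(i, e, a)
  expect_true(all(fit$p > 0.5))
})

test_that("term p-values are invariant to the log base of age", {
  set.seed(11)
  a <- seq(log(10), log(700), length.out = 18)
  psi <- 0.2 + 0.5 * plogis((a - mean(a)) / 0.5)
  cnt <- simulate_counts(psi, depth = 120, rho = 0, seed = 42)
  f1 <- fit_devas_glm(cnt$i, cnt$e, a)
  f2 <- fit_devas_glm(cnt$i, cnt$e, a / log(10))  # log10 age
  expect_equal(f1$p, f2$p, tolerance = 1e-8)
})

test_that("quasi F-test with dispersion 1 approaches the chi-square LRT", {
  # forcing dispersion to 1 at large n, F(1, n-4) converges to chi2/1
  set.seed(7)
  a <- seq(log(5), log(2000), length.out = 400)
  psi <- 0.45 + 0.02 * plogis((a - mean(a)) / 0.6)  # weak signal
  cnt <- simulate_counts(psi, depth = 400, rho = 0, seed = 8)
  fit <- fit_devas_glm(cnt$i, cnt$e, a, dispersion = 1)
  # same nested pair as the sequential linear-term test
  m0 <- glm(cbind(cnt$i, cnt$e) ~ 1, family = binomial())
  m1 <- glm(cbind(cnt$i, cnt$e) ~ a, family = binomial())
  p_chi <- pchisq(m0$deviance - m1$deviance, 1, lower.tail = FALSE)
  expect_equal(fit$p[["a"]], p_chi, tolerance = 0.1)
})

test_that("samples with zero coverage are dropped and small n errors", {
  a <- seq(1, 3, length.out = 10)
  i <- c(rep(20, 8), 0, 0); e <- c(rep(20, 8), 0, 0)
  fit <- fit_devas_glm(i, e, a)
  expect_equal(fit$n, 8L)
  expect_error(fit_devas_glm(c(5, 5, 5, 5, 5), c(5, 5, 5, 5, 5), a[1:5]),
               ">= 6 samples")
})

test_that("bh_adjust reproduces the hand-computed step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.01, 0.04, 0.9)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p) && all(adj <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("devas_test pools BH adjustment across segments and terms", {
  set.seed(3)
  meta <- data.frame(sample_id = paste0("s", 1:12),
                     days_post_conception = round(exp(seq(log(15), log(500),
                                                          length.out = 12))))
  a <- log(meta$days_post_conception)
  mk <- function(id, psi) data.frame(segment_id = id,
                                     sample_id = meta$sample_id,
                                     simulate_counts(psi, 150, 0))
  counts <- rbind(mk("dyn", 0.1 + 0.8 * plogis((a - mean(a)) / 0.4)),
                  mk("flat", rep(0.5, 12)))
  segs <- data.frame(segment_id = c("dyn", "flat"), length = c(100, 100))
  res <- devas_test(counts, meta, segs, lr = 100)
  expect_equal(nrow(res), 2L)
  expect_true(res$significant[res$segment_id == "dyn"])
  expect_false(res$significant[res$segment_id == "flat"])
  # adjusted p-values never smaller than raw
  expect_true(all(res$padj_a >= res$p_a, na.rm = TRUE))
})
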