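test_that("hexamer_fisher reproduces the hypergeometric tail", {
  hx <- "ACGTAC"
  with_hx <- function(n) vapply(seq_len(n), function(k)
    paste0(strrep("T", 20), hx, strrep("T", 20)), "")
  without <- function(n) vapply(seq_len(n), function(k) strrep("T", 46), "")
  # hexamer in all 10 targets, 0 of 10 background: p = 1/choose(20,10)
  expect_equal(hexamer_fisher(with_hx(10), without(10), hx),
               1 / choose(20, 10), tolerance = 1e-12)
  # equal frequencies: no enrichment
  expect_gte(hexamer_fisher(c(with_hx(5), without(5)),
                            c(with_hx(5), without(5)), hx), 0.5)
  # absent everywhere
  expect_equal(hexamer_fisher(without(10), without(10), hx), 1)
  # agrees with fisher.test one-sided on a non-trivial table
  tg <- c(with_hx(7), without(3)); bg <- c(with_hx(2), without(8))
  ft <- fisher.test(matrix(c(7, 3, 2, 8), 2, byrow = TRUE),
                    alternative = "greater")$p.value
  expect_equal(hexamer_fisher(tg, bg, hx), ft, tolerance = 1e-12)
})

test_that("vectorised enrichment equals per-hexamer calls", {
  set.seed(5)
  tg <- random_flanks(15, 60); bg <- random_flanks(25, 60)
  hexes <- c("ACGTAC", "TTTTTT", "GGCGCG")
  p_vec <- hexamer_enrichment(tg, bg, hexes)
  p_ind <- vapply(hexes, function(h) hexamer_fisher(tg, bg, h), 0)
  expect_equal(p_vec, p_ind, tolerance = 1e-12)
})

test_that("Irwin-Hall combination matches closed forms", {
  expect_equal(irwin_hall_combine(0.07), 0.07, tolerance = 1e-10)
  expect_equal(irwin_hall_combine(rep(0.5, 7)), 0.5, tolerance = 1e-10)
  expect_equal(irwin_hall_combine(c(0.1, 0.1)), 0.02, tolerance = 1e-10)
  # symmetry: F_k(s) = 1 - F_k(k - s)
  expect_equal(irwin_hall_cdf(1.3, 3), 1 - irwin_hall_cdf(3 - 1.3, 3),
               tolerance = 1e-10)
  expect_error(irwin_hall_combine(numeric(0)), "at least one")
  expect_error(irwin_hall_combine(c(0.5, 1.5)), "\\[0, 1\\]")
})

test_that("Irwin-Hall CDF agrees with Monte Carlo", {
  set.seed(99)
  s <- rowSums(matrix(runif(2e5), ncol = 2))
  expect_lt(abs(mean(s <= 0.2) - irwin_hall_cdf(0.2, 2)), 0.003)
})

test_that("combining uniform p-values is calibrated (KS uniform)", {
  set.seed(404)
  comb <- replicate(10000, irwin_hall_combine(runif(7)))
  ks <- suppressWarnings(ks.test(comb, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("pwm_hexamer_prob matches the offset formula and its oracle", {
  # deterministic PWM spelling ACGTAC: certain match at offset 0
  det <- matrix(0, 6, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  det[cbind(1:6, match(c("A", "C", "G", "T", "A", "C"),
                       c("A", "C", "G", "T")))] <- 1
  expect_equal(pwm_hexamer_prob("ACGTAC", det), 1)
  expect_equal(pwm_hexamer_prob("TTTTTT", det), 0)
  # uniform length-4 PWM: every offset contributes 0.25^6, lm+5 offsets
  unif <- matrix(0.25, 4, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  expect_equal(pwm_hexamer_prob("ACGTAC", unif), 1 - (1 - 0.25^6)^9,
               tolerance = 1e-12)

  # independent brute-force oracle over offsets
  oracle <- function(hex, pwm) {
    nts <- strsplit(hex, "")[[1]]
    lm <- nrow(pwm)
    po_all <- vapply((1 - lm):5, function(o) {
      p <- 1; m <- 0
      for (j in 1:6) {
        r <- j - o
        if (r >= 1 && r <= lm) p <- p * pwm[r, nts[j]] else m <- m + 1
      }
      p * 0.25^m
    }, 0)
    1 - prod(1 - po_all)
  }
  set.seed(77)
  for (rep in 1:200) {
    lm <- sample(3:10, 1)
    pwm <- matrix(rgamma(lm * 4, 1), lm, 4,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
    pwm <- pwm / rowSums(pwm)
    hex <- paste(sample(c("A", "C", "G", "T"), 6, TRUE), collapse = "")
    expect_equal(pwm_hexamer_prob(hex, pwm), oracle(hex, pwm),
                 tolerance = 1e-12)
  }
  expect_warning(p0 <- pwm_hexamer_prob("ACGTAN", unif), "non-ACGT")
  expect_equal(p0, 0)
})

test_that("annotate_hexamers keeps hexamers at >= half max probability", {
  det <- matrix(0.001 / 3, 6, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  det[cbind(1:6, match(c("A", "C", "G", "T", "A", "C"),
                       c("A", "C", "G", "T")))] <- 0.999
  hexes <- c("ACGTAC", "ACGTAA", "TTTTTT")
  ann <- annotate_hexamers(list(m1 = det), hexes)
  expect_true("ACGTAC" %in% ann$hexamer)
  expect_false("TTTTTT" %in% ann$hexamer)
  # all-uniform PWM: every hexamer ties at max, all annotated
  unif <- matrix(0.25, 4, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  ann2 <- annotate_hexamers(list(u = unif), hexes)
  expect_equal(sort(ann2$hexamer), sort(hexes))
})

test_that("positional_profile bins match starts and planted positions", {
  expect_equal(positional_profile("ACGTAC", rep(strrep("T", 200), 4)),
               rep(0L, 4))
  fl <- vapply(1:6, function(k) {
    s <- strrep("T", 200)
    substr(s, 10, 15) <- "ACGTAC"
    substr(s, 110, 115) <- "ACGTAC"
    s
  }, "")
  prof <- positional_profile("ACGTAC", fl, bin_width = 50)
  expect_equal(prof, c(6L, 0L, 6L, 0L))
})

test_that("planted motifs are recovered across species after combination", {
  set.seed(1234)
  hx <- "ACTAAC"
  sp <- c("human", "mouse", "chicken")
  targets <- lapply(setNames(sp, sp), function(s)
    plant_flank_motifs(random_flanks(60, 200), hx, 0.4)$flanks)
  backgrounds <- lapply(setNames(sp, sp), function(s)
    plant_flank_motifs(random_flanks(120, 200), hx, 0.1)$flanks)
  enr <- combine_species_enrichment(targets, backgrounds)
  expect_lt(enr$padj[enr$hexamer == hx], 0.05)
  expect_gt(median(enr$padj[enr$hexamer != hx]), 0.5)
})

test_that("read_pwms parses CISBP-style text matrices", {
  f <- file.path(tempdir(), "motif1.txt")
  writeLines(c("Pos\tA\tC\tG\tU",
               paste(1:4, 0.7, 0.1, 0.1, 0.1, sep = "\t")), f)
  pw <- read_pwms(c(m1 = f))
  expect_named(pw, "m1")
  expect_equal(dim(pw$m1), c(4L, 4L))
  expect_equal(colnames(pw$m1), c("A", "C", "G", "T"))
  expect_equal(unname(pw$m1[1, "A"]), 0.7)
})
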