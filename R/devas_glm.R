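# Quasi-binomial GLM test for developmentally dynamic splicing.
#
# Per segment, organ and species, inclusion/exclusion counts are modelled
# as a quasi-binomial GLM on a cubic polynomial of log developmental age
# (days from conception; postnatal ages are offset by the species
# gestation time). Each polynomial term is tested with a quasi-likelihood
# F-test against the model with that term removed.

#' Default gestation times (days from conception to birth)
#'
#' @return Named numeric vector for human, macaque, mouse, rat, rabbit,
#'   opossum and chicken.
#' @export
gestation_table <- function() {
  c(human = 280, macaque = 165, mouse = 20, rat = 21, rabbit = 30,
    opossum = 15, chicken = 21)
}

#' Developmental age on the model scale
#'
#' Log days from conception; for postnatal samples, postnatal days plus the
#' species' typical gestation time.
#'
#' @param days_post_conception Days from conception (> 0); use
#'   `postnatal_days + gestation` for postnatal samples, e.g. via
#'   [gestation_table()].
#' @return Natural log of days from conception.
#' @export
log_age <- function(days_post_conception) {
  stopifnot(all(days_post_conception > 0))
  log(days_post_conception)
}

#' Is a segment eligible for the devAS test?
#'
#' Requires coverage `i + e > 9` in at least 60\% of the organ's samples
#' and at least four samples with defined PSI inside `[0.1, 0.9]`.
#'
#' @param i,e Per-sample inclusion/exclusion counts.
#' @param psi Per-sample PSI values (`NA` = undefined).
#' @param min_cov_frac Fraction of samples that must reach coverage 10.
#' @param min_mid_psi Required number of samples with PSI in `psi_range`.
#' @param psi_range Inclusive mid-range PSI interval.
#' @return Logical scalar.
#' @export
devas_eligible <- function(i, e, psi, min_cov_frac = 0.6, min_mid_psi = 4,
                           psi_range = c(0.1, 0.9)) {
  stopifnot(length(i) == length(e), length(i) == length(psi),
            length(i) >= 1L)
  cov_ok <- mean((i + e) > 9) >= min_cov_frac
  mid <- sum(!is.na(psi) & psi >= psi_range[1L] & psi <= psi_range[2L])
  cov_ok && mid >= min_mid_psi
}

#' Fit the devAS quasi-binomial GLM for one segment
#'
#' Fits `cbind(i, e) ~ a + a^2 + a^3` with a quasi-binomial family
#' (logit link, free dispersion). Terms are tested with sequential
#' nested-model quasi-likelihood F-tests (as `anova.glm(test = "F")`
#' reports them): `a` against the intercept model, `a^2` against `a`,
#' `a^3` against `a + a^2`, each F being the quasi-deviance drop divided
#' by the Pearson dispersion of the full model
#' (`sum(pearson residuals^2) / (n - 4)`), with denominator df `n - 4`.
#' Sequential rather than single-term-deletion tests are used because the
#' raw polynomial basis is strongly collinear on a log-age axis: deleting
#' one term from the full model barely changes the fit even for strong
#' monotone trends, which would leave the test with almost no power.
#' Samples with `i + e = 0` are dropped before fitting.
#'
#' @param i,e Per-sample inclusion/exclusion counts.
#' @param a Per-sample log developmental age (see [log_age()]).
#' @param dispersion Optional fixed dispersion; default `NULL` estimates
#'   it from Pearson residuals. Forcing 1 recovers the plain binomial
#'   likelihood-ratio scale.
#' @return List with `p` (named vector: `a`, `a2`, `a3`), `dispersion`,
#'   `n`, `converged`. Non-convergence yields `NA` p-values and
#'   `converged = FALSE`.
#' @export
fit_devas_glm <- function(i, e, a, dispersion = NULL) {
  stopifnot(length(i) == length(e), length(i) == length(a))
  keep <- (i + e) > 0
  i <- i[keep]; e <- e[keep]; a <- a[keep]
  n <- length(i)
  if (n < 6L)
    stop("need >= 6 samples with coverage to identify 4 mean parameters",
         call. = FALSE)
  dat <- data.frame(i = i, e = e, a = a)
  rhs <- c("1", "a", "a + I(a^2)", "a + I(a^2) + I(a^3)")
  fit_one <- function(f) tryCatch(
    suppressWarnings(
      stats::glm(stats::as.formula(paste("cbind(i, e) ~", f)),
                 family = stats::quasibinomial(), data = dat,
                 control = stats::glm.control(maxit = 100))),
    error = function(err) NULL)
  fits <- lapply(rhs, fit_one)
  bad <- list(p = c(a = NA_real_, a2 = NA_real_, a3 = NA_real_),
              dispersion = NA_real_, n = n, converged = FALSE)
  if (any(vapply(fits, is.null, TRUE)) ||
      !fits[[4L]]$converged) return(bad)
  df_den <- n - 4
  if (df_den <= 0) return(bad)
  phi <- if (is.null(dispersion))
    sum(stats::residuals(fits[[4L]], type = "pearson")^2) / df_den
  else dispersion
  dev <- vapply(fits, function(f) f$deviance, 0)
  pvals <- vapply(1:3, function(k) {
    Fstat <- (dev[k] - dev[k + 1L]) / phi
    if (!is.finite(Fstat) || Fstat < 0) Fstat <- 0
    stats::pf(Fstat, 1, df_den, lower.tail = FALSE)
  }, 0)
  names(pvals) <- c("a", "a2", "a3")
  list(p = pvals, dispersion = phi, n = n, converged = TRUE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment, preserving input
#' order; `NA` entries are passed through.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Run the devAS test across segments of one species-organ analysis
#'
#' Applies [devas_eligible()], fits [fit_devas_glm()] per eligible segment
#' and BH-adjusts all term p-values of all eligible segments jointly.
#'
#' @param counts Long counts `data.frame`: `segment_id`, `sample_id`, `i`, `e`.
#' @param meta Sample metadata: `sample_id`, `days_post_conception`.
#' @param segments Segment table with `segment_id` and `length`.
#' @param lr Read length used for the PSI-based eligibility screen.
#' @param alpha Significance level on adjusted p-values.
#' @return `data.frame`: `segment_id`, `eligible`, `p_a`, `p_a2`, `p_a3`,
#'   `padj_a`, `padj_a2`, `padj_a3`, `padj_min`, `dispersion`, `significant`.
#' @export
devas_test <- function(counts, meta, segments, lr, alpha = 0.05) {
  counts$a <- log_age(meta$days_post_conception[
    match(counts$sample_id, meta$sample_id)])
  counts$psi <- compute_psi(
    counts$i, counts$e,
    segments$length[match(counts$segment_id, segments$segment_id)], lr)$value
  res <- lapply(split(counts, counts$segment_id), function(sc) {
    elig <- devas_eligible(sc$i, sc$e, sc$psi)
    if (!elig)
      return(data.frame(segment_id = sc$segment_id[1L], eligible = FALSE,
                        p_a = NA_real_, p_a2 = NA_real_, p_a3 = NA_real_,
                        dispersion = NA_real_))
    fit <- fit_devas_glm(sc$i, sc$e, sc$a)
    data.frame(segment_id = sc$segment_id[1L], eligible = TRUE,
               p_a = fit$p[["a"]], p_a2 = fit$p[["a2"]], p_a3 = fit$p[["a3"]],
               dispersion = fit$dispersion)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  padj <- matrix(bh_adjust(c(out$p_a, out$p_a2, out$p_a3)), ncol = 3)
  out$padj_a <- padj[, 1L]; out$padj_a2 <- padj[, 2L]; out$padj_a3 <- padj[, 3L]
  out$padj_min <- suppressWarnings(
    apply(padj, 1L, function(x) if (all(is.na(x))) NA_real_
          else min(x, na.rm = TRUE)))
  out$significant <- !is.na(out$padj_min) & out$padj_min < alpha
  out
}
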