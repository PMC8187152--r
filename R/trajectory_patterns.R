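# Spline PSI trajectories, dPSI and temporal pattern classification.
#
# PSI is regressed on a cubic B-spline basis of log age with four degrees
# of freedom (one interior knot at the median age by default). dPSI is the
# range of the fitted values at the sampled ages. Pattern classification
# interpolates the fit on a 1,000-point grid of the age axis, splits the
# step changes into positive ("up") and negative ("down") mass and derives
# age-weighted timing statistics for each direction.

#' Fit a PSI trajectory spline
#'
#' Least-squares fit of PSI on a cubic B-spline basis of log age with
#' `df` basis columns plus intercept; by default one interior knot at the
#' median age. Predictions are clipped to `[0, 1]`.
#'
#' @param psi PSI values (`NA` allowed; dropped).
#' @param a Log developmental ages, same length as `psi`.
#' @param df Spline degrees of freedom (basis columns), default 4.
#' @param knots Interior knot positions; default `NULL` places `df - 3`
#'   knots at quantiles of `a` (the median for `df = 4`).
#' @return Object of class `psi_trajectory`: the fitted model, age domain,
#'   fitted PSI at the sampled ages (`fitted`), and `dpsi`.
#' @export
fit_psi_spline <- function(psi, a, df = 4, knots = NULL) {
  keep <- !is.na(psi) & !is.na(a)
  psi <- psi[keep]; a <- a[keep]
  if (length(psi) < 5L)
    stop("need at least 5 defined PSI points to fit df=4 spline",
         call. = FALSE)
  if (length(unique(a)) < 2L)
    stop("need at least 2 distinct ages", call. = FALSE)
  if (is.null(knots) && df > 3L)
    knots <- stats::quantile(a, probs = seq_len(df - 3L) / (df - 2L),
                             names = FALSE, type = 7)
  boundary <- range(a)
  basis <- splines::bs(a, degree = 3L, knots = knots,
                       Boundary.knots = boundary)
  fit <- stats::lm.fit(cbind(1, basis), psi)
  fitted <- pmin(1, pmax(0, cbind(1, basis) %*% fit$coefficients))
  structure(list(coefficients = fit$coefficients, knots = knots,
                 boundary = boundary, ages = a,
                 fitted = as.numeric(fitted),
                 dpsi = max(fitted) - min(fitted)),
            class = "psi_trajectory")
}

#' Predict PSI from a fitted trajectory
#'
#' @param object A `psi_trajectory`.
#' @param newages Log ages at which to predict (clamped to the fitted
#'   domain; extrapolation is not supported).
#' @param ... Unused.
#' @return Predicted PSI, clipped to `[0, 1]`.
#' @export
predict.psi_trajectory <- function(object, newages, ...) {
  newages <- pmin(object$boundary[2L], pmax(object$boundary[1L], newages))
  basis <- splines::bs(newages, degree = 3L, knots = object$knots,
                       Boundary.knots = object$boundary)
  pred <- cbind(1, basis) %*% object$coefficients
  pmin(1, pmax(0, as.numeric(pred)))
}

#' Classify the temporal pattern of a PSI trajectory
#'
#' The fit is evaluated at `n_grid` evenly spaced points on the (log) age
#' domain. Successive differences are split into positive (`up`) and
#' negative (`down`) mass; `up_timing` and `down_timing` are the
#' age-weighted means of each mass (weights = the age at each step's right
#' endpoint). Patterns: `up/(up+down) < 0.3` is "down", `> 0.7` is "up",
#' otherwise `up_timing < down_timing` gives "up-down" and the reverse
#' "down-up". Trajectories with no change are "none".
#'
#' @param fit A `psi_trajectory` from [fit_psi_spline()].
#' @param n_grid Number of grid points (default 1000).
#' @param ratio_lo,ratio_hi Monotonicity thresholds (defaults 0.3 / 0.7).
#' @return List with `up`, `down`, `up_timing`, `down_timing`, `ratio`,
#'   `pattern`.
#' @export
classify_pattern <- function(fit, n_grid = 1000, ratio_lo = 0.3,
                             ratio_hi = 0.7) {
  stopifnot(inherits(fit, "psi_trajectory"))
  grid <- seq(fit$boundary[1L], fit$boundary[2L], length.out = n_grid)
  p <- predict(fit, grid)
  d <- diff(p)
  ak <- grid[-1L]  # age at the right endpoint of each step
  up <- sum(pmax(d, 0))
  down <- sum(pmax(-d, 0))
  up_timing <- if (up > 0) sum(pmax(d, 0) * ak) / up else NA_real_
  down_timing <- if (down > 0) sum(pmax(-d, 0) * ak) / down else NA_real_
  if (up + down <= 1e-9) {
    pattern <- "none"; ratio <- NA_real_
  } else {
    ratio <- up / (up + down)
    pattern <- if (ratio < ratio_lo) "down"
               else if (ratio > ratio_hi) "up"
               else if (up_timing < down_timing) "up-down"
               else "down-up"
  }
  list(up = up, down = down, up_timing = up_timing,
       down_timing = down_timing, ratio = ratio, pattern = pattern)
}

#' devAS call from adjusted p-value and dPSI
#'
#' A segment is developmentally dynamic when its minimum adjusted term
#' p-value is below `alpha` and its dPSI exceeds `min_dpsi` (both strict
#' in the stated directions).
#'
#' @param padj Minimum BH-adjusted term p-value.
#' @param dpsi Fitted dPSI amplitude.
#' @param alpha,min_dpsi Thresholds, defaults 0.05 and 0.2.
#' @return Logical (vectorised).
#' @export
call_devas <- function(padj, dpsi, alpha = 0.05, min_dpsi = 0.2) {
  !is.na(padj) & !is.na(dpsi) & padj < alpha & dpsi > min_dpsi
}

#' devAS call from dPSI alone
#'
#' Variant without the statistical test, used when test power would
#' confound a comparison (threshold 0) or to focus on strong changes
#' (threshold 0.5).
#'
#' @param dpsi Fitted dPSI amplitude.
#' @param threshold Strict lower bound on dPSI.
#' @return Logical (vectorised).
#' @export
call_devas_dpsi_only <- function(dpsi, threshold = 0) {
  !is.na(dpsi) & dpsi > threshold
}

#' Did the PSI change occur before or after birth?
#'
#' Change is "before birth" when the absolute PSI difference between the
#' earliest and newborn stages strictly exceeds that between newborn and
#' the last stage.
#'
#' @param psi_earliest,psi_newborn,psi_last Stage-level PSI values.
#' @return `"before_birth"` or `"after_birth"` (vectorised).
#' @export
birth_timing <- function(psi_earliest, psi_newborn, psi_last) {
  ifelse(abs(psi_newborn - psi_earliest) > abs(psi_last - psi_newborn),
         "before_birth", "after_birth")
}

#' Count devAS exons changing at each stage transition
#'
#' Per consecutive stage pair, counts exons whose stage-mean PSI changes
#' by strictly more than `min_change`.
#'
#' @param psi_by_stage Matrix of stage-mean PSI (exons x ordered stages).
#' @param min_change Strict threshold on `|delta PSI|` (default 0.2).
#' @return Named integer vector, one count per transition.
#' @export
stage_change_counts <- function(psi_by_stage, min_change = 0.2) {
  stopifnot(is.matrix(psi_by_stage), ncol(psi_by_stage) >= 2L)
  st <- colnames(psi_by_stage)
  if (is.null(st)) st <- as.character(seq_len(ncol(psi_by_stage)))
  d <- abs(psi_by_stage[, -1L, drop = FALSE] -
           psi_by_stage[, -ncol(psi_by_stage), drop = FALSE])
  counts <- colSums(d > min_change, na.rm = TRUE)
  names(counts) <- paste(st[-length(st)], st[-1L], sep = "->")
  counts
}
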