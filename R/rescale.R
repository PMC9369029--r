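# Regularization of the plant mutation-effect problem: two calibrated
# linear maps anchor plant-TBP predictions to the solved human-TBP case.
# Equation 1 links relative transcription efficiency F to K_D in nM
# (K_D = a1 - b1*F); equation 2 maps human -ln(K_D) onto the plant scale
# (-ln K_D,plant = a2 + b2 * (-ln K_D,human)).  K_D logarithms are taken of
# the numeric value in nM, so K_D = 1 nM corresponds to -ln K_D = 0.

#' Rescaling coefficients
#'
#' Defaults are the published calibration: `a1 = 1.1` nM, `b1 = 0.9` nM per
#' unit of relative transcription efficiency, `a2 = 7.0` ln units,
#' `b2 = 0.6` (dimensionless slope of the human-to-plant map).
#'
#' @param a1 intercept of the efficiency-to-K_D map, nM (> 0).
#' @param b1 slope magnitude of the same map, nM per unit F (> 0).
#' @param a2 intercept of the human-to-plant map, ln units.
#' @param b2 slope of the human-to-plant map (> 0).
#' @param kd_floor optional positive clamp, nM: when set, non-positive K_D
#'   values from the linear map are clamped here (with a warning) instead of
#'   raising an error.
#' @return object of class `RescaleParameters`.
#' @export
rescale_parameters <- function(a1 = 1.1, b1 = 0.9, a2 = 7.0, b2 = 0.6,
                               kd_floor = NULL) {
  stopifnot(is.numeric(a1), a1 > 0, is.numeric(b1), b1 > 0,
            is.numeric(a2), is.numeric(b2), b2 > 0)
  if (!is.null(kd_floor)) stopifnot(is.numeric(kd_floor), kd_floor > 0)
  structure(list(a1 = a1, b1 = b1, a2 = a2, b2 = b2, kd_floor = kd_floor),
            class = "RescaleParameters")
}

#' @export
print.RescaleParameters <- function(x, ...) {
  cat(sprintf("RescaleParameters: K_D[nM] = %g - %g*F;  -ln(K_D,plant) = %g + %g*(-ln K_D,human)\n",
              x$a1, x$b1, x$a2, x$b2))
  invisible(x)
}

#' Convert relative transcription efficiency to K_D (nM) and back
#'
#' `kd_nM_from_efficiency()` applies the linear calibration
#' `K_D = a1 - b1*F`; with the default coefficients, `F = 0` gives 1.1 nM
#' and each unit of F lowers K_D by 0.9 nM.  Because the map is linear,
#' efficiencies at or above `a1/b1` would imply a non-positive dissociation
#' constant: this is an error unless `kd_floor` is set in `rp`, in which
#' case the value is clamped with a warning.  `efficiency_from_kd_nM()` is
#' the exact inverse.
#'
#' @param F relative transcription efficiency (dimensionless), vectorized.
#' @param kd dissociation constant in nM (> 0), vectorized.
#' @param rp [rescale_parameters()].
#' @return numeric vector (nM, or efficiency units).
#' @examples
#' kd_nM_from_efficiency(0)    # 1.1 nM
#' efficiency_from_kd_nM(1.1)  # 0
#' @export
kd_nM_from_efficiency <- function(F, rp = rescale_parameters()) {
  stopifnot(is.numeric(F), all(is.finite(F)))
  kd <- rp$a1 - rp$b1 * F
  if (any(kd <= 0)) {
    if (is.null(rp$kd_floor)) {
      stop(sprintf("efficiency F >= %.6g implies a non-positive K_D under the linear map; set kd_floor to clamp instead",
                   rp$a1 / rp$b1))
    }
    warning(sprintf("%d non-positive K_D value(s) clamped to the floor %g nM",
                    sum(kd <= 0), rp$kd_floor))
    kd <- pmax(kd, rp$kd_floor)
  }
  kd
}

#' @rdname kd_nM_from_efficiency
#' @export
efficiency_from_kd_nM <- function(kd, rp = rescale_parameters()) {
  stopifnot(is.numeric(kd), all(is.finite(kd)))
  if (any(kd <= 0)) stop("K_D must be positive (nM)")
  (rp$a1 - kd) / rp$b1
}

#' Map a human-scale affinity onto the plant-TBP scale
#'
#' Applies `-ln(K_D,plant) = a2 + b2 * (-ln K_D,human)` — equivalently
#' `a2 - b2 * ln(K_D,human)` — a strictly increasing affine map, so promoter
#' rankings are preserved exactly.
#'
#' @param minus_ln_kd_hs human-scale \eqn{-\ln(K_D)} (ln units of nM),
#'   vectorized.
#' @param rp [rescale_parameters()].
#' @return plant-scale \eqn{-\ln(K_D)} in ln units.
#' @examples
#' rescale_hs_to_at(0)  # 7.0: a 1 nM human K_D maps to e^-7 nM plant K_D
#' @export
rescale_hs_to_at <- function(minus_ln_kd_hs, rp = rescale_parameters()) {
  stopifnot(is.numeric(minus_ln_kd_hs), all(is.finite(minus_ln_kd_hs)))
  rp$a2 + rp$b2 * minus_ln_kd_hs
}

#' Predict plant-TBP affinity of a promoter
#'
#' Composes [estimate_affinity()] (human scale) with [rescale_hs_to_at()];
#' the estimate's standard deviation is propagated through the linear map
#' (multiplied by `b2`).
#'
#' @inheritParams window_scores
#' @param rp [rescale_parameters()].
#' @return `AffinityEstimate` on the plant scale (`scale = "atTBP"`), with
#'   the untransformed human-scale value kept in `human_minus_ln_kd`.
#' @export
predict_plant_affinity <- function(p, m, rp = rescale_parameters()) {
  est <- estimate_affinity(p, m)
  est$human_minus_ln_kd <- est$minus_ln_kd
  est$minus_ln_kd <- rescale_hs_to_at(est$minus_ln_kd, rp)
  est$sd <- rp$b2 * est$sd
  est$scale <- "atTBP"
  est
}

#' Re-calibrate a linear map from paired data
#'
#' Ordinary least squares, used to re-derive either rescaling equation from
#' new paired measurements (e.g. predicted K_D against measured efficiency).
#'
#' @param x,y equal-length numeric vectors, `n >= 3`, `x` not constant.
#' @param level confidence level for the coefficient intervals.
#' @return object of class `linear_calibration`: `intercept`, `slope`,
#'   `se_intercept`, `se_slope`, `ci` (2 x 2 matrix of confidence limits),
#'   `sigma` (residual standard deviation), `r_squared`, `n`, and the
#'   underlying `lm` fit.
#' @examples
#' F <- seq(0, 1, by = 0.25)
#' calibrate_linear(F, 1.1 - 0.9 * F)$slope  # -0.9
#' @export
calibrate_linear <- function(x, y, level = 0.95) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L) stop("at least 3 pairs are required")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (stats::var(x) == 0) stop("x is constant: the slope is unidentifiable")
  dat <- data.frame(x = x, y = y)
  fit <- stats::lm(y ~ x, data = dat)
  # noise-free calibrations are legitimate here; silence the zero-residual note
  sm <- suppressWarnings(summary(fit))
  ci <- suppressWarnings(stats::confint(fit, level = level))
  structure(
    list(intercept = unname(stats::coef(fit)[1L]),
         slope = unname(stats::coef(fit)[2L]),
         se_intercept = sm$coefficients[1L, 2L],
         se_slope = sm$coefficients[2L, 2L],
         ci = ci, ci_level = level,
         sigma = sm$sigma, r_squared = sm$r.squared,
         n = length(x), fit = fit),
    class = "linear_calibration"
  )
}

#' @export
print.linear_calibration <- function(x, ...) {
  cat(sprintf("linear_calibration (n = %d): y = %.6g + %.6g x  (R^2 = %.4f)\n",
              x$n, x$intercept, x$slope, x$r_squared))
  cat(sprintf("  %g%% CI intercept [%.6g, %.6g], slope [%.6g, %.6g]\n",
              100 * x$ci_level, x$ci[1, 1], x$ci[1, 2], x$ci[2, 1], x$ci[2, 2]))
  invisible(x)
}
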