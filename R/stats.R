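# Verification statistics: Pearson r, Spearman R (Pearson on mid-ranks),
# Kendall tau-b, and Goodman-Kruskal gamma, each with a two-sided p-value,
# plus OLS regression with a confidence band for the mean response.
#
# Significance conventions: Pearson and Spearman use the t statistic with
# n - 2 df; tau uses the normal approximation to S = C - D with the
# tie-corrected variance; gamma uses the normal approximation with its
# consistent null-hypothesis asymptotic standard error
#   ASE0 = sqrt(sum((C_i - D_i)^2) - 4 S^2 / n) / (C + D),
# where C_i/D_i count concordances of observation i over both pair
# directions.  For n <= 8, tau and gamma switch to the exact permutation
# distribution over all n! reorderings of y.

# Pairwise concordance bookkeeping shared by tau and gamma.
concordance_counts <- function(x, y) {
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  pr <- dx * dy
  Ci <- rowSums(pr > 0)          # both directions: each pair counted twice
  Di <- rowSums(pr < 0)
  n <- length(x)
  tx <- table(x); ty <- table(y)
  list(
    n = n,
    C = sum(Ci) / 2, D = sum(Di) / 2,
    Ci = Ci, Di = Di,
    ties_x = sum(tx * (tx - 1)) / 2,
    ties_y = sum(ty * (ty - 1)) / 2,
    tx = as.numeric(tx), ty = as.numeric(ty)
  )
}

kendall_tau_b <- function(cc) {
  n0 <- cc$n * (cc$n - 1) / 2
  denom <- sqrt((n0 - cc$ties_x) * (n0 - cc$ties_y))
  if (denom == 0) return(NA_real_)
  (cc$C - cc$D) / denom
}

goodman_kruskal_gamma <- function(cc) {
  if (cc$C + cc$D == 0) return(NA_real_)
  (cc$C - cc$D) / (cc$C + cc$D)
}

# Tie-corrected variance of S = C - D under the null (Kendall).
kendall_var_s <- function(cc) {
  n <- cc$n; t <- cc$tx; u <- cc$ty
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(t * (t - 1) * (2 * t + 5))
  vu <- sum(u * (u - 1) * (2 * u + 5))
  v1 <- sum(t * (t - 1)) * sum(u * (u - 1)) / (2 * n * (n - 1))
  v2 <- sum(t * (t - 1) * (t - 2)) * sum(u * (u - 1) * (u - 2)) /
    (9 * n * (n - 1) * (n - 2))
  (v0 - vt - vu) / 18 + v1 + v2
}

gamma_ase0 <- function(cc) {
  S <- cc$C - cc$D
  inner <- sum((cc$Ci - cc$Di)^2) - 4 * S^2 / cc$n
  if (cc$C + cc$D == 0 || inner <= 0) return(NA_real_)
  sqrt(inner) / (cc$C + cc$D)
}

# All permutations of 1..n as an (n! x n) integer matrix.
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- vector("list", n)
  idx <- seq_len(n)
  for (k in idx) {
    rest <- idx[-k]
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub)))
  }
  do.call(rbind, out)
}

# Exact permutation p-values for |tau| and |gamma| (small n).
rank_permutation_p <- function(x, y, tau_obs, gamma_obs) {
  n <- length(x)
  P <- permutations_of(n)
  pair <- which(upper.tri(diag(n)), arr.ind = TRUE)
  dx <- sign(x[pair[, 1L]] - x[pair[, 2L]])
  yi <- matrix(y[P[, pair[, 1L]]], nrow = nrow(P))
  yj <- matrix(y[P[, pair[, 2L]]], nrow = nrow(P))
  pr <- sign(yi - yj) * matrix(dx, nrow(P), length(dx), byrow = TRUE)
  C <- rowSums(pr > 0); D <- rowSums(pr < 0)
  S <- C - D
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  denom <- sqrt((n0 - sum(tx * (tx - 1)) / 2) * (n0 - sum(ty * (ty - 1)) / 2))
  eps <- 1e-12
  p_tau <- if (is.na(tau_obs) || denom == 0) NA_real_ else {
    mean(abs(S / denom) >= abs(tau_obs) - eps)
  }
  gperm <- ifelse(C + D > 0, S / (C + D), NA_real_)
  p_gamma <- if (is.na(gamma_obs)) NA_real_ else {
    mean(abs(gperm) >= abs(gamma_obs) - eps, na.rm = TRUE)
  }
  list(p_tau = p_tau, p_gamma = p_gamma)
}

# Two-sided p from a correlation coefficient via t with n - 2 df.
cor_t_p <- function(r, n) {
  if (is.na(r)) return(NA_real_)
  if (abs(r) >= 1) return(.Machine$double.xmin)
  t <- r * sqrt((n - 2) / (1 - r^2))
  max(2 * stats::pt(-abs(t), df = n - 2), .Machine$double.xmin)
}

norm_p <- function(z) {
  if (is.na(z)) return(NA_real_)
  max(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
}

#' Correlation battery for predicted vs measured effects
#'
#' Computes the four association measures used to verify affinity
#' predictions against measured expression: Pearson's linear correlation r,
#' Spearman's rank correlation R (Pearson on mid-ranks), Kendall's
#' tie-corrected \eqn{\tau_b}, and the Goodman–Kruskal \eqn{\gamma}
#' \eqn{(C - D)/(C + D)} over concordant and discordant pairs (tied pairs
#' ignored), each with a two-sided p-value.
#'
#' If either variable has zero variance the coefficients are undefined and
#' reported as `NA` with an explanatory `note` (never silently zero).
#'
#' @param x,y equal-length finite numeric vectors, `n >= 3`.
#' @param exact_n permutation-exactness threshold: for `n <=
#'   exact_n` (default 8) the tau and gamma p-values come from the full
#'   permutation distribution instead of the normal approximation.
#' @return object of class `CorrelationReport` with fields `n`, `r`, `p_r`,
#'   `R`, `p_R`, `tau`, `p_tau`, `gamma`, `p_gamma`, and `note` (`NULL`
#'   unless coefficients are undefined).
#' @examples
#' x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
#' correlation_report(x, y)$gamma  # 4/6
#' @export
correlation_report <- function(x, y, exact_n = 8L) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("at least 3 observations are required")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(structure(
      list(n = n, r = NA_real_, p_r = NA_real_, R = NA_real_, p_R = NA_real_,
           tau = NA_real_, p_tau = NA_real_, gamma = NA_real_,
           p_gamma = NA_real_,
           note = "undefined: zero variance in x and/or y"),
      class = "CorrelationReport"))
  }
  r <- stats::cor(x, y)
  R <- stats::cor(rank(x), rank(y))
  cc <- concordance_counts(x, y)
  tau <- kendall_tau_b(cc)
  gam <- goodman_kruskal_gamma(cc)
  if (n <= exact_n) {
    pp <- rank_permutation_p(x, y, tau, gam)
    p_tau <- pp$p_tau; p_gamma <- pp$p_gamma
  } else {
    vS <- kendall_var_s(cc)
    p_tau <- if (is.na(tau) || vS <= 0) NA_real_ else {
      norm_p((cc$C - cc$D) / sqrt(vS))
    }
    ase0 <- gamma_ase0(cc)
    p_gamma <- if (is.na(gam)) NA_real_ else if (gam == 0) 1 else {
      if (is.na(ase0)) .Machine$double.xmin else norm_p(gam / ase0)
    }
  }
  structure(
    list(n = n, r = r, p_r = cor_t_p(r, n), R = R, p_R = cor_t_p(R, n),
         tau = tau, p_tau = p_tau, gamma = gam, p_gamma = p_gamma,
         note = NULL),
    class = "CorrelationReport"
  )
}

#' @export
print.CorrelationReport <- function(x, ...) {
  cat(sprintf("CorrelationReport (n = %d)\n", x$n))
  if (!is.null(x$note)) {
    cat("  ", x$note, "\n")
    return(invisible(x))
  }
  cat(sprintf("  Pearson  r = %8.4f  p = %.3g\n", x$r, x$p_r))
  cat(sprintf("  Spearman R = %8.4f  p = %.3g\n", x$R, x$p_R))
  cat(sprintf("  Kendall  tau = %6.4f  p = %.3g\n", x$tau, x$p_tau))
  cat(sprintf("  G-K      gamma = %4.4f  p = %.3g\n", x$gamma, x$p_gamma))
  invisible(x)
}

#' Linear regression with a confidence band
#'
#' Ordinary least squares of `y` on `x` with standard errors from the
#' residual variance and a pointwise confidence band for the mean response
#' based on the t distribution with `n - 2` degrees of freedom — the
#' dashed-line-plus-band display conventionally drawn through
#' prediction-vs-measurement scatter plots.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`, `x` not constant.
#' @param level band confidence level (default 0.95).
#' @return object of class `RegressionFit`: `intercept`, `slope`,
#'   `se_intercept`, `se_slope`, `sigma`, `ci_level`, `n`, the `lm` object
#'   in `fit`, and `band(newx)` — a function returning a data frame with
#'   columns `x`, `fit`, `lwr`, `upr`.
#' @examples
#' f <- fit_with_ci(0:5, 7.0 + 0.6 * (0:5))
#' c(f$intercept, f$slope)
#' @export
fit_with_ci <- function(x, y, level = 0.95) {
  stopifnot(is.numeric(level), length(level) == 1L, level > 0, level < 1)
  cal <- calibrate_linear(x, y, level = level)
  fit <- cal$fit
  band <- function(newx) {
    pr <- stats::predict(fit, newdata = data.frame(x = newx),
                         interval = "confidence", level = level)
    data.frame(x = newx, fit = pr[, "fit"], lwr = pr[, "lwr"],
               upr = pr[, "upr"])
  }
  structure(
    list(intercept = cal$intercept, slope = cal$slope,
         se_intercept = cal$se_intercept, se_slope = cal$se_slope,
         sigma = cal$sigma, r_squared = cal$r_squared,
         ci_level = level, n = cal$n, fit = fit, band = band),
    class = "RegressionFit"
  )
}

#' @export
print.RegressionFit <- function(x, ...) {
  cat(sprintf("RegressionFit (n = %d): y = %.6g + %.6g x, sigma = %.4g, %g%% band\n",
              x$n, x$intercept, x$slope, x$sigma, 100 * x$ci_level))
  invisible(x)
}

#' Verify one dataset: predictions against measurements
#'
#' Recomputes the plant-scale \eqn{-\ln(K_D)} prediction for every variant
#' in the dataset from its sequence, correlates the predictions with the
#' measured expression values ([correlation_report()]), and fits the
#' regression line with its confidence band ([fit_with_ci()]).  Datasets
#' with fewer than five variants are refused: five is the minimum required
#' for an adequate statistical analysis of a promoter-variant family.
#'
#' @param d a `tata_dataset` (see [tata_dataset()], [read_kb()],
#'   [generate_dataset()]).
#' @param m [affinity_model()].
#' @param rp [rescale_parameters()].
#' @param level confidence level for the regression band.
#' @return object of class `verification`: `dataset_id`, `n`, `predicted`,
#'   `expression`, `report` (`CorrelationReport`), `regression`
#'   (`RegressionFit`).
#' @export
verify_dataset <- function(d, m, rp = rescale_parameters(), level = 0.95) {
  stopifnot(inherits(d, "tata_dataset"))
  if (d$n_variants < 5L) {
    stop(sprintf("dataset %s has %d variants; at least five variants of a promoter are required for an adequate statistical analysis",
                 d$dataset_id, d$n_variants))
  }
  predicted <- vapply(seq_len(nrow(d$records)), function(i) {
    p <- validate_promoter(d$records$seq[i], id = d$records$variant_label[i],
                           expected_length = NULL)
    predict_plant_affinity(p, m, rp)$minus_ln_kd
  }, numeric(1L))
  # equal sequences must yield exactly tied predictions: snap away
  # summation-order noise far below the estimate sd
  predicted <- round(predicted, 9L)
  expression <- d$records$expression
  rep <- correlation_report(predicted, expression)
  reg <- if (stats::var(predicted) > 0) {
    fit_with_ci(predicted, expression, level = level)
  } else NULL
  structure(
    list(dataset_id = d$dataset_id, n = d$n_variants,
         predicted = predicted, expression = expression,
         report = rep, regression = reg),
    class = "verification"
  )
}

#' @export
print.verification <- function(x, ...) {
  cat(sprintf("Verification of dataset %s (n = %d variants)\n",
              x$dataset_id, x$n))
  print(x$report)
  if (!is.null(x$regression)) print(x$regression)
  invisible(x)
}

#' One TSV report row per verified dataset
#'
#' @param v a `verification` object from [verify_dataset()].
#' @return one-row data frame with columns `dataset_id`, `n`, `r`, `p_r`,
#'   `R`, `p_R`, `tau`, `p_tau`, `gamma`, `p_gamma`, `intercept`, `slope`.
#' @export
verification_row <- function(v) {
  stopifnot(inherits(v, "verification"))
  r <- v$report
  data.frame(
    dataset_id = v$dataset_id, n = v$n,
    r = r$r, p_r = r$p_r, R = r$R, p_R = r$p_R,
    tau = r$tau, p_tau = r$p_tau, gamma = r$gamma, p_gamma = r$p_gamma,
    intercept = if (is.null(v$regression)) NA_real_ else v$regression$intercept,
    slope = if (is.null(v$regression)) NA_real_ else v$regression$slope,
    stringsAsFactors = FALSE
  )
}

#' Write a verification report for several datasets
#'
#' @param verifications list of `verification` objects.
#' @param path output TSV path.
#' @param digits significant digits used to format numeric columns (fixed
#'   formatting keeps reports byte-stable across runs).
#' @return `path`, invisibly.
#' @export
write_verification_report <- function(verifications, path, digits = 6L) {
  rows <- do.call(rbind, lapply(verifications, verification_row))
  num <- vapply(rows, is.numeric, logical(1L)) & names(rows) != "n"
  rows[num] <- lapply(rows[num], function(col) {
    ifelse(is.na(col), "NA", sprintf("%.*g", digits, col))
  })
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
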