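# Pairwise wildtype/mutant comparison: the difference of the two
# plant-scale affinity estimates divided by its standard error, against the
# standard normal.  Because the human-to-plant map is affine and the
# estimate sd is propagated through it, the Z value is identical whichever
# scale it is computed on.

#' Compare two promoter variants
#'
#' Estimates plant-scale \eqn{-\ln(K_D)} for both sequences and computes
#' \deqn{Z = (A_2 - A_1) / \sqrt{sd_1^2 + sd_2^2}}
#' with a two-sided p-value from the standard normal.  Under the
#' affinity-expression monotonicity assumption (stronger TBP binding means
#' higher expression), a significantly positive Z predicts expression
#' *excess* for the second promoter relative to the first, a significantly
#' negative Z predicts *deficiency*, and otherwise the change is
#' *insignificant*.
#'
#' @param first,second `PromoterSequence` objects or plain sequence strings
#'   (the first is conventionally the wildtype/prototype).
#' @param m [affinity_model()]; its `epsilon` must be positive.
#' @param rp [rescale_parameters()].
#' @param alpha two-sided significance threshold in (0, 1), default 0.05.
#' @return object of class `ComparisonResult`: `z`, `p_value`, `verdict`
#'   (`"deficiency"`, `"excess"` or `"insignificant"`), `delta`
#'   (second minus first, plant-scale ln units), `alpha`, and the two
#'   plant-scale `AffinityEstimate`s in `estimates`.
#' @examples
#' m <- affinity_model()
#' wt <- paste0(strrep("GC", 21L), "TCACTATATATAG", strrep("CT", 17L), "CTC")
#' cmp <- compare_promoters(wt, wt, m)
#' cmp$verdict  # identical sequences: insignificant
#' @export
compare_promoters <- function(first, second, m = affinity_model(),
                              rp = rescale_parameters(), alpha = 0.05) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  e1 <- predict_plant_affinity(as_promoter(first, id = "first"), m, rp)
  e2 <- predict_plant_affinity(as_promoter(second, id = "second"), m, rp)
  pooled_var <- e1$sd^2 + e2$sd^2
  if (pooled_var <= 0) stop("estimate standard deviations are zero; epsilon must be positive")
  delta <- e2$minus_ln_kd - e1$minus_ln_kd
  z <- delta / sqrt(pooled_var)
  p <- 2 * stats::pnorm(-abs(z))
  verdict <- if (p >= alpha) {
    "insignificant"
  } else if (z > 0) "excess" else "deficiency"
  structure(
    list(z = z, p_value = p, verdict = verdict, delta = delta,
         alpha = alpha, pooled_sd = sqrt(pooled_var),
         estimates = list(first = e1, second = e2)),
    class = "ComparisonResult"
  )
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat("Promoter comparison (plant-TBP scale)\n")
  cat(sprintf("  1st '%s': -ln(K_D) = %.4f;  2nd '%s': -ln(K_D) = %.4f\n",
              x$estimates$first$id, x$estimates$first$minus_ln_kd,
              x$estimates$second$id, x$estimates$second$minus_ln_kd))
  cat(sprintf("  Z = %.4f, p = %.4g (alpha = %g)\n", x$z, x$p_value, x$alpha))
  cat(sprintf("  verdict: predicted expression %s\n", x$verdict))
  invisible(x)
}

# One-row data frame for TSV output of a comparison.
comparison_row <- function(x) {
  data.frame(
    first_id = x$estimates$first$id,
    second_id = x$estimates$second$id,
    minus_ln_kd_1 = x$estimates$first$minus_ln_kd,
    minus_ln_kd_2 = x$estimates$second$minus_ln_kd,
    sd = x$pooled_sd,
    z = x$z,
    p_value = x$p_value,
    verdict = x$verdict,
    stringsAsFactors = FALSE
  )
}
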