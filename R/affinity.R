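# The three-step affinity model: slide (non-specific attraction averaged
# over every window), stop (best PWM window), bend (deformability of the
# best window).  Coordinates are 0-based half-open offsets from the 5' end
# of the supplied fragment.

#' Score every window of a promoter
#'
#' Slides a `window_w`-bp window along the fragment and, for each window,
#' reports the PWM sum (`stop_score`), the non-specific sliding contribution
#' (`slide_score`, summed over the window's `window_w - 1` dinucleotide
#' steps), and the bendability contribution (`bend_score`, same steps).
#' With `scan_both_strands = TRUE` in the model, windows of the reverse
#' complement are appended with strand `"-"`; their `start` is still given
#' in the forward coordinates of the input fragment.
#'
#' @param p a `PromoterSequence` (or plain string, validated on the fly).
#' @param m [affinity_model()] parameters.
#' @return data frame with one row per scanned window, columns `start`
#'   (0-based), `strand`, `window` (the scored string; reverse-complemented
#'   for `"-"`), `stop_score`, `slide_score`, `bend_score`; forward windows
#'   first, each strand in ascending `start` order.
#' @examples
#' m <- affinity_model()
#' p <- validate_promoter(strrep("ACGT", 23L), "toy", expected_length = 92)
#' nrow(window_scores(p, m))  # 92 - 15 + 1
#' @export
window_scores <- function(p, m) {
  p <- as_promoter(p)
  stopifnot(inherits(m, "AffinityModelParameters"))
  if (p$length < m$window_w) {
    stop(sprintf("sequence '%s' (%d bp) is shorter than the %d bp scanning window",
                 p$id, p$length, m$window_w))
  }
  fwd <- strand_windows(p$seq, m)
  fwd$strand <- "+"
  if (!m$scan_both_strands) {
    out <- fwd
  } else {
    rev <- strand_windows(rc_string(p$seq), m)
    # map start back to forward coordinates of the input fragment
    rev$start <- p$length - m$window_w - rev$start
    rev <- rev[order(rev$start), , drop = FALSE]
    rev$strand <- "-"
    out <- rbind(fwd, rev)
  }
  rownames(out) <- NULL
  out[, c("start", "strand", "window", "stop_score", "slide_score",
          "bend_score")]
}

# Score all forward windows of one strand; start is 0-based.
strand_windows <- function(seq, m) {
  w <- m$window_w
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  idx <- match(chars, DNA_BASES)
  starts <- 0:(L - w)
  stop_score <- numeric(length(starts))
  for (j in seq_len(w)) {
    stop_score <- stop_score + m$pwm[cbind(idx[starts + j], j)]
  }
  dn <- paste0(chars[-L], chars[-1L])
  slide_cs <- c(0, cumsum(unname(m$slide_scale[dn])))
  bend_cs <- c(0, cumsum(unname(m$bend_scale[dn])))
  # dinucleotide steps covered by window at start s: s+1 .. s+w-1 (1-based)
  data.frame(
    start = starts,
    window = substring(seq, starts + 1L, starts + w),
    stop_score = stop_score,
    slide_score = slide_cs[starts + w] - slide_cs[starts + 1L],
    bend_score = bend_cs[starts + w] - bend_cs[starts + 1L],
    stringsAsFactors = FALSE
  )
}

#' Estimate TBP binding affinity of a promoter (human-TBP scale)
#'
#' Combines the three steps of the approximation into a single
#' \eqn{-\ln(K_D)} score: `slide` = mean `slide_score` over all scanned
#' windows (the protein samples the whole fragment non-specifically),
#' `stop` = maximal `stop_score` (the protein settles on the best binding
#' site), `bend` = `bend_score` of that best window (complex fixation by DNA
#' bending); the estimate is `c0 + c1*slide + c2*stop + c3*bend` with
#' standard deviation `epsilon`.
#'
#' Ties for the best window are resolved deterministically and
#' strand-symmetrically: smallest scored window string first (C collation),
#' then lowest start, then `+` before `-`.
#'
#' @inheritParams window_scores
#' @return object of class `AffinityEstimate`: `id`, `minus_ln_kd` (ln
#'   units, \eqn{-\ln K_D} for human TBP), `sd` (= `epsilon`),
#'   `best_window` (one-row data frame), `components` (named vector slide /
#'   stop / bend), `scale = "hsTBP"`.
#' @examples
#' est <- estimate_affinity(strrep("ACGT", 23L), affinity_model())
#' est$minus_ln_kd
#' @export
estimate_affinity <- function(p, m) {
  p <- as_promoter(p)
  ws <- window_scores(p, m)
  best <- ws[order(-ws$stop_score, ws$window, ws$start, ws$strand,
                   method = "radix"), , drop = FALSE][1L, , drop = FALSE]
  rownames(best) <- NULL
  comp <- c(slide = mean(ws$slide_score),
            stop = best$stop_score,
            bend = best$bend_score)
  structure(
    list(id = p$id,
         minus_ln_kd = unname(m$c0 + m$c1 * comp[["slide"]] +
                                m$c2 * comp[["stop"]] + m$c3 * comp[["bend"]]),
         sd = m$epsilon,
         best_window = best,
         components = comp,
         scale = "hsTBP"),
    class = "AffinityEstimate"
  )
}

#' @export
print.AffinityEstimate <- function(x, ...) {
  cat(sprintf("AffinityEstimate '%s' [%s scale]\n", x$id, x$scale))
  cat(sprintf("  -ln(K_D) = %.4f (sd %.3f) ln units\n", x$minus_ln_kd, x$sd))
  cat(sprintf("  components: slide %.4f, stop %.4f, bend %.4f\n",
              x$components[["slide"]], x$components[["stop"]],
              x$components[["bend"]]))
  cat(sprintf("  best window: start %d (%s strand) %s\n",
              x$best_window$start, x$best_window$strand, x$best_window$window))
  invisible(x)
}
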