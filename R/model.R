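# Affinity model parameters: PWM, dinucleotide scales, combination
# coefficients.  All pieces are data, loadable from plain-text tables, so the
# model can be re-parameterized without touching code.

PLANT_TATA_CONSENSUS <- "TCACTATATATAG"

#' Build a log-odds PWM from a consensus word
#'
#' Constructs a 4 x `window_w` position weight matrix (rows A, C, G, T; ln
#' units) from a single consensus sequence: at each consensus column the
#' consensus base gets weight `1 + pseudocount` and every other base
#' `pseudocount`, normalized and log-odds-transformed against a uniform
#' background.  If `window_w` exceeds the consensus length, the consensus is
#' centred and flanking columns are uninformative (all-zero log-odds).
#'
#' The default consensus is the plant TATA-box consensus
#' `tcacTATATATAg`.
#'
#' @param consensus consensus word (case-insensitive, A/C/G/T).
#' @param window_w total matrix width in bp (>= consensus length).
#' @param pseudocount added to every base count at consensus columns.
#' @param background background base probability (uniform, default 0.25).
#' @return numeric matrix, 4 rows named A,C,G,T, `window_w` columns.
#' @examples
#' pwm <- pwm_from_consensus()
#' dim(pwm)
#' @export
pwm_from_consensus <- function(consensus = PLANT_TATA_CONSENSUS,
                               window_w = 15L, pseudocount = 0.25,
                               background = 0.25) {
  cons <- strsplit(toupper(consensus), "", fixed = TRUE)[[1L]]
  if (!all(cons %in% DNA_BASES)) stop("consensus must be A/C/G/T only")
  k <- length(cons)
  window_w <- as.integer(window_w)
  if (window_w < k) stop("window_w must be >= consensus length (", k, ")")
  left <- (window_w - k) %/% 2L
  pwm <- matrix(0, nrow = 4L, ncol = window_w,
                dimnames = list(DNA_BASES, NULL))
  total <- 1 + 4 * pseudocount
  for (j in seq_len(k)) {
    p <- rep(pseudocount / total, 4L)
    p[match(cons[j], DNA_BASES)] <- (1 + pseudocount) / total
    pwm[, left + j] <- log(p / background)
  }
  pwm
}

#' Read / write a PWM as a plain-text table
#'
#' The file format is tab-separated with a header `pos A C G T`: one row per
#' matrix column, ln-unit log-odds values, `.` decimal separator.
#'
#' @param path file path.
#' @return `read_pwm()` returns the 4 x w matrix (rows A,C,G,T);
#'   `write_pwm()` returns `path` invisibly.
#' @export
read_pwm <- function(path) {
  if (!file.exists(path)) stop("PWM file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("pos", DNA_BASES)
  if (!all(need %in% names(tab))) {
    stop("PWM file must have columns: ", paste(need, collapse = ", "))
  }
  tab <- tab[order(tab$pos), , drop = FALSE]
  pwm <- t(as.matrix(tab[, DNA_BASES]))
  rownames(pwm) <- DNA_BASES
  colnames(pwm) <- NULL
  storage.mode(pwm) <- "double"
  pwm
}

#' @rdname read_pwm
#' @param pwm 4 x w numeric matrix with rows A,C,G,T.
#' @export
write_pwm <- function(pwm, path) {
  stopifnot(is.matrix(pwm), nrow(pwm) == 4L)
  tab <- data.frame(pos = seq_len(ncol(pwm)), t(pwm))
  names(tab) <- c("pos", DNA_BASES)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 16-value dinucleotide scale from a plain-text table
#'
#' Tab-separated, header `dinucleotide value`; all 16 dinucleotides must be
#' present exactly once.
#'
#' @param path file path.
#' @return named numeric vector over the 16 dinucleotides.
#' @export
read_dinucleotide_scale <- function(path) {
  if (!file.exists(path)) stop("scale file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("dinucleotide", "value") %in% names(tab))) {
    stop("scale file must have columns: dinucleotide, value")
  }
  v <- stats::setNames(as.numeric(tab$value), toupper(tab$dinucleotide))
  check_dinucleotide_scale(v, path)
  v[DINUCLEOTIDES]
}

check_dinucleotide_scale <- function(v, what = "scale") {
  if (!all(DINUCLEOTIDES %in% names(v)) || anyNA(v[DINUCLEOTIDES])) {
    stop(what, " must define a finite value for all 16 dinucleotides")
  }
  invisible(TRUE)
}

#' Default dinucleotide scales
#'
#' `default_slide_scale()` is the non-specific (sliding) affinity
#' contribution: +1 for the AT-rich steps TA/AT/AA/TT, 0 otherwise, an
#' AT-richness proxy for weak sequence-independent TBP-DNA attraction.
#' `default_bend_scale()` loads the bendability table shipped with the
#' package (`inst/extdata/bend_dinucleotide.tsv`), a strand-symmetric
#' deformability ranking of the 16 base steps with the pyrimidine-purine
#' steps TA and CA/TG most flexible.  Both are surrogate parameterizations,
#' replaceable via [affinity_model()] or a config file.
#'
#' @return named numeric vector over the 16 dinucleotides.
#' @export
default_slide_scale <- function() {
  v <- stats::setNames(numeric(16L), DINUCLEOTIDES)
  v[c("TA", "AT", "AA", "TT")] <- 1
  v
}

#' @rdname default_slide_scale
#' @export
default_bend_scale <- function() {
  read_dinucleotide_scale(
    system.file("extdata", "bend_dinucleotide.tsv", package = "planttata",
                mustWork = TRUE))
}

#' Affinity model parameters
#'
#' Bundles everything [estimate_affinity()] needs: the PWM used in the
#' "stop" step, the two dinucleotide scales used in the "slide" and "bend"
#' steps, the linear combination coefficients, the per-estimate standard
#' deviation, and the strand-scanning flag.
#'
#' The affinity score is
#' \deqn{-\ln K_D = c_0 + c_1\,\mathrm{slide} + c_2\,\mathrm{stop} +
#'   c_3\,\mathrm{bend}}
#' where `slide` is the mean non-specific score over all scanned windows,
#' `stop` the maximal PWM score, and `bend` the bendability of the maximal
#' window.
#'
#' @param window_w scanning window width in bp (default 15, a TBP
#'   footprint-scale window).
#' @param pwm 4 x `window_w` log-odds matrix, rows A,C,G,T (default: built
#'   from the plant TATA consensus by [pwm_from_consensus()]).
#' @param slide_scale,bend_scale named 16-value dinucleotide vectors.
#' @param c0,c1,c2,c3 combination coefficients (ln units).
#' @param epsilon standard deviation of one \eqn{-\ln K_D} estimate, ln
#'   units; must be > 0 (the Z comparator divides by it).
#' @param scan_both_strands if `TRUE`, windows on the reverse complement are
#'   scanned as well; default `FALSE` (promoter orientation is fixed by the
#'   TSS).
#' @return object of class `AffinityModelParameters`.
#' @examples
#' m <- affinity_model()
#' m$window_w
#' @export
affinity_model <- function(window_w = 15L,
                           pwm = NULL,
                           slide_scale = default_slide_scale(),
                           bend_scale = default_bend_scale(),
                           c0 = 0, c1 = 1, c2 = 1, c3 = 1,
                           epsilon = 0.5,
                           scan_both_strands = FALSE) {
  window_w <- as.integer(window_w)
  if (window_w < 2L) stop("window_w must be >= 2")
  if (is.null(pwm)) pwm <- pwm_from_consensus(window_w = window_w)
  if (!is.matrix(pwm) || nrow(pwm) != 4L ||
      !identical(rownames(pwm), DNA_BASES)) {
    stop("pwm must be a 4-row matrix with rows named A, C, G, T")
  }
  if (ncol(pwm) != window_w) {
    stop("pwm has ", ncol(pwm), " columns but window_w is ", window_w)
  }
  check_dinucleotide_scale(slide_scale, "slide_scale")
  check_dinucleotide_scale(bend_scale, "bend_scale")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon <= 0) {
    stop("epsilon must be a single positive number")
  }
  structure(
    list(window_w = window_w, pwm = pwm,
         slide_scale = slide_scale[DINUCLEOTIDES],
         bend_scale = bend_scale[DINUCLEOTIDES],
         c0 = c0, c1 = c1, c2 = c2, c3 = c3,
         epsilon = epsilon,
         scan_both_strands = isTRUE(scan_both_strands)),
    class = "AffinityModelParameters"
  )
}

#' @export
print.AffinityModelParameters <- function(x, ...) {
  cat(sprintf("AffinityModelParameters: window %d bp, c = (%g, %g, %g, %g), epsilon = %g, strands = %s\n",
              x$window_w, x$c0, x$c1, x$c2, x$c3, x$epsilon,
              if (x$scan_both_strands) "both" else "forward"))
  invisible(x)
}

#' Read a model configuration file
#'
#' Plain two-column tab-separated `key<TAB>value` text.  Recognized keys:
#' `window_w`, `c0..c3`, `epsilon`, `scan_both_strands`, `pwm_file`,
#' `slide_scale_file`, `bend_scale_file` (paths resolved relative to the
#' config file), the rescale coefficients `a1`, `b1`, `a2`, `b2`, optional
#' `kd_floor`, and `alpha`.  Missing keys fall back to package defaults, so a
#' config may override any subset.
#'
#' @param path config file path.
#' @return list with elements `model` ([affinity_model()]), `rescale`
#'   ([rescale_parameters()]) and `alpha`.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  if (!all(c("key", "value") %in% names(tab))) {
    stop("config file must have columns: key, value")
  }
  kv <- stats::setNames(as.character(tab$value), tab$key)
  here <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(here, p)
  num <- function(key, default) {
    if (key %in% names(kv)) as.numeric(kv[[key]]) else default
  }
  window_w <- as.integer(num("window_w", 15L))
  pwm <- if ("pwm_file" %in% names(kv)) {
    read_pwm(resolve(kv[["pwm_file"]]))
  } else NULL
  slide <- if ("slide_scale_file" %in% names(kv)) {
    read_dinucleotide_scale(resolve(kv[["slide_scale_file"]]))
  } else default_slide_scale()
  bend <- if ("bend_scale_file" %in% names(kv)) {
    read_dinucleotide_scale(resolve(kv[["bend_scale_file"]]))
  } else default_bend_scale()
  model <- affinity_model(
    window_w = window_w, pwm = pwm, slide_scale = slide, bend_scale = bend,
    c0 = num("c0", 0), c1 = num("c1", 1), c2 = num("c2", 1),
    c3 = num("c3", 1), epsilon = num("epsilon", 0.5),
    scan_both_strands = isTRUE(toupper(kv["scan_both_strands"]) %in%
                                 c("TRUE", "1", "YES")))
  kd_floor <- if ("kd_floor" %in% names(kv)) as.numeric(kv[["kd_floor"]]) else NULL
  rescale <- rescale_parameters(a1 = num("a1", 1.1), b1 = num("b1", 0.9),
                                a2 = num("a2", 7.0), b2 = num("b2", 0.6),
                                kd_floor = kd_floor)
  list(model = model, rescale = rescale, alpha = num("alpha", 0.05))
}
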