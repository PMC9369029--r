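# Seeded generator of promoter-variant families shaped like the compiled
# experimental datasets: one wildtype with a planted TATA box plus mutants
# carrying point substitutions in/near the box or short spacer deletions,
# with expression linearly linked to predicted plant-scale affinity plus
# Gaussian noise.

#' Configuration of the synthetic dataset generator
#'
#' @param n_variants number of promoter variants including the wildtype;
#'   at least 5 (the minimum family size admitted for statistical
#'   analysis).
#' @param base_seq optional 90-bp wildtype sequence; by default a random
#'   background with the plant TATA consensus `TCACTATATATAG` planted at
#'   `tata_offset`.
#' @param tata_offset 1-based start of the planted consensus within the
#'   fragment (default 56, placing the box roughly 25-35 bp upstream of the
#'   TSS at the fragment's 3' end).
#' @param mutation_types subset of `c("substitution", "deletion")`:
#'   point substitutions in/near the TATA window, and/or deletions of 1-3 bp
#'   from the spacer between the box and the TSS.
#' @param max_edits maximal number of point substitutions per mutant.
#' @param link_intercept,link_slope linear link between predicted
#'   plant-scale \eqn{-\ln(K_D)} and expression
#'   (`expression = intercept + slope * predicted + noise`).
#' @param noise_sd standard deviation of the Gaussian expression noise
#'   (expression units, >= 0).
#' @param seed integer seed making the dataset fully reproducible.
#' @return object of class `SyntheticConfig`.
#' @export
synthetic_config <- function(n_variants = 24L, base_seq = NULL,
                             tata_offset = 56L,
                             mutation_types = c("substitution", "deletion"),
                             max_edits = 3L,
                             link_intercept = 0, link_slope = 1,
                             noise_sd = 1, seed = 1L) {
  n_variants <- as.integer(n_variants)
  if (n_variants < 5L) {
    stop("n_variants must be at least 5: smaller promoter families do not support an adequate statistical analysis")
  }
  mutation_types <- match.arg(mutation_types, several.ok = TRUE)
  stopifnot(is.numeric(noise_sd), noise_sd >= 0, is.numeric(link_slope),
            is.numeric(link_intercept))
  if (!is.null(base_seq)) {
    base_seq <- validate_promoter(base_seq, id = "wildtype")$seq
  }
  structure(
    list(n_variants = n_variants, base_seq = base_seq,
         tata_offset = as.integer(tata_offset),
         mutation_types = mutation_types, max_edits = as.integer(max_edits),
         link_intercept = link_intercept, link_slope = link_slope,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "SyntheticConfig"
  )
}

# Random 90-bp background with the plant TATA consensus planted at `offset`
# (1-based).  Assumes an active RNG state (callers seed it).
random_promoter_seq <- function(length = 90L, offset = 56L,
                                consensus = PLANT_TATA_CONSENSUS) {
  chars <- sample(DNA_BASES, length, replace = TRUE)
  cons <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  if (offset < 1L || offset + length(cons) - 1L > length) {
    stop("consensus does not fit at the requested offset")
  }
  chars[offset:(offset + length(cons) - 1L)] <- cons
  paste(chars, collapse = "")
}

#' Apply one edit to a promoter fragment
#'
#' Supported edit specs (1-based positions):
#' \itemize{
#'   \item `list(type = "substitution", pos, base)` — replace the base at
#'     `pos`.
#'   \item `list(type = "deletion", pos, len, pad)` — delete `len` bp
#'     starting at `pos` and re-pad the fragment at the 5' end with `pad`
#'     bases (default `"C"`, repeated) so its length — anchored at the TSS
#'     on the 3' side — is preserved.  All downstream coordinates of the
#'     original sequence shift `len` bp towards the 3' end.
#' }
#'
#' @param seq promoter string.
#' @param edit edit specification (see above).
#' @return the edited sequence, same length as the input.
#' @examples
#' mutate_tata("ACGTACGT", list(type = "substitution", pos = 2, base = "A"))
#' @export
mutate_tata <- function(seq, edit) {
  stopifnot(is_string(seq), is.list(edit), !is.null(edit$type))
  L <- nchar(seq)
  pos <- as.integer(edit$pos)
  if (identical(edit$type, "substitution")) {
    base <- toupper(edit$base)
    if (!base %in% DNA_BASES) stop("substitution base must be A/C/G/T")
    if (is.na(pos) || pos < 1L || pos > L) {
      stop("substitution position out of bounds")
    }
    paste0(substr(seq, 1L, pos - 1L), base, substr(seq, pos + 1L, L))
  } else if (identical(edit$type, "deletion")) {
    len <- as.integer(edit$len)
    if (is.na(pos) || is.na(len) || len < 1L || pos < 1L ||
        pos + len - 1L > L) {
      stop("deletion out of bounds")
    }
    pad <- edit$pad %||% strrep("C", len)
    pad <- toupper(pad)
    if (nchar(pad) != len ||
        !all(strsplit(pad, "")[[1L]] %in% DNA_BASES)) {
      stop("pad must supply exactly len A/C/G/T bases")
    }
    paste0(pad, substr(seq, 1L, pos - 1L), substr(seq, pos + len, L))
  } else {
    stop("unknown edit type: ", edit$type)
  }
}

# Draw a random mutant of `base` per the config.  Assumes active RNG.
random_mutant <- function(base, cfg) {
  L <- nchar(base)
  cons_len <- nchar(PLANT_TATA_CONSENSUS)
  region <- max(1L, cfg$tata_offset - 5L):min(L, cfg$tata_offset + cons_len + 4L)
  type <- sample(cfg$mutation_types, 1L)
  if (type == "substitution") {
    k <- sample.int(cfg$max_edits, 1L)
    out <- base
    for (i in seq_len(k)) {
      pos <- sample(region, 1L)
      cur <- substr(out, pos, pos)
      out <- mutate_tata(out, list(type = "substitution", pos = pos,
                                   base = sample(setdiff(DNA_BASES, cur), 1L)))
    }
    out
  } else {
    spacer_start <- cfg$tata_offset + cons_len
    spacer_len <- L - spacer_start + 1L
    if (spacer_len < 1L) stop("no spacer between the TATA box and the TSS: deletion impossible")
    len <- sample.int(min(3L, spacer_len), 1L)
    pos <- sample(spacer_start:(L - len + 1L), 1L)
    pad <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
    mutate_tata(base, list(type = "deletion", pos = pos, len = len, pad = pad))
  }
}

# Generate the variant family (sequences + predictions) deterministically
# from cfg$seed; expression noise is drawn separately (see generate_dataset).
generate_variants <- function(cfg, m, rp) {
  with_seed(cfg$seed, {
    base <- cfg$base_seq %||% random_promoter_seq(offset = cfg$tata_offset)
    seqs <- character(cfg$n_variants)
    seqs[1L] <- base
    for (i in seq_len(cfg$n_variants - 1L)) {
      seqs[i + 1L] <- random_mutant(base, cfg)
    }
    labels <- c("WT", sprintf("m%02d", seq_len(cfg$n_variants - 1L)))
    predicted <- vapply(seq_along(seqs), function(i) {
      p <- validate_promoter(seqs[i], id = labels[i], expected_length = NULL)
      predict_plant_affinity(p, m, rp)$minus_ln_kd
    }, numeric(1L))
    # snap numerically indistinguishable predictions to exact ties (well
    # below epsilon; keeps rank statistics free of summation-order noise)
    predicted <- round(predicted, 9L)
    data.frame(variant_label = labels,
               is_wildtype = c(TRUE, rep(FALSE, cfg$n_variants - 1L)),
               seq = seqs, predicted_minus_ln_kd = predicted,
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic promoter-variant dataset
#'
#' Record 1 is the wildtype (a random background with the plant TATA
#' consensus planted at the configured offset, unless `base_seq` is given);
#' each mutant differs from it by the configured edits.  Expression is
#' `link_intercept + link_slope * predicted + N(0, noise_sd)` on the
#' plant-scale predictions, so the statistical linkage between predictions
#' and "measurements" is exactly known.  Deterministic for a fixed
#' `cfg$seed`; pass `noise_seed` to redraw only the expression noise over a
#' fixed variant family.
#'
#' @param cfg [synthetic_config()].
#' @param m [affinity_model()].
#' @param rp [rescale_parameters()].
#' @param dataset_id,promoter_name,transcribed_gene,conditions,tbp_species,pol,reference
#'   metadata for the resulting [tata_dataset()].
#' @param noise_seed optional separate seed for the expression noise
#'   (default: derived from `cfg$seed`).
#' @return a [tata_dataset()].
#' @examples
#' cfg <- synthetic_config(n_variants = 8, noise_sd = 0, seed = 7)
#' d <- generate_dataset(cfg, affinity_model())
#' d$n_variants
#' @export
generate_dataset <- function(cfg, m, rp = rescale_parameters(),
                             dataset_id = 1L, promoter_name = "synthetic",
                             transcribed_gene = "reporter",
                             conditions = "synthetic",
                             tbp_species = "ntTBP", pol = "II",
                             reference = "synthetic", noise_seed = NULL) {
  stopifnot(inherits(cfg, "SyntheticConfig"),
            inherits(m, "AffinityModelParameters"))
  variants <- generate_variants(cfg, m, rp)
  noise_seed <- noise_seed %||% (cfg$seed + 104729L)
  noise <- with_seed(noise_seed,
                     stats::rnorm(nrow(variants), 0, cfg$noise_sd))
  records <- data.frame(
    variant_label = variants$variant_label,
    is_wildtype = variants$is_wildtype,
    seq = variants$seq,
    expression = cfg$link_intercept +
      cfg$link_slope * variants$predicted_minus_ln_kd + noise,
    species_tag = tbp_species,
    exp_condition = conditions,
    predicted_minus_ln_kd = variants$predicted_minus_ln_kd,
    reference = reference,
    stringsAsFactors = FALSE
  )
  tata_dataset(dataset_id, promoter_name, transcribed_gene, conditions,
               tbp_species, pol, records)
}

#' Expression-noise level for a target explained-variance fraction
#'
#' Given the predicted affinities of a fixed variant family and the link
#' slope, returns the Gaussian noise standard deviation that makes the
#' theoretical squared correlation between predictions and expression equal
#' to `r2`, from the closed form
#' \eqn{r^2 = s^2_{signal} / (s^2_{signal} + \sigma^2)}.
#'
#' @param predicted numeric vector of predicted affinities.
#' @param link_slope linear link slope.
#' @param r2 target squared correlation in (0, 1).
#' @return noise standard deviation.
#' @export
noise_sd_for_target_r2 <- function(predicted, link_slope, r2) {
  stopifnot(is.numeric(r2), r2 > 0, r2 < 1)
  s2 <- stats::var(link_slope * predicted)
  if (s2 == 0) stop("predicted affinities are constant: no signal variance")
  sqrt(s2 * (1 / r2 - 1))
}
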