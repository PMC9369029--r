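# Knowledge-base flat file: a tab-separated, UTF-8, spreadsheet-openable
# table of promoter variants with measured expression and (optionally)
# predicted affinity, grouped into datasets.  Dialect: header row, "."
# decimal separator, no quoting — fields containing tabs or line breaks are
# rejected rather than escaped.

KB_COLUMNS <- c("dataset_id", "promoter_name", "transcribed_gene",
                "conditions", "tbp_species", "pol", "variant_label",
                "is_wildtype", "seq", "expression", "species_tag",
                "exp_condition", "predicted_minus_ln_kd", "reference")

KB_RECORD_COLUMNS <- c("variant_label", "is_wildtype", "seq", "expression",
                       "species_tag", "exp_condition",
                       "predicted_minus_ln_kd", "reference")

#' Construct one promoter-variant dataset
#'
#' A dataset bundles the metadata of one experimental system (promoter,
#' reporter gene, conditions, TBP species, polymerase) with its variant
#' records: sequence, wildtype flag, measured expression, optional
#' predicted affinity, and literature reference.
#'
#' @param dataset_id integer dataset number.
#' @param promoter_name,transcribed_gene,conditions,tbp_species character
#'   metadata fields.
#' @param pol `"II"` or `"III"`.
#' @param records data frame with columns `variant_label`, `is_wildtype`,
#'   `seq`, `expression`, `species_tag`, `exp_condition`,
#'   `predicted_minus_ln_kd`, `reference`; variant labels must be unique.
#' @return object of class `tata_dataset` (with `n_variants = nrow(records)`).
#' @export
tata_dataset <- function(dataset_id, promoter_name, transcribed_gene,
                         conditions, tbp_species, pol, records) {
  dataset_id <- as.integer(dataset_id)
  pol <- as.character(pol)
  if (!pol %in% c("II", "III")) stop("pol must be \"II\" or \"III\"")
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  missing_cols <- setdiff(KB_RECORD_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop("records is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  records <- records[, KB_RECORD_COLUMNS, drop = FALSE]
  if (anyDuplicated(records$variant_label)) {
    stop("variant labels must be unique within a dataset")
  }
  if (!is.numeric(records$expression) || !all(is.finite(records$expression))) {
    stop("expression values must be finite numbers")
  }
  records$is_wildtype <- as.logical(records$is_wildtype)
  rownames(records) <- NULL
  structure(
    list(dataset_id = dataset_id, promoter_name = promoter_name,
         transcribed_gene = transcribed_gene, conditions = conditions,
         tbp_species = tbp_species, pol = pol,
         n_variants = nrow(records), records = records),
    class = "tata_dataset"
  )
}

#' @export
print.tata_dataset <- function(x, ...) {
  cat(sprintf("tata_dataset #%d: %s -> %s (%s; %s TBP; Pol %s); %d variants\n",
              x$dataset_id, x$promoter_name, x$transcribed_gene, x$conditions,
              x$tbp_species, x$pol, x$n_variants))
  invisible(x)
}

kb_field_ok <- function(x) !grepl("[\t\r\n]", x)

#' Write a knowledge base to a tab-separated flat file
#'
#' Tab-separated UTF-8 text with a fixed, documented column order
#' (`dataset_id, promoter_name, transcribed_gene, conditions, tbp_species,
#' pol, variant_label, is_wildtype, seq, expression, species_tag,
#' exp_condition, predicted_minus_ln_kd, reference`), loadable by any
#' spreadsheet program.  Character fields containing tabs or line breaks
#' are rejected.  An empty collection writes a header-only file.
#'
#' @param datasets list of [tata_dataset()] objects (class `tata_kb` or
#'   plain list).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kb <- function(datasets, path) {
  rows <- lapply(datasets, function(d) {
    stopifnot(inherits(d, "tata_dataset"))
    cbind(
      data.frame(dataset_id = d$dataset_id, promoter_name = d$promoter_name,
                 transcribed_gene = d$transcribed_gene,
                 conditions = d$conditions, tbp_species = d$tbp_species,
                 pol = d$pol, stringsAsFactors = FALSE),
      d$records
    )
  })
  tab <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    as.data.frame(stats::setNames(rep(list(character(0L)), length(KB_COLUMNS)),
                                  KB_COLUMNS))
  }
  chr <- vapply(tab, is.character, logical(1L))
  for (colname in names(tab)[chr]) {
    bad <- which(!kb_field_ok(tab[[colname]]))
    if (length(bad)) {
      stop(sprintf("field '%s' in row %d contains an embedded delimiter (tab/newline); the flat-file dialect forbids this",
                   colname, bad[1L]))
    }
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", na = "NA")
  invisible(path)
}

#' Read a knowledge-base flat file
#'
#' Parses and validates a file written in the [write_kb()] dialect.  Rows
#' failing validation (non-integer dataset id, non-numeric expression,
#' invalid sequence characters) are collected into a diagnostics table with
#' their file line numbers, reported via a warning, and dropped; the
#' diagnostics are attached as `attr(result, "problems")`.
#'
#' @param path input path.
#' @return object of class `tata_kb`: a list of [tata_dataset()] objects in
#'   ascending `dataset_id` order.
#' @export
read_kb <- function(path) {
  if (!file.exists(path)) stop("knowledge-base file not found: ", path)
  if (file.size(path) == 0L) stop("knowledge-base file is empty: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  missing_cols <- setdiff(KB_COLUMNS, names(tab))
  if (length(missing_cols)) {
    stop("knowledge-base file is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  tab <- tab[, KB_COLUMNS, drop = FALSE]
  problems <- data.frame(line = integer(0L), message = character(0L),
                         stringsAsFactors = FALSE)
  note <- function(i, msg) {
    # +1 for the header row: data row i sits on file line i + 1
    problems <<- rbind(problems,
                       data.frame(line = i + 1L, message = msg,
                                  stringsAsFactors = FALSE))
  }
  keep <- rep(TRUE, nrow(tab))
  dataset_id <- suppressWarnings(as.integer(tab$dataset_id))
  expression <- suppressWarnings(as.numeric(tab$expression))
  predicted <- suppressWarnings(as.numeric(tab$predicted_minus_ln_kd))
  for (i in seq_len(nrow(tab))) {
    if (is.na(dataset_id[i])) {
      note(i, sprintf("non-integer dataset_id '%s'", tab$dataset_id[i]))
      keep[i] <- FALSE
      next
    }
    if (is.na(expression[i])) {
      note(i, sprintf("non-numeric expression '%s'", tab$expression[i]))
      keep[i] <- FALSE
      next
    }
    seq_ok <- tryCatch({
      validate_promoter(tab$seq[i], id = tab$variant_label[i],
                        expected_length = NULL)
      TRUE
    }, error = function(e) {
      note(i, conditionMessage(e))
      FALSE
    })
    if (!seq_ok) keep[i] <- FALSE
  }
  if (any(!keep)) {
    warning(sprintf("%d malformed row(s) dropped from %s; see attr(,\"problems\")",
                    sum(!keep), path))
  }
  tab <- tab[keep, , drop = FALSE]
  dataset_id <- dataset_id[keep]
  expression <- expression[keep]
  predicted <- predicted[keep]
  if (!nrow(tab)) {
    out <- structure(list(), class = "tata_kb")
    attr(out, "problems") <- problems
    return(out)
  }
  ids <- sort(unique(dataset_id))
  datasets <- lapply(ids, function(id) {
    sel <- dataset_id == id
    meta <- unique(tab[sel, c("promoter_name", "transcribed_gene",
                              "conditions", "tbp_species", "pol")])
    if (nrow(meta) != 1L) {
      stop("dataset ", id, " has inconsistent metadata across its rows")
    }
    records <- data.frame(
      variant_label = tab$variant_label[sel],
      is_wildtype = toupper(tab$is_wildtype[sel]) %in% c("TRUE", "1", "YES"),
      seq = toupper(tab$seq[sel]),
      expression = expression[sel],
      species_tag = tab$species_tag[sel],
      exp_condition = tab$exp_condition[sel],
      predicted_minus_ln_kd = predicted[sel],
      reference = tab$reference[sel],
      stringsAsFactors = FALSE
    )
    tata_dataset(id, meta$promoter_name, meta$transcribed_gene,
                 meta$conditions, meta$tbp_species, meta$pol, records)
  })
  out <- structure(datasets, class = "tata_kb")
  attr(out, "problems") <- problems
  out
}

#' Summarize a knowledge base like a compilation table's TOTAL row
#'
#' Distinct counts of promoters, reporter genes, experimental systems
#' (condition strings), TBP species and polymerases, the total number of
#' variants, and the number of distinct literature references (cells citing
#' several references, separated by `,` or `;`, contribute each reference).
#'
#' @param datasets a `tata_kb` or list of [tata_dataset()] objects with at
#'   least one element.
#' @return object of class `kb_summary`: `n_datasets`, `n_promoters`,
#'   `n_genes`, `n_systems`, `n_tbps`, `n_pols`, `n_variants`,
#'   `n_references`.
#' @export
summarize_kb <- function(datasets) {
  if (!length(datasets)) stop("at least one dataset is required")
  get <- function(field) vapply(datasets, `[[`, character(1L), field)
  refs <- unlist(lapply(datasets, function(d) d$records$reference))
  refs <- trimws(unlist(strsplit(refs, "[,;]")))
  refs <- refs[nzchar(refs)]
  structure(
    list(n_datasets = length(datasets),
         n_promoters = length(unique(get("promoter_name"))),
         n_genes = length(unique(get("transcribed_gene"))),
         n_systems = length(unique(get("conditions"))),
         n_tbps = length(unique(get("tbp_species"))),
         n_pols = length(unique(get("pol"))),
         n_variants = sum(vapply(datasets, `[[`, integer(1L), "n_variants")),
         n_references = length(unique(refs))),
    class = "kb_summary"
  )
}

#' @export
print.kb_summary <- function(x, ...) {
  cat(sprintf("Knowledge base: %d datasets | %d promoters | %d genes | %d systems | %d TBPs | %d Pols | %d variants | %d references\n",
              x$n_datasets, x$n_promoters, x$n_genes, x$n_systems, x$n_tbps,
              x$n_pols, x$n_variants, x$n_references))
  invisible(x)
}

#' Export all variant sequences of a knowledge base as FASTA
#'
#' Record identifiers are `ds<dataset_id>|<variant_label>`.
#'
#' @param datasets a `tata_kb` or list of [tata_dataset()] objects.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @importFrom Biostrings DNAStringSet writeXStringSet
#' @export
export_kb_fasta <- function(datasets, path) {
  seqs <- unlist(lapply(datasets, function(d) {
    stats::setNames(d$records$seq,
                    paste0("ds", d$dataset_id, "|", d$records$variant_label))
  }))
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Metadata of the twelve compiled experimental datasets (promoter families
# with measured mutation effects): dataset number, promoter, reporter gene,
# experimental system, TBP species, polymerase, number of variants, and
# literature reference keys (multi-reference cells comma-separated).
kb_table1_metadata <- function() {
  data.frame(
    dataset_id = 1:12,
    promoter_name = c(
      "TC7", "TC7 (chimeric atTBP system)", "OsPAL", "Pv tRNA-Leu",
      "Pv tRNA-Leu", "AtU6-26 snRNA", "AtU2.2 snRNA", "CaMV 35S",
      "synthetic AtU6-26-based", "synthetic AtU2.2-based", "Pmec", "Pmec"),
    transcribed_gene = c(
      "G-free cassette transcript", "G-free cassette transcript", "OsPAL",
      "Pv tRNA-Leu", "gusA", "AtU6-26 snRNA", "AtU2.2 snRNA", "CaMV 35S",
      "AtU6-26 snRNA", "AtU2.2 snRNA", "gusA", "gusA"),
    conditions = c(
      "in vitro: reconstituted transcription",
      "in vitro: reconstituted transcription",
      "in vitro: rice whole-cell extract",
      "in vitro: tobacco nuclear extract",
      rep("ex vivo: tobacco protoplasts", 6L),
      "in vivo: dark-grown tobacco leaves",
      "in vivo: light-grown tobacco leaves"),
    tbp_species = c("hsTBP", "atTBP", "osTBP", rep("ntTBP", 9L)),
    pol = c("II", "II", "II", "III", "III", "III", "II", "II", "III", "II",
            "II", "II"),
    n_variants = c(24L, 24L, 8L, 16L, 30L, 7L, 7L, 7L, 10L, 5L, 52L, 52L),
    reference = c("R45", "R45", "R46,R47", "R48", "R49", "R50", "R50", "R50",
                  "R51", "R52", "R53", "R53"),
    stringsAsFactors = FALSE
  )
}

#' Schema-faithful synthetic knowledge-base fixture
#'
#' Builds a twelve-dataset knowledge base with the bookkeeping shape of the
#' published compilation of plant promoter-variant experiments (per-dataset
#' variant counts 24, 24, 8, 16, 30, 7, 7, 7, 10, 5, 52, 52 — 242 variants
#' in total — spanning 10 promoters, 7 reporter genes, 6 experimental
#' systems, 4 TBP species, 2 polymerases and 9 references).  The sequences
#' and expression values are synthetic, generated by [generate_dataset()];
#' only the metadata schema and counts mirror the published table, because
#' the underlying measured sequences are not public as plain data.
#'
#' @param m [affinity_model()] used to generate linked expression values.
#' @param rp [rescale_parameters()].
#' @param seed integer seed; the fixture is fully deterministic given it.
#' @param noise_sd expression noise standard deviation passed to the
#'   generator.
#' @return a `tata_kb` with 12 datasets.
#' @export
kb_table1_fixture <- function(m = affinity_model(), rp = rescale_parameters(),
                              seed = 1L, noise_sd = 1) {
  meta <- kb_table1_metadata()
  datasets <- lapply(seq_len(nrow(meta)), function(i) {
    cfg <- synthetic_config(n_variants = meta$n_variants[i],
                            noise_sd = noise_sd,
                            seed = seed * 1000L + i)
    generate_dataset(cfg, m, rp,
                     dataset_id = meta$dataset_id[i],
                     promoter_name = meta$promoter_name[i],
                     transcribed_gene = meta$transcribed_gene[i],
                     conditions = meta$conditions[i],
                     tbp_species = meta$tbp_species[i],
                     pol = meta$pol[i],
                     reference = meta$reference[i])
  })
  structure(datasets, class = "tata_kb")
}
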