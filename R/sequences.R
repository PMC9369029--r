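#' Validate and normalize a promoter sequence
#'
#' Accepts a raw DNA string, strips whitespace, uppercases it, maps U to T
#' (RNA-style input), and rejects any remaining non-ACGT character by naming
#' its position.  The expected fragment is the 90 bp immediately upstream of
#' a transcription start site; other lengths are accepted with a warning and
#' flagged, because the affinity model is calibrated on the 90-bp convention.
#'
#' @param raw single character string with the DNA sequence (whitespace and
#'   line breaks are ignored, so a pasted FASTA body works).
#' @param id label for the sequence, used in messages and reports.
#' @param role one of `"wildtype"`, `"mutant"`, `"prototype"`.
#' @param expected_length fragment length the model is calibrated for
#'   (default 90 bp); a differing length triggers a warning, not an error.
#'
#' @return An object of class `PromoterSequence`: a list with elements
#'   `id`, `seq` (normalized string), `length`, `role` and
#'   `nonstandard_length` (logical flag).
#'
#' @examples
#' p <- validate_promoter(strrep("acgt", 22L), id = "toy", expected_length = 88)
#' p$length
#' @export
validate_promoter <- function(raw, id = "promoter",
                              role = c("wildtype", "mutant", "prototype"),
                              expected_length = 90L) {
  role <- match.arg(role)
  if (!is_string(raw)) stop("`raw` must be a single character string")
  seq <- gsub("[[:space:]]+", "", raw)
  if (!nzchar(seq)) stop("sequence '", id, "' is empty after whitespace removal")
  seq <- toupper(seq)
  seq <- chartr("U", "T", seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% DNA_BASES))
  if (length(bad)) {
    stop(sprintf("sequence '%s': invalid base '%s' at position %d (only A/C/G/T allowed)",
                 id, chars[bad[1L]], bad[1L]))
  }
  len <- length(chars)
  nonstandard <- !is.null(expected_length) && len != expected_length
  if (nonstandard) {
    warning(sprintf("sequence '%s' is %d bp; the model expects %d bp fragments",
                    id, len, as.integer(expected_length)))
  }
  structure(
    list(id = id, seq = seq, length = len, role = role,
         nonstandard_length = isTRUE(nonstandard)),
    class = "PromoterSequence"
  )
}

#' @export
print.PromoterSequence <- function(x, ...) {
  cat(sprintf("PromoterSequence '%s' (%s, %d bp)\n", x$id, x$role, x$length))
  cat(" ", x$seq, "\n")
  invisible(x)
}

#' Read promoter variants from a FASTA file
#'
#' Each record becomes a validated [validate_promoter()] object; the record
#' identifier is taken as the variant label.
#'
#' @param path path to a FASTA file.
#' @param role role assigned to every record (see [validate_promoter()]).
#' @param expected_length see [validate_promoter()].
#' @return A named list of `PromoterSequence` objects.
#' @importFrom Biostrings readDNAStringSet
#' @export
read_promoter_fasta <- function(path, role = "wildtype", expected_length = 90L) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no sequences in FASTA file: ", path)
  ids <- names(set)
  ids[!nzchar(ids)] <- paste0("seq", which(!nzchar(ids)))
  out <- lapply(seq_along(set), function(i) {
    validate_promoter(as.character(set[[i]]), id = ids[i], role = role,
                      expected_length = expected_length)
  })
  names(out) <- ids
  out
}

# Reverse complement of a plain DNA string.
#' @importFrom Biostrings reverseComplement DNAString
rc_string <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Coerce a PromoterSequence or plain string to PromoterSequence.
as_promoter <- function(x, id = "promoter", ...) {
  if (inherits(x, "PromoterSequence")) return(x)
  validate_promoter(x, id = id, ...)
}
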