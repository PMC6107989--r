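# UniProt accession handling.

# Official UniProtKB accession pattern (6- and 10-character forms).
UNIPROT_ACCESSION_REGEX <-
  "^([OPQ][0-9][A-Z0-9]{3}[0-9]|[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})$"

#' Test whether strings are well-formed UniProt accessions
#'
#' Checks each element against the UniProtKB accession pattern (for example
#' `Q04206`, the human RelA/p65 entry). Matching is on form only; no lookup
#' against UniProt is performed.
#'
#' @param x Character vector of candidate accessions.
#' @return Logical vector the same length as `x`.
#' @examples
#' is_uniprot_accession(c("Q04206", "not an id!"))
#' @export
is_uniprot_accession <- function(x) {
  stringr::str_detect(as.character(x), UNIPROT_ACCESSION_REGEX)
}

#' Validate an ordered list of UniProt accessions
#'
#' An accession list is the pipeline's unit of request: it must be non-empty,
#' free of duplicates, and every element must match the UniProt accession
#' pattern. Input order is preserved — it later defines bottom-up stacking of
#' the drawn proteins (first accession = bottom band).
#'
#' Accessions may be given as a character vector or as a single
#' space-separated string (`"Q04206 Q01201 Q04864 P19838 Q00653"`).
#'
#' @param accessions Character vector of accessions, or one space-separated
#'   string.
#' @return Character vector of validated accessions, in input order.
#' @examples
#' accession_list("Q04206 Q01201")
#' @export
accession_list <- function(accessions) {
  if (is.null(accessions)) {
    rlang::abort("`accessions` must not be NULL.", class = "protsketch_validation_error")
  }
  accessions <- as.character(accessions)
  if (length(accessions) == 1L && stringr::str_detect(accessions, "\\s")) {
    accessions <- stringr::str_split_1(stringr::str_trim(accessions), "\\s+")
  }
  if (length(accessions) == 0L) {
    rlang::abort("`accessions` must contain at least one accession.",
                 class = "protsketch_validation_error")
  }
  bad <- accessions[!is_uniprot_accession(accessions)]
  if (length(bad) > 0L) {
    rlang::abort(
      sprintf("Not valid UniProt accession(s): %s",
              paste(sprintf("'%s'", bad), collapse = ", ")),
      class = "protsketch_validation_error"
    )
  }
  dup <- unique(accessions[duplicated(accessions)])
  if (length(dup) > 0L) {
    rlang::abort(
      sprintf("Duplicate accession(s): %s", paste(dup, collapse = ", ")),
      class = "protsketch_validation_error"
    )
  }
  accessions
}
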