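# The nine-column feature table: the pipeline's central interchange object.
#
# Columns, in canonical order:
#   type        feature category (CHAIN, DOMAIN, REGION, MOTIF, REPEAT,
#               MOD_RES, ...)
#   description free-text annotation ("Transcription factor p65", "RHD", ...)
#   begin, end  1-based inclusive amino-acid positions
#   length      end - begin (the tool's convention; see compute_length)
#   accession   UniProt accession
#   entryName   UniProt entry name mnemonic (default chain label)
#   taxid       NCBI taxon id
#   order       1-based stacking index; 1 is the bottom band

FEATURE_COLUMNS <- c("type", "description", "begin", "end", "length",
                     "accession", "entryName", "taxid", "order")

#' Length of a feature in the table's convention
#'
#' Feature length is defined as `end - begin` — the number of residues
#' spanned beyond the first, not the inclusive residue count
#' `end - begin + 1`. Under this convention a whole 551-residue chain
#' annotated 1..551 has length 550 and a single-residue phosphosite
#' annotated 38..38 has length 0. The inclusive count is deliberately not
#' used so that the `length` column matches the convention established for
#' this feature-table format.
#'
#' @param begin,end 1-based inclusive positions (vectorised; recycled by the
#'   usual rules).
#' @return Integer-valued numeric vector of `end - begin`.
#' @examples
#' compute_length(1, 551)   # 550
#' compute_length(19, 306)  # 287
#' compute_length(38, 38)   # 0
#' @export
compute_length <- function(begin, end) {
  begin <- as.numeric(begin)
  end <- as.numeric(end)
  if (any(is.na(begin)) || any(is.na(end))) {
    rlang::abort("`begin` and `end` must be numeric and non-missing.",
                 class = "protsketch_coordinate_error")
  }
  if (any(begin < 1)) {
    rlang::abort("`begin` must be >= 1 (positions are 1-based).",
                 class = "protsketch_coordinate_error")
  }
  if (any(end < begin)) {
    rlang::abort("`end` must be >= `begin`.",
                 class = "protsketch_coordinate_error")
  }
  end - begin
}

#' Coerce and validate a data frame as a feature table
#'
#' Enforces the interchange contract: exactly the nine canonical columns in
#' canonical order, 1-based coordinates with `end >= begin`,
#' `length == end - begin` for every row, and contiguous stacking orders
#' `1..K` with one order value per accession. By default every accession
#' must also carry at least one CHAIN record (processed proteins may carry
#' several, stacked on one band); subsets produced by [select_type()] relax
#' that with `require_chain = FALSE`.
#'
#' @param x Data frame with (at least) the nine canonical columns.
#' @param require_chain Require >= 1 CHAIN record per accession? Default TRUE.
#' @return A tibble of class `feature_table`.
#' @export
as_feature_table <- function(x, require_chain = TRUE) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(FEATURE_COLUMNS, names(x))
  if (length(missing_cols) > 0L) {
    rlang::abort(
      sprintf("Feature table is missing column(s): %s",
              paste(missing_cols, collapse = ", ")),
      class = "protsketch_schema_error"
    )
  }
  x <- x[FEATURE_COLUMNS]
  x$type <- as.character(x$type)
  x$description <- as.character(x$description)
  x$begin <- as.numeric(x$begin)
  x$end <- as.numeric(x$end)
  x$length <- as.numeric(x$length)
  x$accession <- as.character(x$accession)
  x$entryName <- as.character(x$entryName)
  x$taxid <- as.integer(x$taxid)
  x$order <- as.integer(x$order)
  validate_feature_table(x, require_chain = require_chain)
  class(x) <- c("feature_table", class(x))
  x
}

validate_feature_table <- function(x, require_chain = TRUE) {
  if (nrow(x) == 0L) {
    return(invisible(x))
  }
  if (any(is.na(x$begin)) || any(is.na(x$end))) {
    rlang::abort("Feature table has missing coordinates.",
                 class = "protsketch_schema_error")
  }
  if (any(x$begin < 1)) {
    bad <- which(x$begin < 1)[1]
    rlang::abort(sprintf("Row %d: begin (%s) must be >= 1.", bad, x$begin[bad]),
                 class = "protsketch_coordinate_error")
  }
  if (any(x$end < x$begin)) {
    bad <- which(x$end < x$begin)[1]
    rlang::abort(sprintf("Row %d: end (%s) < begin (%s).",
                         bad, x$end[bad], x$begin[bad]),
                 class = "protsketch_coordinate_error")
  }
  if (any(x$length != x$end - x$begin)) {
    bad <- which(x$length != x$end - x$begin)[1]
    rlang::abort(
      sprintf("Row %d: length (%s) != end - begin (%s).",
              bad, x$length[bad], x$end[bad] - x$begin[bad]),
      class = "protsketch_schema_error"
    )
  }
  if (any(is.na(x$order)) || any(x$order < 1L)) {
    rlang::abort("Stacking `order` must be a positive integer for every row.",
                 class = "protsketch_schema_error")
  }
  per_acc <- unique(x[c("accession", "order")])
  if (anyDuplicated(per_acc$accession) > 0L) {
    dup <- per_acc$accession[duplicated(per_acc$accession)][1]
    rlang::abort(
      sprintf("Accession %s carries more than one `order` value.", dup),
      class = "protsketch_schema_error"
    )
  }
  if (require_chain) {
    # full-table invariants; category subsets keep their original order
    # values, so contiguity is only enforced on complete tables
    orders <- sort(unique(x$order))
    if (!identical(orders, seq_along(orders))) {
      rlang::abort(
        sprintf("Stacking orders must be contiguous 1..K; found {%s}.",
                paste(orders, collapse = ", ")),
        class = "protsketch_schema_error"
      )
    }
    chainless <- setdiff(x$accession, x$accession[x$type == "CHAIN"])
    if (length(chainless) > 0L) {
      rlang::abort(
        sprintf("Accession(s) without a CHAIN record: %s",
                paste(chainless, collapse = ", ")),
        class = "protsketch_schema_error"
      )
    }
  }
  invisible(x)
}

#' Flatten raw feature sets into a feature table
#'
#' Turns the nested per-protein feature lists returned by [fetch_features()]
#' or [load_feature_sets()] into one validated nine-column tibble, one row
#' per feature. Coordinates are kept 1-based inclusive as delivered by
#' UniProt; `length` is computed with [compute_length()]; stacking `order`
#' follows the order of `sets` (first protein = 1 = bottom band). Features
#' whose begin or end is absent or non-numeric (UniProt occasionally emits
#' unknown or approximate positions) are dropped, never guessed, and the
#' dropped count is reported via a message and the `"n_skipped"` attribute.
#'
#' @param sets List of raw feature sets.
#' @return A `feature_table` tibble; rows for one protein appear grouped.
#' @examples
#' path <- system.file("extdata", "rela_synthetic.json", package = "protsketch")
#' tbl <- flatten_features(load_feature_sets(path))
#' tbl[1, c("type", "description", "begin", "end", "length")]
#' @export
flatten_features <- function(sets) {
  if (length(sets) == 0L) {
    rlang::abort("`sets` must contain at least one feature set.",
                 class = "protsketch_validation_error")
  }
  n_skipped <- 0L
  rows <- purrr::map(sets, function(set) {
    coord <- function(v) {
      if (is.null(v) || length(v) == 0L) NA_real_
      else suppressWarnings(as.numeric(v[[1]]))
    }
    parsed <- purrr::map(set$features, function(f) {
      begin <- coord(f$begin)
      end <- coord(f$end)
      if (is.na(begin) || is.na(end) || begin < 1 || end < begin) {
        return(NULL)
      }
      tibble::tibble(
        type = as.character(f$type %||% "UNKNOWN"),
        description = as.character(f$description %||% ""),
        begin = begin,
        end = end
      )
    })
    n_skipped <<- n_skipped + sum(purrr::map_lgl(parsed, is.null))
    usable <- purrr::compact(parsed)
    if (length(usable) == 0L) {
      rlang::warn(sprintf("Accession %s has no usable features.", set$accession))
      return(NULL)
    }
    out <- dplyr::bind_rows(usable)
    out$length <- compute_length(out$begin, out$end)
    out$accession <- set$accession
    out$entryName <- set$entryName
    out$taxid <- set$taxid
    out
  })
  rows <- purrr::compact(rows)
  if (length(rows) == 0L) {
    rlang::abort("No usable features in any feature set.",
                 class = "protsketch_empty_error")
  }
  table <- dplyr::bind_rows(rows)
  if (n_skipped > 0L) {
    message(sprintf("Skipped %d feature(s) with absent or non-numeric coordinates.",
                    n_skipped))
  }
  # order over the proteins that survived, in request order, so stacking
  # indices stay contiguous even when a set contributed no usable rows
  table <- assign_order(table, unique(table$accession))
  table <- as_feature_table(table, require_chain = FALSE)
  attr(table, "n_skipped") <- n_skipped
  table
}

#' Assign bottom-up stacking order from an accession order
#'
#' Sets each record's `order` to the 1-based index of its accession in
#' `accession_order`. Order 1 is drawn at the bottom of the schematic, in
#' the manner of a graph, so the first requested protein ends up on the
#' bottom band.
#'
#' @param table Data frame with an `accession` column.
#' @param accession_order Character vector mapping order index to accession.
#' @return `table` with its `order` column (re)assigned.
#' @export
assign_order <- function(table, accession_order) {
  accession_order <- accession_list(accession_order)
  idx <- match(table$accession, accession_order)
  if (any(is.na(idx))) {
    unknown <- unique(table$accession[is.na(idx)])
    rlang::abort(
      sprintf("Record accession(s) not in `accession_order`: %s",
              paste(unknown, collapse = ", ")),
      class = "protsketch_integrity_error"
    )
  }
  table$order <- as.integer(idx)
  table
}

#' Select records of one feature category
#'
#' Schema- and order-preserving subset; an empty subset is valid (for
#' example `"REPEAT"` on a protein with no repeats).
#'
#' @param table A feature table.
#' @param feature_type Category string such as `"CHAIN"` or `"DOMAIN"`.
#' @return Feature-table subset with unchanged `order` values.
#' @examples
#' select_type(rela_fixture(), "DOMAIN")
#' @export
select_type <- function(table, feature_type) {
  out <- dplyr::filter(table, .data$type %in% feature_type)
  as_feature_table(out, require_chain = FALSE)
}

#' Select phosphorylation-site records
#'
#' A record is taken as a phosphosite when its category is `MOD_RES`, its
#' description starts with "Phospho" (case-insensitive: Phosphoserine,
#' Phosphothreonine, Phosphotyrosine, with or without an enzyme suffix), and
#' it is a single residue (`begin == end`). Other modified residues such as
#' acetylation or methylation are excluded.
#'
#' @param table A feature table.
#' @return Feature-table subset of phosphosites; every row has
#'   `begin == end`.
#' @examples
#' select_phospho(rela_fixture())
#' @export
select_phospho <- function(table) {
  out <- dplyr::filter(
    table,
    .data$type == "MOD_RES",
    stringr::str_detect(.data$description,
                        stringr::regex("^phospho", ignore_case = TRUE)),
    .data$begin == .data$end
  )
  as_feature_table(out, require_chain = FALSE)
}

#' @export
print.feature_table <- function(x, ...) {
  if ("accession" %in% names(x)) {
    cat(sprintf("# Feature table: %d record(s), %d protein(s)\n",
                nrow(x), length(unique(x$accession))))
  }
  NextMethod()
  invisible(x)
}
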