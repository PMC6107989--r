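# Feature-table interchange: TSV/CSV with the nine canonical columns, and
# GFF3 export. The dialect is autodetected from the file extension
# (.tsv/.tab -> tab, .csv -> comma); files are UTF-8 with a header row.

interchange_col_types <- function() {
  readr::cols(
    type = readr::col_character(),
    description = readr::col_character(),
    begin = readr::col_double(),
    end = readr::col_double(),
    length = readr::col_double(),
    accession = readr::col_character(),
    entryName = readr::col_character(),
    taxid = readr::col_integer(),
    order = readr::col_integer()
  )
}

dialect_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tsv = "tab", tab = "tab", txt = "tab",
    csv = "comma",
    rlang::abort(
      sprintf("Cannot infer dialect from extension '.%s' (use .tsv or .csv).", ext),
      class = "protsketch_io_error"
    )
  )
}

#' Read a feature table from TSV or CSV
#'
#' Reads an interchange file with the nine canonical columns and validates
#' it with [as_feature_table()], so invariants (coordinates, length rule,
#' contiguous stacking orders) are enforced on ingest as well as at
#' construction.
#'
#' @param path Path to a `.tsv` or `.csv` file.
#' @param require_chain Passed to [as_feature_table()].
#' @return A `feature_table` tibble.
#' @examples
#' path <- system.file("extdata", "five_rel_synthetic.tsv", package = "protsketch")
#' read_feature_table(path)
#' @export
read_feature_table <- function(path, require_chain = TRUE) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: '%s'", path),
                 class = "protsketch_io_error")
  }
  reader <- if (dialect_for(path) == "tab") readr::read_tsv else readr::read_csv
  x <- reader(path, col_types = interchange_col_types(), progress = FALSE)
  problems <- readr::problems(x)
  if (nrow(problems) > 0L) {
    first <- problems[1, ]
    rlang::abort(
      sprintf("Parse problem in '%s' at row %s, column %s: expected %s, got '%s'.",
              path, first$row, first$col, first$expected, first$actual),
      class = "protsketch_parse_error"
    )
  }
  as_feature_table(x, require_chain = require_chain)
}

#' Write a feature table to TSV or CSV
#'
#' @param table A feature table (validated before writing).
#' @param path Output path; dialect follows the extension.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  table <- as_feature_table(table, require_chain = FALSE)
  writer <- if (dialect_for(path) == "tab") readr::write_tsv else readr::write_csv
  writer(table, path, progress = FALSE)
  invisible(path)
}

# Feature category -> Sequence Ontology-flavoured GFF3 type.
GFF3_TYPE_MAP <- c(
  CHAIN = "polypeptide",
  DOMAIN = "polypeptide_domain",
  REGION = "polypeptide_region",
  MOTIF = "polypeptide_motif",
  REPEAT = "polypeptide_repeat",
  MOD_RES = "modified_amino_acid_feature"
)

#' Export a feature table as GFF3
#'
#' One GFF3 line per record: `seqid` is the accession, `source` is
#' `"uniprot"`, the GFF3 type is mapped from the feature category (unmapped
#' categories pass through unchanged), coordinates stay 1-based inclusive
#' per the GFF3 standard, and the description is carried in the attributes
#' column. Writing is delegated to rtracklayer.
#'
#' @param table A feature table.
#' @param path Output path (`.gff3` or `.gff`).
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(table, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    rlang::abort("Package 'rtracklayer' is required for GFF3 export.",
                 class = "protsketch_io_error")
  }
  table <- as_feature_table(table, require_chain = FALSE)
  gff_type <- unname(GFF3_TYPE_MAP[table$type])
  gff_type[is.na(gff_type)] <- table$type[is.na(gff_type)]
  gr <- GenomicRanges::GRanges(
    seqnames = table$accession,
    ranges = IRanges::IRanges(start = table$begin, end = table$end),
    type = gff_type,
    source = "uniprot",
    Name = table$description,
    description = table$description,
    entry_name = table$entryName
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
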