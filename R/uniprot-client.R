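# Client for the UniProt Proteins API features endpoint, plus an offline
# loader for JSON saved in the same response shape. All network traffic in
# the package lives in this file; everything downstream is testable offline.

UNIPROT_FEATURES_ENDPOINT <- "https://www.ebi.ac.uk/proteins/api/features"
UNIPROT_ENDPOINT_VERSION <- "v1"

#' Build the UniProt Proteins API query URL for a set of accessions
#'
#' Encodes one or more accessions as a single comma-separated (URL-encoded)
#' `accession=` parameter on the features endpoint. The URL is deterministic
#' for identical input, so it can serve as a cache key.
#'
#' @param accessions Accessions as accepted by [accession_list()].
#' @param page_size Maximum number of entries requested per page; must be at
#'   least the number of accessions. Default 100.
#' @return A single URL string.
#' @examples
#' build_query_url("Q04206")
#' build_query_url(c("Q04206", "Q01201"), page_size = 10)
#' @export
build_query_url <- function(accessions, page_size = 100L) {
  accessions <- accession_list(accessions)
  page_size <- as.integer(page_size)
  if (length(page_size) != 1L || is.na(page_size) || page_size < length(accessions)) {
    rlang::abort(
      sprintf("`page_size` must be a single integer >= %d (number of accessions).",
              length(accessions)),
      class = "protsketch_validation_error"
    )
  }
  acc_param <- utils::URLencode(paste(accessions, collapse = ","), reserved = TRUE)
  sprintf("%s?offset=0&size=%d&accession=%s",
          UNIPROT_FEATURES_ENDPOINT, page_size, acc_param)
}

# Convert one parsed API entry (a named list) to the internal raw feature-set
# shape: accession, entryName, taxid, sequence_length, features. Tolerates
# absent taxid/sequence; features is always a list (possibly empty).
as_raw_feature_set <- function(entry, where = "entry") {
  for (field in c("accession", "entryName")) {
    value <- entry[[field]]
    if (is.null(value) || !nzchar(as.character(value)[1])) {
      rlang::abort(
        sprintf("Feature set %s is missing required field '%s'.", where, field),
        class = "protsketch_schema_error"
      )
    }
  }
  if (is.null(entry$features)) {
    rlang::abort(
      sprintf("Feature set %s is missing required field 'features'.", where),
      class = "protsketch_schema_error"
    )
  }
  seq_len_aa <- if (!is.null(entry$sequence) && is.character(entry$sequence)) {
    nchar(entry$sequence[[1]])
  } else {
    NA_integer_
  }
  list(
    accession = as.character(entry$accession)[1],
    entryName = as.character(entry$entryName)[1],
    taxid = if (is.null(entry$taxid)) NA_integer_ else as.integer(entry$taxid)[1],
    sequence_length = seq_len_aa,
    features = entry$features
  )
}

parse_feature_response <- function(parsed, where = "response") {
  if (!is.list(parsed)) {
    rlang::abort(sprintf("%s is not a JSON array of feature sets.", where),
                 class = "protsketch_schema_error")
  }
  purrr::imap(parsed, function(entry, i) {
    as_raw_feature_set(entry, where = sprintf("%s[%d]", where, i))
  })
}

cache_file_for <- function(cache_dir, accessions, page_size) {
  key <- paste(sort(accessions), collapse = "_")
  file.path(cache_dir,
            sprintf("features-%s-size%d-%s.json",
                    UNIPROT_ENDPOINT_VERSION, as.integer(page_size), key))
}

#' Fetch feature sets for accessions from the UniProt Proteins API
#'
#' Queries the features endpoint for one or more accessions and returns one
#' raw feature set per resolved accession, re-sorted into request order (the
#' API does not preserve it). Requires network access and the httr package;
#' retries up to 3 times with exponential backoff on server errors and
#' timeouts, and fails immediately on client (4xx) errors.
#'
#' With `cache_dir` set, a successful response body is written to (and
#' subsequently read from) a file keyed by the sorted accession list and the
#' endpoint version, so repeated runs are reproducible offline.
#'
#' @param accessions Accessions as accepted by [accession_list()].
#' @param page_size Page size for the query; see [build_query_url()].
#' @param cache_dir Optional directory for the opt-in response cache.
#' @param max_tries Number of attempts on retryable failures. Default 3.
#' @return List of raw feature sets in request order; accessions the API did
#'   not resolve are reported via a warning and a `"missing"` attribute.
#' @seealso [load_feature_sets()] for fully offline use.
#' @export
fetch_features <- function(accessions, page_size = 100L, cache_dir = NULL,
                           max_tries = 3L) {
  accessions <- accession_list(accessions)
  url <- build_query_url(accessions, page_size = page_size)

  cache_file <- NULL
  if (!is.null(cache_dir)) {
    cache_file <- cache_file_for(cache_dir, accessions, page_size)
    if (file.exists(cache_file)) {
      sets <- load_feature_sets(cache_file)
      return(reorder_to_request(sets, accessions))
    }
  }

  if (!requireNamespace("httr", quietly = TRUE)) {
    rlang::abort("Package 'httr' is required for live UniProt queries.",
                 class = "protsketch_transport_error")
  }

  body <- NULL
  for (attempt in seq_len(max_tries)) {
    response <- tryCatch(
      httr::GET(url, httr::accept_json(), httr::timeout(30)),
      error = function(e) e
    )
    if (inherits(response, "error")) {
      if (attempt == max_tries) {
        rlang::abort(sprintf("UniProt request failed: %s", conditionMessage(response)),
                     class = "protsketch_transport_error")
      }
    } else {
      status <- httr::status_code(response)
      if (status >= 200 && status < 300) {
        body <- httr::content(response, as = "text", encoding = "UTF-8")
        break
      }
      if (status >= 400 && status < 500) {
        rlang::abort(sprintf("UniProt request rejected with HTTP %d.", status),
                     class = "protsketch_transport_error")
      }
      if (attempt == max_tries) {
        rlang::abort(sprintf("UniProt request failed with HTTP %d after %d attempts.",
                             status, max_tries),
                     class = "protsketch_transport_error")
      }
    }
    Sys.sleep(2^(attempt - 1))
  }

  parsed <- tryCatch(
    jsonlite::fromJSON(body, simplifyVector = FALSE),
    error = function(e) {
      rlang::abort(sprintf("UniProt response is not valid JSON: %s",
                           conditionMessage(e)),
                   class = "protsketch_transport_error")
    }
  )
  sets <- parse_feature_response(parsed, where = "API response")
  message("Download has worked")

  if (!is.null(cache_file)) {
    dir.create(dirname(cache_file), recursive = TRUE, showWarnings = FALSE)
    writeLines(body, cache_file, useBytes = TRUE)
  }
  reorder_to_request(sets, accessions)
}

#' Load feature sets from a JSON file in the API response shape
#'
#' Offline counterpart of [fetch_features()]: reads a JSON array of feature
#' sets (each with `accession`, `entryName`, `features`, and optionally
#' `taxid` and `sequence`) exactly as the UniProt Proteins API returns them.
#' No network is touched.
#'
#' @param path Path to a JSON file.
#' @return List of raw feature sets in file order.
#' @examples
#' path <- system.file("extdata", "rela_synthetic.json", package = "protsketch")
#' sets <- load_feature_sets(path)
#' sets[[1]]$entryName
#' @export
load_feature_sets <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: '%s'", path),
                 class = "protsketch_io_error")
  }
  parsed <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      rlang::abort(sprintf("Malformed JSON in '%s': %s", path, conditionMessage(e)),
                   class = "protsketch_parse_error")
    }
  )
  parse_feature_response(parsed, where = sprintf("'%s'", path))
}

#' Re-sort raw feature sets into request order
#'
#' The UniProt API returns entries in its own order; this restores the order
#' of the original request, which defines bottom-up stacking in the drawing.
#' Requested accessions with no matching set are reported with a warning and
#' recorded in the result's `"missing"` attribute, never silently dropped.
#'
#' @param sets List of raw feature sets (from [fetch_features()] or
#'   [load_feature_sets()]).
#' @param accessions Accessions as accepted by [accession_list()].
#' @return `sets` reordered to match `accessions`.
#' @export
reorder_to_request <- function(sets, accessions) {
  accessions <- accession_list(accessions)
  set_accs <- purrr::map_chr(sets, "accession")
  dup <- unique(set_accs[duplicated(set_accs)])
  if (length(dup) > 0L) {
    rlang::abort(
      sprintf("Duplicate accession(s) in feature sets: %s",
              paste(dup, collapse = ", ")),
      class = "protsketch_integrity_error"
    )
  }
  idx <- match(accessions, set_accs)
  missing <- accessions[is.na(idx)]
  if (length(missing) > 0L) {
    rlang::warn(
      sprintf("No feature set returned for accession(s): %s",
              paste(missing, collapse = ", "))
    )
  }
  out <- sets[idx[!is.na(idx)]]
  attr(out, "missing") <- missing
  out
}
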