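# Packaged and synthetic feature tables: every pipeline stage downstream of
# the UniProt client is testable and demonstrable with no network.

#' Feature table for human RelA/p65 (Q04206)
#'
#' A ten-row table for the human RelA (p65) subunit of NF-kappa-B: the
#' mature chain (1-551), the Rel homology domain (RHD, 19-306), the
#' activation domain (415-459), the nuclear localization signal (301-304),
#' a transactivation region (536-544), and five single-residue modified
#' sites (an N-terminal acetylation and four phosphosites at 38, 38, 122
#' and 123). Coordinates follow the historical UniProt annotation of this
#' entry; the site descriptions are synthetic composites, so the table is a
#' reduced stand-in for a live API download, not a current UniProt
#' snapshot.
#'
#' @return A single-protein `feature_table` (all `order` values 1).
#' @examples
#' rela_fixture()
#' @export
rela_fixture <- function() {
  as_feature_table(tibble::tibble(
    type = c("CHAIN", "DOMAIN", "REGION", "MOTIF", "REGION",
             "MOD_RES", "MOD_RES", "MOD_RES", "MOD_RES", "MOD_RES"),
    description = c(
      "Transcription factor p65",
      "RHD",
      "Activation domain",
      "Nuclear localization signal",
      "Transactivation domain",
      "N-acetylmethionine",
      "Phosphoserine",
      "Phosphoserine; by PKA",
      "Phosphoserine; by CK1",
      "Phosphothreonine"
    ),
    begin = c(1, 19, 415, 301, 536, 1, 38, 38, 122, 123),
    end = c(551, 306, 459, 304, 544, 1, 38, 38, 122, 123),
    length = c(550, 287, 44, 3, 8, 0, 0, 0, 0, 0),
    accession = "Q04206",
    entryName = "TF65_HUMAN",
    taxid = 9606L,
    order = 1L
  ))
}

#' Feature table for the five human NF-kappa-B family proteins
#'
#' A five-protein table for Q04206 (RelA/p65), Q01201 (RelB), Q04864
#' (c-Rel), P19838 (NF-kappa-B1 p105/p50) and Q00653 (NF-kappa-B2
#' p100/p52), stacked bottom-up as p105, p100, RelB, c-Rel, RelA. The two
#' precursor entries each carry a second CHAIN record for their processed
#' form (p50, p52) on the same band, giving seven chains over five bands —
#' the configuration that takes seven custom chain labels. Every protein
#' has at least one domain and one phosphosite; the precursors carry
#' ankyrin repeats. Coordinates are approximate synthetic values in the
#' style of the UniProt annotation, not a database snapshot.
#'
#' @return A `feature_table` with orders 1..5 and seven CHAIN records.
#' @examples
#' dplyr::count(five_protein_fixture(), type)
#' @export
five_protein_fixture <- function() {
  row <- function(type, description, begin, end, accession, entryName) {
    tibble::tibble(type = type, description = description,
                   begin = begin, end = end,
                   length = end - begin,
                   accession = accession, entryName = entryName,
                   taxid = 9606L, order = NA_integer_)
  }
  tbl <- dplyr::bind_rows(
    # band 1: NF-kappa-B1 precursor p105 and processed p50
    row("CHAIN", "NF-kappa-B p105 subunit", 1, 968, "P19838", "NFKB1_HUMAN"),
    row("CHAIN", "NF-kappa-B p50 subunit", 1, 433, "P19838", "NFKB1_HUMAN"),
    row("DOMAIN", "RHD", 42, 367, "P19838", "NFKB1_HUMAN"),
    row("DOMAIN", "Death", 800, 890, "P19838", "NFKB1_HUMAN"),
    row("REPEAT", "ANK 1", 540, 570, "P19838", "NFKB1_HUMAN"),
    row("REPEAT", "ANK 2", 577, 607, "P19838", "NFKB1_HUMAN"),
    row("REPEAT", "ANK 3", 611, 641, "P19838", "NFKB1_HUMAN"),
    row("MOTIF", "Nuclear localization signal", 360, 363, "P19838", "NFKB1_HUMAN"),
    row("MOD_RES", "Phosphoserine", 337, 337, "P19838", "NFKB1_HUMAN"),
    row("MOD_RES", "Phosphoserine; by IKK", 932, 932, "P19838", "NFKB1_HUMAN"),
    # band 2: NF-kappa-B2 precursor p100 and processed p52
    row("CHAIN", "NF-kappa-B p100 subunit", 1, 900, "Q00653", "NFKB2_HUMAN"),
    row("CHAIN", "NF-kappa-B p52 subunit", 1, 454, "Q00653", "NFKB2_HUMAN"),
    row("DOMAIN", "RHD", 38, 342, "Q00653", "NFKB2_HUMAN"),
    row("DOMAIN", "Death", 760, 850, "Q00653", "NFKB2_HUMAN"),
    row("REPEAT", "ANK 1", 490, 520, "Q00653", "NFKB2_HUMAN"),
    row("REPEAT", "ANK 2", 527, 557, "Q00653", "NFKB2_HUMAN"),
    row("REPEAT", "ANK 3", 561, 591, "Q00653", "NFKB2_HUMAN"),
    row("MOD_RES", "Phosphoserine; by IKK", 866, 866, "Q00653", "NFKB2_HUMAN"),
    # band 3: RelB
    row("CHAIN", "Transcription factor RelB", 1, 579, "Q01201", "RELB_HUMAN"),
    row("DOMAIN", "RHD", 125, 418, "Q01201", "RELB_HUMAN"),
    row("MOD_RES", "Phosphothreonine", 84, 84, "Q01201", "RELB_HUMAN"),
    row("MOD_RES", "Phosphoserine", 552, 552, "Q01201", "RELB_HUMAN"),
    # band 4: c-Rel
    row("CHAIN", "Proto-oncogene c-Rel", 1, 587, "Q04864", "REL_HUMAN"),
    row("DOMAIN", "RHD", 8, 297, "Q04864", "REL_HUMAN"),
    row("MOTIF", "Nuclear localization signal", 290, 293, "Q04864", "REL_HUMAN"),
    row("MOD_RES", "Phosphoserine", 503, 503, "Q04864", "REL_HUMAN"),
    # band 5: RelA/p65
    dplyr::mutate(rela_fixture(), order = NA_integer_)
  )
  tbl <- assign_order(tbl, c("P19838", "Q00653", "Q01201", "Q04864", "Q04206"))
  as_feature_table(tbl)
}

#' Generate a random feature table
#'
#' Seeded generator for property-style testing and scale experiments. Each
#' protein gets one CHAIN spanning 1..L with L uniform on [10, max_length],
#' a Poisson number of non-overlapping domains inside the chain (overlaps
#' are rejected by resampling, up to 100 attempts per domain, so dense
#' proteins may end up with fewer domains than drawn), and a Poisson number
#' of single-residue phosphosites. Accessions are synthetic (`P00001`,
#' `P00002`, ...), the taxon id is 32630 (synthetic construct), and
#' stacking orders run 1..n_proteins. The caller's random-number state is
#' left untouched.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param seed Integer seed; identical calls give identical tables.
#' @param max_length Maximum chain length in amino acids (>= 10).
#' @param domain_rate Expected domains per protein (Poisson mean).
#' @param phospho_rate Expected phosphosites per protein (Poisson mean).
#' @return A valid `feature_table`.
#' @examples
#' synthetic_table(3, seed = 7)
#' @export
synthetic_table <- function(n_proteins, seed, max_length = 1000,
                            domain_rate = 2, phospho_rate = 4) {
  n_proteins <- as.integer(n_proteins)
  if (is.na(n_proteins) || n_proteins < 1L) {
    rlang::abort("`n_proteins` must be a positive integer.",
                 class = "protsketch_config_error")
  }
  if (!is.numeric(max_length) || max_length < 10) {
    rlang::abort("`max_length` must be >= 10.",
                 class = "protsketch_config_error")
  }
  if (domain_rate < 0 || phospho_rate < 0) {
    rlang::abort("Rates must be non-negative.",
                 class = "protsketch_config_error")
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))

  domain_vocab <- c("Kinase domain", "SH3", "PH", "Zinc finger", "WD40")
  phospho_vocab <- c("Phosphoserine", "Phosphothreonine", "Phosphotyrosine")

  rows <- purrr::map(seq_len(n_proteins), function(i) {
    l <- floor(runif(1, 10, max_length + 1))
    acc <- sprintf("P%05d", i)
    entry <- sprintf("SYN%03d_HUMAN", i)
    out <- list(tibble::tibble(
      type = "CHAIN", description = sprintf("Synthetic chain %d", i),
      begin = 1, end = l, accession = acc, entryName = entry
    ))

    n_dom <- rpois(1, domain_rate)
    placed <- list()
    for (d in seq_len(n_dom)) {
      for (attempt in seq_len(100L)) {
        len <- sample(2:max(2L, min(60L, l - 1L)), 1)
        if (len >= l) next
        begin <- sample(seq_len(l - len), 1)
        end <- begin + len
        overlaps <- any(purrr::map_lgl(placed, function(p) {
          begin <= p[2] && end >= p[1]
        }))
        if (!overlaps) {
          placed[[length(placed) + 1L]] <- c(begin, end)
          out[[length(out) + 1L]] <- tibble::tibble(
            type = "DOMAIN", description = sample(domain_vocab, 1),
            begin = begin, end = end, accession = acc, entryName = entry
          )
          break
        }
      }
    }

    n_ph <- min(rpois(1, phospho_rate), l)
    if (n_ph > 0L) {
      pos <- sort(sample(seq_len(l), n_ph))
      out[[length(out) + 1L]] <- tibble::tibble(
        type = "MOD_RES",
        description = sample(phospho_vocab, n_ph, replace = TRUE),
        begin = pos, end = pos, accession = acc, entryName = entry
      )
    }
    dplyr::bind_rows(out)
  })

  tbl <- dplyr::bind_rows(rows)
  tbl$length <- compute_length(tbl$begin, tbl$end)
  tbl$taxid <- 32630L
  tbl <- assign_order(tbl, sprintf("P%05d", seq_len(n_proteins)))
  as_feature_table(tbl)
}
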