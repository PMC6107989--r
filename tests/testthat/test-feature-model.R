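# Flattening raw feature sets into the nine-column table, the length rule,
# stacking order, and typed selection.

test_that("flattening produces the canonical table for the RelA payload", {
  tbl <- flatten_features(load_feature_sets(rela_fixture_path()))
  expect_s3_class(tbl, "feature_table")
  expect_equal(names(tbl), c("type", "description", "begin", "end", "length",
                             "accession", "entryName", "taxid", "order"))
  expect_equal(tbl$type[1], "CHAIN")
  expect_equal(tbl$description[1], "Transcription factor p65")
  expect_equal(tbl$begin[1], 1)
  expect_equal(tbl$end[1], 551)
  expect_equal(tbl$length, tbl$end - tbl$begin)
  expect_true(all(tbl$taxid == 9606L))
  expect_true(all(tbl$order == 1L))
})

test_that("unusable coordinates are dropped and counted, never guessed", {
  set <- raw_set("Q04206", len = 100, extras = list(
    raw_feature("MOD_RES", "Phosphoserine", 50, 50),
    list(type = "REGION", description = "no coords"),
    raw_feature("REGION", "unknown begin", "unknown", 80)
  ))
  expect_message(tbl <- flatten_features(list(set)), "Skipped 2")
  expect_equal(nrow(tbl), 2L)
  expect_equal(attr(tbl, "n_skipped"), 2L)

  # a set with nothing usable raises a warning; nothing usable anywhere is
  # an error
  hopeless <- list(accession = "P19838", entryName = "NFKB1_TEST",
                   taxid = 9606,
                   features = list(list(type = "REGION", description = "x")))
  expect_warning(tbl2 <- flatten_features(list(set, hopeless)), "P19838")
  expect_equal(sort(unique(tbl2$order)), 1L)  # orders stay contiguous
  expect_error(suppressWarnings(flatten_features(list(hopeless))),
               class = "protsketch_empty_error")
  expect_error(flatten_features(list()), class = "protsketch_validation_error")
})

test_that("flattening is deterministic", {
  sets <- load_feature_sets(rela_fixture_path())
  expect_identical(flatten_features(sets), flatten_features(sets))
})

test_that("feature length is end minus begin, with coordinate errors caught", {
  expect_equal(compute_length(1, 551), 550)
  expect_equal(compute_length(19, 306), 287)
  expect_equal(compute_length(38, 38), 0)
  expect_equal(compute_length(c(1, 19, 415), c(551, 306, 459)),
               c(550, 287, 44))
  expect_error(compute_length(10, 5), class = "protsketch_coordinate_error")
  expect_error(compute_length(0, 5), class = "protsketch_coordinate_error")
  expect_error(compute_length(NA, 5), class = "protsketch_coordinate_error")
})

test_that("stacking order maps accession to its request index, bottom-up", {
  accs <- c("Q04206", "Q01201", "Q04864", "P19838", "Q00653")
  sets <- lapply(seq_along(accs), function(i) {
    raw_set(accs[i], len = 100 * i,
            extras = list(raw_feature("DOMAIN", "RHD", 10, 50)))
  })
  tbl <- flatten_features(sets)
  expect_equal(sort(unique(tbl$order)), 1:5)
  # brute-force index map: every record's order equals the position of its
  # accession in the request
  expect_equal(tbl$order, match(tbl$accession, accs))
  expect_equal(unique(tbl$accession[tbl$order == 1L]), "Q04206")

  relabelled <- assign_order(tbl, rev(accs))
  expect_equal(relabelled$order, match(relabelled$accession, rev(accs)))

  foreign <- tbl
  foreign$accession[1] <- "A12345"
  expect_error(assign_order(foreign, accs),
               class = "protsketch_integrity_error")
})

test_that("table validation enforces the interchange invariants", {
  good <- rela_fixture()
  expect_silent(as_feature_table(good))

  bad_len <- good
  bad_len$length[2] <- bad_len$length[2] + 1
  expect_error(as_feature_table(bad_len), class = "protsketch_schema_error")

  bad_coord <- good
  bad_coord$end[3] <- bad_coord$begin[3] - 1
  expect_error(as_feature_table(bad_coord), class = "protsketch_coordinate_error")

  gap_order <- good
  gap_order$order <- 2L
  expect_error(as_feature_table(gap_order), class = "protsketch_schema_error")

  chainless <- good[good$type != "CHAIN", ]
  expect_error(as_feature_table(chainless), class = "protsketch_schema_error")
  expect_silent(as_feature_table(chainless, require_chain = FALSE))

  expect_error(as_feature_table(good[, 1:4]), class = "protsketch_schema_error")
})

test_that("typed selection preserves schema and order values", {
  rela <- rela_fixture()
  domains <- select_type(rela, "DOMAIN")
  expect_equal(nrow(domains), 1L)
  expect_equal(domains$description, "RHD")
  expect_equal(names(domains), names(rela))

  expect_equal(nrow(select_type(rela, "REPEAT")), 0L)
  expect_equal(nrow(select_type(five_protein_fixture(), "CHAIN")), 7L)

  # subsets of a multi-protein table keep their original order values
  p5_motifs <- select_type(five_protein_fixture(), "MOTIF")
  expect_true(all(p5_motifs$order %in% c(1L, 4L, 5L)))
  expect_equal(nrow(p5_motifs), 3L)
})

test_that("phosphosite selection takes Phospho-prefixed single residues only", {
  tbl <- as_feature_table(tibble::tibble(
    type = c("CHAIN", "MOD_RES", "MOD_RES", "MOD_RES", "MOD_RES"),
    description = c("chain", "Phosphoserine; by CK2", "N-acetylmethionine",
                    "phosphotyrosine", "Omega-N-methylarginine"),
    begin = c(1, 536, 1, 90, 30),
    end = c(600, 536, 1, 90, 30),
    length = c(599, 0, 0, 0, 0),
    accession = "Q04206", entryName = "TF65_HUMAN",
    taxid = 9606L, order = 1L
  ))
  ph <- select_phospho(tbl)
  expect_equal(nrow(ph), 2L)
  expect_true(all(ph$begin == ph$end))
  expect_setequal(ph$description, c("Phosphoserine; by CK2", "phosphotyrosine"))
  expect_equal(nrow(select_phospho(tbl[0, ])), 0L)
})
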