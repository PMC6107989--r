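# Layout geometry: canvas extents, chain bands and labels, to-scale feature
# rectangles, phosphosite markers, and the brute-force glyph-count oracle.

test_that("canvas extent follows the longest protein and the band count", {
  rela <- rela_fixture()
  p <- draw_canvas(rela)
  expect_s3_class(p, "protein_scene")
  expect_equal(p$canvas$max_end, 551)
  expect_gte(p$canvas$x_max, 551)
  expect_lte(p$canvas$x_min, 0)
  expect_equal(p$canvas$n_bands, 1L)
  expect_lte(p$canvas$y_min, 0.5)
  expect_gte(p$canvas$y_max, 1.5)

  p5 <- draw_canvas(five_protein_fixture())
  expect_equal(p5$canvas$n_bands, 5L)
  expect_gte(p5$canvas$y_max, 5.5)

  tiny <- as_feature_table(tibble::tibble(
    type = "CHAIN", description = "one residue", begin = 1, end = 1,
    length = 0, accession = "P00001", entryName = "ONE_TEST",
    taxid = 32630L, order = 1L
  ))
  pt <- draw_canvas(tiny)
  expect_gte(pt$canvas$x_max, 1)

  expect_error(draw_canvas(rela[0, ]), class = "protsketch_empty_error")
})

test_that("chains draw one rect per CHAIN record with labels in the gutter", {
  rela <- rela_fixture()
  p <- draw_chains(draw_canvas(rela), rela)
  chains <- scene_layer(p, "chains")
  expect_equal(nrow(chains), 1L)
  expect_equal(chains$x_start, 1)
  expect_equal(chains$x_end, 551)
  expect_equal(chains$y_center, 1)

  labels <- scene_layer(p, "chain_labels")
  expect_equal(labels$text, "TF65_HUMAN")
  expect_lt(labels$x, 0)  # left gutter

  five <- five_protein_fixture()
  p6 <- draw_chains(draw_canvas(five), five, labels = fig6_labels,
                    fill = "lightsteelblue1", outline = "grey", label_size = 5)
  chains6 <- scene_layer(p6, "chains")
  expect_equal(nrow(chains6), 7L)
  expect_true(all(chains6$fill == "lightsteelblue1"))
  expect_true(all(chains6$outline == "grey"))
  labels6 <- scene_layer(p6, "chain_labels")
  expect_equal(labels6$text, fig6_labels)
  expect_true(all(labels6$size == 5))
  # bottom-up: first label sits on band 1, last on band 5
  expect_equal(labels6$y[1], 1)
  expect_equal(labels6$y[7], 5)

  expect_error(draw_chains(draw_canvas(five), five, labels = c("a", "b")),
               "expected 7, got 2", class = "protsketch_config_error")
  expect_error(draw_domains(draw_canvas(five), five),
               class = "protsketch_validation_error")
})

test_that("feature rectangles are exactly to scale on the right bands", {
  rela <- rela_fixture()
  p <- draw_chains(draw_canvas(rela), rela)
  p <- draw_domains(p, rela)
  p <- draw_regions(p, rela)
  p <- draw_motif(p, rela)

  dom <- scene_layer(p, "domains")
  expect_equal(nrow(dom), 1L)
  expect_equal(c(dom$x_start, dom$x_end), c(19, 306))
  expect_equal(dom$category, "RHD")
  expect_equal(dom$y_center, 1)
  expect_gt(dom$half_height[1], scene_layer(p, "chains")$half_height[1])

  reg <- scene_layer(p, "regions")
  expect_true(all(c(415, 536) %in% reg$x_start))
  expect_true(all(c(459, 544) %in% reg$x_end))

  mot <- scene_layer(p, "motifs")
  expect_equal(c(mot$x_start, mot$x_end), c(301, 304))

  # empty subsets leave a no-op layer
  p <- draw_repeat(p, rela)
  expect_equal(nrow(scene_layer(p, "repeats")), 0L)

  # to-scale invariant against the source records
  for (name in c("domains", "regions", "motifs")) {
    d <- scene_layer(p, name)
    src <- select_type(rela, toupper(sub("s$", "", name)))
    expect_equal(sort(d$x_end - d$x_start), sort(src$end - src$begin))
  }
})

test_that("shared category names share one color and one legend entry", {
  five <- five_protein_fixture()
  p <- draw_domains(draw_chains(draw_canvas(five), five), five)
  dom <- scene_layer(p, "domains")
  rhd_fills <- unique(dom$fill[dom$category == "RHD"])
  expect_length(rhd_fills, 1L)
  legend <- p$legend[p$legend$layer == "domains", ]
  expect_equal(sum(legend$category == "RHD"), 1L)
  expect_setequal(legend$category, unique(dom$category))
})

test_that("phosphosite markers sit above the chain at the site position", {
  rela <- rela_fixture()
  p <- draw_phospho(draw_chains(draw_canvas(rela), rela), rela, size = 3)
  markers <- scene_layer(p, "phospho")
  expect_equal(nrow(markers), 4L)
  expect_setequal(markers$x, c(38, 122, 123))
  expect_true(all(markers$y > 1))
  expect_true(all(markers$size == 3))
  expect_true(all(markers$fill == "yellow"))

  # a site record places its marker at the residue position
  extra <- rela
  extra <- dplyr::bind_rows(extra, tibble::tibble(
    type = "MOD_RES", description = "Phosphoserine; by IKK",
    begin = 536, end = 536, length = 0, accession = "Q04206",
    entryName = "TF65_HUMAN", taxid = 9606L, order = 1L
  ))
  p2 <- draw_phospho(draw_chains(draw_canvas(extra), extra), extra,
                     size = 3, fill = "red")
  m2 <- scene_layer(p2, "phospho")
  expect_true(536 %in% m2$x)
  expect_true(all(m2$fill == "red"))

  # no phospho rows, no markers
  bare <- rela[rela$type != "MOD_RES", ]
  p3 <- draw_phospho(draw_chains(draw_canvas(bare), bare), bare)
  expect_equal(nrow(scene_layer(p3, "phospho")), 0L)
})

test_that("features outside their chain extent are reported, not clipped", {
  tbl <- as_feature_table(tibble::tibble(
    type = c("CHAIN", "DOMAIN"),
    description = c("short chain", "overhanging"),
    begin = c(1, 50), end = c(100, 150), length = c(99, 100),
    accession = "P00001", entryName = "SYN_TEST", taxid = 32630L, order = 1L
  ))
  expect_warning(p <- draw_domains(draw_chains(draw_canvas(tbl), tbl), tbl),
                 "overhanging")
  d <- scene_layer(p, "domains")
  expect_equal(d$x_end, 150)  # still drawn full length
})

test_that("layout is deterministic and matches a brute-force glyph count", {
  build <- function(tbl) {
    p <- draw_chains(draw_canvas(tbl), tbl)
    p <- draw_domains(p, tbl)
    p <- draw_phospho(p, tbl)
    p
  }
  tbl <- synthetic_table(6, seed = 11)
  expect_identical(build(tbl), build(tbl))

  p <- build(tbl)
  # oracle: per-band glyph counts from direct grouping of the records
  counts <- table(factor(tbl$order, levels = seq_len(6)), tbl$type)
  for (band in seq_len(6)) {
    chains <- scene_layer(p, "chains")
    expect_equal(sum(chains$y_center == band), unname(counts[band, "CHAIN"]))
    dom <- scene_layer(p, "domains")
    n_dom <- if ("DOMAIN" %in% colnames(counts)) unname(counts[band, "DOMAIN"]) else 0L
    expect_equal(sum(dom$y_center == band), n_dom)
    ph <- scene_layer(p, "phospho")
    expect_equal(sum(floor(ph$y) == band), nrow(select_phospho(tbl[tbl$order == band, ])))
  }
  # band integrity: all glyphs of one accession share one y band
  chains <- scene_layer(p, "chains")
  expect_equal(length(unique(chains$y_center)), 6L)
})

test_that("tidy and glance summarise a scene", {
  rela <- rela_fixture()
  p <- draw_domains(draw_chains(draw_canvas(rela), rela), rela)
  td <- tidy(p)
  expect_s3_class(td, "tbl_df")
  expect_setequal(unique(td$layer), c("chains", "chain_labels", "domains"))
  g <- glance(p)
  expect_equal(g$n_bands, 1L)
  expect_equal(g$n_glyphs, nrow(td))
  expect_equal(g$n_legend, 1L)

  js <- scene_to_json(p)
  expect_identical(js, scene_to_json(p))
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$canvas$max_end, 551)
})
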