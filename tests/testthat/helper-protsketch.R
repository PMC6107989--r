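# Shared test helpers: in-code construction of raw feature sets in the API
# response shape, and attribute-insensitive table comparison.

# One raw feature entry as the UniProt Proteins API emits it (coordinates
# as strings).
raw_feature <- function(type, description, begin, end) {
  list(type = type, category = "TEST", description = description,
       begin = as.character(begin), end = as.character(end))
}

# One raw feature set for a minimal protein: chain 1..len plus extras.
raw_set <- function(accession, entry_name = paste0(accession, "_TEST"),
                    len = 100, extras = list(), taxid = 9606) {
  list(accession = accession, entryName = entry_name, taxid = taxid,
       features = c(list(raw_feature("CHAIN", "test chain", 1, len)), extras))
}

rela_fixture_path <- function() {
  system.file("extdata", "rela_synthetic.json", package = "protsketch")
}

five_rel_tsv_path <- function() {
  system.file("extdata", "five_rel_synthetic.tsv", package = "protsketch")
}

expect_same_table <- function(actual, expected) {
  expect_true(isTRUE(all.equal(as.data.frame(actual), as.data.frame(expected),
                               check.attributes = FALSE)))
}

scene_layer <- function(scene, name) {
  for (layer in scene$layers) {
    if (layer$name == name) return(layer$data)
  }
  NULL
}

fig6_labels <- c("p50/p105", "p50/p105", "p52/p100", "p52/p100",
                 "Rel B", "c-Rel", "p65/Rel A")
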