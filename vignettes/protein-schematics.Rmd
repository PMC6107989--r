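---
title: "Drawing to-scale protein schematics: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drawing to-scale protein schematics: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protsketch)
```

## The problem and the model

A protein schematic is a one-dimensional map: the mature polypeptide
chain drawn as a horizontal bar in amino-acid coordinates, with annotated
features — structured domains, free-text regions, short motifs, repeat
elements, and post-translationally modified residues — overlaid at their
sequence positions. protsketch treats this as a three-stage
transformation with a tabular core:

1. **Acquisition.** Feature annotations come from the UniProt Proteins
   API features endpoint (or a saved JSON of the same shape). One query
   carries all requested accessions, comma-separated; the service does
   not preserve request order, so results are re-sorted to the request
   before anything downstream sees them. Request order is semantic: it
   becomes the bottom-up stacking order of the drawn proteins.

2. **Normalisation.** Each feature becomes one row of a nine-column
   table: `type`, `description`, `begin`, `end`, `length`, `accession`,
   `entryName`, `taxid`, `order`. Coordinates are 1-based inclusive
   exactly as UniProt delivers them; no conversion happens on ingest, and
   the GFF3 exporter keeps 1-based inclusive coordinates per that
   standard. Features whose coordinates are absent or non-numeric
   (UniProt occasionally emits unknown or approximate positions) are
   dropped with a reported count — a guessed coordinate in a to-scale
   drawing would be a silent lie.

3. **Layout and rendering.** The table maps affinely to geometry: protein
   with stacking order *k* occupies the band centred on *y = k*; a
   feature `[begin, end]` becomes a rectangle from `x = begin` to
   `x = end`. Because a single affine transform maps sequence
   coordinates to drawing coordinates, the on-page width ratio of any two
   features equals their residue-span ratio — the "to scale" contract,
   enforced by an exact integer invariant (`x_end − x_start` equals
   `end − begin`) and tested as such.

## The length convention

The `length` column is defined as `end − begin`, not the inclusive
residue count `end − begin + 1`. A 551-residue chain annotated `1..551`
therefore has length 550, and a single-residue phosphosite `38..38` has
length 0. This is the established convention of the feature-table format
this package interoperates with, and every packaged value follows it; the
column is best read as "span beyond the first residue". Code that needs
residue counts should compute `end − begin + 1` explicitly. The
discrepancy is deliberate and documented rather than corrected, because
silently redefining an interchange column would corrupt round trips with
existing tables.

## Parameters that matter

| Parameter | Where | Default | Units | Why |
|---|---|---|---|---|
| `page_size` | `fetch_features()` | 100 | entries | one page comfortably covers typical family queries; must be ≥ the accession count |
| retries | `fetch_features()` | 3, backoff 1 s/2 s/4 s | — | absorbs transient 5xx/timeouts without masking bad input (4xx fails at once) |
| chain half-height | layout | 0.2 | band units | chains slimmer than feature boxes, so overlays read as annotation |
| feature half-height | layout | 0.25 | band units | slightly taller than the chain; the familiar look of published schematics |
| phosphosite y offset | layout | +0.25 | band units | circles sit on the chain's upper edge, legible at small sizes |
| left gutter / right margin | `draw_canvas()` | 20 % / 10 % of the longest protein | aa | label room left of residue 0; breathing space right of the longest chain |
| y padding | `draw_canvas()` | 0.5 | band units | half a band above and below the stack |
| `label_size`, marker `size` | `draw_chains()`, `draw_phospho()` | 4 / 2 | mm (ggplot2 text/point convention) | matches what users of ggplot-based figures expect to type |
| `base_size` | themes | 11 (default), 10 (publication) | pt | standard ggplot2 base sizes |

None of the band-geometry values is dictated by the data; they are
aesthetic choices fixed once so that output is reproducible, and flagged
here as such.

## Color and legend policy

Each feature layer (domains, regions, motifs, repeats) assigns fills
from a fixed categorical palette keyed by the **sorted** distinct
description strings within that layer. Sorting makes the assignment a
pure function of the category set: the same categories get the same
colors across runs, machines and input orderings, and two proteins
sharing a description (e.g. "RHD") share one color and one legend entry.
The palette wraps after 14 categories; schematics with more distinct
categories than that will reuse colors, which is a legibility limit, not
a correctness one. Chains and phosphosites take user-set colors
(`grey`/`black` and `yellow` by default) and contribute no legend
entries.

## Degenerate inputs and tie-breaks

* A one-residue protein (`CHAIN 1..1`) yields a valid canvas; extents
  are always computed from `max(end)`, never from an assumed minimum.
* Entries annotated with several CHAIN records (processed proteins such
  as p105→p50) keep all chains, stacked on the one band their accession
  owns; labels are therefore per chain record, not per band (see below).
* Overlapping glyphs within a layer draw in table order; no collision
  resolution is attempted, matching the layered look of conventional
  schematics.
* A feature extending beyond its protein's chain extent is drawn in
  full and reported with a warning — clipped geometry would silently
  misrepresent the annotation.
* A ranged modified residue would be marked at `(begin + end) / 2`; for
  the single-residue sites UniProt emits this is just `begin`. The
  phosphosite selector itself only admits single-residue records
  (`MOD_RES`, description starting "Phospho", `begin == end`), the
  minimal rule that captures phosphoserine/-threonine/-tyrosine and
  excludes acetylation and methylation.

## Chain labels: one per chain, not one per band

When several chains share a band, the natural unit for labelling is the
chain record: the five-protein NF-κB figure takes seven labels
(`p50/p105` twice, `p52/p100` twice, `Rel B`, `c-Rel`, `p65/Rel A`)
because the two precursor bands each carry two chain records. A
labels-per-band rule could not express the precursor/processed-form
naming at all, so `draw_chains()` validates `length(labels)` against the
number of CHAIN records and reports expected vs. given on mismatch.
Default labels are the UniProt entry names.

## Deterministic SVG as the primary backend

`render_scene()` serialises the scene geometry straight to SVG 1.1
elements in a fixed order with fixed `%.2f` coordinate formatting, no
timestamps and no generated ids: two renders of the same scene and theme
are byte-identical. That makes figures diffable in version control and
gives the test suite a snapshot surface that cannot flake. Fonts are
referenced by family name only (`Helvetica, Arial, sans-serif`), keeping
files portable at the cost of metric-exact text layout — text placement
uses character-count estimates, adequate for legends and labels but not
for typography-critical output. PNG output rasterises the ggplot2
`autoplot()` view of the same geometry through the cairo device at a
configurable DPI (default 300); PNG bytes are device-dependent and carry
no determinism contract.

## What the synthetic generator emulates — and what it does not

`synthetic_table(n_proteins, seed, max_length, domain_rate,
phospho_rate)` builds test universes: per protein one chain `1..L` with
`L` uniform on `[10, max_length]` (default `max_length` 1000, spanning
the single-domain-protein to p105-precursor scale), a Poisson(`domain_rate`,
default 2) number of non-overlapping domains placed inside the chain by
rejection sampling (up to 100 attempts per domain, then fewer domains —
simple and reproducible), and a Poisson(`phospho_rate`, default 4) number
of single-residue phosphosites. Domain descriptions draw from a small
fixed vocabulary so legend logic is exercised; the taxon id is 32630
(synthetic construct); the caller's RNG state is saved and restored.

The generator emulates the *structure* real annotations have — chains,
contained interval features, point sites, multi-protein stacks — not
their content: no evidence codes, no isoform coordinate systems, no
ragged or approximate coordinates, no biologically realistic domain
families. Passing property tests on generated tables therefore
demonstrates geometric and schema correctness on well-formed input; the
messiness of live UniProt data is covered separately by the ingest rules
(coordinate dropping, missing-field errors) and by fixtures transcribed
in the API's own response shape.

Test problem sizes were chosen to probe the invariants at meaningful
scale while staying quick on a laptop: the to-scale property runs over
100 seeded three-protein tables, the invariant sweep uses one 50-protein
table, and rendering properties sample 20 seeds.

## Known limitations

* Only the UniProt *features* endpoint is supported — no full-entry
  records, no ID mapping, no BioMart/Ensembl queries. Accession lists
  from such sources are accepted as files instead.
* No label collision avoidance and no interactive output; dense
  figures may need manual `label_size` tuning.
* Variant-type features (`VARIANT`, `MUTAGEN`) have no dedicated
  semantics; they would render as generic rectangles via the typed
  selectors if requested.
* UniProt annotation content changes between releases; packaged
  fixtures are frozen transcriptions (marked `synthetic`), so live
  queries for the same accessions will generally return more rows than
  the fixtures contain.
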