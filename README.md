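# protsketch

Protein schematics — the horizontal bar diagrams that show a protein's
chain with its domains, motifs and phosphorylation sites drawn to scale —
are among the most common figures in molecular biology, and among the
least reproducible: most are drawn by hand. protsketch generates them
programmatically. Given one or more UniProt accession numbers (or an
offline feature file), it retrieves the annotated features of each
protein, normalises them into a tidy table, and renders a to-scale,
publication-style schematic of one protein or a whole family, entirely
from a script.

It is written for bench scientists and bioinformaticians who want protein
figures that can be regenerated, versioned and shared as code.

## The model

Every annotated feature is an interval on the amino-acid sequence. The
pipeline reduces each protein to a set of records

```
(type, description, begin, end, length, accession, entryName, taxid, order)
```

where `type` is the UniProt feature category (`CHAIN`, `DOMAIN`,
`REGION`, `MOTIF`, `REPEAT`, `MOD_RES`), `begin`/`end` are 1-based
inclusive residue positions, `length = end − begin` (the format's
convention: a single-residue site has length 0), and `order` is the
bottom-up stacking index — protein *k* of *K* is drawn on horizontal band
*y = k*, with band 1 at the bottom. The drawing is affine in sequence
space: a feature spanning `[begin, end]` becomes a rectangle of width
`end − begin` in amino-acid units on its protein's band, so relative
feature sizes are visually faithful within and across proteins.
Phosphosites (`MOD_RES` records whose description starts with "Phospho")
are drawn as circles just above the chain.

The pipeline is four composable stages, each usable on its own:

1. **client** — `fetch_features()` / `load_feature_sets()`: UniProt
   Proteins API or offline JSON in the same shape.
2. **model** — `flatten_features()` and friends: the validated
   nine-column tibble.
3. **layout** — `draw_canvas()`, `draw_chains()`, `draw_domains()`,
   `draw_regions()`, `draw_motif()`, `draw_repeat()`, `draw_phospho()`:
   renderer-independent geometry.
4. **render** — `render_scene()` (deterministic SVG, or PNG) and
   `autoplot()` (ggplot2).

## Worked example

```r
library(protsketch)

rela <- rela_fixture()          # packaged table for human RelA/p65 (Q04206)
dplyr::select(rela, type, description, begin, end, length)[1:5, ]
#> # A tibble: 5 × 5
#>   type   description                 begin   end length
#>   <chr>  <chr>                       <dbl> <dbl>  <dbl>
#> 1 CHAIN  Transcription factor p65        1   551    550
#> 2 DOMAIN RHD                            19   306    287
#> 3 REGION Activation domain             415   459     44
#> 4 MOTIF  Nuclear localization signal   301   304      3
#> 5 REGION Transactivation domain        536   544      8
```

The chain is 551 residues (length 550 under the `end − begin`
convention); the Rel homology domain (RHD) spans residues 19–306. Build
and render the schematic:

```r
p <- draw_canvas(rela) |>
  draw_chains(rela, label_size = 2.5) |>
  draw_domains(rela) |>
  draw_phospho(rela, size = 3)

glance(p)
#> # A tibble: 1 × 6
#>   n_bands n_layers n_glyphs n_legend x_min x_max
#>     <int>    <int>    <int>    <int> <dbl> <dbl>
#> 1       1        4        7        1 -110.  606.

render_scene(p, publication_theme(), "rela.svg")   # byte-stable SVG
autoplot(p)                                        # or a ggplot
```

One band, seven glyphs (chain, its label, the RHD rectangle, four
phosphosite circles), one legend entry; the x-axis runs past residue 551
with a left gutter for the label. A live version of the same figure is
one call away: `fetch_features("Q04206") |> flatten_features()`.

For families, stack proteins bottom-up and customise freely — the
five-protein NF-κB fixture carries seven chains over five bands (the
p105→p50 and p100→p52 precursors share bands with their processed
forms):

```r
five <- five_protein_fixture()
p <- draw_canvas(five) |>
  draw_chains(five, fill = "lightsteelblue1", outline = "grey",
              labels = c("p50/p105", "p50/p105", "p52/p100", "p52/p100",
                         "Rel B", "c-Rel", "p65/Rel A"), label_size = 5) |>
  draw_phospho(five, size = 3, fill = "red")
render_scene(p, protein_theme(background = "white"), "nfkb.svg")
```

## Command line

The installed `exec/protsketch` script exposes the same pipeline:

```sh
protsketch fetch Q04206 -o rel.json
protsketch draw rel.json --show domains,regions,motifs,phospho \
    --phospho-size 3 --theme publication --title "Human Rel A/p65" -o fig.svg
```

Exit codes are stable for pipelines: 0 success, 2 usage/validation
error, 3 transport error. A `--config` file of `key=value` lines makes a
figure recipe checked into version control.

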