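# syntenymap

Synteny — conservation of gene order — is one of the most reliable
comparative-genomic signals for orthology and for functional association
between prokaryotic genes. `syntenymap` is an offline R toolkit for
geneticists and phylogeneticists who want, for a single query protein and a
set of annotated bacterial or archaeal replicons, an answer to: *where is
this protein encoded, what is its genomic neighborhood there, and which
neighborhood genes are orthologous across genomes?*

## The method

For a query protein *q* and genomes *G₁…Gₙ* (≤ 100 per job):

1. **Self-normalization.** *q* is aligned to itself with
   Smith-Waterman-Gotoh (BLOSUM62; affine gap cost `11 + k·1` for a gap of
   length *k*), giving *S(q,q)*. Every later hit is reported as the
   normalized score `100·S(q,t)/S(q,q)` — self-match = 100, with 30% as
   the conventional discriminant for *bona fide* orthology (user-settable
   between 10 and 100).
2. **Six-frame translated search.** *q* is locally aligned to every
   stop-delimited translated block (≥ 10 residues) of all six reading
   frames of each genome; hit midpoints are mapped back to genomic
   coordinates. Genomes are ranked by best normalized hit; hitless genomes
   form the *not found* list.
3. **Windows.** A 15 kb window (default) is extracted around each retained
   hit, with wrap-around on circular replicons, and populated with the
   annotated CDS it overlaps (translation table 11).
4. **Star coloring.** The top-ranked segment's proteins are compared
   all-vs-all; connected components of the thresholded normalized-score
   matrix each get one color (paralogs share a color). All other segments
   are compared only to this reference and inherit the color of their best
   match, staying neutral grey below threshold.
5. **Scale-exact maps.** All tracks render at one global scale (SVG and
   paginated PDF, plus CSV/JSON exports), so gene length is comparable
   across rows and gene *fusions* are visible directly: a fused gene's
   arrow is exactly as wide as its parts combined.

Two companion components support larger analyses: a depth-7 taxonomy tree
(`normalize_lineage()`, `build_taxon_tree()`, `select_node()`,
`search_taxa()`) for lineage-driven genome selection from a flat lineage
table, and a multi-query cluster scanner (`scan_clusters()`,
`scan_library()`) that chains hits to several query proteins while
consecutive hit centers lie < 8000 bp apart — the procedure for finding
rare complete gene clusters, such as the four-gene
YgjD/YeaZ/YjeE/RimN tRNA-modification cluster, across a genome library.

A seeded fixture generator (`make_fixture_genome()`) plants proteins,
paralogs and fusions as CDS in random-background GenBank replicons with
exact ground truth; it drives the test suite and is exported for your own
benchmarking.

## Worked example

```r
library(syntenymap)
set.seed(1)
p <- lapply(c(110, 95, 100), random_protein)
spec <- function(acc, org, starts) list(
  accession = acc, organism = org, length_bp = 30000,
  genes = lapply(seq_along(starts), function(i)
    list(protein = p[[i]], start = starts[i], strand = 1L,
         locus_tag = paste0(acc, "_", i))))
genomes <- make_fixture_library(
  list(spec("GX01", "Synthetica prima", c(12000, 13000, 14000)),
       spec("GY01", "Synthetica secunda", c(5000, 6000, 7000))),
  seed = 9)
report <- run_synteny(p[[1]], genomes)
report
#> <synteny_report> query 110 aa | 2 segment row(s) | 0 not found
#>    1. GX01 (Synthetica prima): 3 genes, 3 colored
#>    2. GY01 (Synthetica secunda): 3 genes, 3 colored
report_table(report)[, c("rank","accession","locus_tag","start","end","color","norm_score")]
#>   rank accession locus_tag start   end color norm_score
#> 1    1      GX01    GX01_1 12000 12333     1        100
#> 2    1      GX01    GX01_2 13000 13288     2        100
#> 3    1      GX01    GX01_3 14000 14303     3        100
#> 4    2      GY01    GY01_1  5000  5333     1        100
#> 5    2      GY01    GY01_2  6000  6288     2        100
#> 6    2      GY01    GY01_3  7000  7303     3        100
```

Both genomes carry the planted three-gene neighborhood; GX01 ranks first
(tie at 100% broken by accession) and becomes the coloring reference, and
each GY01 gene inherits the color of its GX01 ortholog (`color` 1–3) at
normalized score 100. `render_svg(report, path = "synteny.svg")` draws the
two tracks to one scale; `export_csv()` / `export_json()` write the same
table and full data model.

A shell entry point wrapping these functions ships at
`inst/cli/syntenymap.R` (subcommands `run`, `tax`, `scan`, `fixtures`).

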