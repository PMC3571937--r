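---
title: "Methods: translated-search synteny maps for prokaryotic genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: translated-search synteny maps for prokaryotic genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntenymap)
```

## The problem and the method

Conservation of gene order (shared synteny) is among the strongest
comparative-genomic signals for orthology and for functional association
between genes. Given one query protein and a set of annotated prokaryotic
replicons, `syntenymap` answers: *in which of these genomes is the query
found, what does its genomic neighborhood look like there, and which
neighborhood genes are orthologous across genomes?*

The pipeline is a multiple-center star procedure:

1. **Self-score.** The query protein is aligned to itself
   (Smith-Waterman-Gotoh, affine gaps). All later scores are expressed as a
   percentage of this self-score — the *normalized score*, a self-calibrated
   orthology measure with a conventional discriminant of 30% for *bona
   fide* orthology.
2. **Translated search.** The query is compared against the DNA of every
   selected genome in all six reading frames. Stop codons split each frame
   into blocks; every block of at least 10 residues is locally aligned to
   the query, and hits at or above the threshold are mapped back to genomic
   coordinates (frame- and strand-aware midpoint).
3. **Ranking.** Genomes are sorted by their best normalized hit; genomes
   with no hit form the *not found* list, which is part of every report.
4. **Window extraction.** A fixed-width window (default 15 kb) is extracted
   around each retained hit center and populated with the CDS features it
   overlaps, translated under genetic code 11 per the annotation.
5. **Reference coloring.** The proteins of the top-ranked genome's segment
   are compared all-vs-all; pairs at or above the threshold are edges and
   connected components receive one color each, so paralogs within the
   reference window share a color.
6. **Color propagation.** Every other segment's proteins are compared *only
   to the reference* (star topology); a gene inherits the color of its best
   reference match when that match reaches the threshold, and is drawn
   neutral grey otherwise.
7. **Rendering.** All tracks are drawn at one global scale, so a gene twice
   as long is exactly twice as wide in the map. This makes gene *fusions*
   visible directly: a fused gene's arrow is as wide as its parts combined,
   and it carries the color of its better-matching part.

A separate scanner (`scan_clusters()`/`scan_library()`) detects multi-gene
clusters directly: hits to several query proteins are pooled per genome and
greedily chained while consecutive hit centers lie strictly less than a
bound (default 8000 bp) apart; a chain containing every query is a
*complete* cluster. This is the procedure for finding rare complete
operon-like arrangements — e.g. the four-protein tRNA-modification complex
(YgjD/YeaZ/YjeE/RimN) — across a genome library.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_norm_score` | 30 (%) | Orthology discriminant; accepted range 10–100. Hit filtering is anti-monotone in it. |
| `mode` | `best_hit` | One segment per genome, or `all_hits` with >50%-overlapping windows merged. |
| `width` | 15000 (bp) | Window width. Linear replicons clip at the ends; circular replicons wrap to exactly `width`. |
| `gap_open`, `gap_extend` | 11, 1 | Affine gap penalties; a gap of length *k* costs `gap_open + k * gap_extend`. BLOSUM62 substitution scores. |
| `max_gap` | 8000 (bp) | Cluster-scan chaining bound, strict `<`, measured center-to-center. |
| genome cap | 100 | Maximal genomes per job, enforced before any computation. |

The matrix and gap defaults are the conventional protein-search settings
(BLOSUM62 with 11/1); the original service did not document its choices, so
these are this package's own defaults, and any NCBI-format matrix can be
substituted via `read_score_matrix()`.

## Design choices made where the design was open

* **Local, not global, alignment.** The method's own description mentions a
  "global" SWG step, but the operation — detecting orthologs among windows
  full of unrelated proteins — only makes sense locally: global alignment
  of unrelated proteins yields uninterpretable negative scores. Local is
  the default; a `mode = "global"` switch exists for auditability.
* **Pairwise normalization by the longer sequence's self-score.** In the
  coloring steps, a pair's score is divided by the self-score of the longer
  of the two proteins. A fusion protein therefore scores moderately
  (roughly the fraction it shares) rather than 100% against each part,
  which is exactly the behavior that keeps fusions distinguishable.
* **Star topology.** Non-reference segments are compared only to the
  reference, never to each other. Tie-breaks in propagation go to the
  leftmost reference gene; ranking ties go to the lexicographically
  smaller accession. Both choices exist purely for determinism.
* **Depth-7 lineage padding.** Lineages are kept at a constant rank depth
  of 7. Incomplete lineages with a known superkingdom are stored as
  `<superkingdom>:unclassified` with the phylum kept in the third slot when
  available; lineages lacking a superkingdom go under
  `Prokaryote:unclassified`. The alternative reading — literally truncating
  incomplete lineages to two levels — would break the uniform leaf depth
  that recursive node selection relies on, so padding was chosen.
* **Coordinates.** Internally 0-based half-open everywhere; GenBank's
  1-based inclusive coordinates are converted at the parse boundary only.
  Origin-spanning CDS on circular replicons are rotated out at parse time
  (the offset is recorded), so all window arithmetic stays linear.
* **Translation.** Fixed to genetic code 11 (bacteria/archaea). The
  annotation is authoritative: internal stops in an annotated CDS are
  preserved, only the trailing stop is removed. Ambiguity codes other than
  `N` are rejected at parse time; `X` and `*` score zero against
  everything so annotation artifacts cannot create spurious orthology.
* **Each replicon is scored independently**; multi-replicon organisms are
  not pooled.
* **Native translated search.** The six-frame search is implemented
  natively (stop-delimited blocks, each locally aligned) rather than
  wrapping an external search executable, which keeps runs deterministic
  and dependency-free at desk scale. Blocks shorter than 10 residues are
  skipped as noise floor.

## What the synthetic genomes emulate — and what they do not

`make_fixture_genome()` plants given proteins as CDS (back-translated under
code 11 with seeded codon choice, fixed TAA stop) into random-background
replicons, and verifies the background is free of planted 30-mers on either
strand. This gives exact ground truth: planted orthologs must score 100%,
decoy genomes must stay below threshold, fusion CDS lengths are known to
the base pair. Default study conditions used in the tests and the
acceptance script: 30 kb genomes, a five-gene cluster (proteins of 85–120
residues, ~1 kb spacing) carried by three genomes — one with a paralog pair
at ~93% identity, one with a two-gene fusion — plus one cluster-free
genome; the cluster scan uses four queries on a ten-genome library of
which exactly two carry the complete four-gene plant within 8 kb.

Real data differ in ways these fixtures deliberately do not model: genuine
homology gradients (fixture proteins are either planted or random, so
near-threshold behavior is exercised only via constructed mutants), biased
codon usage and GC skew, overlapping genes, pseudogenes, sequencing gaps,
and annotation errors. Passing tests therefore demonstrate the correctness
of the machinery (coordinate mapping, scoring, chaining, coloring,
rendering), not field performance on borderline orthologs.

## Numerical and degenerate-input behavior

Empty sequences align with score 0 and empty spans. A local score is never
negative. A query shorter than 10 residues after cleaning is an error (the
self-score denominator must be meaningful). CDS intervals that are not a
multiple of 3 are translated up to the last complete codon with a warning.
Windows wider than a circular replicon degrade to the whole replicon.
`normalized_score` is clipped to [0, 100] and requires a strictly positive
denominator. Problem sizes in the test suite (30–40 kb genomes, ≤ 10
genomes per run, 200 oracle alignment pairs of ≤ 15 residues, coloring
oracles up to 8 genes) were chosen as the smallest sizes that still
exercise every boundary of the contracts.

## Known limitations

* The native translated search is exhaustive (no k-mer seeding); it is
  meant for up to ~100 desk-scale replicons per job, not for chromosome-
  scale libraries. The 100-genome cap reflects this.
* Frameshifted homologs split across two stop-delimited blocks are scored
  per block and may fall below threshold individually.
* No e-value statistics: ranking and filtering use normalized scores only.
* Colors cascade only from the reference; a gene family absent from the
  reference window remains uncolored in every row.
* EMBL/GFF3 input, pseudogene handling and strain-level sub-ranks are out
  of scope.

## A small worked example

```{r example, eval = FALSE}
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
render_svg(report, path = "synteny.svg")
export_csv(report, path = "synteny.csv")
```
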