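# tadlink

Linking differentially methylated regions (DMRs) to genes through the 3D
organization of the genome.

## The problem

Comparative epigenomics can identify genomic regions whose DNA methylation
differs between closely related groups — for example, modern-human-derived
DMRs that separate present-day humans from archaic humans. A DMR that
overlaps a promoter or a gene body can be assigned to that gene directly, but
many DMRs are *non-genic* (ngDMRs) and carry no positional label. Chromatin
is folded into topologically associating domains (TADs) whose boundary
anchors are brought into physical contact by loops, so a regulatory element
near one anchor can act on a gene near the opposite anchor despite an
enormous linear separation. `tadlink` implements that reasoning as a
reproducible pipeline for anyone with per-cell-type TAD calls (BED), a DMR
list, gene models, a genome FASTA and a gene-to-body-part annotation table.

## The method

1. **Consensus TADs.** With four cell types (basis cell type A, others B, C,
   D), every basis TAD `T_i` receives a conservation score

   `S_i = median( max_{T_j in T_B} J(T_i, T_j), max_{T_k in T_C} J(T_i, T_k), max_{T_l in T_D} J(T_i, T_l) )`

   where `J` is the Jaccard overlap (intersection length over union length)
   of two intervals. TADs of at least 100 kb with `S_i > 0.5` are tested by
   permutation (random same-length intervals on the same chromosome, p =
   (r+1)/(n+1)) and kept at Benjamini–Hochberg q < 0.05. Each conserved TAD
   is reported in two boundary variants: the *intersection* (section shared
   by all four cell types) and the *union* (full span).
2. **Placement tests.** Whether DMRs fall inside consensus TADs is tested
   against composition-matched Monte Carlo nulls (random intervals of equal
   length, GC content and CpG density); whether inside-TAD DMRs sit within
   50 kb of a TAD boundary is tested by uniform repositioning within the
   containing TAD. Both report an empirical p-value and a 2-cell chi-square
   against the simulation-mean expectation.
3. **DMR–gene linking.** For each ngDMR–gene pair sharing a TAD, a *linear*
   distance (edge gap along the chromosome) and a *spatial* distance (sum of
   the two features' distances to opposite TAD anchors) are computed; the
   ngDMR is linked to the closest gene when the smaller distance is below
   50 kb. Newly linked genes are merged with a prior differentially
   methylated gene (DMG) list.
4. **Organ enrichment.** The combined DMG list is tested per body part
   against a user-supplied gene-to-organ table: expected counts are
   `|list| * |organ| / |background|`, p-values come from random same-size
   gene draws (or the exact hypergeometric tail), with BH FDR across organs.

A first-class synthetic-data generator (`simulate_dataset()`) emulates all
five inputs with planted ground truth — conserved TADs with boundary jitter,
boundary-proximal and anchor-opposite DMRs, organ enrichment at a chosen
fold — so the whole pipeline is testable offline.

## Worked example

```r
library(tadlink)

sim <- simulate_dataset(
  chrom_sizes = c(chr1 = 1e7, chr2 = 1e7), n_tads = 30,
  n_genes = 100, n_dmrs = 80, frac_dmrs_genic = 0.3,
  frac_dmrs_boundary_proximal = 0.6, n_spatial_pairs = 3,
  planted = c(organ_05 = 3), seed = 42
)

cons <- call_consensus_tads(
  sim$tads[[sim$basis]], sim$tads[names(sim$tads) != sim$basis],
  sim$chrom_sizes, seed = 42
)
glance(cons)
#> # A tibble: 1 × 7
#>   n_basis n_tested n_conserved frac_conserved n_dropped span_intersection
#>     <int>    <int>       <int>          <dbl>     <int>             <dbl>
#> 1      30       19          15            0.5         0           8526586
```

Half of the 30 basis TADs were planted as conserved (5 kb boundary jitter)
and exactly those 15 are recovered. The placement tests then quantify how the
80 DMRs sit relative to the intersection variant:

```r
tads_i <- consensus_variant(cons, "intersection")
inside_tad_test(sim$dmrs, tads_i, sim$genome, seed = 42)
#> Placement test: fraction_inside_tads
#>   observed 0.6625, expected 0.4238 (mean of 200 simulations)
#>   Monte Carlo p = 0.004975; chi-square = 18.66 (df = 1), p = 1.559e-05

boundary_proximity_test(sim$dmrs, tads_i, n_sims = 10000, seed = 42)
#> Placement test: n_boundary_proximal
#>   observed 45, expected 11.22 (mean of 10000 simulations)
#>   Monte Carlo p = 9.999e-05; chi-square = 129 (df = 1), p = 6.908e-30
```

66% of DMRs fall inside consensus TADs versus 42% expected from
composition-matched randomization, and 45 inside-TAD DMRs are within 50 kb
of a boundary versus 11 expected — the planted boundary preference is
recovered at the smallest p the simulation counts allow. Linking the
non-genic DMRs and merging with a (here empty) prior DMG list:

```r
links <- link_dmrs_to_genes(dplyr::filter(sim$dmrs, !genic), sim$genes, tads_i)
merge_dmg_lists(links)
#> DMG merge: 31 linked DMRs -> 10 genes (10 new, 0 already present); 10 combined DMGs
```

Body-part enrichment against an annotation table with one organ planted at
3-fold among 60 true DMGs:

```r
genes <- sprintf("g%04d", 1:1000)
dmgs  <- withr::with_seed(70, sample(genes, 60))
ann <- simulate_organ_annotations(genes, dmgs, n_organs = 20, base_rate = 0.2,
                                  planted = c(organ_07 = 3), seed = 71)
head(tidy(organ_enrichment_test(dmgs, ann$annotations, seed = 72)), 3)
#> # A tibble: 3 × 8
#>   organ    observed expected enrichment_ratio        p     fdr significant depleted
#>   <chr>       <int>    <dbl>            <dbl>    <dbl>   <dbl> <lgl>       <lgl>
#> 1 organ_07       39     13.0             2.99 1.000e-4 0.00200 TRUE        FALSE
#> 2 organ_04       15     11.0             1.37 1.14 e-1 0.737   FALSE       FALSE
#> 3 organ_05       14     10.3             1.36 1.38 e-1 0.737   FALSE       FALSE
```

The planted organ is detected at FDR 0.002 with an estimated enrichment
ratio of 2.99 against the planted fold of 3. Every result type has `tidy()`,
`glance()` and `autoplot()` methods; `run_pipeline()` chains all four stages
from files on disk and writes TSV/BED/JSON artifacts plus a machine-readable
`summary.json`.

## Acceptance script

`scripts/acceptance.R` regenerates the default synthetic dataset from the
given seed, runs the complete pipeline end to end (consensus calling, both
placement tests for both boundary variants, linking, enrichment) and writes
the acceptance report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/tadlink-methods.Rmd` documents the statistical model, the null
models and their assumptions, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, and known
limitations.
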