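---
title: "tadlink: models, null distributions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tadlink: models, null distributions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadlink)
```

`tadlink` asks a single scientific question in four statistical steps: can
non-genic differentially methylated regions (ngDMRs) be assigned to target
genes by exploiting the folded, domain-structured organization of the
genome? This vignette records the models behind each step, the null
distributions used to calibrate them, every tunable parameter with its
default and rationale, and the design choices made where the methodology was
genuinely open. It states no empirical result that the package's test suite
does not itself compute.

## Coordinates and the overlap primitive

All intervals are 0-based, half-open (BED convention); 1-based inputs must
be converted at the I/O layer. Chromosome names are compared as exact
strings — `read_bed(add_chr_prefix = TRUE)` is the only normalization
offered, so silent cross-naming mismatches cannot occur. The Jaccard overlap
of two intervals is intersection length over union length, where the union
of two *disjoint* same-chromosome intervals is the sum of their lengths (the
set of bases), not the spanning interval. The two readings coincide whenever
the intervals overlap, and disjoint pairs score zero overlap regardless, so
this choice only fixes an edge case — but it fixes it in the set-theoretic
direction that keeps `J = 0` exactly equivalent to "no shared base".

## Consensus TAD calling

Topologically associating domains (TADs) are taken as pre-called intervals,
one BED file per cell type; calling TADs from Hi-C contact matrices is out
of scope. One cell type is designated the *basis* — conventionally the one
with the most TAD calls, so that the consensus is computed over the richest
annotation (the package warns, but does not refuse, when another cell type
has more). Each basis TAD `T_i` is scored against the other three cell
types:

$$S_i = \mathrm{median}\left(
  \max_{T_j \in T_B} \frac{|T_i \cap T_j|}{|T_i \cup T_j|},\;
  \max_{T_k \in T_C} \frac{|T_i \cap T_k|}{|T_i \cup T_k|},\;
  \max_{T_l \in T_D} \frac{|T_i \cap T_l|}{|T_i \cup T_l|}
\right)$$

The median over three maxima means one cell type may entirely lack the
domain without disqualifying it, but two must support it for a score above
0.5. Conserved TADs must satisfy three filters: length at least `min_length`
(default 100 kb — below typical TAD scale, boundary calls are unreliable),
score strictly greater than `score_threshold` (default 0.5, strict so that a
TAD matched at exactly half its span in two cell types does not pass), and
permutation q-value below `q_threshold` (default 0.05).

**Permutation null.** Only TADs passing the first two filters are tested:
each is replaced `n_permutations` times (default 1000, resolving p down to
about 0.001 — enough to clear q < 0.05 after adjustment at desk scale) by a
uniform-random interval of the same length, and the p-value is
`(r + 1) / (n + 1)`, never zero. Three choices here were open and are
resolved as follows:

* Random intervals are placed on the **same chromosome** as the original
  TAD, preserving chromosome-level TAD density rather than mixing
  chromosomes with different domain coverage.
* Permutations run **per TAD** with a seed derived from the global seed and
  the TAD index, so results are reproducible and independent of evaluation
  order.
* Benjamini–Hochberg adjustment is computed **over the tested set** (TADs
  with `S_i > 0.5`), matching the set for which p-values exist.

**Boundary variants.** Because boundary (anchor) positions are
experimentally fuzzy, every conserved TAD is reported twice: the
*intersection* variant `[max(starts), min(ends))` and the *union* variant
`[min(starts), max(ends))` over the basis TAD and its three best-match TADs
(the argmax-Jaccard TAD per cell type; ties broken by leftmost start, then
shortest, for determinism). A conserved TAD whose four intervals share no
common section — possible when the score is carried by only two cell types —
is dropped from the output entirely, with a counted warning. The drop rule
is stated for the intersection geometry, but one record holds both variants,
so the record goes as a whole; the alternative (keeping a union-only
record) would make the two variants' TAD sets diverge in membership and
complicate every downstream comparison.

Basis TADs may overlap one another; they are scored independently and never
merged.

## DMR placement tests

**Inside-TAD test.** The statistic is the fraction of DMRs overlapping any
consensus TAD by at least 1 bp. The null replaces every DMR by a
*composition-matched* random interval: identical length, GC fraction within
`gc_tol` (default 0.05 absolute) and CpG-dinucleotide density within
`cpg_tol` (default 0.005 per bp), found by rejection sampling against the
supplied genome. The tolerances are a package choice — "similar
composition" needs an operational width — set tight enough to preserve the
CpG-island-like structure that distinguishes methylation-relevant sequence,
and loose enough that sampling terminates; after `max_tries` (default 1000)
failed candidates the tolerances are doubled with a logged warning, so the
procedure cannot hang on an outlier DMR, and relaxations are counted in the
pipeline summary rather than silently absorbed. Matched intervals may land
anywhere in the genome (position chosen uniformly over all admissible
starts, chromosomes weighted by admissible-start count); the composition of
each candidate is evaluated against precomputed cumulative GC/CpG arrays, so
the cost per candidate is constant.

**Boundary-proximity test.** Restricted to DMRs that overlap a TAD; each is
assigned to its largest-overlap TAD (ties to the leftmost) and its distance
to the nearer boundary is clamped at zero when it crosses one. A DMR within
`proximal_cutoff` (default 50 kb, inclusive — "up to 50 kb" — motivated by
the typical enhancer–target separation) of a boundary counts as proximal,
and the statistic is the proximal count. The null repositions every
participating DMR uniformly at random *fully within its containing TAD*.
This conditions on TAD membership, so the test isolates boundary preference
from the inside-TAD preference already tested above; a genome-wide null
would confound the two signals. DMRs longer than their containing TAD are
excluded with a warning. Edge-based (not midpoint) distance is used,
consistent with the 1 bp overlap convention elsewhere.

Both tests report the Monte Carlo p-value `(r + 1) / (n + 1)` (simulation at
least as extreme as observed) and a two-cell chi-square goodness-of-fit of
the observed inside/outside (or proximal/non-proximal) counts against the
simulation-mean expectation, df = 1, computed on counts without continuity
correction. Default simulation counts are 200 (inside test) and 10,000
(boundary test); both tests refuse fewer than 100. The Monte Carlo p is the
primary inference; the chi-square is reported because it summarizes the
same comparison on the count scale and extends below the Monte Carlo
resolution floor.

## Linear and spatial DMR–gene distances

For an ngDMR and a gene that both overlap the same consensus TAD, two
distances are computed. The *linear* distance is the gap between nearest
edges along the chromosome (zero when touching or overlapping), defined only
within a shared TAD — that restriction is what justifies the relatively
permissive 50 kb association radius. The *spatial* distance models
anchor-mediated contact: with `dL(x)`/`dR(x)` the clamped distances of
feature `x`'s nearest edge to the left/right TAD boundary,

$$d_{\mathrm{spatial}} = \min\big(dL(\mathrm{DMR}) + dR(\mathrm{gene}),\;
dR(\mathrm{DMR}) + dL(\mathrm{gene})\big).$$

"Different ends of the same TAD" is deliberately operationalized by this
min-over-pairings formula rather than a separate near-anchor eligibility
rule: the 50 kb threshold itself already forces both features close to
opposite anchors, and a hard eligibility cutoff would introduce a second
arbitrary constant. The effective distance of a DMR–gene pair is the smaller
of the two distances, minimized over all shared TADs; each ngDMR links to
its closest gene if that distance is strictly below `max_distance` (default
50 kb). A DMR yields at most one link; a gene may receive many. Ties are
deterministic: the linear route wins a linear/spatial tie, equally close
genes resolve lexicographically by gene id, and equal routes through
different TADs resolve by TAD id. Distances are measured to the nearest
gene-body edge by default — symmetric with the treatment of DMRs — with
`gene_anchor = "tss"` offered for transcription-start-site distance
(membership in a TAD is still judged by the full gene body).

Genic/non-genic status is taken from the input DMR table's flag: deciding
promoter overlap belongs to the upstream DMR-calling pipeline, not this
package.

## Organ enrichment

The enrichment statistic mirrors a standard gene-to-phenotype annotation
screen. The background is every gene in the annotation table; query genes
absent from it are discarded with a message. Per organ, `expected` equals
`|query| * |organ genes| / |background|` — the only formula consistent with
a non-integer expected column — and the enrichment ratio is
observed/expected. The default p-value is empirical: `n_draws` (default
10,000) random same-size gene sets drawn without replacement from the
background, one-sided for enrichment, `(r + 1) / (n + 1)`. An exact
hypergeometric tail is available (`method = "hypergeometric"`) and is used
in the test suite as the independent oracle for the empirical mode, never
as its implementation. FDR is Benjamini–Hochberg across all organs in the
table (not only nominally significant ones), and rows with FDR < 0.05 are
flagged. Depletion is flagged (`observed < expected`) but untested by
default, since the screen is directional.

## The synthetic world

`simulate_dataset()` generates, under one seed, every input the pipeline
consumes; a seed fixes every emitted file byte-for-byte. Defaults define a
desk-scale world: 2 chromosomes x 20 Mb, 60 TADs per cell type, 200 genes,
150 DMRs — large enough for stable Monte Carlo behaviour, small enough that
the whole suite runs in minutes.

* **Genome.** Bases are drawn i.i.d. at `gc = 0.40`; CpG dinucleotide sites
  are then destroyed (the G of a CG flipped to C, preserving GC content) or
  created (with a compensating base swap) until the CG rate matches
  `cpg_rate = 0.01`. Mammalian genomes are strongly CpG-depleted — roughly
  1 CG per 100 bp against an i.i.d. expectation of 4 — and the defaults
  reproduce that regime, which is what makes composition-matched
  randomization meaningfully different from uniform randomization.
* **TAD calls.** The basis cell type tiles each chromosome with
  non-overlapping TADs (lengths uniform on 200–800 kb, the scale of typical
  domain calls; boundaries randomized by stick-breaking over the leftover
  space). A `conserved_fraction` (default 0.5) of basis TADs is replicated
  in the other three cell types with Gaussian boundary jitter
  (`boundary_jitter_sd`, default 5 kb) — Gaussian rather than uniform so
  the conservation score degrades smoothly as jitter grows — and the
  remaining space is tiled independently at the basis TAD density. With
  zero jitter every planted TAD scores exactly 1.
* **Genes and DMRs.** Genes are uniform over the genome (lengths 2–50 kb).
  DMRs (lengths 0.5–3 kb, the scale of methylation-called regions) are a
  mixture: a genic fraction placed inside gene bodies (default 0.65,
  mirroring the observed share of genic DMRs in comparative methylome
  data), a boundary-proximal fraction placed within 50 kb of a conserved
  TAD anchor avoiding genes (default 0.3), and a uniform non-genic
  remainder. Because the placement categories are disjoint by construction,
  the two fractions must not sum above 1 — the generator errors rather than
  silently reinterpreting the mixture. `n_spatial_pairs` DMR–gene pairs are
  planted at opposite anchors of large conserved TADs (offsets under 20 kb
  each, linear separation far above 50 kb), creating ground-truth links
  that only the spatial route can find; other simulated genes are kept out
  of those TADs so the planted partner remains the unique closest gene and
  ground-truth recovery is well-defined.
* **Annotations.** Each gene joins each of `n_organs` (default 20) body
  parts independently at `base_rate` (default 0.2, giving organ sets large
  enough for stable expected counts at desk scale). For planted organs the
  query-gene membership rate is solved so that the *expected measured
  enrichment ratio equals the requested fold*, accounting for the query's
  own contribution to the background frequency — planting the naive rate
  `fold x base_rate` would deflate the measured ratio whenever the query is
  a non-negligible share of the background, making "fold" untestable as
  stated.

What the generator does **not** emulate: real chromosome length
distributions, isochore/GC-banding structure, CpG islands as discrete
features, nested or overlapping TAD hierarchies, methylation signal itself,
and any correlation between gene density and domain structure. A green test
therefore establishes that the statistics are calibrated and the planted
effects recoverable under a clean stochastic world — not that the
biological effect sizes of any particular dataset will reproduce.

## Numerical and degenerate-input behaviour

Monte Carlo p-values use `(r + 1) / (n + 1)` throughout and cannot be zero;
chi-square statistics are set to `NA` with a warning when the simulation
expectation is degenerate (0 or 1). All randomness flows from explicit
`seed` arguments through isolated RNG scopes (`withr`), so package calls
never disturb the caller's RNG state; derived per-task seeds stay within
32-bit integer range. Empty interval tables are valid inputs to readers
(warning) but not to tests (error), and zero-length intervals are rejected
at validation with line-numbered errors at the I/O layer. The consensus
caller, the linker and the enrichment test are deterministic given a seed;
byte-identical rerun of the full pipeline is part of the test suite.

## Known limitations

* Consensus TADs inherit the resolution of the input calls; the method
  cannot recover domains absent from the basis cell type, and a
  basis-centric score is asymmetric by design.
* The spatial distance treats both TAD anchors as a single contact point;
  real loop anchors have extent and directionality (CTCF orientation) that
  the model ignores.
* The boundary-proximity null conditions on the assigned containing TAD;
  for union-variant TADs that overlap, assignment by largest overlap is a
  heuristic.
* Composition matching controls GC and CpG density but not higher-order
  sequence structure (repeats, motif content).
* At default simulation counts the smallest attainable Monte Carlo p-values
  are 1/201 and 1/10001; printed zeros in enrichment-style tables from
  finite-draw tools correspond to this resolution floor, not to exact
  zeros.
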