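---
title: "Functional kinome profiling: models, parameters and design choices"
author: "kinomepipe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional kinome profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinomepipe)
```

## The problem

Peptide-array kinome profiling measures the activity of the kinases in
a tissue lysate indirectly: immobilized reporter peptides are
phosphorylated by sample kinases, and the accumulating
phospho-antibody fluorescence of each spot is imaged at several
exposure times (10, 20, 50, 100, 200 ms). Two chip chemistries cover
the serine/threonine kinome (144 peptides, 12×12) and the tyrosine
kinome (196 peptides, 14×14). The analytical chain from spot
intensities to biology involves many small decisions; this vignette
records the models `kinomepipe` uses, why, and what its validation on
synthetic data does and does not establish.

## Kinetic model and quality control

Within the captured exposure window the phospho-signal of a healthy
reporter peptide grows approximately linearly with exposure time, so we
reduce each (chip, sample, peptide) series by ordinary least squares,
`intensity = slope · exposure + intercept`, and carry the slope
forward. Quality control mirrors the two classic failure modes:

* **undetectable** — maximum observed intensity below `min_signal`
  (default 5 intensity units, roughly twice the background SD of the
  generator's default noise), or a non-increasing slope. A flat peptide
  is classed undetectable, not nonlinear: "linear increase" is read as
  requiring slope > 0.
* **nonlinear** — R² below `min_r2` (default 0.90). Series with fewer
  than three exposures cannot support the check and fail here too.

A peptide enters the comparison only if it passes in *every* sample on
every chip; this all-sample rule is what produces a single
"passed QC" count per comparison. The retained signal is
`slope × reference_exposure` (default 100 ms) — a scale-interpretable
model prediction rather than any single raw exposure. Signals are
therefore exactly linear in the kinetic slope, which the tests exploit
(scaling all intensities by c scales all signals by c).

## Differential phosphorylation

Fold changes are computed within each technical-replicate chip
(`log2` of the treatment/control ratio of group mean signals) and then
averaged across chips, so chip-level intensity scale differences cancel.
Group means, not medians, are used: the emulated design pools biological
replicates into a small number of wells per group, leaving too few
values per chip for robust location estimates to help. Two independent
flags are derived: the ±0.2 log2FC "biologically significant" flag
(strict inequality; a mean of exactly 0.2 is not flagged), and the
15 % activity-change rule used to select upstream-analysis input,
interpreted on the linear fold-change scale: |2^log2FC − 1| ≥ 0.15.
The two are deliberately not collapsed: 15 % up is log2FC ≥ 0.2016
while 15 % down is log2FC ≤ −0.2345, so a peptide at log2FC = −0.21 is
flagged at ±0.2 yet is not a 15 % hit.

The ternary direction score assigns each mapped substrate +1 above
0.2, −1 below −0.2, 0 otherwise (boundary values score 0, following the
strict "greater than" reading), averages within a kinase or family, and
calls the direction from the sign of the mean.

## Resampling enrichment

Kinase families are scored by comparing the observed number of hit
substrates to a null built by drawing |hits| peptides uniformly without
replacement from the QC-passing universe (default `n_iter = 2000`,
seeded, seed recorded in the output). The null is exactly
hypergeometric, so the permutation mean and SD must converge to
`nK/N` and `sqrt(nK/N(1−K/N)(N−n)/(N−1))`; the test-suite and the
acceptance script verify convergence on a 20-peptide instance at
10,000 iterations. Scores are unsigned counts; direction comes from the
ternary score, keeping the two sources of evidence separable.

## Harmonizing rankers

Different upstream-kinase tools score on incomparable scales, so each
ranker is reduced to percentiles `rank/K` (average ties, best score →
1.0), a convention invariant under any strictly monotone transform of
the raw scores. Family-level rankers are expanded to member kinases via
the packaged alias/family vocabulary (a small curated table covering
the kinase families the synthetic maps use; a full HGNC download is out
of scope). Mean and median percentiles are computed over the rankers in
which a kinase is present — absence is recorded, not imputed as zero,
matching the empty-circle convention of bubble plots (`absent_as_zero`
offers the alternative). Quartiles are `ceiling(4·percentile)` clipped
to 1..4.

## Network integration

Top-quartile kinases (harmonized mean percentile > 0.75, STK and PTK
tables merged with the larger value winning) become prizes on the
interaction graph — the prize is the percentile rank of the mean
percentile among the hits — and edge costs are `1 − confidence`,
keeping costs in [0, 1) on the same scale as prizes (`1/confidence` is
available). The solver minimizes

> β · (sum of excluded prizes) + Σ selected edge costs + ω · (number of trees)

with β = ω = 1 by default. The per-tree charge ω is essential: without
it the all-singletons solution is always optimal and no connectivity is
ever bought. For a *fixed* node set the optimal edges have a closed
form — the minimum spanning forest over reduced costs `cost − ω`,
keeping only edges cheaper than ω — so the search is over node sets
only. The default solver is a deterministic local search (single-node
toggles plus edge-paired add/remove moves, three fixed starts: prized
nodes, all nodes, empty) using that closed-form inner step; an exact
mode enumerates all subsets on graphs of up to 12 nodes. Because both
modes evaluate the identical objective, the heuristic can never report
a better value than the optimum, and on random 10-node instances it
matches it in ≈98 % of cases — properties the acceptance checks
measure rather than assume. Ties prefer more collected prize, then
fewer edges, which is why two unconnectable prized nodes are returned
as two singleton trees rather than being dropped.

Hub nodes are ranked by degree within a focal subnetwork (ties: prize,
then name). Degree was chosen over betweenness for transparency on the
small forests involved; hidden nodes — selected despite zero prize —
are reported explicitly since they are often the interesting
connectors.

## Pathway analysis and term clustering

Over-representation uses the one-sided hypergeometric upper tail with
Benjamini–Hochberg FDR across tested sets (α = 0.05). The combined
score is `−ln(p) · z` with z the standardized deviation of a term's
p-value rank from its expectation under random queries of the same size
(100 seeded permutations; positive = better than expected); a pure
`−ln(p)` mode exists for exact work. Significant terms are clustered on
cosine distance with average linkage; k is fixed or chosen by maximal
average silhouette over k ∈ [2, min(10, n−1)], with degenerate
geometries (n < 3 or all distances ≈ 0) collapsing to one cluster. The
most representative term is the member most cosine-similar to its
cluster's mean embedding, ties broken lexicographically so the choice
is reproducible. Embeddings are an input (TSV); 2-D scatter
coordinates are presentation-only — supplied coordinates pass through,
otherwise classical MDS of the cosine distances is used — and no
assertion anywhere depends on them.

## Validation statistics

Group comparisons reported as mean ± SEM with n are reproduced by the
pooled (equal-variance) Student's t-test reconstructed from summaries
(`SD = SEM·√n`); the pooled rather than Welch form is used because it
is what such published summaries round-trip to (and it agrees with a
raw-data pooled t to machine precision when the summaries are computed
from the raw values). Simple regression reports OLS slope/intercept,
R² = 1 − SSE/SST and the F(1, n−2) p-value. Multi-group ANOVA is out of
scope: no multi-group comparison appears in the supported workflow.

## The synthetic generator

The generator is the package's ground-truth instrument, emulating the
study design it stands in for: two groups (sedentary vs exercise),
three samples per group, triplicate chips, the five-exposure capture,
and per-chip analysis. Normal peptides follow the linear kinetic with
additive Gaussian noise (default SD 1 against baseline slopes of
0.5–3 intensity/ms); a planted family multiplies the treatment group's
slope by `2^effect`, so the planted effect *is* the expected log2FC of
the derived signal — what makes Monte-Carlo recovery tests exact in
expectation. Dead peptides emit `|N(0, noise_sd/10)|` (indistinguishable
from background); saturating peptides follow
`amplitude·(1 − exp(−t/5 ms))`, flat across the captured window and
hence strongly nonlinear. Failure counts are `floor(frac · n)` with a
seeded shuffle choosing the peptides; identical configurations are
byte-identical. The demo plants IKK +1.0 log2 on the STK chip and EGFR
+0.8 on the PTK chip with 10 % dead and 10 % saturating peptides, and
the demo gene-set library pairs each kinase family with exactly its
member kinases plus random decoy sets, a deliberately clean planted
structure.

What the generator does *not* emulate: biological replicate-to-replicate
variance beyond i.i.d. noise, spatial artifacts within the grid,
washing/cycle chemistry, peptide-specific kinetic saturation in the
normal regime, and correlated multi-mapping of substrates beyond a
simple deterministic overlap. Passing tests therefore demonstrate that
the implementation is correct and self-consistent under the stated
model — not that real arrays satisfy that model.

## Problem sizes and numerics

The validation experiments run at fixed, documented sizes chosen to
give stable rates while staying quick: 10,000 resampling iterations for
the convergence check, 50 random 10-node graphs for the solver oracle,
50 seeded simulated experiments for planted-effect recovery, 100 random
small universes (≤ 15 genes) for the enumeration check. Objective
comparisons in the solver use a 1e-12 tie tolerance; R² is clipped to
[0, 1] against floating drift; p-values are floored at the smallest
positive double before taking logs. All randomness flows from
user-supplied integer seeds, which are echoed into outputs and the run
manifest.

## Known limitations

* The alias/family vocabulary is a small curated fixture, not HGNC.
* The exact solver is limited to 12 nodes by design; beyond that only
  the heuristic bound (never better than optimal) is guaranteed.
* External rankers are consumed as score tables; the tools themselves
  (and any web services) are out of scope.
* Embedding fitting is out of scope; embeddings are inputs, and the
  bundled ones are synthetic prototypes with noise.
* The orchestration runs one two-group comparison per invocation;
  multi-region designs are handled by separate runs.
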