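---
title: "Methods: modelling gene expression from histone marks at enhancers and promoters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling gene expression from histone marks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epm)
```

This vignette explains the models and procedures the package implements,
the assumptions behind them, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where the design was genuinely open.

## The scientific setting

Promoters and enhancers are decorated with combinations of histone
modifications that track the transcriptional state of their target genes:
H3K4me3 and H3K27ac with activation, H3K27me3 with repression, H3K4me1
with enhancers. A chromatin-state segmentation (here a 9-state model)
summarizes these combinations along the genome. The package's question is
quantitative: treating per-region mark levels as predictors, how well does
a linear model explain log expression, and which marks carry the
information — at promoters, and separately at the enhancers linked to each
gene through chromatin contacts?

## From segmentation to regulatory regions

All coordinates are 0-based half-open (BED convention); 1-based dialects
are converted at the reader boundary so no off-by-one drift can accumulate
between modules.

**Transition enrichment.** On a coalesced track (touching same-state
segments merged), the observed count O(x,y) is the number of times a
segment of state y immediately follows one of state x along a chromosome;
chromosome boundaries contribute nothing. Expected counts use the standard
contingency expectation E(x,y) = out(x)·in(y)/N — independence of origin
and destination marginals — because a stronger null is not identifiable
from segment order alone. The enrichment R = O/E exposes the block
structure of the state space (active states transition into active states,
poised into poised), which motivates the merging step. A flag
(`coalesce = FALSE`) lets users count transitions on the raw track since
segmentation output conventions differ.

**Merging and filtering.** Runs of touching segments whose states map to
the same group (active: 1–4; poised: 6–7) become candidate regions.
Intermediate (5), repressed-only (8) and unmarked (9) segments break runs
and are never emitted. Two filters follow, in this order: candidates
shorter than `min_length` (default 600 bp) are discarded as background,
then any surviving active region touching a surviving poised region (0-bp
gap) is discarded together with it as ambiguous. Applying the length
filter first matters: a short poised fragment adjacent to a long active
region removes only itself, not its neighbour.

**Classification.** A candidate is a promoter iff it overlaps by ≥ 1 bp
the window of ± 500 bp around any TSS; the window is implemented as
[t − 500, t + 501), i.e. 1001 bp including both boundary bases. The
prose convention "± 500 bp" does not fix inclusivity; the symmetric
window was chosen and the half-width is a parameter (`window`) for users
who prefer 1000 bp. Promoter precedence is absolute: only candidates that
are not promoters are tested against p300 peaks for enhancer status, and
no mark-content filtering is applied afterwards (H3K4me3-bearing enhancers
are deliberately kept). Candidates with neither TSS-window nor p300
support are dropped. Distal enhancers are those strictly more than 5 kb
from the nearest TSS; intragenic enhancers are those overlapping a gene
body (TSS-to-end span) by ≥ 1 bp.

## Hi-C association and the contact-enrichment test

An enhancer is linked to a gene when a promoter of the *same* chromatin
category (active–active or poised–poised) overlaps the opposite anchor of
a significant interaction, and the gene is a target of that promoter.
Anchors are used exactly as called (5-kb bins); both anchor orderings are
tried and rows are deduplicated on (enhancer, promoter, gene). Two
alternative association rules are provided: a stricter interaction filter
(FDR ≤ 0 and ln p ≤ −100) and a pure distance rule (same-category pairs
strictly closer than 1 Mb, the approximate size of a topologically
associating domain).

The preference of poised enhancers for bivalent promoters is tested with
a one-sided exact binomial test on contact triples: across all
(interaction, enhancer, promoter) triples where a tested-class enhancer
touches one anchor and any promoter the other, k counts triples whose
promoter is of the target class and n all of them. The null probability
p0 is an explicit input. The default helper estimates it as the marginal
frequency of the target promoter class among promoter-overlapping anchor
instances with both enhancer classes pooled — the natural exchangeable
null — but any externally derived value can be supplied, since the
marginal is itself influenced by the effect under test.

## Signal quantification

Per-region signal is `scale · reads / library_size / length` — the count
of reads overlapping the region by ≥ 1 bp, normalized by the library size
and averaged by region length, with a per-million scale so values are
order 1 (any fixed scale cancels in the log-linear model up to the
intercept, and in MA differences). Reads straddling two regions count in
both; a midpoint assignment mode is provided because counting conventions
differ between tools. The same function quantifies fixed-width genome
bins (default 2 kb, matching the typical size of the regulatory regions);
terminal partial bins are kept and flagged, and the mean-per-bp definition
keeps them comparable.

## Cyclic MA-LOESS normalization

Samples of the same mark collected from heterogeneous sources carry
smooth intensity-dependent biases. For two samples, M = log₂x₁ − log₂x₂
and A = (log₂x₁ + log₂x₂)/2; under the assumption that most rows are
unchanged, the M-versus-A trend should be flat at 0, and a robust local
regression of M on A estimates the bias. The multi-sample generalization
cycles over all unordered sample pairs: each pair's fitted trend is
charged half against each sample (+fit/2 and −fit/2), per-sample charges
are averaged over a sample's pairs and applied in log₂ space, and rounds
repeat until the largest mean absolute applied correction falls below
`tol` (default 0.01, max 3 rounds). Because each round's corrections sum
to zero across samples at every A, a row's average log intensity is
invariant, so cumulative corrections can be stored as a single
piecewise-linear curve per sample on a fixed 256-point A-grid with
constant extrapolation — making the model deterministic, serializable to
JSON, and applicable to tables other than the one it was fitted on. That
fit-on-bins/apply-on-regions split is the intended use for ChIP signal:
bias is estimated where data are plentiful (all 2-kb bins) and applied to
the regions of interest. Expression tables (rows = genes) are normalized
with the identical machinery.

Numerical choices: the pairwise abscissa is the mean of logs (matching
the microarray lineage of the method) rather than the log of the mean —
the prose definition is ambiguous and both are implemented behind
`a_method`; the smoother is `stats::loess`, degree 1, span 2/3,
symmetric (bisquare) family, falling back to least squares when the
robust scale degenerates (e.g. an exactly constant M); fits use a seeded
subset of at most 5000 rows for genome-scale tables and predict on the
grid; rows with a zero in any sample are removed before fitting because a
zero cannot be told apart from a dropout and the log transform is
undefined there.

When the table contains a minority of genuinely changing rows (the
situation the housekeeping/bivalent validation emulates), the robust
reweighting needs more than the default 3 rounds to settle; the
package's own checks run `max_rounds = 6, tol = 1e-4` there. With a
changing minority of ~15% and planted log₂ slopes of 0.3–0.8 per step,
converged normalization leaves housekeeping per-sample medians within
0.05 log₂ units while essentially all planted trends keep their sign —
the behaviour expected of a normalization that removes global biases
without erasing real biology.

## The expression model

The response is y = log₂(FPKM + 0.1) and each predictor
x_j = log₂(signal_j + 0.1); the pseudocount keeps zeros finite and the
transform invertible above log₂(0.1). The fit is ordinary least squares.
Variable importance is the absolute t-statistic |t_j| = |β̂_j|/SE(β̂_j)
(shares normalized over marks, intercept excluded); t is scale-invariant
in y, so importance does not depend on expression units. Zero-residual
fits are flagged (`perfect_fit`) and their t reported as infinite rather
than a number. Rank-deficient designs error, naming the collinear
columns. Mark-exclusion models (e.g. dropping H3K27me3 to unmask its
anticorrelated partner H3K27ac) are configuration — a subset of the
`marks` argument — not separate code paths.

**Duplication.** In enhancer mode a gene enters the dataset once per
associated enhancer, all rows sharing its y. Algebraically this equals
weighted least squares with integer weights, which the test suite asserts
against an independent normal-equations oracle.

**Splitting and cross-validation.** Train/test splits (80/20) and CV fold
partitions (10-fold, 3 repeats) operate at gene level by default: row-level
splitting would place identical y values of a duplicated gene on both
sides, leaking the response across the split. A row-level mode is retained
for fidelity experiments. Pearson r between predicted and measured y is
computed over rows by default (duplicated genes contribute one term per
row); a gene-mean aggregation mode exists but changes the estimand and is
non-default.

**Randomization control.** Expression values are permuted over all genes
before dataset assembly, so any apparent model performance that survives
reflects structure in the data rather than a mark–expression relationship.
The package's checks score the noise-fit model against an independently
permuted expression vector over the full dataset, which makes the control
a pure null: its r follows ~N(0, 1/√n) and at n = 2000 is pinned within
±0.1 with large margin. Scoring it on a small held-out subset of the same
permutation is also possible via `evaluate_model` but mixes in the
sampling noise of the subset (sd ≈ 0.05 at 400 rows), which is why a
single random-model r from a small test set can legitimately reach ±0.15.

**Cross-context evaluation.** For each context (cell type, time point,
tissue) a model is fitted on all rows and evaluated on every other
context's full dataset; the diagonal is left empty. If the
mark–expression relationship is universal, off-diagonal r stays near the
within-context value. Model-versus-random performance differences are
tested with a classical paired t-test, pairs aligned by evaluation set,
starred at < 0.05 (*), < 0.01 (**), < 0.001 (***), < 0.0001 (****).

## The synthetic-data generator

Every input the pipeline consumes can be generated from a single
`synth_truth()` parameter set, deterministically given a seed. The
defaults are the study conditions the package is validated under:

* **Marks and coefficients** — ten marks; true β mixes activating
  (positive) and repressive (negative) effects with H3K27me3 strongest
  (−0.8); intercept 1. Log-signal is multivariate normal (mean 2, sd 1,
  exchangeable correlation 0.2; an optional override plants a strong
  anticorrelation between H3K27me3 and H3K27ac to emulate their chemical
  mutual exclusivity).
* **Noise** — σ is derived from the target correlation r* = 0.8 through
  r*² = Var(Xβ)/(Var(Xβ) + σ²), so the theoretical test-set performance
  is known exactly and coefficient recovery can be checked against OLS
  sampling theory.
* **Regions and contacts** — promoters carry a TSS of their target gene,
  enhancers a p300 peak clear of TSS windows, one region per 5-kb anchor
  bin so contact counting is unambiguous; 24% of promoters are bivalent
  (the expected-by-chance probability p0 = 0.24) and poised-enhancer
  contacts hit a bivalent promoter with probability q = 0.29, so the
  planted enrichment matches the effect size the contact test is meant to
  detect.
* **Trajectories and biases** — expression tables across contexts contain
  a housekeeping subset (30%) with equal true means, a bivalent-like
  subset (15%) with planted increasing log₂ trends of 0.3–0.8 per step,
  and stable remainder; per-sample biases are smooth bounded functions of
  A (amplitude 1 log₂ by default) or constants, stored so recovery can be
  checked.
* **Segmentation** — a Markov alternation over the 9 states with
  within-group transitions enriched and frequent unmarked spacers, run
  lengths of 200 bp × geometric(mean 3) bins, tiling each chromosome.

Signal is generated directly at region level (fast, exercises the
modelling path); a read-level path exists through `quantify` on interval
sets. What the generator does **not** emulate: read-level artefacts
(GC bias, duplicates, fragment-size effects), Hi-C matrix structure
(anchors are planted, not called from a contact map), overlapping or
nested regulatory regions, and mark-specific peak shapes. Passing tests
therefore demonstrate that the algorithms are implemented correctly and
behave as the theory predicts under the stated statistical structure —
not that any particular biological dataset will reach r = 0.8.

## Problem sizes of the built-in checks

The test-suite checks run at sizes chosen to make the relevant sampling
theory sharp while keeping the suite quick: transition oracles on 20
random 1000-segment tracks; linking oracles on 2000 interactions × 500
enhancers × 500 promoters × 20 seeds; binomial calibration on 200
null datasets and 100 powered datasets (~500 contact trials each); model
recovery on 20 seeds of 2000 genes × 10 marks; normalization checks on
2000–2500-row tables with 2–5 samples.

## Known limitations

* The expected-transition null assumes marginal independence; segment
  lengths and higher-order structure are not modelled.
* p0 for the contact test is an estimate when derived from the pooled
  marginal; strongly unbalanced enhancer classes can bias it toward the
  majority class's preference.
* LOESS normalization assumes most rows are unchanged; it will partially
  absorb a truly global shift in biology, and spike-in-based scaling is
  out of scope.
* The linear model treats marks additively on the log scale; interactions
  and saturation are not represented, and importance shares inherit the
  usual caveats of collinear predictors (the masking behaviour the
  mark-exclusion models are for).
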