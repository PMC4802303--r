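---
title: "Methods: phosphatase-specific dephosphorylation-site prediction"
author: "dephossite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phosphatase-specific dephosphorylation-site prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dephossite)
```

# The problem

Protein tyrosine phosphatases remove phosphate groups from phosphotyrosine
residues. Experimentally validated dephosphorylation sites are scarce, so
sequence-based predictors are trained per enzyme — here PTP1B, SHP-1 and
SHP-2 — on peptide windows of `2n + 1` residues centered on a candidate
tyrosine. Tyrosines shown to be dephosphorylated by an enzyme are the
positive class; all other tyrosines of the same substrate proteins are
negatives, giving a strong (~1:14) class imbalance. Windows that would
extend past a protein terminus are padded with the symbol `-`, which is
treated as a 21st residue type throughout.

This package implements three predictors over that shared window
representation, the evaluation protocols used to compare them, a
per-position enrichment analysis, and a synthetic benchmark generator.

# Dataset construction

`loadDataset()` extracts windows from FASTA substrates and a site table,
then removes redundancy per class with `redundancyReduce()`: windows are
visited in lexicographic `(protein_id, position)` order and a window is
dropped when it matches any retained window at or above the identity
threshold (default 0.70, the conventional choice for this problem). Two
conventions had to be fixed because they determine the retained counts:

* identity is the fraction of equal symbols over the **full** window
  length, with `-` aligned to `-` counting as a match — the simplest rule
  consistent with fixed-width windows;
* the greedy order above makes the reduction deterministic and
  idempotent; any order satisfies the post-condition (no retained pair at
  or above the threshold), but counts differ slightly between orders.

The reduction is applied within each class only, following the wording of
the protocol it reproduces; comparing across classes as well would be a
one-line change and is worth a sensitivity analysis if counts matter.

When the site table carries explicitly labelled negative rows they are
used as the negative class; otherwise every unannotated tyrosine of the
substrate proteins is harvested. The explicit form is what the synthetic
generator writes, and makes a write/load round trip exact; the harvesting
form matches how the curated datasets were originally assembled.

Nonstandard residue letters (B, Z, X, U, ...) are mapped to an inert
bucket: substitution lookups score 0 and the CKSAAP encoding simply loses
their frequency mass. Refusing such inputs would break real FASTA files.

# The MGPS scorer

A query window $a$ is compared with a positive reference window $b$ by

$$ s(a, b) = \sum_{i=1}^{2n+1} w_i \cdot \mathrm{sub}(a_i, b_i), $$

where `sub` is BLOSUM62 extended with a zero row/column for `-`, and the
center term is fixed at $w_{n+1} \cdot 1$ — the tyrosine–tyrosine
comparison carries no information, so pinning its substitution score to 1
lets the center weight act as a pure offset. Negative sums are clipped to
zero, and the model score of a query is the mean clipped similarity over
**all** positive references, zeros included. The clipping makes the model
a soft nearest-neighbour method: references below the (implicit) zero
threshold simply stop contributing. An alternative averaging over only
the non-zero similarities is available (`averageNonzero = TRUE`) but off
by default, matching the mean-over-all-positives definition.

## Weight training

`trainMgpsWeights()` initializes the center weight to 7 (the BLOSUM62
tyrosine self-score) and all other weights to 1, then hill-climbs the
leave-one-out AUC: positions are swept left to right; at each position
the candidates $w_i + 1$ and $w_i - 1$ are scored by jackknife AUC and
the best candidate is accepted only on **strict** improvement. Sweeps
repeat until one passes without an accepted move. Details that the
procedure's plain statement leaves open were resolved as follows:

* the acceptance rule is argmax over (incumbent, $+1$, $-1$); ties keep
  the incumbent, and a tie between the two candidates prefers $+1$. A
  literal reading of the published step ("if $a_2 > a_1$ take $w_{i2}$")
  could accept an AUC decrease; the monotone trace the procedure plainly
  intends rules that out.
* non-center weights are constrained to stay $\ge 0$ (a position either
  helps or is ignored); the center weight is unconstrained and may go
  negative, since it only shifts scores relative to the clipping zero.
* during the training-time jackknife, a positive being scored is removed
  from the reference set (otherwise its self-similarity inflates the
  objective); negatives are scored against all positives.
* if all initial scores tie (degenerate data), training warns and
  returns the initial weights.

The accepted moves and their AUCs are recorded in the model's
`trainingTrace()`; the AUC column is non-decreasing by construction.
Peptide length is selected by `selectMgpsLength()`: weights are trained
at each candidate length (re-windowed symmetrically around the center)
and the length with maximal post-training jackknife AUC wins, ties going
to the shorter window. The conventional scan is 9 to 61 step 2.

Because the hill climb is only locally optimal and its exact trajectory
depends on sweep order, published tuned weight vectors are treated as
loadable artifacts (`mgpsModelFromWeights()`), not as a retraining
target.

# The CKSAAP SVM

`cksaapEncode()` maps a window to the composition of $k$-spaced amino
acid pairs: for each spacing $k = 0..4$ it counts ordered symbol pairs at
positions $(p, p + k + 1)$ over the 21-symbol alphabet and divides by the
number of such pairs, $2n - k$. Each $k$-slice therefore sums to 1 and
the full vector has $21 \times 21 \times 5 = 2205$ entries. The feature
index map is frozen (`cksaapFeatureNames()`): $k$-major, then first
symbol, then second symbol, over the alphabet `ACDEFGHIKLMNPQRSTVWY-`.

An RBF-kernel soft-margin SVM is trained on these vectors (solver:
e1071/libsvm). Frequencies are already bounded in $[0, 1]$, so no feature
scaling is applied. No class weighting is used — the imbalance correction
via a positive-class weight belongs to the kNN baseline, which is where
it was described. The decision value (signed distance to the hyperplane)
is the score, so ROC analysis is possible; no probability calibration.
`trainCksaap()` grid-searches $(\gamma, C)$ — conventionally powers of
two over $2^{-10}..2^{10}$ — by mean AUC over repeated stratified 5-fold
cross validation, optionally tuning the window length jointly. Trained
models store support vectors, dual coefficients and offset explicitly and
recompute the decision function themselves, so models serialize to JSON
and round-trip exactly; the coefficient sign is oriented after training
so positives score higher. Published tuned values per enzyme are exposed
as `cksaapPreset()`.

# The kNN baseline

`knnScore()` ranks all training windows by raw BLOSUM62 similarity to the
query (positions summed, `-` scoring 0, no center override, no clipping),
multiplies positive-sample similarities by a class weight $w \ge 1$
(tuned 1..7 step 0.1; `knnPreset()` carries the published values), and
returns the fraction of positives among the top $k = 5$ — hence exactly
six attainable scores. Ties in the ranking are broken by placing
positives before negatives at equal weighted score, then by pool order;
some frozen rule is required for reproducibility and this one is the most
favourable consistent reading. During any cross-validated scoring the
query itself is excluded from the pool.

# Evaluation

`computeAuc()` is the midrank Mann–Whitney statistic — the probability
that a random positive outscores a random negative, ties counting ½ —
and equals the trapezoidal area under the empirical ROC. The test suite
checks it against an $O(n^2)$ pairwise oracle and against pROC.

Thresholds use the convention score $\ge t$ ⇒ positive, enumerated at
observed score values plus the trivial all-negative threshold.
`operatingPoint()` reports (SPE, SEN, MCC) at the threshold whose
realized specificity is the *smallest attainable value at or above* the
requested level (0.90/0.85/0.80 by default). For coarse scorers such as
the six-valued kNN vote, adjacent levels can collapse onto the same
threshold; `operatingPoints()` then flags the looser level unavailable
("–"), which is how such entries appear in per-level comparisons.

`jackknifeEval()` is deterministic leave-one-out; `repeatedKfold()` draws
stratified folds per repeat from an explicit seed (per-repeat seed =
base + repeat − 1) and reports per-repeat pooled out-of-fold AUCs. With
$k = n$ and one repeat the fold assignment degenerates to leave-one-out
exactly. Hyperparameters are tuned once globally and folds only refit the
sample-dependent parts (MGPS reference set, kNN pool, SVM solution) —
the only computationally coherent reading of per-fold evaluation with
published global parameter tables.

Complementarity between predictors is the Pearson correlation of their
cross-validated score vectors. `trainEnsemble()` combines score columns
with a linear-kernel SVM. Two details matter at the ~1:14 imbalance of
these data: the component columns are standardized first (mean
similarities and decision values live on unrelated scales), and the
combiner uses inverse-class-frequency class weights — an unweighted soft
margin provably prefers the trivial all-negative solution ($w = 0$) when
positives are this rare, leaving only numerical noise as a "score". The
feature-level CKSAAP SVM stays unweighted; the correction belongs to the
combiner, whose two inputs are already strong rankers. Since the
combiner itself can leak, ensemble evaluation uses a nested jackknife
(the combiner scoring a sample never saw it), with a `naive = TRUE`
refit mode available for comparison with protocols that skipped the
outer loop.

# Positional enrichment

`fisherEnrichment()` compares, per (position offset, residue incl. `-`),
the presence/absence counts in positives vs negatives with a two-sided
Fisher exact test, flags $p < 0.01$, and assigns the direction from the
odds ratio (Haldane-corrected only when a cell is zero). Residue-level
2×2 tables (rather than full 21-category tables per position) are what
reported residue-level findings imply. No multiplicity correction is
applied at the fixed 0.01 threshold — the convention for positional logo
analyses — but `correct = "BH"` is available. Degenerate margins give
$p = 1$ by convention.

# The synthetic generator

`generateSynthetic()` emulates the structure of the curated data: one
synthetic protein per window; positives carry planted residue
enrichments at enzyme-specific offsets (`enzymeProfile()` lists them,
following the residues reported significant for each enzyme), negatives
draw every flank position from Robinson–Robinson background frequencies,
and windows are terminally truncated with probability 0.10 (0.30
C-terminally for the SHP-2 profile, emulating C-terminus-proximal
substrates). Enriched residues reach a target probability of 0.35 at
full `motifStrength`; strength 0 removes the motif entirely, making the
classes exchangeable — the null used for type-I-error checks. Default
class sizes mirror the curated sets (63/898, 50/852, 51/718). Identical
seeds give byte-identical output, and the generator restores the global
RNG state.

What the generator does **not** emulate: positional correlations between
residues, homology between windows (each window is drawn independently,
so redundancy reduction rarely fires), shared proteins between positives
and negatives, and curation biases. Passing tests on synthetic data
therefore demonstrate that the algorithms recover planted signal under
realistic sizes and imbalance — not that real-data performance numbers
transfer.

# Problem sizes in the shipped checks

The test suite and the acceptance script run on synthetic data at the
default per-enzyme sizes (961/902/769 windows) for scoring-level checks,
and smaller sets (tens of positives, hundreds of negatives) where models
are retrained many times. The SVM runs at fixed or small grids
($\gamma \in \{2^{-7}, 2^{-5}\}$, $C \in \{1, 8\}$, 2×5-fold) and MGPS
length scans use short candidate lists; these are the package's chosen
benchmark sizes, while the full published grids remain the documented
defaults of the user-facing functions. Reproducing numbers from the
curated benchmark requires the curated peptide datasets themselves,
which are journal supplementary material and not redistributed here; the
acceptance tests that depend on them look under
`inst/extdata/curated/<TAG>_dataset.tsv` and fail until those files are
supplied.

# Known limitations

* The hill climb is greedy and order-dependent; it finds local optima,
  and longer windows can overfit the jackknife objective.
* The jackknife objective is reused for both weight tuning and reported
  evaluation on the same data; out-of-sample performance claims need the
  repeated k-fold protocol or an independent set.
* The 6-valued kNN score cannot realize every specificity level; the
  operating-point machinery reports this rather than interpolating.
* Redundancy-reduced counts depend on the documented greedy order; other
  orders give counts differing by a few windows.
* Proteome scanning assigns calls from training-time score thresholds;
  on proteins unlike the training substrates these specificities are
  nominal, not guaranteed.
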