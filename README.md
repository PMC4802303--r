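# dephossite

Prediction of phosphatase-specific tyrosine **dephosphorylation** sites.
Kinase-side phosphorylation-site predictors are plentiful; the inverse
problem — which tyrosines does a given protein tyrosine phosphatase
(PTP1B, SHP-1 or SHP-2) act on — has far less tooling. `dephossite` is an
R package for researchers who want to train, evaluate and apply
sequence-based dephosphorylation-site predictors from peptide windows of
`2n + 1` residues centered on a candidate tyrosine (terminal shortfalls
padded with `-`).

Three predictors share that window representation:

* **MGPS** — a position-weighted BLOSUM62 similarity scorer. A query
  window *a* is compared with every positive training window *b* by

  ```
  s(a, b) = Σᵢ wᵢ · sub(aᵢ, bᵢ),      score(a) = mean⁺(s(a, b))
  ```

  where `sub` is BLOSUM62 with `-` scoring 0, the center term is fixed at
  `w_center · 1`, negative sums clip to 0, and the mean runs over all
  positive references. The weights `wᵢ` are trained by hill climbing on
  the leave-one-out AUC: the center weight starts at 7 (the BLOSUM62 Y/Y
  self-score), all others at 1, and positions are swept left to right
  trying ±1 moves, accepting only strict AUC improvements.
* **CKSAAP + SVM** — the composition of k-spaced amino-acid pairs
  (k = 0..4 over the 21-symbol alphabet, a 21 × 21 × 5 = 2205-dim
  frequency vector per window) fed to an RBF-kernel soft-margin SVM,
  with (γ, C) grid-searched by repeated stratified 5-fold CV.
* **kNN** — the classic baseline: raw BLOSUM62 similarity ranking with
  positive-sample similarities up-weighted, score = positive fraction of
  the top k = 5 neighbours (six attainable values).

Around them: dataset construction (window extraction, 70% pairwise
identity reduction), jackknife and repeated stratified k-fold protocols
with ROC/AUC and fixed-specificity operating points (0.90/0.85/0.80),
per-position Fisher's exact enrichment, predictor complementarity
(Pearson correlation of cross-validated scores) and a linear-SVM
ensemble, plus a seeded synthetic motif-dataset generator for
benchmarking. Published tuned parameters for all three predictors ship
as presets (`mgpsModelFromWeights()`, `cksaapPreset()`, `knnPreset()`).

See `vignettes/dephossite-methods.Rmd` for the full model description,
conventions and limitations.

## Worked example

```r
library(dephossite)

ts <- generateSynthetic("PTP1B", seed = 1)   # 63 pos / 898 neg, 21-mers
#> SiteTrainingSet (PTP1B): 63 positives, 898 negatives, window 21

model <- trainMgps(ts)
#> MgpsModel (PTP1B): window 21, 63 reference positives, jackknife AUC 0.918
round(positionWeights(model), 1)
#>  [1] 0 2 2 2 3 2 0 1 3 2 9 3 2 0 1 0 2 0 0 1 2
```

The trained weights say which window positions carry signal: offsets with
planted enrichments (e.g. −9, −2, ±1 for the PTP1B profile) earn weights
above the uninformative flanks, the center offset acts as a tuned bias,
and the jackknife AUC of 0.918 is the leave-one-out ranking quality on
the training set. The enrichment table recovers the planted motif:

```r
enr <- fisherEnrichment(ts)
head(enr[order(enr$p), c("offset", "residue", "oddsRatio", "p", "direction")], 5)
#>     offset residue oddsRatio            p direction
#> 34      -9       P  9.976744 6.071383e-11      over
#> 181     -2       P  9.053191 9.376064e-11      over
#> 251      1       Y 10.825000 1.601853e-10      over
#> 209     -1       Y  9.577778 7.107213e-10      over
#> 51      -8       K  8.381198 1.519231e-09      over
```

Scanning a protein scores every tyrosine and calls it at the stored
specificity thresholds (nested: a 90%-specificity call implies the 85%
and 80% calls):

```r
predictSites(model, c(DEMO = "MSDEPRYAAKPDYEEPYSRV"))
#>   position               peptide     score call_0.90
#> 1        7 ----MSDEPRYAAKPDYEEPY 5.1111111      TRUE
#> 2       13 DEPRYAAKPDYEEPYSRV--- 4.2698413      TRUE
#> 3       17 YAAKPDYEEPYSRV------- 0.9206349     FALSE
```

The same workflow is scriptable from a shell via the bundled tool
(`inst/exec/dephossite`): `dephossite synth|encode|train|predict|
evaluate|enrich`, e.g.

```sh
dephossite synth --enzyme PTP1B --dir data/
dephossite train --dataset data/PTP1B_dataset.tsv --method mgps --out mgps.json
dephossite predict --model mgps.json --fasta query.fasta --out preds.tsv
```

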