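# trtkit

Antigen-agnostic prediction of **tumor-reactive T cell (TRT) clonotypes**
from paired scRNA-seq/scTCR-seq data, with the model-selection machinery to
build the predictor and the combinatorial pipeline to turn its output into a
small panel of therapeutically attractive TCRs.

Tumor biopsies mix genuinely tumor-reactive clones with bystanders.
`trtkit` predicts, per clonotype, whether it is tumor-reactive using only
the transcriptome of its cells — no antigen information — and then narrows
the predicted reactive clones to one high-avidity candidate TCR per
physicochemical TCR cluster.

## What it computes

**Reactivity models.** Two families predict cell-wise reactivity; a
clonotype's score is the maximum over its cells, scaled by training mean/sd,
and binarized at the training-accuracy-maximizing threshold:

* *Signature scores* — a differential-expression step (single-cell Wilcoxon,
  or quasi-likelihood F / moderated t with empirical-Bayes variance
  shrinkage on clone-average log10-normalized profiles) derives an up/down
  gene signature (criterion: P or |logFC|; length; side), which scores cells
  by mean z-scaled expression, rank-recovery AUC, a capped U statistic, or
  centered mean ranks.
* *Elastic-net logistic models* — penalized logistic regression over
  z-scaled expression (correlation-pruned at |r| > 0.8, optionally filtered
  by rank test or DE significance) or principal components.

**Model selection.** Leave-one-patient-out (LOPO) *nested* cross-validation:
the inner LOPO loop tunes hyperparameters by mean Matthews correlation
coefficient, MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN)) with the
zero-denominator → 0 convention; the outer loop estimates cross-patient
generalization; the winner is refit on all data. Y-randomization (100 label
permutations) verifies the framework cannot learn from noise: mean MCC ≈ 0,
mean accuracy ≈ 50%.

**Repertoire metrics.** Richness (unique clones) and clonality
1 − H/ln S (1 − Pielou's evenness) plus compartment cumulative frequencies.

**MixTRTpred pipeline.** Filter out low structural-avidity TCRs (a logistic
classifier on CDR3β physicochemical features, Atchley-factor embedding of
the central residues) → rank survivors by reactivity score → keep the top
20 → UPGMA clustering of a physicochemical TCR distance → report the top
scorer of each of 5 clusters.

**Synthetic cohorts.** A negative-binomial multi-patient generator with
planted up/down programs, clone structure, CDR3 sequence families, and
ground-truth avidity makes every stage testable without patient data.

## Worked example

```r
library(trtkit)

# a 4-patient synthetic cohort with a moderate planted reactivity program
sim <- simulate_cohort(sim_config(n_patients = 4, clones_per_patient = 30,
                                  n_genes = 500, effect_size = 1, seed = 303))

# nested LOPO CV over a small signature-model registry
registry <- list(trt_model_spec("sig_ql_f", "signature",
  list(de_method = "ql_f_pseudobulk"),
  expand.grid(criterion = "p_value", length = c(30, 60), side = "up",
              score_method = "average", stringsAsFactors = FALSE)))
ncv <- nested_cv(registry, sim$cm, sim$ct)
ncv$summary
#>      model mean_mcc mean_accuracy pooled_mcc folds
#> 1 sig_ql_f    0.885         0.942      0.883     4

# score all clones with the final model, add avidity calls, select candidates
ct <- predict_trt(ncv$final_model, sim$cm, sim$ct)
av <- fit_avidity_model(ct$cdr3b, sim$ct$avidity_truth)
ct <- predict_avidity(av, ct)
panel <- run_mixtrtpred(ct, top_n = 20, k = 5)
panel
#> CandidatePanel: 5 TCR candidates (top_n=20, k=5, 28 survivors of 120 clones)
#>   clone_id patient             cdr3a          cdr3b trt_score cluster frequency
#> 1 P01_C020     P01     HYLCRETFHHNTT  YEYTAAREMPRCD      1.78       1    0.0111
#> 2 P03_C003     P03  TEFCRQWKDLVAFCMY   PGEMKHCQFDHV      1.56       2    0.0408
#> 3 P01_C019     P01   KAEGEMTCNMQMLLN     CMYNMKEFFT      1.44       3    0.0222
#> 4 P02_C008     P02     VWEYRGMFKYREW  TQGPSSMHKRYVS      1.33       4    0.0879
#> 5 P02_C003     P02 TEYQVFCGLHNLFRTQP NLHWKRCNRHCATV      1.28       5    0.0220
```

Reading the output: the outer LOPO mean MCC of 0.885 says the selected
configuration separates reactive from bystander clones almost perfectly on
held-out patients of this synthetic cohort; the panel lists one clone per
TCR cluster, each predicted tumor-reactive and high-avidity, ordered by
scaled reactivity score, with its within-patient repertoire frequency.

## Package layout

```
R/                  implementation (IO/data model, simulator, DE engines,
                    scoring, elastic-net models, nested CV + metrics,
                    repertoire metrics, TCR features/clustering, pipeline)
tests/testthat/     unit, property and end-to-end suites with independent
                    brute-force oracles
vignettes/          methods vignette: models, assumptions, design choices
inst/cli/trtkit.R   command-line wrapper
scripts/acceptance.R  null-calibration reproduction
```
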