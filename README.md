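# pneumotext

Text mining and epidemiology for chest X-ray reports taken after
central venous catheter (CVC) procedures. The package answers a
clinical question — *does routine imaging after CVC insertion and
removal find enough pneumothoraces to be worthwhile?* — by extracting
pneumothorax status from free-text radiology reports and clinician
requests, then running the cohort-level statistics on the extracted
labels.

It is written for clinical-NLP and health-services researchers. The
source records are protected health data, so the package also ships a
fully seeded synthetic corpus generator with the cohort's demographic
and lexical structure (German- or English-flavoured reports with
institutional abbreviations, misspellings, negated mentions and
contraindication phrases); every stage is developed and tested against
corpora whose ground truth is known by construction.

## The method

1. **Rule layer.** Categorized regular expressions match affirmative
   pneumothorax mentions, negated mentions and contraindication
   phrases; on overlapping spans negated > contraindication >
   affirmative, so "kein pneumothorax" is never an affirmative hit.
   Study inclusion rules (age ≥ 18, X-ray within 12 h, no incorrect
   placement / follow-up / missing data) are applied in fixed order.
2. **Features.** Reports are lowercased, punctuation-stripped and
   stopword-filtered (curated list: function words + institutional
   boilerplate), abbreviations canonicalized, then turned into a sparse
   bi-gram document–term matrix. Terms with document frequency
   f_t ≤ 0.01·N are pruned; the vocabulary is fitted on the training
   split only.
3. **Class imbalance.** SMOTE from the interpolation formula
   x_new = x_minority + λ·(x_neighbor − x_minority), λ ~ U(0,1), k = 5
   nearest minority neighbours, oversampling the training minority to
   1:1.
4. **Classifier.** Random forest, 250 trees, mtry = 2, Gini impurity
   1 − Σ p_i², seeded and single-threaded; the score of a record is its
   vote fraction and the label is score ≥ 0.5 (ties positive).
   Evaluation is on a stratified 20% held-out split: accuracy,
   sensitivity, specificity, F1, and a trapezoid ROC/AUC equal to the
   Mann–Whitney statistic.
5. **Epidemiology.** 2×2 chi-square (with and without Yates
   correction), logistic regression of pneumothorax on age and gender
   (native IRLS; male coded 1), a linear model of pneumothorax size on
   removal status, and incidence summaries.

## Worked example

Desk-scale epidemiology from the published contingency counts
(16,274/106 after insertion, 792/3 after removal):

```r
library(pneumotext)

incidence_summary(cvc_incidence_counts())$summary
#> # A tibble: 3 × 5
#>   group         n cases incidence incidence_pct
#>   <chr>     <dbl> <int>     <dbl>         <dbl>
#> 1 insertion 16380   106   0.00647           0.6
#> 2 removal     795     3   0.00377           0.4
#> 3 overall   17175   109   0.00635           0.6

chi <- chi_square_2x2(cvc_incidence_counts())   # Yates-corrected
sprintf("X2 = %.5f, p = %.4f", chi$statistic, chi$p_value)
#> "X2 = 0.49951, p = 0.4797"
```

The association between procedure type and pneumothorax is
non-significant (p = 0.48 corrected, p = 0.35 uncorrected): removal is
not measurably safer or riskier than insertion at these event counts.

A full synthetic pipeline run — generate a screened cohort of 3,000
records at 8% prevalence with a 10% misspelling rate, train and
evaluate the classifier, and fit the risk model:

```r
cfg <- default_config(seed = 7, n_records = 3000)
cfg$cohort$hours_range <- c(0, 12)
base <- do.call(cohort_params, c(cfg$cohort, list(seed = 0L)))
cfg$cohort$outcome_model$intercept <- calibrate_outcome_intercept(base, 0.08)
cfg$lexicon$misspelling_rate <- 0.1

res <- run_pipeline(cfg)
res$report
#> <evaluation_report> tp=50 fp=0 tn=550 fn=0
#>   accuracy 1.000 | sensitivity 1.000 | specificity 1.000 | f1 1.000 | auc 1.0000

res$stats$logistic
#> <logistic_fit> (IRLS, 5 iterations)
#>              Estimate  Std. Error   Z value   p value
#> intercept -1.57716673 0.208070865 -7.579950 3.457e-14
#> age       -0.01469211 0.002939319 -4.998474 5.779e-07
#> gender     0.20331392 0.135201639  1.503783 1.326e-01
#> null deviance 1730.6 | residual deviance 1702.9 | AIC 1708.9
```

All 50 held-out positives are recovered with no false positives; the
fitted age effect (−0.0147 log-odds per year) recovers the generating
coefficient within its standard error. On real institutional text —
open vocabulary, irregular negation — these figures would be lower;
the synthetic corpus validates the machinery, not clinical
performance.

The ablation grid (`run_ablation()`) re-runs the pipeline over
stopwords on/off, bi- vs tri-grams, SMOTE on/off and 100–300 trees
with a shared split seed, and a thin CLI
(`inst/cli/pneumotext.R`, subcommands `generate | train | evaluate |
ablate | stats | run`) wraps the same functions for shell use.

## Package layout

- `R/` — synthetic cohort and corpus generation, text preprocessing and
  pattern matching, DTM features, SMOTE + forest, evaluation and
  ablation, epidemiological statistics, pipeline orchestration
- `inst/extdata/` — shipped pattern libraries (YAML), stopword lists,
  versioned benchmark configuration
- `inst/cli/pneumotext.R` — command-line interface
- `vignettes/pneumotext-methods.Rmd` — the model, its assumptions,
  parameter choices and limitations
- `tests/testthat/` — unit, property and acceptance tests
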