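# riskstrat

Hybrid risk stratification for heterogeneous health-survey data.

Population-health cohorts mix continuous biometric and laboratory
measurements, ordinal self-report scales, and binary condition or
behavior indicators, often drawn from different surveys with different
coding schemes and missing-data patterns. `riskstrat` implements a
controlled framework for studying how learning-based models organize
such data into risk strata:

1. **Harmonization.** A declarative variable manifest maps each raw
   column into a risk signal *s<sub>j</sub> = ϕ<sub>j</sub>(x<sub>j</sub>)*:
   continuous variables are median-imputed and standardized,
   *z<sub>j</sub> = (x<sub>j</sub> − μ<sub>j</sub>)/σ<sub>j</sub>*;
   ordinal variables keep their order as consecutive integers; binary
   variables become 0/1 indicators. Variables whose missing fraction
   exceeds τ<sub>m</sub> = 0.3 are excluded before imputation.
2. **Risk induction.** A continuous risk index (a direction-signed,
   weight-configurable linear combination of the signals) is
   discretized into *K* = 3 ordinal classes at its empirical tertiles.
   The classes are induced from the data, not externally defined
   outcomes; a trivial baseline that pushes the index through the
   fitted tertile edges therefore reconstructs them perfectly on the
   fitting partition and upper-bounds every learned model.
3. **Hybrid model.** A multinomial logistic regression (L2 penalty,
   C ∈ {0.01, 0.1, 1, 10} chosen by cross-validated macro-F1,
   iteration cap 3000) and a 500-tree random forest (minimum leaf
   size 3) are trained on a stratified 70% partition. Their class
   probabilities are aggregated as a convex combination
   *R(x) = Σ w<sub>i</sub> f<sub>i</sub>(x)*, *Σ w<sub>i</sub> = 1*,
   *w<sub>i</sub> ≥ 0*, with the weight found on the grid
   {0.0, 0.1, …, 1.0} by 5-fold cross-validated multiclass
   cross-entropy.
4. **Diagnostics.** Accuracy, macro precision/recall/F1, macro
   one-vs-rest ROC-AUC, normalized confusion matrices,
   Pearson/Spearman correlation between *R(x)* and the risk index,
   fold-stability summaries with log₁₀(1 − m) distances to the
   optimum, and a perturbation-based attribution
   *Φ<sub>j</sub> = R(x) − R(x<sup>(j)</sup>)* that replaces one signal
   at a time with its training-set median/mode — deterministic, with
   no coalition sampling.

A seeded synthetic-cohort generator (clinical-heavy, behavioral-heavy,
and integrated archetypes, with configurable missingness, loadings on a
latent risk factor, and optional threshold/interaction nonlinearity)
makes the whole pipeline testable without downloading survey data.

## Worked example

```r
library(riskstrat)

spec <- cohort_spec(n = 3000, archetype = "integrated", seed = 42)
gen  <- generate_cohort(spec)
cfg  <- run_config(gen$data, make_manifest(spec), seed = 42,
                   output_dir = "run42")
res  <- run_pipeline(cfg)
#> [riskstrat] validate: 3000 records in
#> [riskstrat] validate: 2998 records out (2 duplicates, 0 implausible cells)
#> [riskstrat] split: 2099 train / 899 test
#> [riskstrat] risk induction: K = 3, train class counts 700/699/700
#> [riskstrat] hybrid: w = 1 (linear) / 0 (nonlinear), C = 10
#> [riskstrat] trivial baseline (fit partition): accuracy 1

res$baseline$accuracy      # 1 — the induced task is reconstructible by design
res$metrics$hybrid
#> accuracy 0.9889 | macro P 0.9889 R 0.9888 F1 0.9888 | OvR AUC 0.9998 (n = 899)
res$correlation
#> $pearson  0.9629  $spearman  0.9996
res$attribution
#> Attribution over 899 records; baseline R0 = 1.01566
#>   ord_3   0.2775
#>   ord_1   0.1632
#>   ord_2   0.1524
```

Reading these numbers: the trivial baseline hits accuracy 1.000 on its
fitting partition because the class labels are a deterministic function
of the index it thresholds — it is a reconstruction, not a prediction.
The hybrid model approximates the induced tertile boundaries on held-out
records (accuracy 0.989 here); on this linear, integrated-archetype
cohort the weight search settles on the linear component. The Spearman
correlation near 1 shows the learned representation preserves the risk
ordering; the Pearson value slightly below it reflects the monotone but
nonlinear mapping from index to expected class. Attribution shares rank
the harmonized signals by their mean absolute contribution to *R(x)*.

All artifacts (harmonized signals, labels, metrics JSON, stability and
attribution CSVs, run manifest) are written under `output_dir`. A thin
command-line front end for the `synth` and `run` verbs ships at
`inst/cli/riskstrat.R`.

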