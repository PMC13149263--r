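## Shared fixtures and independent oracles, built in code.

tiny_manifest <- function() {
  variable_manifest(
    variable_spec("glucose", kind = "continuous", direction = 1,
                  range = c(40, 600), na_codes = c("9999")),
    variable_spec("sbp", kind = "continuous", direction = 1,
                  range = c(60, 260)),
    variable_spec("genhealth", kind = "ordinal", direction = 1,
                  codes = c("1" = 0, "2" = 1, "3" = 2, "4" = 3, "5" = 4)),
    variable_spec("smoker", kind = "binary", direction = 1,
                  codes = c("1" = 1, "2" = 0))
  )
}

tiny_table <- function() {
  data.frame(
    glucose = c(90, 110, 126, 150, 200, 85, 95, 105, 115, 140),
    sbp = c(110, 120, 130, 140, 150, 115, 125, 118, 122, 135),
    genhealth = c(1, 2, 3, 4, 5, 1, 2, 3, 2, 4),
    smoker = c(1, 2, 1, 2, 1, 2, 1, 2, 1, 2)
  )
}

## Harmonized cohort + induced labels in one call, for model-level tests.
fitted_cohort <- function(n = 400, archetype = "integrated", seed = 1,
                          nonlinearity = "none", ...) {
  spec <- cohort_spec(n = n, archetype = archetype, seed = seed,
                      nonlinearity = nonlinearity, ...)
  gen <- generate_cohort(spec)
  man <- make_manifest(spec)
  val <- validate_cohort(gen$data, man)
  keep <- !duplicated(apply(gen$data, 1, function(r)
    paste(trimws(as.character(r)), collapse = "\r")))
  sm <- fit_transform_signals(val$data, man)
  idx <- build_risk_index(sm)
  list(spec = spec, gen = gen, manifest = man, data = val$data, sm = sm,
       idx = idx, labels = discretize_by_quantiles(idx, 3),
       truth_kept = lapply(gen$truth[c("latent", "risk_score")],
                           function(v) v[keep]))
}

## Independent oracle: one-vs-rest AUC by all-pairs concordance
## (ties count 1/2), macro-averaged over classes present in truth.
brute_macro_ovr_auc <- function(truth, prob) {
  truth <- as.character(truth)
  classes <- intersect(colnames(prob), unique(truth))
  aucs <- vapply(classes, function(cl) {
    pos <- prob[truth == cl, cl]
    neg <- prob[truth != cl, cl]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(pairs)
  }, numeric(1))
  mean(aucs)
}
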