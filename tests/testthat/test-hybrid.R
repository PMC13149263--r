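test_that("stratified split hits the 70/30 ratio per class and is reproducible", {
  y <- rep(0:2, each = 100)
  sp <- make_split(y, seed = 42)
  expect_equal(length(sp$train_indices), 210L)
  expect_equal(length(sp$test_indices), 90L)
  for (cl in 0:2)
    expect_equal(sum(y[sp$train_indices] == cl), 70L)
  expect_length(intersect(sp$train_indices, sp$test_indices), 0)
  expect_setequal(c(sp$train_indices, sp$test_indices), seq_along(y))

  sp2 <- make_split(y, seed = 42)
  expect_identical(sp, sp2)

  ## unbalanced classes: per-class train counts within 1 of 0.7 * n_k
  y2 <- rep(0:2, times = c(500, 300, 200))
  sp3 <- make_split(y2, seed = 7)
  for (cl in 0:2) {
    got <- sum(y2[sp3$train_indices] == cl)
    expect_lte(abs(got - 0.7 * sum(y2 == cl)), 1)
  }
  expect_lte(abs(length(sp3$train_indices) - 700), 1)

  ## fold stratification: per-fold class proportions near global
  glob <- prop.table(table(y2[sp3$train_indices]))
  for (f in 1:5) {
    fold_y <- y2[sp3$train_indices][sp3$fold_assignments == f]
    expect_true(all(abs(prop.table(table(fold_y)) - glob) < 0.02))
  }

  expect_error(make_split(c(rep(0, 100), rep(1, 3)), seed = 1), "class '1'")
})

test_that("base models fit linearly separable bands and are seed-deterministic", {
  withr::with_seed(11, {
    n <- 300
    x1 <- rnorm(n); x2 <- rnorm(n)
    score <- x1 + x2
    y <- cut(score, c(-Inf, -1, 1, Inf), labels = FALSE) - 1L
    X <- cbind(f1 = x1, f2 = x2)
  })
  bm <- fit_base_models(X, y, seed = 5)
  p <- riskstrat:::predict_linear(bm$linear, X, bm$classes)
  expect_gte(mean(riskstrat:::argmax_class(p) == as.character(y)), 0.95)

  expect_error(fit_base_models(X, rep(1, nrow(X)), seed = 1), "two classes")

  bm2 <- fit_base_models(X, y, seed = 5)
  probe <- X[1:25, ]
  expect_identical(riskstrat:::predict_forest(bm$forest, probe, bm$classes),
                   riskstrat:::predict_forest(bm2$forest, probe, bm2$classes))
})

test_that("combine_probabilities is a convex combination with expected-class R", {
  p1 <- matrix(c(1, 0, 0,
                 0.2, 0.5, 0.3), 2, byrow = TRUE, dimnames = list(NULL, 0:2))
  p2 <- matrix(c(0, 0, 1,
                 0.6, 0.2, 0.2), 2, byrow = TRUE, dimnames = list(NULL, 0:2))
  cb <- combine_probabilities(p1, p2, 0.5)
  expect_equal(cb$prob[1, ], c(`0` = 0.5, `1` = 0, `2` = 0.5))
  expect_equal(cb$R[1], 1.0)
  expect_equal(cb$class[1], "0")    # argmax tie -> lower class

  expect_identical(combine_probabilities(p1, p2, 1)$prob, p1)
  expect_identical(combine_probabilities(p1, p2, 0)$prob, p2)

  for (w in seq(0, 1, 0.25)) {
    cbw <- combine_probabilities(p1, p2, w)
    expect_equal(rowSums(cbw$prob), c(1, 1), tolerance = 1e-9)
    expect_true(all(cbw$prob >= pmin(p1, p2) - 1e-12 &
                      cbw$prob <= pmax(p1, p2) + 1e-12))
  }
  expect_error(combine_probabilities(p1, p2[1, , drop = FALSE], 0.5), "shape")
  expect_error(combine_probabilities(p1, p2, 1.2), "0, 1")
})

test_that("weight search favors the nonlinear model on non-planar structure", {
  ## XOR-band structure: class boundary not representable by a plane
  withr::with_seed(21, {
    n <- 600
    x1 <- rnorm(n); x2 <- rnorm(n)
    score <- x1 * x2
    y <- cut(score, quantile(score, c(0, 1/3, 2/3, 1)),
             labels = FALSE, include.lowest = TRUE) - 1L
    X <- cbind(f1 = x1, f2 = x2)
  })
  sw <- search_weights(X, y, grid = c(0, 0.5, 1), seed = 2,
                       hyperparams = utils::modifyList(default_hyperparams(),
                                                       list(C_grid = 1)))
  expect_equal(sw$w, 0)   # full nonlinear share
  losses <- sw$search$cv_loss
  expect_lt(losses[sw$search$w == 0], losses[sw$search$w == 1])

  ## singleton grid: no search
  sw1 <- search_weights(X, y, grid = 0.3, seed = 2,
                        hyperparams = utils::modifyList(default_hyperparams(),
                                                        list(C_grid = 1)))
  expect_equal(sw1$w, 0.3)
})

test_that("hybrid model satisfies the simplex constraint and endpoint equivalence", {
  fc <- fitted_cohort(n = 300, seed = 31)
  hp <- utils::modifyList(default_hyperparams(),
                          list(C_grid = 1, n_estimators = 100))
  m <- fit_hybrid(fc$sm$signals, fc$labels$class_labels, seed = 3,
                  hyperparams = hp)
  expect_equal(sum(m$weights), 1, tolerance = 1e-12)
  expect_true(all(m$weights >= 0))

  pr <- predict(m, fc$sm$signals)
  expect_equal(rowSums(pr$prob), rep(1, nrow(fc$sm$signals)), tolerance = 1e-9)

  ## degenerate grids reproduce the pure base models exactly
  m1 <- fit_hybrid(fc$sm$signals, fc$labels$class_labels, grid = 1,
                   seed = 3, hyperparams = hp)
  p_lin <- riskstrat:::predict_linear(m1$linear, fc$sm$signals, m1$classes)
  expect_equal(predict(m1, fc$sm$signals)$prob, p_lin, tolerance = 1e-12)
  m0 <- fit_hybrid(fc$sm$signals, fc$labels$class_labels, grid = 0,
                   seed = 3, hyperparams = hp)
  p_for <- riskstrat:::predict_forest(m0$forest, fc$sm$signals, m0$classes)
  expect_equal(predict(m0, fc$sm$signals)$prob, p_for, tolerance = 1e-12)

  ## column order at predict time is irrelevant (name-based alignment)
  perm <- sample(ncol(fc$sm$signals))
  expect_identical(predict(m, fc$sm$signals[, perm]), pr)
  expect_error(predict(m, fc$sm$signals[, -1]), "absent")

  ## single-record input
  one <- predict(m, fc$sm$signals[1, , drop = FALSE])
  expect_equal(sum(one$prob), 1, tolerance = 1e-9)

  ## training accuracy is a sane reflection of the CV estimate
  cvacc <- mean(m$fold_metrics$accuracy[m$fold_metrics$model == "hybrid"])
  expect_gte(mean(pr$class == as.character(fc$labels$class_labels)),
             cvacc - 0.05)
})

test_that("weight search favors the linear model when the true boundary is linear", {
  ## stochastic linear structure: classes are tertiles of the latent
  ## factor, signals are noisy linear views of it, so the true posterior
  ## is smooth and monotone in a single linear direction
  ws <- vapply(1:20, function(seed) {
    spec <- cohort_spec(n = 2000, archetype = "integrated",
                        missing_rates = 0, seed = seed)
    gen <- generate_cohort(spec)
    man <- make_manifest(spec)
    val <- validate_cohort(gen$data, man)
    keep <- !duplicated(apply(gen$data, 1, function(r)
      paste(trimws(as.character(r)), collapse = "\r")))
    lab <- discretize_by_quantiles(gen$truth$latent[keep], 3)
    sm <- fit_transform_signals(val$data, man)
    sw <- search_weights(sm$signals, lab$class_labels, seed = seed,
                         hyperparams = utils::modifyList(default_hyperparams(),
                                                         list(C_grid = 1)))
    sw$w
  }, numeric(1))
  expect_gte(mean(ws >= 0.5), 0.8)
})
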