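#' Default hyperparameters for the hybrid model
#'
#' Matches the fixed configuration used throughout: logistic regression
#' with an L2 penalty chosen from `C_grid` by cross-validated macro-F1
#' and an iteration cap of 3000; a 500-tree random forest with minimum
#' leaf size 3.
#'
#' @return Named list of hyperparameters.
#' @export
default_hyperparams <- function() {
  list(C_grid = c(0.01, 0.1, 1, 10), max_iter = 3000,
       n_estimators = 500, min_samples_leaf = 3)
}

#' Stratified train/test split with stratified CV folds
#'
#' Allocates `ratio` of the records to the training partition by
#' stratified sampling on the class labels (largest-remainder rounding,
#' so the total is within one record of `ratio * n`), then assigns
#' 5-fold cross-validation folds within the training partition, again
#' stratified by class. Fully reproducible from `seed`.
#'
#' @param labels Class label vector (length n >= 10).
#' @param ratio Training fraction (default 0.7).
#' @param cv_folds Number of CV folds on the training partition.
#' @param seed Integer seed.
#' @return A `split_plan`: `train_indices`, `test_indices`,
#'   `fold_assignments` (aligned with `train_indices`), `labels`,
#'   `ratio`, `seed`.
#' @export
make_split <- function(labels, ratio = 0.7, cv_folds = 5L, seed = 1L) {
  n <- length(labels)
  if (n < 10L) stop("need at least 10 records to split")
  seed <- stopifnot_scalar_seed(seed)
  classes <- sort(unique(labels))
  counts <- table(factor(labels, levels = classes))
  total_train <- round(ratio * n)
  ## largest-remainder allocation of the train quota across classes
  exact <- ratio * as.numeric(counts)
  base <- floor(exact)
  rem <- total_train - sum(base)
  if (rem > 0) {
    order_frac <- order(exact - base, decreasing = TRUE)
    base[order_frac[seq_len(rem)]] <- base[order_frac[seq_len(rem)]] + 1L
  } else if (rem < 0) {
    order_frac <- order(exact - base)
    base[order_frac[seq_len(-rem)]] <- base[order_frac[seq_len(-rem)]] - 1L
  }
  too_small <- base < cv_folds
  if (any(too_small))
    stop("class '", classes[which(too_small)[1L]],
         "' is too small to stratify across ", cv_folds, " folds")
  withr::with_seed(seed, {
    train_idx <- integer(0)
    folds <- integer(0)
    for (k in seq_along(classes)) {
      members <- which(labels == classes[k])
      picked <- sample(members, base[k])
      train_idx <- c(train_idx, picked)
      folds <- c(folds, rep_len(seq_len(cv_folds), base[k])[sample.int(base[k])])
    }
  })
  ord <- order(train_idx)
  structure(
    list(train_indices = train_idx[ord], test_indices = setdiff(seq_len(n), train_idx),
         fold_assignments = folds[ord], labels = labels, ratio = ratio,
         cv_folds = as.integer(cv_folds), seed = seed),
    class = "split_plan"
  )
}

## ---- base models -----------------------------------------------------

as_model_frame <- function(X) as.data.frame(X, check.names = FALSE)

fit_linear <- function(X, y, C, max_iter, classes) {
  df <- as_model_frame(X)
  df$.risk_class <- factor(y, levels = classes)
  fit <- nnet::multinom(.risk_class ~ ., data = df, decay = 1 / C,
                        maxit = max_iter, trace = FALSE, MaxNWts = 1e5)
  if (!is.null(fit$convergence) && fit$convergence != 0)
    warning("multinomial logistic solver did not converge within ",
            max_iter, " iterations")
  fit
}

predict_linear <- function(fit, X, classes) {
  p <- stats::predict(fit, newdata = as_model_frame(X), type = "probs")
  if (is.null(dim(p))) {
    ## single row -> vector over classes; two classes -> P(second level)
    p <- if (length(p) == length(classes) && nrow(X) == 1L)
      matrix(p, nrow = 1L) else cbind(1 - p, p)
  }
  p <- matrix(as.numeric(p), nrow = nrow(X))
  colnames(p) <- classes
  p
}

fit_forest <- function(X, y, n_estimators, min_samples_leaf, classes, seed) {
  ranger::ranger(x = as_model_frame(X), y = factor(y, levels = classes),
                 num.trees = n_estimators, min.node.size = min_samples_leaf,
                 probability = TRUE, seed = seed, num.threads = 1)
}

predict_forest <- function(fit, X, classes) {
  p <- stats::predict(fit, data = as_model_frame(X),
                      num.threads = 1)$predictions
  out <- matrix(0, nrow = nrow(X), ncol = length(classes),
                dimnames = list(NULL, classes))
  out[, colnames(p)] <- p
  out
}

## Stratified fold assignment for internal CV (no train/test split).
assign_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    members <- which(y == cl)
    folds[members] <- rep_len(seq_len(k), length(members))[sample.int(length(members))]
  }
  folds
}

select_linear_C <- function(X, y, hyper, classes, folds = 5L, seed = 1L) {
  if (length(hyper$C_grid) == 1L) return(hyper$C_grid)
  withr::with_seed(seed, fold_id <- assign_folds(y, folds))
  f1_by_C <- vapply(hyper$C_grid, function(C) {
    f1 <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      if (length(unique(y[tr])) < 2L) return(NA_real_)
      fit <- fit_linear(X[tr, , drop = FALSE], y[tr], C, hyper$max_iter, classes)
      p <- predict_linear(fit, X[!tr, , drop = FALSE], classes)
      macro_f1(y[!tr], argmax_class(p))
    }, numeric(1))
    mean(f1, na.rm = TRUE)
  }, numeric(1))
  hyper$C_grid[which.max(f1_by_C)]
}

#' Fit the two base classifiers
#'
#' The linear component is a multinomial logistic regression with an L2
#' penalty (strength chosen from `C_grid` by cross-validated macro-F1;
#' penalty weight is `1/C`) and an iteration cap of at least 3000. The
#' nonlinear component is a probability random forest with 500 trees and
#' minimum leaf size 3. Both expose per-class probabilities.
#'
#' @param X Numeric signal matrix (complete, named columns).
#' @param y Class labels (at least two classes present).
#' @param hyperparams See [default_hyperparams()].
#' @param seed Integer seed (forest growth and C-selection folds).
#' @return List with `linear`, `forest`, `classes`, `C`.
#' @export
fit_base_models <- function(X, y, hyperparams = default_hyperparams(), seed = 1L) {
  classes <- as.character(sort(unique(y)))
  if (length(classes) < 2L) stop("need at least two classes to fit base models")
  seed <- stopifnot_scalar_seed(seed)
  C <- select_linear_C(X, y, hyperparams, classes, seed = seed)
  linear <- fit_linear(X, y, C, hyperparams$max_iter, classes)
  forest <- fit_forest(X, y, hyperparams$n_estimators,
                       hyperparams$min_samples_leaf, classes, seed)
  list(linear = linear, forest = forest, classes = classes, C = C)
}

#' Convex combination of base-model probabilities
#'
#' `combined = w * P_linear + (1 - w) * P_nonlinear`. The predicted
#' class is the row argmax (ties to the lower class); the continuous
#' representation `R(x)` is the expected ordinal class
#' `sum_c c * combined[, c]` with classes ordered `0 .. C-1`.
#'
#' @param prob_linear,prob_nonlinear Row-stochastic n x C matrices with
#'   identical column order.
#' @param w Weight on the linear model, in `[0, 1]`.
#' @return List with `prob`, `class` (character, column names), `R`.
#' @export
combine_probabilities <- function(prob_linear, prob_nonlinear, w) {
  if (!identical(dim(prob_linear), dim(prob_nonlinear)))
    stop("probability matrices have mismatched shapes")
  if (w < 0 || w > 1) stop("`w` must lie in [0, 1]")
  prob <- w * prob_linear + (1 - w) * prob_nonlinear
  ordinal <- seq_len(ncol(prob)) - 1
  list(prob = prob, class = argmax_class(prob),
       R = as.vector(prob %*% ordinal))
}

#' Grid search for the convex combination weight
#'
#' For each fold of a stratified cross-validation on the training data,
#' both base models are fitted on the fold-train part and their
#' validation probabilities cached; every candidate weight is then
#' scored by mean multiclass cross-entropy of the combined probabilities
#' (macro-F1 is recorded alongside). The winner is the argmin-loss
#' weight; ties go to the larger nonlinear share (smaller `w`). Folds
#' whose training part misses a class are skipped with a warning.
#'
#' @param X,y Training signals and class labels.
#' @param grid Candidate weights on the linear model, subset of `[0, 1]`.
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed.
#' @param hyperparams Hyperparameters with a single `C_grid` value
#'   (already selected) or a grid to select per call.
#' @param fold_id Optional externally supplied fold assignment (e.g.
#'   from a [make_split()] plan) overriding the internal one.
#' @return List with `w` (winner), `search` (data.frame of per-candidate
#'   mean CV loss and macro-F1), `fold_metrics` (per fold x model
#'   validation metrics at the winning weight), `folds_used`.
#' @export
search_weights <- function(X, y, grid = seq(0, 1, by = 0.1), folds = 5L,
                           seed = 1L, hyperparams = default_hyperparams(),
                           fold_id = NULL) {
  if (!length(grid) || any(grid < 0 | grid > 1))
    stop("`grid` must be a non-empty subset of [0, 1]")
  seed <- stopifnot_scalar_seed(seed)
  if (is.null(fold_id))
    withr::with_seed(seed, fold_id <- assign_folds(y, folds))
  classes <- as.character(sort(unique(y)))
  C <- select_linear_C(X, y, hyperparams, classes, seed = seed)
  hyper <- utils::modifyList(hyperparams, list(C_grid = C))
  cache <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (!any(!tr)) next
    if (length(unique(y[tr])) < length(classes)) {
      warning("fold ", f, " misses a class in its training part; skipped")
      next
    }
    bm <- fit_base_models(X[tr, , drop = FALSE], y[tr], hyper,
                          seed = seed + f)
    cache[[f]] <- list(
      p1 = predict_linear(bm$linear, X[!tr, , drop = FALSE], classes),
      p2 = predict_forest(bm$forest, X[!tr, , drop = FALSE], classes),
      truth = y[!tr])
  }
  used <- which(!vapply(cache, is.null, logical(1)))
  if (!length(used)) stop("all cross-validation folds were skipped")

  score_w <- function(w) {
    per_fold <- vapply(used, function(f) {
      cb <- combine_probabilities(cache[[f]]$p1, cache[[f]]$p2, w)
      c(loss = cross_entropy(cb$prob, cache[[f]]$truth),
        f1 = macro_f1(cache[[f]]$truth, cb$class))
    }, numeric(2))
    rowMeans(per_fold)
  }
  scores <- vapply(grid, score_w, numeric(2))
  search <- data.frame(w = grid, cv_loss = scores["loss", ],
                       cv_macro_f1 = scores["f1", ])
  best_loss <- min(search$cv_loss)
  winners <- grid[search$cv_loss <= best_loss + 1e-12]
  w_star <- min(winners)   # tie -> larger nonlinear share

  fold_metrics <- do.call(rbind, lapply(used, function(f) {
    rows <- lapply(c(linear = 1, nonlinear = 0, hybrid = w_star), function(w) {
      cb <- combine_probabilities(cache[[f]]$p1, cache[[f]]$p2, w)
      m <- classification_metrics(cache[[f]]$truth, cb$class, cb$prob)
      data.frame(fold = f, accuracy = m$accuracy, f1_macro = m$f1_macro,
                 roc_auc_macro = m$roc_auc_macro)
    })
    cbind(model = names(rows), do.call(rbind, rows))
  }))
  rownames(fold_metrics) <- NULL
  list(w = w_star, search = search, fold_metrics = fold_metrics,
       folds_used = used)
}

#' Fit the full hybrid risk-stratification model
#'
#' Selects the linear penalty by cross-validated macro-F1, searches the
#' convex combination weight on a discrete grid by 5-fold
#' cross-validation, then retrains both base models on the full training
#' data with the winning configuration.
#'
#' @param X Training signal matrix (named columns).
#' @param y Training class labels.
#' @param grid Weight grid (default `0, 0.1, ..., 1`).
#' @param folds CV folds (default 5).
#' @param seed Integer seed driving fold assignment and forest growth.
#' @param hyperparams See [default_hyperparams()].
#' @param fold_id Optional externally supplied fold assignment.
#' @return A `hybrid_model` object.
#' @export
fit_hybrid <- function(X, y, grid = seq(0, 1, by = 0.1), folds = 5L,
                       seed = 1L, hyperparams = default_hyperparams(),
                       fold_id = NULL) {
  seed <- stopifnot_scalar_seed(seed)
  classes <- as.character(sort(unique(y)))
  if (length(classes) < 2L) stop("need at least two classes")
  C <- select_linear_C(X, y, hyperparams, classes, seed = seed)
  hyper <- utils::modifyList(hyperparams, list(C_grid = C))
  sw <- search_weights(X, y, grid = grid, folds = folds, seed = seed,
                       hyperparams = hyper, fold_id = fold_id)
  bm <- fit_base_models(X, y, hyper, seed = seed)
  w_vec <- c(linear = sw$w, nonlinear = 1 - sw$w)
  stopifnot(abs(sum(w_vec) - 1) < 1e-12, all(w_vec >= 0))
  structure(
    list(linear = bm$linear, forest = bm$forest, classes = classes,
         w = sw$w, weights = w_vec, grid = grid, search = sw$search,
         fold_metrics = sw$fold_metrics, signal_names = colnames(X),
         hyperparams = hyper,
         training_metadata = list(seed = seed, C = C, folds = folds,
                                  n_train = nrow(X))),
    class = "hybrid_model"
  )
}

#' Predict with a fitted hybrid model
#'
#' Columns of `X` are aligned to the training signals by name; order is
#' irrelevant, absent signals are an error.
#'
#' @param object A `hybrid_model`.
#' @param X Signal matrix for new records.
#' @param ... Unused.
#' @return List with `class` (character labels), `prob` (n x C matrix),
#'   `R` (continuous representation).
#' @export
predict.hybrid_model <- function(object, X, ...) {
  miss <- setdiff(object$signal_names, colnames(X))
  if (length(miss))
    stop("signal(s) absent at predict time: ", paste(miss, collapse = ", "))
  X <- X[, object$signal_names, drop = FALSE]
  p1 <- predict_linear(object$linear, X, object$classes)
  p2 <- predict_forest(object$forest, X, object$classes)
  combine_probabilities(p1, p2, object$w)
}

#' @export
print.hybrid_model <- function(x, ...) {
  cat("Hybrid risk model:", length(x$classes), "classes,",
      length(x$signal_names), "signals\n")
  cat(sprintf("  weights: linear %.2f / nonlinear %.2f (C = %g)\n",
              x$w, 1 - x$w, x$training_metadata$C))
  invisible(x)
}
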