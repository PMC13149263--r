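## Per-class macro metrics from a confusion table. Zero-division policy:
## a class that is never predicted gets precision 0 (with a warning from
## the public wrapper); classes absent from the truth are excluded from
## macro averages.
confusion_table <- function(truth, predicted) {
  levels <- as.character(sort(unique(c(truth, predicted))))
  table(factor(as.character(truth), levels = levels),
        factor(as.character(predicted), levels = levels))
}

macro_prf <- function(truth, predicted, warn = FALSE) {
  tab <- confusion_table(truth, predicted)
  present <- rowSums(tab) > 0
  if (warn && !all(present))
    warning("class(es) absent from truth excluded from macro averages: ",
            paste(rownames(tab)[!present], collapse = ", "))
  tp <- diag(tab)
  prec_den <- colSums(tab)
  rec_den <- rowSums(tab)
  prec <- ifelse(prec_den > 0, tp / prec_den, 0)
  if (warn && any(prec_den[present] == 0))
    warning("class(es) never predicted; precision set to 0: ",
            paste(rownames(tab)[present & prec_den == 0], collapse = ", "))
  rec <- ifelse(rec_den > 0, tp / rec_den, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(precision = mean(prec[present]), recall = mean(rec[present]),
       f1 = mean(f1[present]), table = tab, present = present)
}

macro_f1 <- function(truth, predicted) macro_prf(truth, predicted)$f1

## Macro one-vs-rest ROC-AUC on class probabilities (ties count 1/2,
## via trapezoidal AUC). Returns NA when fewer than two classes occur.
macro_ovr_auc <- function(truth, prob) {
  classes <- colnames(prob)
  truth <- as.character(truth)
  present <- classes[classes %in% unique(truth)]
  if (length(present) < 2L) return(NA_real_)
  aucs <- vapply(present, function(cl) {
    resp <- factor(truth == cl, levels = c(FALSE, TRUE))
    as.numeric(pROC::auc(resp, prob[, cl], levels = c(FALSE, TRUE),
                         direction = "<", quiet = TRUE))
  }, numeric(1))
  mean(aucs)
}

#' Classification metrics for the induced risk task
#'
#' Accuracy, macro-averaged precision/recall/F1 (classes unweighted;
#' classes absent from the truth are excluded with a warning; a class
#' never predicted contributes precision 0 with a warning), macro
#' one-vs-rest ROC-AUC on class probabilities, and the row-normalized
#' confusion matrix.
#'
#' @param truth True class labels.
#' @param predicted Predicted class labels.
#' @param prob Optional n x C row-stochastic probability matrix with
#'   class names as columns (required for ROC-AUC).
#' @return A `metric_report`: `accuracy`, `precision_macro`,
#'   `recall_macro`, `f1_macro`, `roc_auc_macro` (NA with a flag when
#'   undefined), `confusion`, `confusion_normalized`, `n_evaluated`.
#' @export
classification_metrics <- function(truth, predicted, prob = NULL) {
  stopifnot(length(truth) == length(predicted))
  m <- macro_prf(truth, predicted, warn = TRUE)
  auc <- NA_real_
  auc_flag <- NULL
  if (!is.null(prob)) {
    stopifnot(nrow(prob) == length(truth))
    if (length(unique(as.character(truth))) < 2L) {
      auc_flag <- "single-class truth: ROC-AUC undefined"
      warning(auc_flag)
    } else {
      auc <- macro_ovr_auc(truth, prob)
    }
  }
  tab <- m$table
  norm <- tab / pmax(rowSums(tab), 1L)
  structure(
    list(accuracy = mean(as.character(truth) == as.character(predicted)),
         precision_macro = m$precision, recall_macro = m$recall,
         f1_macro = m$f1, roc_auc_macro = auc, roc_auc_flag = auc_flag,
         confusion = unclass(tab), confusion_normalized = unclass(norm),
         n_evaluated = length(truth)),
    class = "metric_report"
  )
}

#' Correlation between the learned representation and the risk index
#'
#' Pearson product-moment and Spearman rank correlation (average ranks
#' for ties) between the continuous hybrid representation `R(x)` and the
#' continuous risk index the classes were induced from.
#'
#' @param R_values Continuous representation values.
#' @param risk_index Continuous risk-index values.
#' @return List with `pearson` and `spearman`.
#' @export
representation_correlation <- function(R_values, risk_index) {
  stopifnot(length(R_values) == length(risk_index), length(R_values) >= 3L)
  if (stats::var(R_values) == 0) stop("`R_values` is constant")
  if (stats::var(risk_index) == 0) stop("`risk_index` is constant")
  list(pearson = stats::cor(R_values, risk_index),
       spearman = stats::cor(R_values, risk_index, method = "spearman"))
}

#' Fold-stability summary for one metric
#'
#' Mean, sample standard deviation (ddof 1), and the per-fold distance
#' to the optimum `log10(1 - m)`. Folds at or beyond the cap
#' `1 - floor` (a saturated metric) are flagged and reported at the
#' capped distance `log10(floor)`.
#'
#' @param fold_values Numeric vector of per-fold metric values (>= 2).
#' @param floor Cap on `1 - m` (default `1e-6`, distance -6).
#' @return A `stability_report`: `mean`, `sd`, `log_distance`, `capped`
#'   (logical per fold), `fold_values`.
#' @export
cv_stability <- function(fold_values, floor = 1e-6) {
  stopifnot(length(fold_values) >= 2L)
  gap <- 1 - fold_values
  capped <- gap < floor
  if (any(capped)) gap[capped] <- floor
  structure(
    list(mean = mean(fold_values), sd = stats::sd(fold_values),
         log_distance = log10(gap), capped = capped,
         fold_values = fold_values, floor = floor,
         sd_convention = "sample (ddof = 1)"),
    class = "stability_report"
  )
}

#' Stability table across models and metrics
#'
#' @param fold_metrics A data.frame with columns `model`, `fold`, and
#'   one column per metric (as produced by [search_weights()]).
#' @return Long-format data.frame: model, metric, fold, value,
#'   log_distance, mean, sd, capped.
#' @export
stability_table <- function(fold_metrics) {
  metric_cols <- setdiff(names(fold_metrics), c("model", "fold"))
  out <- list()
  for (mod in unique(fold_metrics$model)) {
    sub <- fold_metrics[fold_metrics$model == mod, , drop = FALSE]
    for (met in metric_cols) {
      st <- cv_stability(sub[[met]])
      out[[length(out) + 1L]] <- data.frame(
        model = mod, metric = met, fold = sub$fold, value = sub[[met]],
        log_distance = st$log_distance, mean = st$mean, sd = st$sd,
        capped = st$capped)
    }
  }
  do.call(rbind, out)
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro P %.4f R %.4f F1 %.4f | OvR AUC %s (n = %d)\n",
              x$accuracy, x$precision_macro, x$recall_macro, x$f1_macro,
              ifelse(is.na(x$roc_auc_macro), "NA",
                     sprintf("%.4f", x$roc_auc_macro)), x$n_evaluated))
  invisible(x)
}
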