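#' Build the continuous risk index
#'
#' The index is a direction-signed linear combination of harmonized
#' signals: `score_i = sum_j w_j * d_j * s_ij`, where `d_j` is the
#' manifest risk direction and the default weights are equal
#' (`1/p` over the `p` signals with nonzero direction). The index is an
#' induced construct for structural analysis, not a clinically validated
#' score.
#'
#' @param sm A `signal_matrix` from [fit_transform_signals()].
#' @param weights Optional named weights per signal; `NULL` means equal
#'   weights over direction-nonzero signals.
#' @return Numeric score vector with a `"weights"` attribute recording
#'   the effective per-signal weights (direction-signed).
#' @export
build_risk_index <- function(sm, weights = NULL) {
  stopifnot(inherits(sm, "signal_matrix"))
  d <- sm$directions[sm$signal_names]
  active <- names(d)[d != 0]
  if (!length(active)) stop("risk index undefined: all risk directions are zero")
  if (is.null(weights)) {
    w <- stats::setNames(rep(1 / length(active), length(active)), active)
  } else {
    if (is.null(names(weights))) stop("`weights` must be named by signal")
    if (!all(is.finite(weights))) stop("`weights` must be finite")
    miss <- setdiff(active, names(weights))
    if (length(miss)) stop("missing weight for signal(s): ",
                           paste(miss, collapse = ", "))
    w <- weights[active]
  }
  eff <- w * d[active]
  score <- as.vector(sm$signals[, active, drop = FALSE] %*% eff)
  attr(score, "weights") <- eff
  score
}

#' Discretize a risk index into ordinal classes by quantiles
#'
#' Interior cut points are the `k/K` empirical quantiles
#' (order-statistic interpolation, R type 7). A record's class is the
#' number of cut points strictly below its score, so scores tied with a
#' cut point fall in the lower class.
#'
#' @param scores Continuous risk-index vector.
#' @param K Number of ordinal classes (default 3).
#' @return An `induced_risk_labels` object: `risk_index`, `class_labels`
#'   (integers `0 .. K-1`), `quantile_edges`, `K`, `index_weights`.
#' @export
discretize_by_quantiles <- function(scores, K = 3L) {
  K <- as.integer(K)
  if (K < 2L) stop("`K` must be an integer >= 2")
  if (length(scores) < K) stop("need at least K scores")
  if (max(scores) == min(scores))
    stop("risk index is constant; quantile edges are degenerate ",
         "(inspect the index weights and signal directions)")
  edges <- stats::quantile(scores, probs = seq_len(K - 1L) / K,
                           type = 7, names = FALSE)
  labels <- vapply(scores, function(s) sum(edges < s), integer(1))
  structure(
    list(risk_index = scores, class_labels = labels,
         quantile_edges = edges, K = K,
         index_weights = attr(scores, "weights"),
         quantile_type = 7L),
    class = "induced_risk_labels"
  )
}

#' Trivial score-threshold baseline
#'
#' Classifies evaluation scores directly by the quantile edges fitted on
#' another (or the same) partition. No learning occurs; on the fitting
#' partition with a tie-free index this reconstructs the induced classes
#' exactly, upper-bounding any learned model on the induced task.
#'
#' @param labels_fit An `induced_risk_labels` fitted on the reference
#'   partition.
#' @param scores_eval Risk-index values to classify.
#' @return Integer class vector in `0 .. K-1`.
#' @export
trivial_baseline <- function(labels_fit, scores_eval) {
  stopifnot(inherits(labels_fit, "induced_risk_labels"))
  edges <- labels_fit$quantile_edges
  vapply(scores_eval, function(s) sum(edges < s), integer(1))
}

#' Threshold-based binary outcome from a raw clinical variable
#'
#' `y_i = 1` iff the raw (untransformed) clinical value strictly exceeds
#' `tau`. Records with a missing value are excluded; an index map links
#' the outcome back to source rows. This outcome path is independent of
#' every harmonization transform by construction.
#'
#' @param z Raw clinical column (numeric, may contain `NA`).
#' @param tau Finite clinical threshold.
#' @param source_signal Name of the clinical variable (metadata).
#' @return An `outcome_labels` object: `y`, `index_map`, `threshold`,
#'   `source_signal`.
#' @export
threshold_outcome <- function(z, tau, source_signal = "clinical") {
  if (!is.finite(tau)) stop("`tau` must be finite")
  keep <- which(!is.na(z))
  if (!length(keep)) stop("all values of the outcome variable are missing")
  structure(
    list(y = as.integer(z[keep] > tau), index_map = keep,
         threshold = tau, source_signal = source_signal),
    class = "outcome_labels"
  )
}

#' Write induced risk labels and their sidecar
#'
#' @param labels An `induced_risk_labels` object.
#' @param csv_path Output CSV (record id, risk index, class).
#' @param json_path Output JSON (quantile edges, index weights, K).
#' @return Invisibly, the two paths.
#' @export
write_risk_labels <- function(labels, csv_path, json_path) {
  utils::write.csv(
    data.frame(record = seq_along(labels$risk_index),
               risk_index = labels$risk_index,
               class = labels$class_labels),
    csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(quantile_edges = labels$quantile_edges, K = labels$K,
         index_weights = as.list(labels$index_weights %||% list()),
         quantile_type = labels$quantile_type),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}

#' @export
print.induced_risk_labels <- function(x, ...) {
  cat("Induced risk labels: n =", length(x$risk_index), ", K =", x$K, "\n")
  cat("  quantile edges:", paste(signif(x$quantile_edges, 6), collapse = ", "), "\n")
  cat("  class counts:", paste(tabulate(x$class_labels + 1L, x$K), collapse = "/"), "\n")
  invisible(x)
}
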