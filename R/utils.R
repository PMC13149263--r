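#' @keywords internal
"_PACKAGE"

## Statistical mode of a numeric vector; ties broken toward the smallest
## value so imputation is deterministic without a seed.
stat_mode <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  tab <- table(x)
  as.numeric(names(tab)[which(tab == max(tab))[1L]])
}

## Multiclass cross-entropy of a row-stochastic probability matrix against
## integer/factor truth aligned to `colnames(prob)`.
cross_entropy <- function(prob, truth) {
  idx <- match(as.character(truth), colnames(prob))
  if (anyNA(idx)) stop("truth contains classes absent from probability columns")
  p <- prob[cbind(seq_len(nrow(prob)), idx)]
  -mean(log(pmax(p, 1e-15)))
}

## Row argmax with ties resolved toward the lower class index.
argmax_class <- function(prob) {
  cls <- colnames(prob)
  cls[apply(prob, 1L, which.max)]
}

stopifnot_scalar_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  as.integer(seed)
}
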