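## Fixture constants used to rescale standardized continuous signals to
## plausible clinical ranges (glucose-, blood-pressure-, BMI-like, ...).
## The values are arbitrary presentation constants; all modelling happens
## on the standardized scale.
.clinical_scales <- data.frame(
  center = c(100, 120, 80, 27, 190, 70, 35, 14, 5.5, 98.6),
  spread = c(25, 15, 10, 4, 35, 10, 8, 1.5, 0.6, 0.8)
)

#' Specify a synthetic cohort
#'
#' Archetypes mirror the composition patterns of large health surveys:
#' `"clinical"` is continuous-heavy (6 continuous + 5 binary signals,
#' like a lab/biometric extract), `"behavioral"` and `"integrated"` are
#' self-report-heavy (2 continuous + 4 binary + 3 ordinal). Signal
#' counts, per-signal missingness (MCAR), loadings on a single latent
#' risk factor, noise level, and an optional nonlinear risk structure
#' are all configurable.
#'
#' @param n Number of records.
#' @param archetype `"clinical"`, `"behavioral"`, or `"integrated"`.
#' @param n_continuous,n_ordinal,n_binary Signal counts (defaults set by
#'   archetype).
#' @param missing_rates Per-signal missing fractions in `[0, 1)`;
#'   recycled (default 0.05).
#' @param loadings Per-signal loadings on the latent risk factor;
#'   recycled (default 0.8).
#' @param nonlinearity `"none"`, `"threshold"` (diagnostic-cutoff
#'   indicator effects on continuous signals), or `"interaction"`
#'   (pairwise products of continuous signals) in the planted risk
#'   score.
#' @param noise_sd Standard deviation of per-signal noise (default 0.5).
#' @param seed Integer seed.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n, archetype = c("integrated", "clinical", "behavioral"),
                        n_continuous = NULL, n_ordinal = NULL, n_binary = NULL,
                        missing_rates = 0.05, loadings = 0.8,
                        nonlinearity = c("none", "threshold", "interaction"),
                        noise_sd = 0.5, seed = 1L) {
  archetype <- match.arg(archetype)
  nonlinearity <- match.arg(nonlinearity)
  defaults <- switch(archetype,
                     clinical = c(cont = 6L, ord = 0L, bin = 5L),
                     behavioral = c(cont = 2L, ord = 3L, bin = 4L),
                     integrated = c(cont = 2L, ord = 3L, bin = 4L))
  n_continuous <- as.integer(n_continuous %||% defaults["cont"])
  n_ordinal <- as.integer(n_ordinal %||% defaults["ord"])
  n_binary <- as.integer(n_binary %||% defaults["bin"])
  p <- n_continuous + n_ordinal + n_binary
  if (p < 1L) stop("need at least one signal")
  if (any(missing_rates < 0 | missing_rates >= 1))
    stop("missing_rates must lie in [0, 1)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(
    list(n = as.integer(n), archetype = archetype,
         n_continuous = n_continuous, n_ordinal = n_ordinal,
         n_binary = n_binary,
         missing_rates = rep_len(missing_rates, p),
         loadings = rep_len(loadings, p),
         nonlinearity = nonlinearity, noise_sd = noise_sd,
         seed = stopifnot_scalar_seed(seed)),
    class = "cohort_spec"
  )
}

synth_colnames <- function(spec) {
  c(if (spec$n_continuous) paste0("cont_", seq_len(spec$n_continuous)),
    if (spec$n_ordinal) paste0("ord_", seq_len(spec$n_ordinal)),
    if (spec$n_binary) paste0("bin_", seq_len(spec$n_binary)))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a standard-normal latent risk factor `u` per record; each
#' signal's noiseless core is `loading * u` plus Gaussian noise.
#' Continuous signals are affinely rescaled to plausible clinical
#' ranges; ordinal signals are the latent value cut into five ordered
#' levels (codes 1-5); binary signals threshold the latent value at
#' zero (codes 1 = risk present, 2 = absent). Missingness is planted
#' completely at random per signal.
#'
#' The planted ground-truth risk score equals `u` when `nonlinearity`
#' is `"none"`. With `"threshold"`, continuous signals contribute
#' two-sided diagnostic-cutoff indicators (deviation beyond 0.8 SD in
#' either direction, a J-shaped risk profile) instead of their linear
#' values; with `"interaction"`, products of consecutive continuous
#' signal pairs are used. Non-continuous signals contribute their
#' observed encodings. Both variants make the planted score a
#' non-monotone function of the observed signal space that a linear
#' decision surface cannot reconstruct, while a flexible model can.
#'
#' @param spec A [cohort_spec()].
#' @return List with `data` (raw cohort data.frame with NAs planted),
#'   `truth` (`latent`, `risk_score`, `loadings`, `directions`,
#'   `missing_mask`), and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  nm <- synth_colnames(spec)
  p <- length(nm)
  withr::with_seed(spec$seed, {
    u <- stats::rnorm(spec$n)
    latent <- vapply(seq_len(p), function(j)
      spec$loadings[j] * u + spec$noise_sd * stats::rnorm(spec$n),
      numeric(spec$n))
    colnames(latent) <- nm
    dat <- matrix(NA_real_, spec$n, p, dimnames = list(NULL, nm))
    for (j in seq_len(p)) {
      v <- nm[j]
      if (startsWith(v, "cont_")) {
        k <- ((j - 1L) %% nrow(.clinical_scales)) + 1L
        dat[, j] <- .clinical_scales$center[k] +
          .clinical_scales$spread[k] * latent[, j]
      } else if (startsWith(v, "ord_")) {
        sd_l <- sqrt(spec$loadings[j]^2 + spec$noise_sd^2)
        cuts <- stats::qnorm(c(0.2, 0.4, 0.6, 0.8), sd = max(sd_l, 1e-12))
        dat[, j] <- findInterval(latent[, j], cuts) + 1    # codes 1..5
      } else {
        dat[, j] <- ifelse(latent[, j] > 0, 1, 2)          # 1 = risk present
      }
    }
    ## planted ground-truth risk score; the nonlinear variants are exact
    ## functions of the observed signal space (cutoff indicators on the
    ## continuous signals, observed encodings elsewhere), so a flexible
    ## model can reconstruct their quantile classes while a linear
    ## decision surface cannot
    if (spec$nonlinearity == "none" || spec$n_continuous == 0L) {
      risk_score <- u
    } else {
      cont_idx <- which(startsWith(nm, "cont_"))
      other_idx <- setdiff(seq_len(p), cont_idx)
      if (spec$nonlinearity == "threshold") {
        ## two-sided diagnostic cutoffs (J-shaped risk): a continuous
        ## signal is flagged when it deviates from its center by more
        ## than 0.8 SD in either direction
        sd_l <- sqrt(spec$loadings[cont_idx]^2 + spec$noise_sd^2)
        nl <- rowSums(abs(sweep(latent[, cont_idx, drop = FALSE], 2,
                                pmax(sd_l, 1e-12), "/")) > 0.8)
      } else {
        pairs <- cbind(cont_idx, c(cont_idx[-1], cont_idx[1]))
        nl <- rowSums(latent[, pairs[, 1], drop = FALSE] *
                        latent[, pairs[, 2], drop = FALSE])
      }
      ## observed encodings of the non-continuous signals: ordinal level
      ## (codes 1..5) and binary risk indicator
      obs_other <- if (length(other_idx)) {
        rowSums(vapply(other_idx, function(j)
          if (startsWith(nm[j], "ord_")) {
            sd_l <- sqrt(spec$loadings[j]^2 + spec$noise_sd^2)
            cuts <- stats::qnorm(c(0.2, 0.4, 0.6, 0.8), sd = max(sd_l, 1e-12))
            findInterval(latent[, j], cuts) + 1
          } else as.numeric(latent[, j] > 0),
          numeric(spec$n)))
      } else NULL
      risk_score <- as.vector(scale(nl)) +
        if (!is.null(obs_other)) as.vector(scale(obs_other)) else 0
    }
    mask <- matrix(FALSE, spec$n, p, dimnames = list(NULL, nm))
    for (j in seq_len(p)) {
      if (spec$missing_rates[j] > 0) {
        hit <- stats::runif(spec$n) < spec$missing_rates[j]
        mask[, j] <- hit
        dat[hit, j] <- NA
      }
    }
  })
  list(data = as.data.frame(dat),
       truth = list(latent = u, risk_score = risk_score,
                    loadings = stats::setNames(spec$loadings, nm),
                    directions = stats::setNames(sign(spec$loadings), nm),
                    missing_mask = mask),
       spec = spec)
}

#' Manifest matching a synthetic cohort
#'
#' Builds a [variable_manifest()] consistent with [generate_cohort()]
#' output: continuous signals get generous plausibility ranges covering
#' everything generated, ordinal signals map codes 1-5 to 0-4, binary
#' signals map code 1 (risk present) to 1 and code 2 to 0. Risk
#' directions equal the sign of each planted loading.
#'
#' @param spec A [cohort_spec()].
#' @return A `variable_manifest`.
#' @export
make_manifest <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  nm <- synth_colnames(spec)
  specs <- lapply(seq_along(nm), function(j) {
    v <- nm[j]
    dir <- sign(spec$loadings[j])
    if (startsWith(v, "cont_")) {
      k <- ((j - 1L) %% nrow(.clinical_scales)) + 1L
      half <- 8 * .clinical_scales$spread[k] *
        sqrt(spec$loadings[j]^2 + spec$noise_sd^2 + 1e-12)
      variable_spec(v, kind = "continuous", direction = dir,
                    range = .clinical_scales$center[k] + c(-half, half),
                    source_tag = "synthetic")
    } else if (startsWith(v, "ord_")) {
      variable_spec(v, kind = "ordinal", direction = dir,
                    codes = stats::setNames(0:4, as.character(1:5)),
                    source_tag = "synthetic")
    } else {
      variable_spec(v, kind = "binary", direction = dir,
                    codes = c("1" = 1, "2" = 0), source_tag = "synthetic")
    }
  })
  variable_manifest(specs)
}
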