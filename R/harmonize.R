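#' Validate a raw cohort table against a manifest
#'
#' Applies the exclusion rules that precede harmonization: sentinel
#' codes are recoded to missing, exact duplicate rows (after string
#' normalization) are removed, and continuous values outside each
#' variable's plausibility range are set to missing. Counts of affected
#' rows/cells are returned in an exclusion report.
#'
#' @param raw_table A data.frame whose columns are a superset of the
#'   manifest's variable names.
#' @param manifest A [variable_manifest()].
#' @return A list with `data` (cleaned data.frame) and `report`
#'   (named counts: `duplicates`, `implausible`, `sentinel_missing`,
#'   plus `per_variable` cell counts).
#' @export
validate_cohort <- function(raw_table, manifest) {
  stopifnot(is.data.frame(raw_table))
  if (nrow(raw_table) < 1L) stop("cohort table is empty")
  vars <- vapply(manifest, `[[`, character(1), "name")
  missing_cols <- setdiff(vars, names(raw_table))
  if (length(missing_cols))
    stop("manifest column(s) absent from table: ",
         paste(missing_cols, collapse = ", "))

  dat <- raw_table
  sentinel_n <- 0L
  for (e in manifest) {
    col <- dat[[e$name]]
    if (length(e$na_codes)) {
      hit <- !is.na(col) & trimws(as.character(col)) %in% e$na_codes
      sentinel_n <- sentinel_n + sum(hit)
      col[hit] <- NA
    }
    dat[[e$name]] <- suppressWarnings(as.numeric(as.character(col)))
  }

  ## duplicates: exact full-row identity on the normalized string form
  key <- apply(dat, 1L, function(r) paste(trimws(as.character(r)), collapse = "\r"))
  dup <- duplicated(key)
  n_dup <- sum(dup)
  dat <- dat[!dup, , drop = FALSE]

  implausible <- 0L
  per_var <- stats::setNames(integer(length(manifest)),
                             vapply(manifest, `[[`, character(1), "name"))
  for (e in manifest) {
    col <- dat[[e$name]]
    if (e$kind == "continuous") {
      bad <- !is.na(col) & (col < e$range[1] | col > e$range[2])
    } else {
      bad <- !is.na(col) & !(as.character(col) %in% names(e$codes))
    }
    if (any(bad)) {
      col[bad] <- NA
      dat[[e$name]] <- col
      implausible <- implausible + sum(bad)
      per_var[e$name] <- sum(bad)
    }
  }
  if (nrow(dat) == 0L) stop("no records remain after exclusion rules")
  rownames(dat) <- NULL
  list(data = dat,
       report = list(duplicates = n_dup, implausible = implausible,
                     sentinel_missing = sentinel_n, per_variable = per_var,
                     n_records = nrow(dat)))
}

#' Filter variables by missingness
#'
#' A variable is dropped iff its fraction of missing values strictly
#' exceeds `tau_m` (the retention boundary itself is kept).
#'
#' @param data Cleaned cohort data.frame (from [validate_cohort()]).
#' @param manifest A [variable_manifest()]; only manifest variables are
#'   assessed.
#' @param tau_m Missingness threshold in `[0, 1]` (default 0.3).
#' @return List with `retained`, `dropped` (variable names) and
#'   `missing_fraction` (named vector).
#' @export
filter_by_missingness <- function(data, manifest, tau_m = 0.3) {
  if (!is.numeric(tau_m) || tau_m < 0 || tau_m > 1)
    stop("`tau_m` must lie in [0, 1]")
  vars <- vapply(manifest, `[[`, character(1), "name")
  frac <- vapply(vars, function(v) mean(is.na(data[[v]])), numeric(1))
  dropped <- vars[frac > tau_m]
  retained <- setdiff(vars, dropped)
  if (!length(retained))
    warning("no variables survive the missingness filter (tau_m = ", tau_m, ")")
  list(retained = retained, dropped = dropped, missing_fraction = frac)
}

## Encode one variable column according to its spec; returns a matrix of
## one or more signal columns plus the transform record.
encode_variable <- function(col, e) {
  if (e$kind == "continuous") stop("internal: encode_variable is categorical-only")
  mapped <- unname(e$codes[as.character(col)])   # unknown codes -> NA
  if (e$kind %in% c("ordinal", "binary")) {
    m <- stat_mode(mapped)
    mapped[is.na(mapped)] <- m
    sig <- matrix(mapped, ncol = 1L,
                  dimnames = list(NULL, e$harmonized_name))
    params <- list(kind = e$kind, codes = e$codes, mode = m,
                   levels = sort(unique(unname(e$codes))))
    return(list(signals = sig, params = params))
  }
  ## nominal: one indicator per non-reference level; reference = most
  ## frequent encoded level (defensive path, rarely exercised)
  m <- stat_mode(mapped)
  mapped[is.na(mapped)] <- m
  levs <- sort(unique(unname(e$codes)))
  nonref <- setdiff(levs, m)
  sig <- vapply(nonref, function(l) as.numeric(mapped == l),
                numeric(length(mapped)))
  sig <- matrix(sig, ncol = length(nonref),
                dimnames = list(NULL, paste0(e$harmonized_name, "_", nonref)))
  list(signals = sig,
       params = list(kind = "nominal", codes = e$codes, mode = m,
                     reference_level = m, indicator_levels = nonref))
}

#' Fit the harmonization transform and produce the signal matrix
#'
#' Continuous variables are imputed with their median and standardized
#' to zero mean and unit (population) standard deviation; ordinal
#' variables are mapped to consecutive integers preserving order; binary
#' variables become 0/1 indicators; all imputation statistics,
#' standardization parameters and reference values (median of the
#' transformed continuous signal, mode of the encoded categorical
#' signal) are stored for later reuse on new data.
#'
#' @param data Cleaned cohort data.frame (from [validate_cohort()]).
#' @param manifest A [variable_manifest()].
#' @param tau_m Missingness threshold applied before fitting.
#' @return A `signal_matrix` object: `signals` (numeric matrix),
#'   `transform_params`, `reference_values`, `missing_fraction`,
#'   `directions`, `dropped`, `flags`.
#' @export
fit_transform_signals <- function(data, manifest, tau_m = 0.3) {
  filt <- filter_by_missingness(data, manifest, tau_m)
  if (!length(filt$retained)) stop("no variables survive the missingness filter")
  sig_cols <- list(); params <- list(); refs <- numeric(); dirs <- numeric()
  flags <- character()
  for (e in manifest[filt$retained]) {
    col <- data[[e$name]]
    if (e$kind == "continuous") {
      med <- stats::median(col, na.rm = TRUE)
      col[is.na(col)] <- med
      mu <- mean(col)
      sigma <- sqrt(mean((col - mu)^2))   # population SD
      if (sigma > 0) z <- (col - mu) / sigma
      else { z <- rep(0, length(col)); flags <- c(flags, e$harmonized_name) }
      sig_cols[[e$harmonized_name]] <-
        matrix(z, ncol = 1L, dimnames = list(NULL, e$harmonized_name))
      params[[e$harmonized_name]] <-
        list(kind = "continuous", mu = mu, sigma = sigma, median = med,
             sd_convention = "population")
      refs[e$harmonized_name] <- stats::median(z)
      dirs[e$harmonized_name] <- e$direction
    } else {
      enc <- encode_variable(col, e)
      sig_cols[[e$harmonized_name]] <- enc$signals
      for (nm in colnames(enc$signals)) {
        params[[nm]] <- enc$params
        refs[nm] <- stat_mode(enc$signals[, nm])
        dirs[nm] <- e$direction
      }
    }
  }
  signals <- do.call(cbind, unname(sig_cols))
  mf <- filt$missing_fraction
  structure(
    list(signals = signals, signal_names = colnames(signals),
         transform_params = params, reference_values = refs,
         missing_fraction = mf, directions = dirs,
         retained = filt$retained, dropped = filt$dropped,
         zero_variance = flags, tau_m = tau_m,
         source_variables = stats::setNames(
           rep(filt$retained, vapply(sig_cols, ncol, integer(1))),
           colnames(signals))),
    class = "signal_matrix"
  )
}

#' Apply a fitted harmonization transform to new records
#'
#' Uses the stored means, standard deviations, medians, modes, and code
#' maps; never re-estimates anything from the new data. Unknown
#' categorical codes and missing cells are imputed with the fit-time
#' statistics.
#'
#' @param data New cohort data.frame sharing the manifest's raw columns.
#' @param fitted A `signal_matrix` from [fit_transform_signals()].
#' @param manifest The same [variable_manifest()] used at fit time.
#' @return A `signal_matrix` with transformed `signals`; all fit-time
#'   parameters are carried over unchanged.
#' @export
apply_transform <- function(data, fitted, manifest) {
  stopifnot(inherits(fitted, "signal_matrix"))
  missing_cols <- setdiff(fitted$retained, names(data))
  if (length(missing_cols))
    stop("signal source column(s) absent from new records: ",
         paste(missing_cols, collapse = ", "))
  sig_cols <- list()
  for (v in fitted$retained) {
    e <- manifest[[v]]
    col <- suppressWarnings(as.numeric(as.character(data[[v]])))
    if (e$kind == "continuous") {
      p <- fitted$transform_params[[e$harmonized_name]]
      bad <- !is.na(col) & (col < e$range[1] | col > e$range[2])
      col[bad] <- NA
      col[is.na(col)] <- p$median
      z <- if (p$sigma > 0) (col - p$mu) / p$sigma else rep(0, length(col))
      sig_cols[[e$harmonized_name]] <-
        matrix(z, ncol = 1L, dimnames = list(NULL, e$harmonized_name))
    } else {
      first_sig <- colnames_for(e, fitted)[1L]
      p <- fitted$transform_params[[first_sig]]
      mapped <- unname(p$codes[as.character(col)])
      mapped[is.na(mapped)] <- p$mode
      if (p$kind %in% c("ordinal", "binary")) {
        sig_cols[[e$harmonized_name]] <-
          matrix(mapped, ncol = 1L, dimnames = list(NULL, e$harmonized_name))
      } else {
        sig <- vapply(p$indicator_levels, function(l) as.numeric(mapped == l),
                      numeric(length(mapped)))
        sig_cols[[e$harmonized_name]] <-
          matrix(sig, ncol = length(p$indicator_levels),
                 dimnames = list(NULL, paste0(e$harmonized_name, "_",
                                              p$indicator_levels)))
      }
    }
  }
  out <- fitted
  out$signals <- do.call(cbind, unname(sig_cols))[, fitted$signal_names, drop = FALSE]
  out
}

colnames_for <- function(e, fitted) {
  nm <- names(fitted$source_variables)[fitted$source_variables == e$name]
  nm
}

#' Write harmonized signals and their transform sidecar
#'
#' @param sm A `signal_matrix`.
#' @param csv_path Output CSV for the harmonized signals.
#' @param json_path Output JSON sidecar (transform parameters, reference
#'   values, missing fractions, drop list).
#' @return Invisibly, the two paths.
#' @export
write_signal_matrix <- function(sm, csv_path, json_path) {
  utils::write.csv(as.data.frame(sm$signals), csv_path, row.names = FALSE)
  side <- list(transform_params = sm$transform_params,
               reference_values = as.list(sm$reference_values),
               missing_fraction = as.list(sm$missing_fraction),
               dropped = sm$dropped, zero_variance = sm$zero_variance,
               tau_m = sm$tau_m)
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("Signal matrix:", nrow(x$signals), "records x", ncol(x$signals),
      "signals\n")
  cat("  dropped by missingness (tau_m =", x$tau_m, "):",
      if (length(x$dropped)) paste(x$dropped, collapse = ", ") else "none", "\n")
  invisible(x)
}
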