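test_that("validate_cohort removes duplicates and implausible values with correct counts", {
  man <- tiny_manifest()
  tab <- tiny_table()

  dup <- rbind(tab, tab[1, ])
  v <- validate_cohort(dup, man)
  expect_equal(v$report$duplicates, 1L)
  expect_equal(nrow(v$data), 10L)

  bad <- tab
  bad$glucose[2] <- 9999    # sentinel code for glucose
  bad$glucose[3] <- 700     # out of range
  bad$sbp[5] <- 20          # out of range
  v <- validate_cohort(rbind(bad, bad[1, ]), man)
  expect_equal(v$report$duplicates, 1L)
  expect_equal(v$report$sentinel_missing, 1L)
  expect_equal(v$report$implausible, 2L)
  ## planted violations total 3 beyond duplication, by hand count
  expect_equal(v$report$implausible + v$report$sentinel_missing, 3L)
  expect_true(is.na(v$data$glucose[2]) && is.na(v$data$glucose[3]) &&
                is.na(v$data$sbp[5]))

  expect_error(validate_cohort(tab[, -1], man), "glucose")
})

test_that("missingness filter drops strictly above tau_m and is monotone in tau_m", {
  fracs <- c(0, .1, .29, .30, .31, 1.0)
  n <- 100
  cols <- lapply(fracs, function(f) {
    x <- rnorm(n) * 10 + 120
    x[seq_len(round(f * n))] <- NA
    x
  })
  dat <- as.data.frame(cols)
  names(dat) <- paste0("v", seq_along(fracs))
  man <- variable_manifest(lapply(names(dat), function(v)
    variable_spec(v, kind = "continuous", direction = 1, range = c(-1000, 1000))))

  res <- filter_by_missingness(dat, man, tau_m = 0.3)
  expect_setequal(res$dropped, c("v5", "v6"))   # .31 and 1.0; boundary .30 kept
  expect_true("v4" %in% res$retained)

  ## monotonicity: larger tau_m retains a superset
  prev <- character(0)
  for (tau in c(0, .1, .3, .5, 1)) {
    r <- suppressWarnings(filter_by_missingness(dat, man, tau))
    expect_true(all(prev %in% r$retained))
    prev <- r$retained
  }
  expect_warning(filter_by_missingness(dat[, "v6", drop = FALSE],
                                       man["v6"], 0.3), "no variables")
})

test_that("continuous standardization uses population SD and median imputation", {
  man <- variable_manifest(variable_spec("x", kind = "continuous",
                                         direction = 1, range = c(-100, 100)))
  sm <- fit_transform_signals(data.frame(x = c(1, 2, 3)), man)
  expect_equal(as.vector(sm$signals[, "x"]),
               c(-1.22474487139159, 0, 1.22474487139159), tolerance = 1e-12)
  expect_equal(sm$transform_params$x$sigma, sqrt(2 / 3), tolerance = 1e-12)

  ## zero variance -> constant 0 with flag, not an error
  sm0 <- fit_transform_signals(data.frame(x = c(5, 5, 5)), man)
  expect_equal(as.vector(sm0$signals[, "x"]), c(0, 0, 0))
  expect_true("x" %in% sm0$zero_variance)

  ## imputation with fit median precedes moment estimation, and the
  ## median is preserved (odd observed count)
  x <- c(1, 2, 3, 4, 100, NA, NA)
  smi <- fit_transform_signals(data.frame(x = x), man)
  expect_equal(smi$transform_params$x$median, 3)
  imputed <- smi$signals[, "x"] * smi$transform_params$x$sigma +
    smi$transform_params$x$mu
  expect_equal(median(imputed), 3)
})

test_that("standardized signals have mean 0 and unit SD on their fit data", {
  fc <- fitted_cohort(n = 300, seed = 4)
  cont <- names(which(vapply(fc$sm$transform_params,
                             function(p) p$kind == "continuous", logical(1))))
  for (v in cont) {
    z <- fc$sm$signals[, v]
    expect_lt(abs(mean(z)), 1e-9)
    expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-9)
  }
  expect_true(all(fc$sm$missing_fraction[fc$sm$retained] <= 0.3))
  expect_false(anyNA(fc$sm$signals))
})

test_that("categorical encoding follows the manifest without artificial levels", {
  man <- tiny_manifest()
  tab <- tiny_table()
  sm <- fit_transform_signals(tab, man)
  expect_setequal(unique(sm$signals[, "smoker"]), c(0, 1))
  expect_equal(sm$signals[, "smoker"], ifelse(tab$smoker == 1, 1, 0),
               ignore_attr = TRUE)
  expect_equal(sort(unique(sm$signals[, "genhealth"])), 0:4)

  ## mode imputation with ties broken toward the smallest encoded value
  man2 <- variable_manifest(variable_spec("b", kind = "binary", direction = 1,
                                          codes = c("1" = 1, "2" = 0)))
  sm2 <- fit_transform_signals(data.frame(b = c(1, 2, NA, NA)), man2,
                               tau_m = 0.5)
  expect_equal(sm2$signals[3:4, "b"], c(0, 0), ignore_attr = TRUE)
})

test_that("apply_transform reuses fit statistics and round-trips on fit data", {
  fc <- fitted_cohort(n = 200, seed = 9)
  again <- apply_transform(fc$data, fc$sm, fc$manifest)
  expect_equal(again$signals, fc$sm$signals, tolerance = 1e-12)

  ## a record equal to all fit medians maps to (median - mu) / sigma
  med_row <- fc$data[1, , drop = FALSE]
  cont <- names(which(vapply(fc$sm$transform_params,
                             function(p) p$kind == "continuous", logical(1))))
  for (v in cont) med_row[[v]] <- fc$sm$transform_params[[v]]$median
  out <- apply_transform(med_row, fc$sm, fc$manifest)
  for (v in cont) {
    p <- fc$sm$transform_params[[v]]
    expect_equal(out$signals[1, v], (p$median - p$mu) / p$sigma,
                 ignore_attr = TRUE)
  }

  ## a missing cell in new data is imputed with the FIT median
  miss_row <- fc$data[2, , drop = FALSE]
  miss_row[[cont[1]]] <- NA
  out2 <- apply_transform(miss_row, fc$sm, fc$manifest)
  p <- fc$sm$transform_params[[cont[1]]]
  expect_equal(out2$signals[1, cont[1]], (p$median - p$mu) / p$sigma,
               ignore_attr = TRUE)

  expect_error(apply_transform(fc$data[, -1], fc$sm, fc$manifest), "cont_1")
})

test_that("standardization is invariant to affine shifts of the raw column", {
  man <- variable_manifest(variable_spec("x", kind = "continuous",
                                         direction = 1, range = c(-1e6, 1e6)))
  x <- rnorm(50, 100, 15)
  base <- fit_transform_signals(data.frame(x = x), man)$signals
  shifted <- fit_transform_signals(data.frame(x = x + 37), man)$signals
  scaled <- fit_transform_signals(data.frame(x = x * 3.5), man)$signals
  expect_equal(base, shifted, tolerance = 1e-9)
  expect_equal(base, scaled, tolerance = 1e-9)
})
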