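test_that("corrected response is the analyte/IS area ratio", {
  expect_equal(corrected_response(1000, 500), 2.0)
  expect_equal(corrected_response(0, 500), 0.0)
  expect_true(is.na(corrected_response(1000, 0)))   # missing IS, no ratio
  expect_true(is.na(corrected_response(1000, NA)))
  expect_error(corrected_response(-1, 500), ">= 0")
})

test_that("an exact line is fit exactly", {
  x <- 10^seq(-7, -4)
  fit <- fit_calibration(make_cal_series(x, 2 * x))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$lloq, min(x))
  expect_equal(fit$uloq, max(x))
  expect_equal(fit$n_levels_used, 4)
})

test_that("weighted fit equals the normal-equation oracle", {
  # heteroscedastic toy set: proportional scatter around y = 3x + 1e-3
  x <- c(1e-7, 5e-7, 1e-6, 5e-6, 1e-5, 5e-5, 1e-4)
  y <- 3 * x * c(1.08, 0.93, 1.02, 0.97, 1.05, 0.99, 1.01) + 1e-3
  fit <- fit_calibration(make_cal_series(x, y))
  oracle <- wls_oracle(x, y, 1 / x)
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
  expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-10)

  # property: oracle equivalence on 100 random small instances
  withr::with_seed(99, {
    for (rep in 1:100) {
      n <- sample(4:9, 1)
      xr <- sort(10^runif(n, -8, -4))
      yr <- runif(1, 0.5, 5) * xr * rlnorm(n, 0, 0.2) + abs(rnorm(1, 0, 1e-4))
      fit <- fit_calibration(make_cal_series(xr, yr))
      orc <- wls_oracle(xr, yr, 1 / xr)
      expect_equal(fit$slope, orc$slope, tolerance = 1e-10)
      expect_equal(fit$intercept, orc$intercept, tolerance = 1e-10)
    }
  })
})

test_that("blank level is excluded from the weighted fit", {
  x <- 10^seq(-7, -4)
  series <- make_cal_series(c(0, x), c(0.5, 2 * x))  # corrupt blank response
  fit <- fit_calibration(series)
  expect_equal(fit$slope, 2, tolerance = 1e-12)      # unaffected by blank
  expect_equal(fit$n_levels_used, 4)
})

test_that("1/x weighting beats unweighted fits at the low end under proportional noise", {
  x <- rep(10^seq(-7, -3), each = 2)
  err_w <- err_u <- numeric(40)
  withr::with_seed(7, {
    for (r in 1:40) {
      y <- 2 * x * rlnorm(length(x), 0, 0.15)
      fw <- fit_calibration(make_cal_series(x, y))
      fu <- fit_calibration(make_cal_series(x, y), weighting = "none")
      x0 <- min(x)
      y0 <- mean(y[x == x0])
      err_w[r] <- abs((y0 - fw$intercept) / fw$slope / x0 - 1)
      err_u[r] <- abs((y0 - fu$intercept) / fu$slope / x0 - 1)
    }
  })
  expect_lt(mean(err_w), mean(err_u))
})

test_that("degenerate calibration inputs are rejected", {
  x <- 10^seq(-7, -4)
  expect_error(fit_calibration(make_cal_series(x[1:2], 2 * x[1:2])),
               "fewer than 3")
  expect_error(fit_calibration(make_cal_series(x, rep(1, 4))),
               "all responses equal")
})

test_that("interpolation inverts the calibration line with range flags", {
  fit <- fit_calibration(make_cal_series(10^seq(-7, -4), 2 * 10^seq(-7, -4)))
  res <- interpolate_conc(fit, 2e-5)
  expect_equal(res$conc_M, 1e-5)
  expect_equal(res$flag, "ok")
  # below the blank-level response: clamped to zero, below LLOQ
  res_lo <- interpolate_conc(fit, -1e-9)
  expect_equal(res_lo$conc_M, 0)
  expect_equal(res_lo$flag, "below_lloq")
  # above the top calibrant response
  res_hi <- interpolate_conc(fit, 2 * 1e-3)
  expect_equal(res_hi$flag, "above_uloq")
  # strictly increasing in the ratio
  ratios <- seq(1e-7, 1e-4, length.out = 50)
  concs <- interpolate_conc(fit, ratios)$conc_M
  expect_true(all(diff(concs) > 0))
})

test_that("preparation factors correct the spike dilution", {
  expect_equal(apply_prep_factors(1e-5, spike_fraction = 0.2), 1.25e-5)
  expect_equal(apply_prep_factors(1, spike_fraction = 0.05), 1 / 0.95)
  expect_equal(apply_prep_factors(3.2e-6), 3.2e-6)  # all factors 1
  expect_error(apply_prep_factors(1, spike_fraction = 1), "spike_fraction")
})

test_that("quantify_table inverts a noiseless study to the extract truth", {
  cfg <- noiseless_config()
  sim <- simulate_study(cfg)
  models <- fit_calibration_curves(sim$calibration)
  ext <- quantify_table(sim$raw, models, prep = sim$prep, panel = sim$panel)
  truth <- sim$extract_truth
  key <- function(d) paste(d$sample_id, d$metabolite_id)
  expected <- truth$conc_extract_M[match(key(ext), key(truth))]
  ok <- ext$flag == "ok"
  expect_gt(mean(ok), 0.95)  # only range flags at the extremes may remain
  expect_lt(max(abs(ext$conc_extract_M[ok] / expected[ok] - 1)), 1e-9)
  # calibrant rows are never emitted as sample concentrations
  expect_false(any(grepl("^cal_", ext$sample_id)))
  # every cell carries exactly one flag
  expect_false(anyNA(ext$flag))
  expect_true(all(ext$flag %in% c("ok", "below_lloq", "above_uloq",
                                  "missing", "missing_is", "no_model")))
})

test_that("missing channels and models are flagged per cell", {
  cfg <- noiseless_config(seed = 17)
  sim <- simulate_study(cfg)
  raw <- sim$raw
  # remove one IS row and one analyte row
  is_idx <- which(raw$channel == "internal_standard")[1]
  victim_is <- raw[is_idx, c("sample_id", "metabolite_id")]
  a_idx <- which(raw$channel == "analyte")[2]
  victim_a <- raw[a_idx, c("sample_id", "metabolite_id")]
  raw <- raw[-c(is_idx, a_idx), ]
  models <- fit_calibration_curves(sim$calibration)
  # drop one model entirely
  dropped <- names(models)[5]
  ext <- quantify_table(raw, models[-5], prep = sim$prep, panel = sim$panel)
  get_flag <- function(s, m) ext$flag[ext$sample_id == s & ext$metabolite_id == m]
  expect_equal(get_flag(victim_is$sample_id, victim_is$metabolite_id),
               "missing_is")
  expect_equal(get_flag(victim_a$sample_id, victim_a$metabolite_id),
               "missing")
  expect_true(all(ext$flag[ext$metabolite_id == dropped] == "no_model"))
  # other metabolites unaffected
  expect_gt(mean(ext$flag[ext$metabolite_id != dropped] == "ok"), 0.9)
})
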