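test_that("ground truth spans the documented concentration ranges", {
  cfg <- study_config(seed = 3)
  truth <- generate_ground_truth(cfg, default_panel())
  spans <- tapply(truth$conc_intracellular_M, truth$group_id,
                  function(v) log10(max(v) / min(v)))
  expect_true(all(spans >= 3))  # >= 3 decades within every group
  panel_span <- log10(max(truth$conc_intracellular_M) /
                        min(truth$conc_intracellular_M))
  expect_gt(panel_span, 6)      # ~7 decades across the whole panel
  expect_lt(panel_span, 8)
})

test_that("ground-truth adenylates keep the energy charge physiological", {
  cfg <- study_config(seed = 4)
  truth <- generate_ground_truth(cfg, default_panel())
  ec <- attr(truth, "ec_truth")$ec
  expect_true(all(ec >= cfg$ec_range[1] & ec <= cfg$ec_range[2]))
  # recompute from the concentrations themselves
  for (g in unique(truth$group_id)) {
    get <- function(m) truth$conc_intracellular_M[
      truth$group_id == g & truth$metabolite_id == m]
    ec_g <- energy_charge(get("AMP"), get("ADP"), get("ATP"))
    expect_true(ec_within_physiological(ec_g))
  }
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- study_config(seed = 9)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$biomass, s2$biomass)
  expect_identical(s1$calibration, s2$calibration)
  expect_identical(s1$raw, s2$raw)
  s3 <- simulate_study(study_config(seed = 10))
  expect_false(identical(s1$raw$area, s3$raw$area))
})

test_that("biomass records follow the organism-kind schema", {
  cfg <- study_config(seed = 2)
  bm <- simulate_biomass(cfg)
  micro <- bm$organism_kind == "microorganism"
  expect_true(all(!is.na(bm$dry_weight_g[micro])))
  expect_true(all(is.na(bm$cell_density_per_L[micro])))
  expect_true(all(is.na(bm$cell_volume_pL[micro])))
  expect_true(all(!is.na(bm$cell_density_per_L[!micro])))
  expect_true(all(!is.na(bm$cell_volume_pL[!micro])))
  expect_true(all(bm$extract_volume_L > 0))
})

test_that("zero biomass jitter makes replicates identical", {
  cfg <- study_config(seed = 2, biomass_cv = 0)
  bm <- simulate_biomass(cfg)
  for (g in unique(bm$group_id)) {
    sub <- bm[bm$group_id == g, ]
    expect_equal(length(unique(sub$dry_weight_g)), 1)
    expect_equal(length(unique(sub$cell_density_per_L)), 1)
  }
})

test_that("analyte/IS ratio cancels the shared matrix factor exactly", {
  cfg <- study_config(seed = 13, noise_cv = 0, matrix_effect_sd = 0.3,
                      missing_rate = 0, outlier_rate = 0, biomass_cv = 0)
  sim <- simulate_study(cfg)
  raw <- sim$raw
  a <- raw[raw$channel == "analyte", ]
  i <- raw[raw$channel == "internal_standard", ]
  key <- function(d) paste(d$sample_id, d$metabolite_id)
  ratio <- a$area / i$area[match(key(a), key(i))]
  truth <- sim$extract_truth
  conc <- truth$conc_extract_M[match(key(a), key(truth))]
  # within each metabolite the ratio/concentration quotient is a constant
  for (m in unique(a$metabolite_id)[1:10]) {
    sel <- a$metabolite_id == m & conc > 0
    quotient <- ratio[sel] / conc[sel]
    expect_lt(diff(range(quotient)) / mean(quotient), 1e-9)
  }
})

test_that("missingness matches its configured rate at panel scale", {
  cfg <- study_config(seed = 21)
  sim <- simulate_study(cfg)
  n_cells <- nrow(sim$biomass) * nrow(sim$panel)
  n_analyte <- sum(sim$raw$channel == "analyte")
  frac <- 1 - n_analyte / n_cells
  tol <- 3 * sqrt(0.04 * 0.96 / n_cells)
  expect_lt(abs(frac - 0.04), tol)
})

test_that("outlier injection matches its configured rate", {
  cfg <- study_config(seed = 22, noise_cv = 0, matrix_effect_sd = 0,
                      missing_rate = 0, outlier_rate = 0.1, biomass_cv = 0)
  sim <- simulate_study(cfg)
  raw <- sim$raw
  a <- raw[raw$channel == "analyte", ]
  key <- function(d) paste(d$sample_id, d$metabolite_id)
  truth <- sim$extract_truth
  conc <- truth$conc_extract_M[match(key(a), key(truth))]
  # with all noise off an injected outlier is an exact x3-x10 multiplier
  dev <- a$area / conc  # proportional to sensitivity except where bumped
  combo <- paste(a$group_id, a$metabolite_id)
  bumped <- vapply(split(dev, combo),
                   function(v) max(v) / min(v) > 2.9, logical(1))
  rate <- mean(bumped)
  tol <- 3 * sqrt(0.1 * 0.9 / length(bumped))
  expect_lt(abs(rate - 0.1), tol)
  # at most one replicate bumped per combo
  n_bumped <- vapply(split(dev, combo),
                     function(v) sum(v / min(v) > 2.9), double(1))
  expect_true(all(n_bumped <= 1))
})

test_that("noiseless calibration series reproduces the response model", {
  cfg <- noiseless_config()
  panel <- default_panel()
  instrument <- instrument_response(panel, cfg$seed + 10L)
  cal <- simulate_calibration(cfg, panel, instrument)
  blank_analyte <- cal$area[cal$role == "blank" & cal$channel == "analyte"]
  expect_true(all(blank_analyte == 0))
  m <- panel$metabolite_id[1]
  fit_ratio <- fit_calibration(cal[cal$metabolite_id == m, ])
  expect_equal(fit_ratio$slope,
               1 / instrument$is_conc_M[instrument$metabolite_id == m],
               tolerance = 1e-9)
  fit_area <- fit_calibration(cal[cal$metabolite_id == m, ],
                              response = "analyte")
  expect_equal(fit_area$slope,
               instrument$sensitivity[instrument$metabolite_id == m],
               tolerance = 1e-9)
})
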