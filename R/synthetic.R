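# Synthetic multi-organism study generator -----------------------------------
#
# Forward model (per sample s, metabolite m):
#   amount_mol        = conc_intracellular * total_cell_volume(s)
#   conc_extract      = amount_mol / extract_volume
#   conc_analyzed     = conc_extract * (1 - spike) * lyo_factor / recon_factor
#   analyte_area      = sensitivity_m * conc_analyzed * matrix_sm * eps
#   IS_area           = sensitivity_m * is_conc_m     * matrix_sm * eps'
# The matrix factor matrix_sm is shared between the two channels of a
# (sample, metabolite) cell, so the analyte/IS ratio cancels it -- this is the
# property that motivates isotope dilution and that the ablation flag of
# run_pipeline() removes.

cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

# lognormal multiplicative noise with mean 1 and coefficient of variation cv
rlnorm_mean1 <- function(n, cv) {
  s <- cv_to_sdlog(cv)
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Default group descriptors for the synthetic study
#'
#' Eight biological groups emulating a panel of two bacteria/yeast-like
#' microorganisms, two microalga-like microorganisms (with an osmolyte-style
#' high proline pool), and four human cell lines (two adherent, two
#' suspension, with an aerobic-glycolysis-style high lactate pool).
#' Microorganism groups carry a culture biomass density and a literature
#' specific cell volume; cell-line groups carry a cell density and a
#' measured mean cell volume (pL).
#'
#' @return A data frame of group descriptors consumed by [study_config()].
#' @export
default_study_groups <- function() {
  data.frame(
    group_id      = c("bsub", "scer", "noce", "ptri",
                      "hek293", "hela_s3", "nb4", "mccar"),
    organism_kind = c(rep("microorganism", 4),
                      "adherent_cell_line", "adherent_cell_line",
                      "suspension_cell_line", "suspension_cell_line"),
    aa_profile    = c("prokaryote", rep("eukaryote", 7)),
    high_proline  = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    high_lactate  = c(rep(FALSE, 4), rep(TRUE, 4)),
    biomass_density_g_per_L = c(0.40, 0.50, 0.20, 0.20, NA, NA, NA, NA),
    specific_volume_L_per_g = c(4.09e-3, 2.66e-3, 1.18e-3, 2.51e-3,
                                NA, NA, NA, NA),
    cell_density_per_L = c(NA, NA, NA, NA, 2e9, 2e9, 5e8, 5e8),
    cell_volume_pL     = c(NA, NA, NA, NA, 2.0, 2.5, 0.9, 1.2),
    sampled_volume_L   = c(0.010, 0.010, 0.015, 0.015, rep(0.005, 4)),
    extract_volume_L   = rep(5e-4, 8),
    stringsAsFactors = FALSE
  )
}

#' Configuration of a synthetic study
#'
#' @param groups Data frame of group descriptors (see
#'   [default_study_groups()] for the schema).
#' @param n_replicates Biological replicates per group (>= 3, default 5).
#' @param seed Integer seed; every generator output is a pure function of
#'   `(config, seed)`.
#' @param noise_cv Coefficient of variation of the independent lognormal
#'   measurement noise on each channel (default 0.10).
#' @param matrix_effect_sd CV of the lognormal ionization/matrix factor
#'   shared between the analyte and internal-standard channel of a
#'   (sample, metabolite) cell (default 0.30).
#' @param missing_rate Probability that a (sample, metabolite) cell is
#'   dropped from the raw table (default 0.04).
#' @param outlier_rate Probability that a (group, metabolite) replicate
#'   vector receives a single multiplicative x3-x10 outlier (default 0.02).
#' @param biomass_cv Replicate-level lognormal jitter on biomass readings
#'   (default 0.05).
#' @param ec_range Band in which each group's true adenylate energy charge is
#'   drawn (default `c(0.75, 0.93)`).
#' @param calibration_levels Calibrant concentrations in mol/L, including a
#'   blank at 0 (default blank + 10^-11 ... 10^-3).
#' @param calibration_replicates Injections per calibration level (default 2).
#' @return A validated `study_config` list.
#' @export
study_config <- function(groups = default_study_groups(),
                         n_replicates = 5,
                         seed = 1,
                         noise_cv = 0.10,
                         matrix_effect_sd = 0.30,
                         missing_rate = 0.04,
                         outlier_rate = 0.02,
                         biomass_cv = 0.05,
                         ec_range = c(0.75, 0.93),
                         calibration_levels = c(0, 10^seq(-11, -3, by = 1)),
                         calibration_replicates = 2) {
  assert_columns(groups, c("group_id", "organism_kind", "aa_profile",
                           "high_proline", "high_lactate",
                           "biomass_density_g_per_L",
                           "specific_volume_L_per_g", "cell_density_per_L",
                           "cell_volume_pL", "sampled_volume_L",
                           "extract_volume_L"), "groups")
  if (anyDuplicated(groups$group_id)) stop_mq("duplicated group_id")
  bad_kind <- setdiff(groups$organism_kind,
                      c("microorganism", "suspension_cell_line",
                        "adherent_cell_line"))
  if (length(bad_kind)) stop_mq("unknown organism_kind: ",
                                paste(bad_kind, collapse = ", "))
  assert_scalar_num(n_replicates, "n_replicates")
  if (n_replicates < 3) stop_mq("n_replicates must be >= 3 (Dixon's Q needs n >= 3)")
  assert_scalar_num(seed, "seed")
  assert_fraction(missing_rate, "missing_rate", upper = 0.5)
  assert_fraction(outlier_rate, "outlier_rate", upper = 0.5)
  assert_scalar_num(noise_cv, "noise_cv"); if (noise_cv < 0) stop_mq("noise_cv < 0")
  assert_scalar_num(matrix_effect_sd, "matrix_effect_sd")
  if (matrix_effect_sd < 0) stop_mq("matrix_effect_sd < 0")
  assert_scalar_num(biomass_cv, "biomass_cv"); if (biomass_cv < 0) stop_mq("biomass_cv < 0")
  if (length(ec_range) != 2 || ec_range[1] >= ec_range[2] ||
      ec_range[1] <= 0.5 || ec_range[2] >= 1) {
    stop_mq("ec_range must be an increasing pair inside (0.5, 1)")
  }
  lv <- sort(unique(calibration_levels))
  if (sum(lv > 0) < 3) stop_mq("need >= 3 non-blank calibration levels")
  structure(list(groups = groups,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed),
                 noise_cv = noise_cv,
                 matrix_effect_sd = matrix_effect_sd,
                 missing_rate = missing_rate,
                 outlier_rate = outlier_rate,
                 biomass_cv = biomass_cv,
                 ec_range = ec_range,
                 calibration_levels = lv,
                 calibration_replicates = as.integer(calibration_replicates)),
            class = "study_config")
}

# class-specific log10 concentration bands (mol/L); the deoxynucleoside
# phosphates sit lowest and the amino acids highest, so each group spans
# >= 3 decades and the full panel ~7 once the osmolyte-style proline pool
# (up to 1e-1 M) is in place.
truth_band <- function(met_class, aa_profile) {
  switch(met_class,
         deoxynucleoside_phosphate = c(-8.0, -6.5),
         nucleoside_phosphate      = c(-5.5, -3.5),
         glycolysis                = c(-6.0, -3.3),
         PPP                       = c(-6.5, -4.0),
         TCA                       = c(-5.5, -3.0),
         organic_acid_other        = c(-5.5, -3.0),
         amino_acid = if (identical(aa_profile, "prokaryote")) {
           c(-4.5, -3.0)
         } else {
           c(-4.0, -2.3)
         },
         stop_mq("unknown met_class: ", met_class))
}

#' Generate ground-truth intracellular concentrations
#'
#' Per (group, metabolite) concentrations are drawn log-uniformly within
#' class-specific bands. The adenylates AMP/ADP/ATP are drawn jointly so
#' that each group's true energy charge falls inside `config$ec_range`;
#' groups flagged `high_proline` / `high_lactate` receive an elevated
#' proline / lactate pool.
#'
#' @param config A [study_config()].
#' @param panel A [default_panel()]-style metabolite panel.
#' @return A `ground_truth` data frame with columns `group_id`,
#'   `metabolite_id`, `conc_intracellular_M`; the per-group true energy
#'   charge is stored in attribute `ec_truth`.
#' @export
generate_ground_truth <- function(config, panel) {
  panel <- validate_panel(panel)
  groups <- config$groups
  withr::with_seed(config$seed, {
    out <- vector("list", nrow(groups))
    ec_truth <- data.frame(group_id = groups$group_id, ec = NA_real_)
    for (g in seq_len(nrow(groups))) {
      band <- t(vapply(panel$met_class, truth_band,
                       numeric(2), aa_profile = groups$aa_profile[g]))
      u <- stats::runif(nrow(panel))
      conc <- 10^(band[, 1] + u * (band[, 2] - band[, 1]))
      names(conc) <- panel$metabolite_id

      # adenylates constrained so EC lies in the configured band
      total <- 10^stats::runif(1, -3, -2.5)
      ec <- stats::runif(1, config$ec_range[1], config$ec_range[2])
      f_adp <- stats::runif(1, 0.08, min(0.30, 1.8 * (1 - ec)))
      adeny <- c(ATP = (ec - f_adp / 2) * total,
                 ADP = f_adp * total,
                 AMP = (1 - ec - f_adp / 2) * total)
      conc[names(adeny)] <- adeny
      ec_truth$ec[g] <- ec

      if (isTRUE(groups$high_proline[g]) && "Pro" %in% names(conc)) {
        conc["Pro"] <- 10^stats::runif(1, -1.3, -1.0)
      }
      if (isTRUE(groups$high_lactate[g]) && "LAC" %in% names(conc)) {
        conc["LAC"] <- 10^stats::runif(1, -2.8, -2.2)
      }
      out[[g]] <- data.frame(group_id = groups$group_id[g],
                             metabolite_id = panel$metabolite_id,
                             conc_intracellular_M = unname(conc),
                             stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, out)
    rownames(truth) <- NULL
    structure(truth, ec_truth = ec_truth,
              class = c("ground_truth", "data.frame"))
  })
}

#' Simulate per-replicate biomass records
#'
#' Microorganism groups get a sampled culture volume and dry weight;
#' cell-line groups get a cell density (cells/L) and a measured mean cell
#' volume (pL), all with lognormal replicate jitter of CV `config$biomass_cv`.
#'
#' @param config A [study_config()].
#' @param seed RNG seed (defaults to `config$seed + 1`).
#' @return A data frame of biomass records, one per (group, replicate).
#' @export
simulate_biomass <- function(config, seed = config$seed + 1L) {
  groups <- config$groups
  nr <- config$n_replicates
  idx <- rep(seq_len(nrow(groups)), each = nr)
  rec <- groups[idx, , drop = FALSE]
  rec$sample_id <- paste0(rec$group_id, "_r", rep(seq_len(nr), nrow(groups)))
  withr::with_seed(seed, {
    n <- nrow(rec)
    jit_dw   <- rlnorm_mean1(n, config$biomass_cv)
    jit_dens <- rlnorm_mean1(n, config$biomass_cv)
    jit_vol  <- rlnorm_mean1(n, config$biomass_cv)
    micro <- rec$organism_kind == "microorganism"
    out <- data.frame(
      sample_id = rec$sample_id,
      group_id = rec$group_id,
      organism_kind = rec$organism_kind,
      sampled_volume_L = rec$sampled_volume_L,
      dry_weight_g = ifelse(micro,
                            rec$biomass_density_g_per_L *
                              rec$sampled_volume_L * jit_dw,
                            NA_real_),
      cell_density_per_L = ifelse(micro, NA_real_,
                                  rec$cell_density_per_L * jit_dens),
      cell_volume_pL = ifelse(micro, NA_real_,
                              rec$cell_volume_pL * jit_vol),
      extract_volume_L = rec$extract_volume_L,
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    out
  })
}

#' Instrument response parameters for the synthetic study
#'
#' Draws a per-metabolite detector sensitivity (peak area per mol/L) and the
#' constant internal-standard concentration present in every injected
#' solution. Labeled-extract internal standards vary between metabolites
#' (the extract contains each metabolite at its own level); matched
#' isotopologues and the labeled amino-acid mix are spiked at a fixed 5 uM.
#'
#' @param panel Metabolite panel.
#' @param seed RNG seed.
#' @return Data frame with columns `metabolite_id`, `sensitivity`, `is_conc_M`.
#' @export
instrument_response <- function(panel, seed) {
  panel <- validate_panel(panel)
  withr::with_seed(seed, {
    n <- nrow(panel)
    sens <- 10^(9 + stats::rnorm(n, 0, 0.4))
    is_conc <- ifelse(panel$is_kind == "labeled_extract",
                      10^(log10(2e-6) + stats::rnorm(n, 0, 0.3)),
                      5e-6)
    data.frame(metabolite_id = panel$metabolite_id,
               sensitivity = sens, is_conc_M = is_conc,
               stringsAsFactors = FALSE)
  })
}

# extract concentration implied by the ground truth for each biomass record
forward_extract_conc <- function(truth, biomass, panel) {
  grid <- expand.grid(metabolite_id = panel$metabolite_id,
                      sample_id = biomass$sample_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  b <- biomass[match(grid$sample_id, biomass$sample_id), ]
  grid$group_id <- b$group_id
  key_t <- paste(truth$group_id, truth$metabolite_id)
  c_int <- truth$conc_intracellular_M[
    match(paste(grid$group_id, grid$metabolite_id), key_t)]
  micro <- b$organism_kind == "microorganism"
  tcv <- ifelse(micro, b$dry_weight_g *
                  forward_specific_volume(b$group_id, attr(truth, "spec_vol")),
                b$cell_density_per_L * b$sampled_volume_L *
                  b$cell_volume_pL * 1e-12)
  grid$conc_extract_M <- c_int * tcv / b$extract_volume_L
  grid
}

# specific volumes keyed by group (stored on the truth object by
# simulate_study; falls back to the config lookup when called directly)
forward_specific_volume <- function(group_id, spec_vol_map) {
  unname(spec_vol_map[group_id])
}

#' Simulate raw peak areas for all study samples
#'
#' Applies the forward response model: both channels of a (sample,
#' metabolite) cell share a lognormal matrix factor (CV
#' `config$matrix_effect_sd`) and carry independent lognormal measurement
#' noise (CV `config$noise_cv`). Single-replicate multiplicative outliers
#' (factor 3-10) are injected at `config$outlier_rate` per (group,
#' metabolite), and cells go missing at `config$missing_rate`.
#'
#' @param truth Output of [generate_ground_truth()].
#' @param biomass Output of [simulate_biomass()].
#' @param prep Preparation factors, see [default_prep_factors()].
#' @param config The [study_config()].
#' @param panel Metabolite panel.
#' @param instrument Output of [instrument_response()]; defaults to a draw
#'   keyed on `config$seed + 10`.
#' @param seed RNG seed (defaults to `config$seed + 2`).
#' @return A long raw peak table (`sample_id`, `group_id`, `metabolite_id`,
#'   `channel`, `area`, `role`, `level_conc_M`) with the per-cell extract
#'   truth attached as attribute `extract_truth`.
#' @export
simulate_raw_peaks <- function(truth, biomass, prep, config, panel,
                               instrument = instrument_response(panel, config$seed + 10L),
                               seed = config$seed + 2L) {
  panel <- validate_panel(panel)
  prep <- validate_prep_factors(prep)
  spec_vol <- stats::setNames(config$groups$specific_volume_L_per_g,
                              config$groups$group_id)
  attr(truth, "spec_vol") <- spec_vol
  grid <- forward_extract_conc(truth, biomass, panel)

  pidx <- match(grid$metabolite_id, panel$metabolite_id)
  method <- panel$method[pidx]
  fac <- prep[match(method, prep$method), ]
  conc_analyzed <- grid$conc_extract_M * (1 - fac$spike_fraction) *
    fac$lyophilization_concentration_factor / fac$reconstitution_dilution_factor

  iidx <- match(grid$metabolite_id, instrument$metabolite_id)
  sens <- instrument$sensitivity[iidx]
  is_conc <- instrument$is_conc_M[iidx]

  withr::with_seed(seed, {
    n <- nrow(grid)
    mf <- rlnorm_mean1(n, config$matrix_effect_sd)
    eps_a <- rlnorm_mean1(n, config$noise_cv)
    eps_i <- rlnorm_mean1(n, config$noise_cv)
    analyte <- sens * conc_analyzed * mf * eps_a
    is_area <- sens * is_conc * mf * eps_i

    # single-replicate multiplicative outliers, at most one per
    # (group, metabolite)
    combo_key <- paste(grid$group_id, grid$metabolite_id)
    combos <- unique(combo_key)
    hit <- stats::runif(length(combos)) < config$outlier_rate
    pick <- ceiling(stats::runif(length(combos)) * config$n_replicates)
    fact <- stats::runif(length(combos), 3, 10)
    if (any(hit)) {
      rep_no <- as.integer(sub(".*_r", "", grid$sample_id))
      sel <- match(combo_key, combos)
      bump <- hit[sel] & rep_no == pick[sel]
      analyte[bump] <- analyte[bump] * fact[sel][bump]
    }

    keep <- stats::runif(n) >= config$missing_rate
  })

  raw <- data.frame(
    sample_id = rep(grid$sample_id, 2),
    group_id = rep(grid$group_id, 2),
    metabolite_id = rep(grid$metabolite_id, 2),
    channel = rep(c("analyte", "internal_standard"), each = nrow(grid)),
    area = c(analyte, is_area),
    role = "sample",
    level_conc_M = NA_real_,
    stringsAsFactors = FALSE
  )
  raw <- raw[rep(keep, 2), , drop = FALSE]
  rownames(raw) <- NULL
  attr(raw, "extract_truth") <- grid[, c("sample_id", "group_id",
                                         "metabolite_id", "conc_extract_M")]
  raw
}

#' Simulate a calibration series
#'
#' Same response model as the study samples but with matrix factor 1
#' (analytical standards in neat solution) and the internal standard spiked
#' identically. Includes the blank level.
#'
#' @inheritParams simulate_raw_peaks
#' @param seed RNG seed (defaults to `config$seed + 3`).
#' @return A long raw peak table with roles `calibrant` / `blank` and the
#'   nominal level concentration in `level_conc_M`.
#' @export
simulate_calibration <- function(config, panel,
                                 instrument = instrument_response(panel, config$seed + 10L),
                                 seed = config$seed + 3L) {
  panel <- validate_panel(panel)
  levels <- config$calibration_levels
  reps <- config$calibration_replicates
  grid <- expand.grid(metabolite_id = panel$metabolite_id,
                      rep = seq_len(reps),
                      level = seq_along(levels),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$level_conc_M <- levels[grid$level]
  iidx <- match(grid$metabolite_id, instrument$metabolite_id)
  sens <- instrument$sensitivity[iidx]
  is_conc <- instrument$is_conc_M[iidx]
  withr::with_seed(seed, {
    n <- nrow(grid)
    eps_a <- rlnorm_mean1(n, config$noise_cv)
    eps_i <- rlnorm_mean1(n, config$noise_cv)
    analyte <- sens * grid$level_conc_M * eps_a
    is_area <- sens * is_conc * eps_i
  })
  data.frame(
    sample_id = rep(sprintf("cal_L%02d_r%d", grid$level, grid$rep), 2),
    group_id = "calibration",
    metabolite_id = rep(grid$metabolite_id, 2),
    channel = rep(c("analyte", "internal_standard"), each = nrow(grid)),
    area = c(analyte, is_area),
    role = rep(ifelse(grid$level_conc_M == 0, "blank", "calibrant"), 2),
    level_conc_M = rep(grid$level_conc_M, 2),
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [generate_ground_truth()],
#' [simulate_biomass()], [simulate_calibration()], and
#' [simulate_raw_peaks()] under the seeds derived from `config$seed`.
#'
#' @param config A [study_config()].
#' @param panel A metabolite panel.
#' @return A `synthetic_study` list with elements `config`, `panel`,
#'   `truth`, `ec_truth`, `biomass`, `instrument`, `prep`, `calibration`,
#'   `raw`, and `extract_truth`.
#' @export
simulate_study <- function(config = study_config(), panel = default_panel()) {
  truth <- generate_ground_truth(config, panel)
  biomass <- simulate_biomass(config)
  instrument <- instrument_response(panel, config$seed + 10L)
  prep <- default_prep_factors()
  calibration <- simulate_calibration(config, panel, instrument)
  raw <- simulate_raw_peaks(truth, biomass, prep, config, panel, instrument)
  structure(list(config = config, panel = panel, truth = truth,
                 ec_truth = attr(truth, "ec_truth"), biomass = biomass,
                 instrument = instrument, prep = prep,
                 calibration = calibration, raw = raw,
                 extract_truth = attr(raw, "extract_truth")),
            class = "synthetic_study")
}
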