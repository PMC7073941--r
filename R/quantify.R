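# Raw peak areas -> extract concentrations -----------------------------------

#' Default sample-preparation factors per analytical method
#'
#' The internal-standard spike dilutes the extract by its volume fraction:
#' the labeled whole-cell extract is added at 20% v/v (capIC and the
#' organic-acid LC method) and the labeled amino-acid mix at 5% v/v.
#' Lyophilization/reconstitution factors default to 1, i.e. `extract_volume`
#' refers to the final reconstituted extract.
#'
#' @return Data frame with one row per method: `method`, `spike_fraction`,
#'   `lyophilization_concentration_factor`, `reconstitution_dilution_factor`.
#' @export
default_prep_factors <- function() {
  data.frame(
    method = c("capIC", "LC_organic_acid", "LC_amino_acid"),
    spike_fraction = c(0.20, 0.20, 0.05),
    lyophilization_concentration_factor = 1,
    reconstitution_dilution_factor = 1,
    stringsAsFactors = FALSE
  )
}

validate_prep_factors <- function(prep) {
  assert_columns(prep, c("method", "spike_fraction",
                         "lyophilization_concentration_factor",
                         "reconstitution_dilution_factor"), "prep factors")
  if (any(prep$spike_fraction < 0 | prep$spike_fraction >= 1)) {
    stop_mq("spike_fraction must lie in [0, 1)")
  }
  if (any(prep$lyophilization_concentration_factor <= 0) ||
      any(prep$reconstitution_dilution_factor <= 0)) {
    stop_mq("prep factors must be > 0")
  }
  prep
}

#' Isotope-dilution corrected response
#'
#' The analyte peak area divided by the peak area of its co-eluting
#' stable-isotope-labeled internal standard. Because ionization suppression
#' or enhancement acts multiplicatively and identically on both channels,
#' the ratio cancels the matrix effect.
#'
#' @param analyte_area,is_area Non-negative peak areas (vectorized).
#' @return The dimensionless response ratio; `NA` where the internal
#'   standard is absent or zero (flagged `missing_is` downstream).
#' @export
#' @examples
#' corrected_response(1000, 500)  # 2
corrected_response <- function(analyte_area, is_area) {
  if (any(analyte_area < 0, na.rm = TRUE)) stop_mq("analyte_area must be >= 0")
  ifelse(is.na(is_area) | is_area <= 0, NA_real_, analyte_area / is_area)
}

#' Fit a weighted linear calibration curve for one metabolite
#'
#' Least-squares fit of response versus nominal calibrant concentration with
#' 1/x weighting (each point weighted by the reciprocal of its nominal
#' concentration). The blank (x = 0), where 1/x is undefined, is excluded
#' from the fit. Lower/upper limits of quantification follow the
#' conventional back-calculation rule: a level is accepted when its mean
#' back-calculated concentration is within +/-20% of nominal (+/-25% at the
#' lowest level); LLOQ/ULOQ are the lowest/highest accepted levels.
#'
#' @param series Long raw peak table slice for a single metabolite with
#'   roles `calibrant`/`blank`, both channels, and `level_conc_M`.
#' @param weighting `"one_over_x"` (default) or `"none"`.
#' @param response `"ratio"` (isotope-dilution corrected, default) or
#'   `"analyte"` (raw analyte area; used by the ablation mode).
#' @param lloq_tol,lloq_tol_lowest Back-calculation acceptance tolerances.
#' @return A `calibration_model`: slope, intercept, `r_squared`, `lloq`,
#'   `uloq`, `n_levels_used`, and the per-level back-calculation table.
#' @export
fit_calibration <- function(series, weighting = c("one_over_x", "none"),
                            response = c("ratio", "analyte"),
                            lloq_tol = 0.20, lloq_tol_lowest = 0.25) {
  weighting <- match.arg(weighting)
  response <- match.arg(response)
  assert_columns(series, c("metabolite_id", "sample_id", "channel", "area",
                           "role", "level_conc_M"), "calibration series")
  met <- unique(series$metabolite_id)
  if (length(met) != 1L) {
    stop_mq("fit_calibration expects a single metabolite (got ",
            length(met), ")")
  }
  cal <- series[series$role %in% c("calibrant", "blank"), ]
  a <- cal[cal$channel == "analyte", ]
  i <- cal[cal$channel == "internal_standard", ]
  y <- if (response == "ratio") {
    corrected_response(a$area, i$area[match(a$sample_id, i$sample_id)])
  } else {
    a$area
  }
  x <- a$level_conc_M
  use <- x > 0 & !is.na(y)                      # blank excluded from the fit
  x <- x[use]; y <- y[use]
  if (length(unique(x)) < 3L) {
    stop_mq("unfit calibration model for ", met,
            ": fewer than 3 usable non-blank levels")
  }
  if (diff(range(y)) == 0) {
    stop_mq("degenerate calibration fit for ", met, ": all responses equal")
  }
  w <- if (weighting == "one_over_x") 1 / x else rep(1, length(x))
  fit <- stats::lm(y ~ x, weights = w)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope <= 0) {
    stop_mq("degenerate calibration fit for ", met, ": non-positive slope")
  }
  wmean <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * stats::residuals(fit)^2) / sum(w * (y - wmean)^2)

  lv <- sort(unique(x))
  ybar <- vapply(lv, function(l) mean(y[x == l]), numeric(1))
  back <- (ybar - intercept) / slope
  rel_err <- abs(back / lv - 1)
  tol <- ifelse(lv == min(lv), lloq_tol_lowest, lloq_tol)
  accepted <- rel_err <= tol
  back_calc <- data.frame(level_conc_M = lv, back_calc_M = back,
                          rel_err = rel_err, accepted = accepted)
  structure(list(metabolite_id = met, slope = slope, intercept = intercept,
                 weighting = weighting, response = response,
                 r_squared = r2,
                 lloq = if (any(accepted)) min(lv[accepted]) else Inf,
                 uloq = if (any(accepted)) max(lv[accepted]) else -Inf,
                 n_levels_used = length(lv), back_calc = back_calc),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> %s: y = %.4g + %.4g x (%s, %s), r2 = %.4f\n  LLOQ %.3g M, ULOQ %.3g M (%d levels)\n",
    x$metabolite_id, x$intercept, x$slope, x$weighting, x$response,
    x$r_squared, x$lloq, x$uloq, x$n_levels_used))
  invisible(x)
}

#' Fit calibration curves for every metabolite in a calibration table
#'
#' @param cal_table Long calibration peak table (roles `calibrant`/`blank`).
#' @param ... Passed to [fit_calibration()].
#' @return Named list of `calibration_model`s; metabolites whose fit fails
#'   are dropped with a warning (other metabolites are unaffected).
#' @export
fit_calibration_curves <- function(cal_table, ...) {
  mets <- unique(cal_table$metabolite_id)
  models <- stats::setNames(vector("list", length(mets)), mets)
  for (m in mets) {
    models[[m]] <- tryCatch(
      fit_calibration(cal_table[cal_table$metabolite_id == m, , drop = FALSE], ...),
      error = function(e) {
        warning("calibration failed for ", m, ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
  }
  models[!vapply(models, is.null, logical(1))]
}

#' Interpolate concentrations from a calibration model
#'
#' Inverts the calibration line: `conc = (ratio - intercept) / slope`.
#' Values below the LLOQ are flagged `below_lloq` (negative interpolations
#' clamp to 0), values above the ULOQ are flagged `above_uloq`.
#'
#' @param model A `calibration_model`.
#' @param ratio Corrected response(s) to invert (vectorized).
#' @return Data frame with columns `conc_M` and `flag`.
#' @export
interpolate_conc <- function(model, ratio) {
  stopifnot(inherits(model, "calibration_model"))
  conc <- (ratio - model$intercept) / model$slope
  flag <- rep("ok", length(conc))
  flag[which(conc < model$lloq)] <- "below_lloq"
  flag[which(conc > model$uloq)] <- "above_uloq"
  conc[which(conc < 0)] <- 0
  flag[is.na(conc)] <- NA_character_
  data.frame(conc_M = conc, flag = flag, stringsAsFactors = FALSE)
}

#' Correct a concentration for sample-preparation dilution/concentration
#'
#' Multiplies by the net dilution of the internal-standard spike,
#' `1 / (1 - spike_fraction)`, and by
#' `reconstitution_dilution_factor / lyophilization_concentration_factor`.
#'
#' @param conc Concentration(s) in the analyzed solution (mol/L).
#' @param spike_fraction Internal-standard spike volume fraction (v/v).
#' @param lyophilization_concentration_factor,reconstitution_dilution_factor
#'   Net concentration/dilution applied during processing (both > 0).
#' @return Concentration in the original extract (mol/L).
#' @export
#' @examples
#' apply_prep_factors(1e-5, spike_fraction = 0.2)  # 1.25e-5
apply_prep_factors <- function(conc, spike_fraction = 0,
                               lyophilization_concentration_factor = 1,
                               reconstitution_dilution_factor = 1) {
  if (any(spike_fraction < 0 | spike_fraction >= 1)) {
    stop_mq("spike_fraction must lie in [0, 1)")
  }
  if (any(lyophilization_concentration_factor <= 0) ||
      any(reconstitution_dilution_factor <= 0)) {
    stop_mq("prep factors must be > 0")
  }
  conc / (1 - spike_fraction) * reconstitution_dilution_factor /
    lyophilization_concentration_factor
}

#' Quantify a raw peak table into extract concentrations
#'
#' Applies, per (sample, metabolite): isotope-dilution correction
#' ([corrected_response()]), calibration interpolation
#' ([interpolate_conc()]), and preparation-factor correction
#' ([apply_prep_factors()]). Calibrant/blank rows are never emitted as
#' sample concentrations. Cells without an analyte record are flagged
#' `missing`; cells without a usable internal standard are flagged
#' `missing_is`; metabolites without a calibration model are flagged
#' `no_model`.
#'
#' @param raw Long raw peak table (role `sample` rows are quantified).
#' @param models Named list of `calibration_model`s from
#'   [fit_calibration_curves()].
#' @param prep Preparation factors table, see [default_prep_factors()].
#' @param panel Metabolite panel (maps each metabolite to its method).
#' @param is_correction Set `FALSE` to ablate isotope dilution: raw analyte
#'   areas are interpolated from analyte-response calibration models.
#' @return Extract concentration table: `sample_id`, `group_id`,
#'   `metabolite_id`, `conc_extract_M`, `flag`, `unit`.
#' @export
quantify_table <- function(raw, models, prep = default_prep_factors(),
                           panel = default_panel(), is_correction = TRUE) {
  prep <- validate_prep_factors(prep)
  panel <- validate_panel(panel)
  smp <- raw[raw$role == "sample", , drop = FALSE]
  if (!nrow(smp)) stop_mq("raw table contains no sample rows")
  samples <- unique(smp[, c("sample_id", "group_id")])
  mets <- unique(smp$metabolite_id)

  grid <- expand.grid(metabolite_id = mets, sample_id = samples$sample_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$group_id <- samples$group_id[match(grid$sample_id, samples$sample_id)]
  key <- function(d) paste(d$sample_id, d$metabolite_id)
  a <- smp[smp$channel == "analyte", ]
  i <- smp[smp$channel == "internal_standard", ]
  grid$analyte <- a$area[match(key(grid), key(a))]
  grid$is_area <- i$area[match(key(grid), key(i))]

  method <- panel$method[match(grid$metabolite_id, panel$metabolite_id)]
  fac <- prep[match(method, prep$method), ]

  conc <- rep(NA_real_, nrow(grid))
  flag <- rep(NA_character_, nrow(grid))
  for (m in mets) {
    sel <- grid$metabolite_id == m
    model <- models[[m]]
    if (is.null(model)) {
      flag[sel] <- "no_model"
      next
    }
    resp <- if (is_correction) {
      corrected_response(pmax(grid$analyte[sel], 0), grid$is_area[sel])
    } else {
      grid$analyte[sel]
    }
    ip <- interpolate_conc(model, resp)
    conc[sel] <- apply_prep_factors(
      ip$conc_M,
      spike_fraction = fac$spike_fraction[sel],
      lyophilization_concentration_factor =
        fac$lyophilization_concentration_factor[sel],
      reconstitution_dilution_factor =
        fac$reconstitution_dilution_factor[sel])
    flag[sel] <- ip$flag
  }
  no_analyte <- is.na(grid$analyte)
  flag[no_analyte] <- "missing"
  conc[no_analyte] <- NA_real_
  if (is_correction) {
    bad_is <- !no_analyte & !(flag %in% "no_model") &
      (is.na(grid$is_area) | grid$is_area <= 0)
    flag[bad_is] <- "missing_is"
    conc[bad_is] <- NA_real_
  }
  data.frame(sample_id = grid$sample_id, group_id = grid$group_id,
             metabolite_id = grid$metabolite_id,
             conc_extract_M = conc, flag = flag, unit = "mol_per_L",
             stringsAsFactors = FALSE)
}
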