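# Extract concentrations -> intracellular molar concentrations ---------------

#' Literature cell models (dry weight, volume, specific volume)
#'
#' The packaged table of single-cell dry weight (g/cell), cell volume
#' (L/cell), and specific cell volume (L/g) for the four microorganisms of
#' the default study panel. Values are stored as printed in the source
#' table; note the S. cerevisiae specific volume is the printed rounding
#' (2.66e-3) rather than the exact quotient (2.667e-3).
#'
#' @return Data frame with columns `organism_id`, `organism`, `cell_dw_g`,
#'   `cell_volume_L`, `specific_volume_L_per_g`, `volume_source`.
#' @export
cell_models <- function() {
  read_pkg_csv("cell_models.csv")
}

#' Specific cell volume
#'
#' Cell volume per gram of cell dry weight, used to convert per-dry-weight
#' metabolite amounts into intracellular molarity.
#'
#' @param cell_dw Cell dry weight in g/cell (> 0, vectorized).
#' @param cell_volume Cell volume in L/cell (> 0, vectorized).
#' @return Specific cell volume in L/g.
#' @export
#' @examples
#' specific_cell_volume(2.2e-13, 9e-16)  # 4.09e-3 L/g
specific_cell_volume <- function(cell_dw, cell_volume) {
  if (any(!is.finite(cell_dw)) || any(cell_dw <= 0)) {
    stop_mq("cell_dw must be > 0")
  }
  if (any(!is.finite(cell_volume)) || any(cell_volume <= 0)) {
    stop_mq("cell_volume must be > 0")
  }
  cell_volume / cell_dw
}

#' Half-parallelepiped cell volume
#'
#' Geometric cell-volume model for fusiform cells such as the diatom
#' P. tricornutum: length x width x height / 2, converted from cubic
#' micrometers to liters (1 um^3 = 1e-15 L).
#'
#' @param length_um,width_um,height_um Linear dimensions in micrometers (> 0).
#' @param unit `"L"` (default) or `"um3"`. Rounding a volume to significant
#'   figures is best done on the um^3 value, where the arithmetic is exact
#'   in floating point (e.g. 122.5 um^3), before converting to liters.
#' @return Cell volume in liters (or um^3).
#' @export
#' @examples
#' half_parallelepiped_volume(20, 3.5, 3.5)  # 1.225e-13 L
half_parallelepiped_volume <- function(length_um, width_um, height_um,
                                       unit = c("L", "um3")) {
  unit <- match.arg(unit)
  dims <- c(length_um, width_um, height_um)
  if (any(!is.finite(dims)) || any(dims <= 0)) {
    stop_mq("all dimensions must be > 0")
  }
  v <- length_um * width_um * height_um / 2
  if (unit == "L") v * 1e-15 else v
}

#' Metabolite amount per unit biomass
#'
#' Converts an extract concentration to mol per g dry weight
#' (microorganisms) or mol per cell (cell lines), using the biomass record
#' of the sample.
#'
#' @param conc_extract Extract concentration in mol/L (vectorized).
#' @param extract_volume Extract volume in L.
#' @param biomass A single biomass record (one-row data frame or list) with
#'   `organism_kind` and either `dry_weight_g` (microorganism) or
#'   `cell_density_per_L` + `sampled_volume_L` (cell lines).
#' @return Amount per biomass (mol/g DW or mol/cell).
#' @export
per_biomass_amount <- function(conc_extract, extract_volume, biomass) {
  assert_scalar_num(extract_volume, "extract_volume", positive = TRUE)
  amount <- conc_extract * extract_volume
  kind <- biomass$organism_kind
  if (identical(kind, "microorganism")) {
    dw <- biomass$dry_weight_g
    if (is.null(dw) || is.na(dw) || dw <= 0) {
      stop_mq("microorganism biomass record lacks a positive `dry_weight_g`")
    }
    amount / dw
  } else if (kind %in% c("suspension_cell_line", "adherent_cell_line")) {
    dens <- biomass$cell_density_per_L
    vol <- biomass$sampled_volume_L
    if (is.null(dens) || is.na(dens) || dens <= 0) {
      stop_mq("cell-line biomass record lacks a positive `cell_density_per_L`")
    }
    if (is.null(vol) || is.na(vol) || vol <= 0) {
      stop_mq("cell-line biomass record lacks a positive `sampled_volume_L`")
    }
    amount / (dens * vol)
  } else {
    stop_mq("unknown organism_kind: ", kind)
  }
}

#' Intracellular molar concentration
#'
#' Divides a per-biomass amount by the matching cell-volume quantity:
#' mol/g DW by the specific cell volume (L/g), or mol/cell by the measured
#' cell volume (L/cell). Exactly one of the two volume arguments must be
#' supplied.
#'
#' @param per_biomass Amount per biomass (mol/g or mol/cell, vectorized).
#' @param specific_volume_L_per_g Specific cell volume in L/g
#'   (microorganism path).
#' @param cell_volume_L Measured cell volume in L/cell (cell-line path).
#' @return Intracellular concentration in mol/L.
#' @export
#' @examples
#' intracellular_concentration(1e-15, cell_volume_L = 1e-12)  # 1e-3 M
intracellular_concentration <- function(per_biomass,
                                        specific_volume_L_per_g = NULL,
                                        cell_volume_L = NULL) {
  has_sv <- !is.null(specific_volume_L_per_g)
  has_cv <- !is.null(cell_volume_L)
  if (has_sv == has_cv) {
    stop_mq("supply exactly one of `specific_volume_L_per_g` (mol/g path) ",
            "or `cell_volume_L` (mol/cell path)")
  }
  div <- if (has_sv) specific_volume_L_per_g else cell_volume_L
  if (any(!is.finite(div)) || any(div <= 0)) {
    stop_mq("cell volume quantities must be > 0")
  }
  per_biomass / div
}

#' Normalize an extract concentration table to intracellular concentrations
#'
#' Joins the extract table with per-sample biomass records and applies
#' [per_biomass_amount()] / [intracellular_concentration()] row-wise.
#' Microorganism samples use the specific cell volume of their group from
#' `group_models`; cell-line samples use their own measured cell volume.
#'
#' @param extract_tab Output of [quantify_table()].
#' @param biomass Biomass records (one row per sample), see
#'   [simulate_biomass()] for the schema.
#' @param group_models Data frame mapping microorganism `group_id` to
#'   `specific_volume_L_per_g`.
#' @return Intracellular concentration table: `group_id`, `sample_id`,
#'   `metabolite_id`, `per_biomass`, `per_biomass_unit`,
#'   `conc_intracellular_M`, `flag`.
#' @export
normalize_intracellular <- function(extract_tab, biomass, group_models = NULL) {
  assert_columns(extract_tab, c("sample_id", "group_id", "metabolite_id",
                                "conc_extract_M", "flag"), "extract table")
  assert_columns(biomass, c("sample_id", "organism_kind", "sampled_volume_L",
                            "extract_volume_L"), "biomass table")
  b <- biomass[match(extract_tab$sample_id, biomass$sample_id), ]
  if (anyNA(b$sample_id)) {
    stop_mq("biomass records missing for sample(s): ",
            paste(unique(extract_tab$sample_id[is.na(b$sample_id)]),
                  collapse = ", "))
  }
  micro <- b$organism_kind == "microorganism"
  if (any(micro)) {
    if (is.null(group_models)) {
      stop_mq("`group_models` (group_id -> specific_volume_L_per_g) is ",
              "required for microorganism groups")
    }
    assert_columns(group_models, c("group_id", "specific_volume_L_per_g"),
                   "group_models")
    sv <- group_models$specific_volume_L_per_g[
      match(extract_tab$group_id, group_models$group_id)]
    if (any(micro & (is.na(sv) | sv <= 0))) {
      stop_mq("missing specific volume for microorganism group(s): ",
              paste(unique(extract_tab$group_id[micro & is.na(sv)]),
                    collapse = ", "))
    }
  } else {
    sv <- rep(NA_real_, nrow(extract_tab))
  }
  if (any(micro & (is.na(b$dry_weight_g) | b$dry_weight_g <= 0))) {
    stop_mq("microorganism sample(s) lack a positive `dry_weight_g`")
  }
  cl <- !micro
  if (any(cl & (is.na(b$cell_density_per_L) | is.na(b$cell_volume_pL)))) {
    stop_mq("cell-line sample(s) lack `cell_density_per_L` or `cell_volume_pL`")
  }

  amount <- extract_tab$conc_extract_M * b$extract_volume_L
  per_biomass <- ifelse(micro,
                        amount / b$dry_weight_g,
                        amount / (b$cell_density_per_L * b$sampled_volume_L))
  conc_int <- ifelse(micro,
                     per_biomass / sv,
                     per_biomass / (b$cell_volume_pL * 1e-12))
  data.frame(group_id = extract_tab$group_id,
             sample_id = extract_tab$sample_id,
             metabolite_id = extract_tab$metabolite_id,
             per_biomass = per_biomass,
             per_biomass_unit = ifelse(micro, "mol_per_g_DW", "mol_per_cell"),
             conc_intracellular_M = conc_int,
             flag = extract_tab$flag,
             stringsAsFactors = FALSE)
}
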