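# Metabolite panel registry --------------------------------------------------

PANEL_CLASSES <- c("amino_acid", "glycolysis", "PPP", "TCA",
                   "nucleoside_phosphate", "deoxynucleoside_phosphate",
                   "organic_acid_other")
PANEL_METHODS <- c("capIC", "LC_organic_acid", "LC_amino_acid")
PANEL_IS_KINDS <- c("matched_isotopologue", "labeled_extract",
                    "labeled_amino_acid_mix")
PANEL_COLUMNS <- c("metabolite_id", "name", "abbreviation", "met_class",
                   "method", "is_kind", "pathway_position")

#' The packaged central-carbon metabolite panel
#'
#' Returns the registry of the 68 panel metabolites: the 20 proteinogenic
#' amino acids, 12 ribonucleoside mono-/di-/triphosphates, 12
#' deoxyribonucleoside mono-/di-/triphosphates, and 24 intermediates of
#' glycolysis, the pentose phosphate pathway, the TCA cycle, and overflow /
#' anaplerotic organic acids. Each metabolite carries its class, the
#' analytical method quantifying it (capillary ion chromatography or one of
#' two LC-MS/MS methods), and the kind of stable-isotope-labeled internal
#' standard used for its isotope-dilution correction.
#'
#' @return A `metabolite_panel`: a data frame with columns `metabolite_id`,
#'   `name`, `abbreviation`, `met_class`, `method`, `is_kind`,
#'   `pathway_position`, plus attribute `version`.
#' @export
#' @examples
#' panel <- default_panel()
#' nrow(panel)                       # 68
#' table(panel$met_class)
default_panel <- function() {
  validate_panel(read_pkg_csv("metabolite_panel.csv"), version = "1")
}

#' Load a metabolite panel from a CSV file
#'
#' @param path Path to a CSV file with header
#'   `metabolite_id,name,abbreviation,met_class,method,is_kind,pathway_position`.
#' @return A validated `metabolite_panel` data frame.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop_mq(sprintf("panel file not found: %s", path))
  validate_panel(utils::read.csv(path, stringsAsFactors = FALSE),
                 version = basename(path))
}

#' Write a metabolite panel to CSV
#'
#' @param panel A `metabolite_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  panel <- validate_panel(panel)
  utils::write.csv(panel[, PANEL_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Validate a metabolite panel
#'
#' Enforces the registry invariants: required columns present, unique
#' metabolite ids, and class / method / internal-standard values drawn from
#' the recognised vocabularies.
#'
#' @param panel A data frame of panel rows.
#' @param version Optional version tag stored as an attribute.
#' @return The panel, classed as `metabolite_panel`.
#' @export
validate_panel <- function(panel, version = NULL) {
  assert_columns(panel, setdiff(PANEL_COLUMNS, "pathway_position"), "panel")
  if (!"pathway_position" %in% names(panel)) panel$pathway_position <- NA_character_
  dup <- unique(panel$metabolite_id[duplicated(panel$metabolite_id)])
  if (length(dup)) {
    stop_mq("duplicated metabolite_id in panel: ", paste(dup, collapse = ", "))
  }
  bad_class <- setdiff(unique(panel$met_class), PANEL_CLASSES)
  if (length(bad_class)) {
    stop_mq("unknown met_class value(s): ", paste(bad_class, collapse = ", "))
  }
  bad_method <- setdiff(unique(panel$method), PANEL_METHODS)
  if (length(bad_method)) {
    stop_mq("unknown method value(s): ", paste(bad_method, collapse = ", "))
  }
  bad_is <- setdiff(unique(panel$is_kind), PANEL_IS_KINDS)
  if (length(bad_is)) {
    stop_mq("unknown is_kind value(s): ", paste(bad_is, collapse = ", "))
  }
  class(panel) <- c("metabolite_panel", "data.frame")
  if (!is.null(version)) attr(panel, "version") <- version
  panel
}

#' @export
print.metabolite_panel <- function(x, ...) {
  cat(sprintf("<metabolite_panel> %d metabolites\n", nrow(x)))
  print(table(class = x$met_class))
  invisible(x)
}
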