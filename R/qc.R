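# Quality control: adenylate energy charge and Dixon's Q outlier test --------

#' Adenylate energy charge
#'
#' Atkinson's energy charge of the adenylate pool,
#' `(ATP + 0.5 * ADP) / (ATP + ADP + AMP)`, a readout of the energy status
#' of the cell and of the quality of sampling/quenching: physiologically
#' intact cells sit around 0.7-0.95.
#'
#' @param amp,adp,atp Intracellular concentrations (mol/L, >= 0, vectorized).
#' @return Energy charge in `[0, 1]`.
#' @export
#' @examples
#' energy_charge(1, 1, 1)  # 0.5
energy_charge <- function(amp, adp, atp) {
  if (any(c(amp, adp, atp) < 0, na.rm = TRUE)) {
    stop_mq("adenylate concentrations must be >= 0")
  }
  total <- amp + adp + atp
  if (any(total <= 0, na.rm = TRUE)) {
    stop_mq("energy charge undefined: AMP + ADP + ATP must be > 0")
  }
  (atp + 0.5 * adp) / total
}

#' Physiological-range check for the energy charge
#'
#' @param ec Energy charge value(s) in `[0, 1]`.
#' @param lo,hi Inclusive physiological band (default 0.7-0.95).
#' @return Logical: `TRUE` iff `lo <= ec <= hi`.
#' @export
ec_within_physiological <- function(ec, lo = 0.7, hi = 0.95) {
  if (any(ec < 0 | ec > 1, na.rm = TRUE)) stop_mq("ec must lie in [0, 1]")
  ec >= lo & ec <= hi
}

#' Two-tailed critical values for Dixon's Q (r10) test
#'
#' Reads the packaged Rorabacher (1991) two-tailed critical-value table
#' (fixture `dixon_q_critical_v1.csv`) for sample sizes 3-10 at confidence
#' levels 90/95/99%.
#'
#' @param n Sample size(s), 3 <= n <= 10.
#' @param alpha Significance level: 0.10, 0.05 (default), or 0.01.
#' @return Critical value(s) of Q.
#' @export
dixon_q_critical <- function(n, alpha = 0.05) {
  tab <- .metquant_cache$dixon
  if (is.null(tab)) {
    tab <- read_pkg_csv("dixon_q_critical_v1.csv")
    .metquant_cache$dixon <- tab
  }
  col <- c("0.1" = "cl90", "0.05" = "cl95", "0.01" = "cl99")[as.character(alpha)]
  if (is.na(col)) stop_mq("alpha must be one of 0.10, 0.05, 0.01")
  if (any(n < 3 | n > 10)) stop_mq("Dixon's Q is tabulated for 3 <= n <= 10")
  tab[[col]][match(n, tab$n)]
}

#' Dixon's Q outlier test
#'
#' Classic r10 ("Q") single-outlier test for small samples: the gap between
#' the suspect value and its nearest neighbour divided by the range, tested
#' at the more extreme end against the two-tailed critical value. At most
#' one value is rejected (no iteration).
#'
#' @param values Numeric vector, 3 <= length <= 10.
#' @param alpha Significance level (see [dixon_q_critical()]).
#' @return List with `outlier_index` (index into `values`, or `NA` if none
#'   rejected), `q` (the statistic), `q_crit`, and `tested` (`FALSE` when
#'   the range is zero and no test is possible).
#' @export
#' @examples
#' dixon_q(c(0.10, 0.15, 0.16, 0.17, 0.95))  # rejects 0.95
dixon_q <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3) stop_mq("Dixon's Q requires n >= 3")
  if (n > 10) stop_mq("Dixon's Q (r10) is tabulated only up to n = 10")
  if (anyNA(values)) stop_mq("values must not contain NA")
  q_crit <- dixon_q_critical(n, alpha)
  rng <- diff(range(values))
  if (rng == 0) {
    return(list(outlier_index = NA_integer_, q = NA_real_, q_crit = q_crit,
                tested = FALSE))
  }
  s <- sort(values)
  gap_low <- s[2] - s[1]
  gap_high <- s[n] - s[n - 1]
  # test the more extreme end; ties go to the high end
  if (gap_high >= gap_low) {
    q <- gap_high / rng
    idx <- which.max(values)
  } else {
    q <- gap_low / rng
    idx <- which.min(values)
  }
  list(outlier_index = if (q > q_crit) idx else NA_integer_,
       q = q, q_crit = q_crit, tested = TRUE)
}

#' Reject single-replicate outliers per (group, metabolite)
#'
#' Runs [dixon_q()] on each (group, metabolite) replicate vector of
#' intracellular concentrations (quantified cells only, 3-10 replicates).
#' Rejected replicates have their flag set to `outlier` and are treated as
#' missing downstream.
#'
#' @param intra_tab Output of [normalize_intracellular()].
#' @param alpha Significance level for Dixon's Q.
#' @return List with `table` (the flag-updated table) and `ledger` (one row
#'   per tested (group, metabolite): `q`, `q_crit`, `outlier_sample`).
#' @export
reject_outliers <- function(intra_tab, alpha = 0.05) {
  assert_columns(intra_tab, c("group_id", "sample_id", "metabolite_id",
                              "conc_intracellular_M", "flag"),
                 "intracellular table")
  ok <- which(intra_tab$flag == "ok")
  keys <- paste(intra_tab$group_id[ok], intra_tab$metabolite_id[ok], sep = "\r")
  ledger <- list()
  for (k in unique(keys)) {
    rows <- ok[keys == k]
    vals <- intra_tab$conc_intracellular_M[rows]
    if (length(vals) < 3 || length(vals) > 10) next
    res <- dixon_q(vals, alpha)
    if (!res$tested) next
    out_sample <- if (!is.na(res$outlier_index)) {
      intra_tab$sample_id[rows[res$outlier_index]]
    } else NA_character_
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    ledger[[length(ledger) + 1L]] <- data.frame(
      group_id = parts[1], metabolite_id = parts[2],
      q_statistic = res$q, q_critical = res$q_crit,
      outlier_sample = out_sample, stringsAsFactors = FALSE)
    if (!is.na(res$outlier_index)) {
      intra_tab$flag[rows[res$outlier_index]] <- "outlier"
    }
  }
  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(group_id = character(), metabolite_id = character(),
               q_statistic = numeric(), q_critical = numeric(),
               outlier_sample = character(), stringsAsFactors = FALSE)
  list(table = intra_tab, ledger = ledger)
}

#' Quality-control report for an intracellular concentration table
#'
#' Rejects per-(group, metabolite) outliers with Dixon's Q, then computes
#' each group's adenylate energy charge per replicate (requiring quantified
#' AMP, ADP, and ATP in that replicate), its mean and SD across replicates,
#' and the physiological-range flag. Groups missing an adenylate get an
#' unavailable (NA) energy charge rather than aborting the report.
#'
#' @param intra_tab Output of [normalize_intracellular()].
#' @param alpha Dixon's Q significance level.
#' @param ec_limits Inclusive physiological energy-charge band.
#' @param reject Set `FALSE` to skip outlier rejection.
#' @return A `qc_report` list: `ec` (per-group mean/SD/in-range),
#'   `outliers` (Dixon ledger), `missingness` (per-group fraction of
#'   non-quantified cells), and `table` (the flag-updated table).
#' @export
qc_report <- function(intra_tab, alpha = 0.05, ec_limits = c(0.7, 0.95),
                      reject = TRUE) {
  if (reject) {
    rej <- reject_outliers(intra_tab, alpha)
    intra_tab <- rej$table
    ledger <- rej$ledger
  } else {
    ledger <- NULL
  }
  groups <- unique(intra_tab$group_id)
  ec_rows <- lapply(groups, function(g) {
    sub <- intra_tab[intra_tab$group_id == g & intra_tab$flag == "ok" &
                       intra_tab$metabolite_id %in% c("AMP", "ADP", "ATP"), ]
    wide <- stats::reshape(sub[, c("sample_id", "metabolite_id",
                                   "conc_intracellular_M")],
                           idvar = "sample_id", timevar = "metabolite_id",
                           direction = "wide")
    need <- paste0("conc_intracellular_M.", c("AMP", "ADP", "ATP"))
    if (!all(need %in% names(wide))) {
      return(data.frame(group_id = g, n_replicates = 0L, ec_mean = NA_real_,
                        ec_sd = NA_real_, ec_in_range = NA,
                        stringsAsFactors = FALSE))
    }
    cc <- stats::complete.cases(wide[, need])
    wide <- wide[cc, , drop = FALSE]
    if (!nrow(wide)) {
      return(data.frame(group_id = g, n_replicates = 0L, ec_mean = NA_real_,
                        ec_sd = NA_real_, ec_in_range = NA,
                        stringsAsFactors = FALSE))
    }
    ec <- energy_charge(wide[[need[1]]], wide[[need[2]]], wide[[need[3]]])
    data.frame(group_id = g, n_replicates = nrow(wide),
               ec_mean = mean(ec),
               ec_sd = if (length(ec) > 1) stats::sd(ec) else NA_real_,
               ec_in_range = ec_within_physiological(mean(ec), ec_limits[1],
                                                     ec_limits[2]),
               stringsAsFactors = FALSE)
  })
  miss <- vapply(groups, function(g) {
    sub <- intra_tab[intra_tab$group_id == g, ]
    mean(sub$flag != "ok")
  }, numeric(1))
  structure(list(ec = do.call(rbind, ec_rows),
                 outliers = ledger,
                 missingness = data.frame(group_id = groups,
                                          frac_not_quantified = unname(miss),
                                          stringsAsFactors = FALSE),
                 table = intra_tab),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\nPer-group adenylate energy charge:\n")
  print(x$ec, row.names = FALSE)
  n_rej <- if (is.null(x$outliers)) 0L else sum(!is.na(x$outliers$outlier_sample))
  cat(sprintf("Dixon's Q rejections: %d\n", n_rej))
  invisible(x)
}
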