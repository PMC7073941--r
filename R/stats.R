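# Downstream statistics: filtering, imputation, scaling, PCA, tests ----------

#' Build a samples x metabolites concentration matrix
#'
#' Cells whose flag is not `ok` (missing, missing internal standard, out of
#' quantification range, rejected outliers) become `NA`.
#'
#' @param intra_tab Intracellular concentration table.
#' @return Numeric matrix (rows = samples, columns = metabolites) with the
#'   sample-to-group mapping in attribute `groups`.
#' @export
concentration_matrix <- function(intra_tab) {
  assert_columns(intra_tab, c("sample_id", "group_id", "metabolite_id",
                              "conc_intracellular_M", "flag"),
                 "intracellular table")
  samples <- unique(intra_tab$sample_id)
  mets <- unique(intra_tab$metabolite_id)
  m <- matrix(NA_real_, nrow = length(samples), ncol = length(mets),
              dimnames = list(samples, mets))
  ok <- intra_tab$flag == "ok"
  m[cbind(match(intra_tab$sample_id[ok], samples),
          match(intra_tab$metabolite_id[ok], mets))] <-
    intra_tab$conc_intracellular_M[ok]
  groups <- intra_tab$group_id[match(samples, intra_tab$sample_id)]
  attr(m, "groups") <- stats::setNames(groups, samples)
  m
}

sample_groups <- function(mat) {
  g <- attr(mat, "groups")
  if (is.null(g)) stop_mq("matrix lacks the `groups` attribute")
  g[rownames(mat)]
}

keep_columns <- function(mat, keep) {
  out <- mat[, keep, drop = FALSE]
  attr(out, "groups") <- attr(mat, "groups")
  out
}

#' Prevalence filter
#'
#' Retains metabolites quantified in strictly more than `threshold` of the
#' biological groups (default > 50%). A group counts as covered when at
#' least one of its replicates has a quantified value. `unit = "samples"`
#' counts individual samples instead of groups.
#'
#' @param mat Concentration matrix from [concentration_matrix()].
#' @param threshold Fraction that must be strictly exceeded (default 0.5).
#' @param unit Count prevalence over `"groups"` (default) or `"samples"`.
#' @return The filtered matrix.
#' @export
prevalence_filter <- function(mat, threshold = 0.5,
                              unit = c("groups", "samples")) {
  unit <- match.arg(unit)
  if (!nrow(mat) || !ncol(mat)) stop_mq("empty concentration matrix")
  frac <- if (unit == "groups") {
    g <- sample_groups(mat)
    apply(mat, 2, function(col) {
      mean(vapply(split(col, g), function(v) any(!is.na(v)), logical(1)))
    })
  } else {
    colMeans(!is.na(mat))
  }
  keep_columns(mat, frac > threshold)
}

#' Minimum-value imputation
#'
#' Replaces each missing cell by the minimum measured value of that
#' metabolite across all samples.
#'
#' @param mat Concentration matrix.
#' @return The matrix with no missing values.
#' @export
impute_min <- function(mat) {
  empty <- colSums(!is.na(mat)) == 0
  if (any(empty)) {
    stop_mq("column(s) with no measured value cannot be imputed: ",
            paste(colnames(mat)[empty], collapse = ", "))
  }
  for (j in seq_len(ncol(mat))) {
    na <- is.na(mat[, j])
    if (any(na)) mat[na, j] <- min(mat[, j], na.rm = TRUE)
  }
  mat
}

#' Auto-scaling (unit variance scaling)
#'
#' Per metabolite column: subtract the mean and divide by the sample
#' standard deviation (n - 1), the standard pretreatment before PCA in
#' metabolomics.
#'
#' @param mat Complete (post-imputation) concentration matrix.
#' @return The scaled, dimensionless matrix.
#' @export
autoscale <- function(mat) {
  if (anyNA(mat)) stop_mq("autoscale requires a complete matrix; impute first")
  sds <- apply(mat, 2, stats::sd)
  zero <- sds == 0
  if (any(zero)) {
    stop_mq("zero-variance column(s): ",
            paste(colnames(mat)[zero], collapse = ", "))
  }
  out <- scale(mat, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "groups") <- attr(mat, "groups")
  out
}

#' Principal component analysis with per-group confidence ellipses
#'
#' Eigen-decomposition of the sample covariance of the (already autoscaled)
#' matrix via [stats::prcomp()]. The sign convention is fixed by making the
#' largest-magnitude loading of each component positive. Per-group 95%
#' confidence ellipses are derived from the 2-D score covariance scaled by
#' the chi-square(2 df) quantile, or by the small-sample Hotelling-T2
#' scaling.
#'
#' @param mat Autoscaled complete matrix.
#' @param n_components Number of components to return (default 2).
#' @param conf_level Confidence level of the ellipses (default 0.95).
#' @param ellipse `"chisq"` (default) or `"hotelling"`.
#' @return A `pca_result` list: `scores`, `loadings`,
#'   `explained_variance_fraction` (all components), and `ellipses`.
#' @export
run_pca <- function(mat, n_components = 2, conf_level = 0.95,
                    ellipse = c("chisq", "hotelling")) {
  ellipse <- match.arg(ellipse)
  if (nrow(mat) < 2) stop_mq("PCA requires at least 2 samples")
  if (anyNA(mat)) stop_mq("PCA requires a complete matrix")
  max_rank <- min(nrow(mat) - 1L, ncol(mat))
  if (n_components > max_rank) {
    stop_mq("n_components must be <= min(samples - 1, metabolites) = ",
            max_rank)
  }
  pc <- stats::prcomp(mat, center = FALSE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  for (k in seq_len(ncol(pc$rotation))) {
    if (pc$rotation[which.max(abs(pc$rotation[, k])), k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  loadings <- pc$rotation[, seq_len(n_components), drop = FALSE]
  groups <- sample_groups(mat)
  ell <- NULL
  if (n_components >= 2) {
    ell <- do.call(rbind, lapply(unique(groups), function(g) {
      xy <- scores[groups == g, 1:2, drop = FALSE]
      n <- nrow(xy)
      if (n < 3) {
        return(data.frame(group_id = g, n = n, center_x = mean(xy[, 1]),
                          center_y = mean(xy[, 2]), semi_axis_1 = NA_real_,
                          semi_axis_2 = NA_real_, angle_rad = NA_real_,
                          stringsAsFactors = FALSE))
      }
      cv <- stats::cov(xy)
      scale2 <- if (ellipse == "chisq") {
        stats::qchisq(conf_level, df = 2)
      } else {
        2 * (n - 1) / (n - 2) * stats::qf(conf_level, 2, n - 2)
      }
      eig <- eigen(cv, symmetric = TRUE)
      data.frame(group_id = g, n = n,
                 center_x = mean(xy[, 1]), center_y = mean(xy[, 2]),
                 semi_axis_1 = sqrt(pmax(eig$values[1], 0) * scale2),
                 semi_axis_2 = sqrt(pmax(eig$values[2], 0) * scale2),
                 angle_rad = atan2(eig$vectors[2, 1], eig$vectors[1, 1]),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_fraction = expl,
                 groups = groups, ellipses = ell,
                 full = pc),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components; explained: %s\n",
              ncol(x$scores),
              paste(sprintf("%.1f%%",
                            100 * x$explained_variance_fraction[
                              seq_len(ncol(x$scores))]),
                    collapse = ", ")))
  invisible(x)
}

#' Pooled-variance two-sample t-tests with Benjamini-Hochberg FDR
#'
#' Per metabolite: two-tailed equal-variance (pooled) t-test between two
#' groups, Benjamini-Hochberg step-up adjusted q-values, and the log2 fold
#' change of the group means. A metabolite is significant when its q-value
#' is at most `alpha`.
#'
#' @param mat Concentration matrix (imputed; unscaled concentrations so that
#'   the means and fold changes are molar).
#' @param group_a,group_b Group identifiers to compare (a vs b).
#' @param alpha FDR level (default 0.05).
#' @return Data frame: `metabolite_id`, `mean_a`, `mean_b`, `log2_fc`,
#'   `t_statistic`, `df`, `p_value`, `q_value`, `significant`.
#' @export
ttest_fdr <- function(mat, group_a, group_b, alpha = 0.05) {
  groups <- sample_groups(mat)
  xa <- mat[groups == group_a, , drop = FALSE]
  xb <- mat[groups == group_b, , drop = FALSE]
  na <- nrow(xa); nb <- nrow(xb)
  if (na < 2 || nb < 2) {
    stop_mq("each group needs >= 2 replicates (got ", na, " and ", nb, ")")
  }
  res <- lapply(colnames(mat), function(m) {
    a <- xa[, m]; b <- xb[, m]
    ma <- mean(a); mb <- mean(b)
    sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
      (na + nb - 2)
    if (sp2 == 0) {
      tt <- if (ma == mb) 0 else sign(ma - mb) * Inf
    } else {
      tt <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    }
    df <- na + nb - 2
    p <- 2 * stats::pt(-abs(tt), df)
    data.frame(metabolite_id = m, mean_a = ma, mean_b = mb,
               log2_fc = log2_fold_change(ma, mb),
               t_statistic = tt, df = df, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value <= alpha
  rownames(out) <- NULL
  out
}

#' Log2 fold change of two means
#'
#' @param mean_a,mean_b Positive group means (vectorized).
#' @return `log2(mean_a / mean_b)`; `NA` where either mean is not positive.
#' @export
#' @examples
#' log2_fold_change(4, 1)  # 2
log2_fold_change <- function(mean_a, mean_b) {
  ifelse(is.na(mean_a) | is.na(mean_b) | mean_a <= 0 | mean_b <= 0,
         NA_real_, log2(mean_a / mean_b))
}

#' Per-group mean intracellular concentrations
#'
#' Means over quantified (`flag == "ok"`) replicates.
#'
#' @param intra_tab Intracellular concentration table.
#' @return Data frame: `group_id`, `metabolite_id`, `mean_conc_M`, `n`.
#' @export
group_means <- function(intra_tab) {
  ok <- intra_tab[intra_tab$flag == "ok", ]
  agg <- stats::aggregate(conc_intracellular_M ~ group_id + metabolite_id,
                          data = ok, FUN = mean)
  cnt <- stats::aggregate(conc_intracellular_M ~ group_id + metabolite_id,
                          data = ok, FUN = length)
  names(agg)[3] <- "mean_conc_M"
  agg$n <- cnt$conc_intracellular_M
  agg
}

#' Metabolite-class composition per group
#'
#' Percent contribution of each metabolite class to the total measured
#' metabolite level of a group; rows of one group sum to 100.
#'
#' @param means Output of [group_means()] (or any data frame with
#'   `group_id`, `metabolite_id`, `mean_conc_M`).
#' @param panel Metabolite panel supplying the class of each metabolite.
#' @return Data frame: `group_id`, `met_class`, `percent`.
#' @export
class_composition <- function(means, panel = default_panel()) {
  assert_columns(means, c("group_id", "metabolite_id", "mean_conc_M"),
                 "means table")
  means$met_class <- panel$met_class[match(means$metabolite_id,
                                           panel$metabolite_id)]
  if (anyNA(means$met_class)) {
    stop_mq("metabolite(s) not in panel: ",
            paste(unique(means$metabolite_id[is.na(means$met_class)]),
                  collapse = ", "))
  }
  out <- do.call(rbind, lapply(split(means, means$group_id), function(d) {
    total <- sum(d$mean_conc_M)
    if (total <= 0) stop_mq("zero total concentration in group ",
                            d$group_id[1])
    cls <- tapply(d$mean_conc_M, d$met_class, sum)
    data.frame(group_id = d$group_id[1], met_class = names(cls),
               percent = 100 * as.numeric(cls) / total,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Order-of-magnitude summary of group mean concentrations
#'
#' The decade of each (group, metabolite) mean: `floor(log10(mean))`, so a
#' mean of 2.3e-4 M maps to -4 and decade boundaries (1e-3) map to their own
#' decade (-3).
#'
#' @param means Output of [group_means()].
#' @return Data frame: `group_id`, `metabolite_id`, `order_of_magnitude`.
#' @export
magnitude_heatmap <- function(means) {
  assert_columns(means, c("group_id", "metabolite_id", "mean_conc_M"),
                 "means table")
  oom <- ifelse(is.na(means$mean_conc_M) | means$mean_conc_M <= 0,
                NA_integer_, as.integer(floor(log10(means$mean_conc_M))))
  data.frame(group_id = means$group_id, metabolite_id = means$metabolite_id,
             order_of_magnitude = oom, stringsAsFactors = FALSE)
}
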