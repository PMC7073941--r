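make_matrix <- function(values, groups) {
  m <- values
  attr(m, "groups") <- stats::setNames(groups, rownames(m))
  m
}

test_that("prevalence filter keeps metabolites in > 50% of groups", {
  groups <- rep(paste0("g", 1:8), each = 2)
  m <- matrix(1, nrow = 16, ncol = 3,
              dimnames = list(paste0("s", 1:16), c("keep5", "drop4", "all")))
  m[groups %in% paste0("g", 6:8), "keep5"] <- NA   # present in 5/8 groups
  m[groups %in% paste0("g", 5:8), "drop4"] <- NA   # present in 4/8 groups
  m <- make_matrix(m, groups)
  out <- prevalence_filter(m)
  expect_setequal(colnames(out), c("keep5", "all"))  # strict > 0.5
  # identity on an all-present matrix
  full <- make_matrix(matrix(1, 16, 2, dimnames = list(paste0("s", 1:16),
                                                       c("a", "b"))), groups)
  expect_equal(colnames(prevalence_filter(full)), c("a", "b"))
  # sample-level counting
  out_s <- prevalence_filter(m, unit = "samples")
  expect_true("keep5" %in% colnames(out_s))
})

test_that("minimum imputation fills each column with its observed minimum", {
  m <- make_matrix(matrix(c(1, 2, NA, 5, NA, NA, 4, 7, 6),
                          nrow = 3, dimnames = list(paste0("s", 1:3),
                                                    c("a", "b", "c"))),
                   c("g1", "g1", "g2"))
  out <- impute_min(m)
  expect_equal(unname(out[, "a"]), c(1, 2, 1))
  expect_equal(unname(out[, "b"]), c(5, 5, 5))   # two missing, same minimum
  expect_equal(unname(out[, "c"]), c(4, 7, 6))   # untouched
  m_bad <- m; m_bad[, "a"] <- NA
  expect_error(impute_min(m_bad), "a")
})

test_that("auto-scaling centers and unit-scales every metabolite", {
  withr::with_seed(51, {
    m <- make_matrix(matrix(rlnorm(40, 0, 1), nrow = 8,
                            dimnames = list(paste0("s", 1:8), paste0("m", 1:5))),
                     rep(c("g1", "g2"), each = 4))
    out <- autoscale(m)
    expect_equal(unname(colMeans(out)), rep(0, 5), tolerance = 1e-12)
    expect_equal(unname(apply(out, 2, sd)), rep(1, 5), tolerance = 1e-12)
  })
  two <- make_matrix(matrix(c(1, 3), 2, 1,
                            dimnames = list(c("s1", "s2"), "a")),
                     c("g1", "g2"))
  expect_equal(unname(autoscale(two)[, 1]),
               c(-1, 1) / sqrt(2), tolerance = 1e-12)
  cst <- make_matrix(matrix(c(1, 1, 2, 3), 2, 2,
                            dimnames = list(c("s1", "s2"), c("flat", "x"))),
                     c("g1", "g2"))
  expect_error(autoscale(cst), "flat")
})

test_that("PCA reconstructs the scaled matrix and orders variance", {
  withr::with_seed(52, {
    m <- matrix(rnorm(60), nrow = 10,
                dimnames = list(paste0("s", 1:10), paste0("m", 1:6)))
    m <- make_matrix(m, rep(c("g1", "g2"), each = 5))
    s <- autoscale(m)
    full <- run_pca(s, n_components = min(nrow(s) - 1, ncol(s)))
    expect_equal(sum(full$explained_variance_fraction), 1, tolerance = 1e-12)
    expect_true(all(diff(full$explained_variance_fraction) <= 1e-12))
    recon <- full$scores %*% t(full$loadings)
    expect_lt(max(abs(recon - s)), 1e-8)
    # sign convention: largest-magnitude loading per component positive
    for (k in seq_len(ncol(full$loadings))) {
      ld <- full$loadings[, k]
      expect_gt(ld[which.max(abs(ld))], 0)
    }
  })
})

test_that("rank-1 data loads entirely on the first component", {
  v <- c(1, 2, 3, 4, 5)
  m <- outer(v, c(1, -2, 0.5, 3))
  dimnames(m) <- list(paste0("s", 1:5), paste0("m", 1:4))
  m <- make_matrix(m, c("g1", "g1", "g1", "g2", "g2"))
  p <- run_pca(autoscale(m), n_components = 2)
  expect_equal(p$explained_variance_fraction[1], 1, tolerance = 1e-12)
})

test_that("group confidence ellipses are finite and centred on the scores", {
  cfg <- study_config(seed = 61)
  run <- run_pipeline(cfg)
  ell <- run$pca$ellipses
  expect_equal(nrow(ell), 8)
  expect_true(all(is.finite(ell$semi_axis_1[ell$n >= 3])))
  g1 <- ell$group_id[1]
  sc <- run$pca$scores[run$pca$groups == g1, ]
  expect_equal(ell$center_x[1], mean(sc[, 1]))
  # hotelling scaling inflates small-sample ellipses
  p_h <- run_pca(run$matrix_scaled, ellipse = "hotelling")
  expect_true(all(p_h$ellipses$semi_axis_1 > ell$semi_axis_1))
})

test_that("pooled t-test matches the closed-form oracle", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  m <- matrix(c(a, b), ncol = 1, dimnames = list(paste0("s", 1:10), "met"))
  m <- make_matrix(m, rep(c("A", "B"), each = 5))
  res <- ttest_fdr(m, "A", "B")
  orc <- pooled_t_oracle(a, b)
  expect_equal(res$t_statistic, orc$t)
  expect_equal(res$p_value, orc$p)
  expect_equal(res$log2_fc, log2(3 / 4))
  # independent cross-check against stats::t.test
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$p_value, unname(tt$p.value))
  expect_equal(res$t_statistic, unname(tt$statistic))
})

test_that("identical groups are never significant", {
  withr::with_seed(53, {
    vals <- rlnorm(5, -9, 1)
    m <- matrix(rep(vals, 2), ncol = 1,
                dimnames = list(paste0("s", 1:10), "met"))
    m <- make_matrix(m, rep(c("A", "B"), each = 5))
    res <- ttest_fdr(m, "A", "B")
    expect_equal(res$p_value, 1)
    expect_false(res$significant)
  })
})

test_that("BH q-values match brute-force step-up enumeration", {
  p <- c(0.01, 0.02, 0.03, 0.5)
  expect_equal(p.adjust(p, "BH"), bh_oracle(p))
  withr::with_seed(54, {
    for (r in 1:50) {
      pv <- runif(sample(3:30, 1))^sample(1:3, 1)
      expect_equal(p.adjust(pv, "BH"), bh_oracle(pv))
    }
  })
  # monotone consistency: q >= p, ranking preserved
  withr::with_seed(55, {
    pv <- runif(20)
    q <- p.adjust(pv, "BH")
    expect_true(all(q >= pv))
    expect_true(all(diff(q[order(pv)]) >= -1e-15))
  })
})

test_that("log2 fold change is the signed ratio on the log2 scale", {
  c0 <- 3.7e-4
  expect_equal(log2_fold_change(4 * c0, c0), 2)    # four-fold higher
  expect_equal(log2_fold_change(c0, c0), 0)
  expect_equal(log2_fold_change(c0, 2 * c0), -1)
  expect_equal(log2_fold_change(c0, 2 * c0), -log2_fold_change(2 * c0, c0))
  expect_true(is.na(log2_fold_change(0, c0)))
})

test_that("class composition percentages are conserved", {
  panel <- default_panel()
  # one-class table: 100%
  aa <- panel$metabolite_id[panel$met_class == "amino_acid"][1:3]
  means1 <- data.frame(group_id = "g1", metabolite_id = aa,
                       mean_conc_M = c(1e-4, 2e-4, 3e-4))
  comp1 <- class_composition(means1, panel)
  expect_equal(comp1$percent, 100)
  # multi-class fixture: proline at 34% of the total pool
  ids <- c("Pro", "Glu", "ATP", "CIT")
  total <- 1e-2
  means2 <- data.frame(group_id = "alga", metabolite_id = ids,
                       mean_conc_M = c(0.34, 0.40, 0.06, 0.20) * total)
  comp2 <- class_composition(means2, panel)
  expect_equal(sum(comp2$percent), 100, tolerance = 1e-9)
  pro_share <- 100 * means2$mean_conc_M[1] / sum(means2$mean_conc_M)
  expect_equal(pro_share, 34)
  expect_equal(comp2$percent[comp2$met_class == "amino_acid"], 74)
})

test_that("magnitude heatmap uses floor(log10) with boundary convention", {
  means <- data.frame(group_id = "g", metabolite_id = c("a", "b", "c", "d"),
                      mean_conc_M = c(2.3e-4, 1e-3, 9.99e-3, NA))
  hm <- magnitude_heatmap(means)
  expect_equal(hm$order_of_magnitude, c(-4L, -3L, -3L, NA))
})
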