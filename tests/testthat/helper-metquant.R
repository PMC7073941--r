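# Shared fixtures and independent oracles used across test files.

# noise-free study configuration: the pipeline must invert the generator
# exactly under this config
noiseless_config <- function(seed = 11) {
  study_config(seed = seed, noise_cv = 0, matrix_effect_sd = 0,
               missing_rate = 0, outlier_rate = 0, biomass_cv = 0)
}

# brute-force weighted least squares via the 2x2 normal equations,
# solved in rescaled coordinates (x/sx, y/sy) to keep the system
# well-conditioned over many decades of x
wls_oracle <- function(x, y, w) {
  sx <- max(abs(x)); sy <- max(abs(y))
  xs <- x / sx; ys <- y / sy
  A <- matrix(c(sum(w), sum(w * xs), sum(w * xs), sum(w * xs^2)), 2, 2)
  b <- c(sum(w * ys), sum(w * xs * ys))
  sol <- solve(A, b)
  list(intercept = sol[1] * sy, slope = sol[2] * sy / sx)
}

# brute-force Benjamini-Hochberg step-up: q_(i) = min_{j >= i} n p_(j) / j
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- vapply(seq_len(n), function(i) {
    min(vapply(i:n, function(j) min(n * p[o][j] / j, 1), numeric(1)))
  }, numeric(1))
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# closed-form pooled-variance two-sample t-test
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), na + nb - 2))
}

# brute-force Dixon r10: compute the gap/range statistic at both ends
# directly and reject the more extreme end when it exceeds the critical value
dixon_oracle <- function(values, q_crit) {
  s <- sort(values)
  n <- length(s)
  rng <- s[n] - s[1]
  if (rng == 0) return(list(q = NA_real_, outlier_index = NA_integer_))
  q_low <- (s[2] - s[1]) / rng
  q_high <- (s[n] - s[n - 1]) / rng
  if (q_high >= q_low) {
    list(q = q_high,
         outlier_index = if (q_high > q_crit) which.max(values) else NA_integer_)
  } else {
    list(q = q_low,
         outlier_index = if (q_low > q_crit) which.min(values) else NA_integer_)
  }
}

# build a single-metabolite calibration series table from (level, ratio)
# pairs: IS area fixed at `is_area`, analyte area = ratio * is_area
make_cal_series <- function(levels, ratios, metabolite_id = "MET",
                            is_area = 1e5) {
  n <- length(levels)
  data.frame(
    sample_id = rep(sprintf("cal_%02d", seq_len(n)), 2),
    group_id = "calibration",
    metabolite_id = metabolite_id,
    channel = rep(c("analyte", "internal_standard"), each = n),
    area = c(ratios * is_area, rep(is_area, n)),
    role = rep(ifelse(levels == 0, "blank", "calibrant"), 2),
    level_conc_M = rep(levels, 2),
    stringsAsFactors = FALSE
  )
}

# minimal intracellular table builder for qc/stats unit tests
make_intra <- function(group_id, sample_id, metabolite_id, conc,
                       flag = "ok") {
  data.frame(group_id = group_id, sample_id = sample_id,
             metabolite_id = metabolite_id, per_biomass = NA_real_,
             per_biomass_unit = "mol_per_g_DW",
             conc_intracellular_M = conc, flag = flag,
             stringsAsFactors = FALSE)
}
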