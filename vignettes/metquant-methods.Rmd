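---
title: "metquant: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metquant: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metquant)
```

## Scope

`metquant` converts integrated peak areas from targeted tandem-MS metabolite
profiling into absolute intracellular concentrations and runs the QC and
statistics that this workflow entails. It deliberately starts *after* peak
integration: there is no chromatogram, retention-time, or vendor-file
handling, and no modeling of cultivation, quenching, or extraction
chemistry. Those wet-lab steps enter only through their arithmetic
footprint: spike fractions, dilution factors, biomass readings, and cell
volumes.

## The quantification model

For a sample $s$ and metabolite $m$, the measured analyte area is assumed
multiplicative in the true concentration:

$$A_{sm} = k_m \, c_{sm} \, \mu_{sm} \, \varepsilon_{sm},$$

where $k_m$ is the detector sensitivity, $\mu_{sm}$ a matrix
(ionization-suppression) factor, and $\varepsilon$ measurement noise. The
internal standard of $m$ is present at a constant concentration in every
injected solution and co-elutes with the analyte, so its area carries the
*same* $\mu_{sm}$. The corrected response

$$y_{sm} = A_{sm} / A^{IS}_{sm}$$

therefore does not depend on the matrix factor at all — this cancellation
is the reason isotope dilution is considered mandatory for absolute MS
quantification, and it is an exact algebraic property of the model rather
than an approximation. The package makes the premise measurable:
`run_pipeline(..., is_correction = FALSE)` quantifies from raw analyte
areas instead, and with any nonzero matrix-effect dispersion the recovery
error strictly increases (a test asserts this on a fixed seed).

Calibration fits $y = a + b x$ over the nominal standard concentrations $x$
by weighted least squares with weights $1/x$. Weighting matters because MS
peak-area noise is roughly proportional to the signal: unweighted fits let
the top calibrants dominate and degrade accuracy at the low end (a test
demonstrates the improvement under proportional noise). Numerical choices:

* The blank ($x = 0$) is excluded from the fit — $1/x$ is undefined there.
* Limits of quantification follow the conventional bioanalytical
  back-calculation rule: a level is accepted when its mean back-calculated
  concentration is within ±20 % of nominal (±25 % at the lowest level);
  LLOQ/ULOQ are the lowest/highest accepted levels. The rule is a declared
  convention of this package — sources describing the workflow typically
  report LOQ flags without printing their acceptance criterion.
* Fewer than 3 usable non-blank levels, an all-equal response vector, or a
  non-positive slope abort the fit for that metabolite only; other
  metabolites are unaffected and affected cells are flagged `no_model`.
* Interpolated concentrations below the LLOQ are clamped at 0 and flagged
  `below_lloq`; flagged values are reported but treated as missing by the
  statistics stage, consistent with imputing non-quantified values.

Preparation factors then undo what sample processing did to the extract:
division by $(1 - \text{spike fraction})$ for the internal-standard spike
(20 % v/v for the labeled whole-cell extract, 5 % v/v for the labeled
amino-acid mix) and the lyophilization/reconstitution ratio (both default 1,
i.e. `extract_volume` denotes the final reconstituted volume).

Biomass normalization assumes all extracted metabolite originated from the
cell interior and distributes over total cell volume, with no
periplasm/vacuole compartmentation. Microorganisms: amount / dry weight,
then / specific cell volume (L/g, literature values shipped in
`cell_models()`). Cell lines: amount / cells sampled, then / the
*per-replicate measured* cell volume (pL), not a literature value. One
packaged-table note: the yeast specific volume is stored as printed
(2.66e-3 L/g) although exact division of its own inputs gives 2.667e-3; the
consistency test for that row uses a 0.5 % tolerance rather than silently
"correcting" the table. A second numerical note: rounding a volume such as
122.5 µm³ to three significant figures should happen on the µm³ value,
which is exact in floating point, not after multiplying by 1e-15 — the
binary representation of the product sits just above the decimal half and
would round the wrong way (`half_parallelepiped_volume(unit = "um3")`).

## Quality control

The adenylate energy charge, $EC = ([ATP] + \tfrac12 [ADP]) / ([ATP] +
[ADP] + [AMP])$, is computed per replicate from recovered intracellular
concentrations and averaged per group after outlier rejection. The formula
is Atkinson's; the physiological band 0.7–0.95 is checked with inclusive
endpoints (the source range gives no open/closed indication; inclusive is
the conservative reading). Groups missing an adenylate get an unavailable
EC rather than aborting the report; single-replicate groups report no SD.

Outlier rejection uses Dixon's classic $r_{10}$ ("Q") statistic — suspect
gap over range, tested at the more extreme end (ties go to the high end),
at most one rejection per replicate vector, no iteration — against the
two-tailed 95 % critical values of the standard table (shipped as the
versioned fixture `dixon_q_critical_v1.csv`, $3 \le n \le 10$, also 90 %
and 99 % columns). $r_{10}$ is the textbook variant for $n \le 10$, which
covers the five-replicate design. Zero-range vectors yield a no-test
result. Rejection operates per (group, metabolite) on final intracellular
values before any averaging; rejected replicates become missing downstream.
Whether rejection should precede or follow biomass normalization is not
settled by the workflow description this package follows; testing on final
values is the default and `qc_report(reject = FALSE)` plus direct calls to
`reject_outliers()` let a user place the step elsewhere.

## Statistics

* **Prevalence filter**: keep metabolites quantified in strictly more than
  50 % of *biological groups* (a group counts when any replicate is
  quantified). Counting over groups rather than samples reflects reading
  "the panel" as the organism panel; `prevalence_unit = "samples"` switches.
* **Imputation**: missing cells take the global minimum measured value of
  that metabolite.
* **Auto-scaling**: per-metabolite mean-centering and division by the
  sample SD ($n - 1$) — the standard meaning of auto-scaling in
  metabolomics. Zero-variance columns are an error naming the column.
* **PCA**: `stats::prcomp` on the scaled matrix; the sign of each component
  is fixed by making its largest-magnitude loading positive. 95 %
  confidence ellipses per group come from the 2-D score covariance scaled
  by the $\chi^2_2$ 0.95 quantile; `ellipse = "hotelling"` applies the
  small-sample $T^2$ scaling instead (larger ellipses at $n = 5$).
* **Tests**: pooled-variance two-tailed t-tests per metabolite on the
  imputed (unscaled) concentrations — the t statistic is invariant to
  column scaling, and means/fold changes must stay molar — with
  Benjamini–Hochberg step-up q-values (`stats::p.adjust`; the FDR method is
  BH because that is the documented default of the common web tooling for
  this analysis). Zero pooled variance with equal means is defined as
  $p = 1$.
* **Summaries**: log₂ fold changes of group means (non-positive means give
  NA); class composition as percent of the group's total measured pool
  (rows sum to 100); order-of-magnitude heatmap as
  $\lfloor \log_{10}(\text{mean}) \rfloor$, so decade boundaries belong to
  their own decade (1e-3 M → −3). Pathway "graphing" is an exported table
  (metabolite, pathway position, log₂FC, significance) for any renderer.

## The synthetic study

The generator emulates the structure of a multi-organism central-carbon
profiling study: 8 groups (2 bacteria/yeast-like microorganisms, 2
microalga-like with an osmolyte-style proline pool of 0.05–0.1 M, 4 human
cell lines with elevated lactate) × 5 replicates over the packaged
68-metabolite panel. Per-class log-uniform concentration bands put
deoxynucleoside phosphates lowest (1e-8–3e-7 M) and amino acids highest,
giving ≥ 3 decades within each group and ~7 across the panel; adenylates
are drawn jointly so each group's true EC lies in `ec_range` (default
0.75–0.93, inside the physiological band so that noisy recovery stays
within 0.7–0.95). Noise is multiplicative lognormal throughout: a matrix
factor with CV `matrix_effect_sd` (default 0.30) shared between the two
channels of a cell, independent channel noise with CV `noise_cv` (default
0.10), 5 % CV replicate jitter on biomass readings (`biomass_cv`; the
replicate-level biomass variance of real studies is rarely reported — this
is a declared free parameter). Cells go missing at `missing_rate` (default
0.04) and single replicates receive ×3–10 outliers at `outlier_rate`
(default 0.02, at most one per group × metabolite — Dixon's Q is a
single-outlier test). Calibration uses a blank plus 9 decade-spaced levels
(1e-11–1e-3 M) with duplicate injections, standard bioanalytical practice
that stabilizes the fitted slope and the back-calculation acceptance;
instrument sensitivities and internal-standard concentrations are drawn
once per study (labeled-extract IS levels vary by metabolite, spiked mixes
are constant 5 µM).

Every output is a pure function of `(config, seed)`; sub-generators use
fixed offsets from the study seed.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: chromatographic interferences and integration
errors, additive baseline noise (a blank therefore measures exactly zero),
internal-standard drift and batch effects, carry-over and extraction losses,
compartmentation, and biological covariance between metabolites beyond the
class structure. The recovery results should be read as validating the
*arithmetic chain and its statistical machinery*, not the wet-lab accuracy
of any particular instrument.

## Validation design and problem sizes

The test suite runs the chain in three regimes: noise-free (the pipeline
must invert the generator to floating-point accuracy), matrix-effect-only
(quantification must remain exact — the cancellation property), and default
noise (median absolute relative recovery error over quantified replicate
cells must stay ≤ 15 %, and ablating isotope correction must strictly
worsen it on the same seed). The recovery statistic is computed at
replicate level — the stricter reading; `evaluate_recovery(by = "group")`
gives the group-mean variant. Hand-implemented primitives are checked
against independent oracles: the weighted fit against a direct
normal-equation solution (rescaled to stay well-conditioned over many
decades), Dixon's Q against a brute-force both-ends enumeration (1,000
random instances) plus an empirical type-I check at $\alpha = 0.05$
(10,000 simulations at $n = 5$, expected rate in [0.03, 0.07]), and BH
q-values against brute-force step-up enumeration (1,000 random p-vectors).
Default problem sizes (8 × 5 × 68 study, the simulation counts above) keep
the whole suite under a minute on a single core while leaving the binomial
checks (e.g. the 4 % missingness rate within 3 SDs) statistically
meaningful.

## Known limitations

* The 68-metabolite registry reconstructs the documented class structure
  (20 amino acids, 12 + 12 (deoxy)nucleoside phosphates, 24 central-carbon
  intermediates); a few intermediate identities are this package's choice
  where only class counts are documented.
* Metabolites measurable by several methods are assigned one primary method
  in the registry to avoid double quantification; load a custom panel CSV
  to remap.
* Dixon's Q is limited to 3–10 replicates by its critical-value table;
  larger designs need a different outlier strategy.
* Below-LLOQ information is reduced to a flag; no censored-data modeling.
* The t-test contrast is a single pair of groups per call; run `ttest_fdr`
  repeatedly for more contrasts.
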