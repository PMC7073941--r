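# metquant

Absolute quantification of targeted tandem-MS metabolomics data: from
integrated peak areas to intracellular molar concentrations, with the QC
metrics and downstream statistics that belong to that workflow.

## The problem

Targeted LC/IC-MS/MS metabolite profiling yields peak areas, which are not
comparable between metabolites (ionization efficiency differs) nor between
samples (co-eluting matrix suppresses or enhances ionization). The standard
remedy is **isotope dilution**: every sample and calibrant is spiked with
stable-isotope-labeled internal standards, and each analyte's area is divided
by the area of its labeled isotopologue. Because the matrix factor acts
multiplicatively and identically on both channels, the ratio cancels it:

```
response_m,s = area_analyte / area_IS
conc_analyzed = (response - intercept) / slope        # weighted calibration
conc_extract  = conc_analyzed / (1 - spike) * recon / lyo
amount        = conc_extract * V_extract
per_biomass   = amount / DW            (microorganisms, mol/g)
              = amount / (cells)       (cell lines, mol/cell)
conc_cell     = per_biomass / specific_volume   or   / cell_volume
```

Calibration curves are least-squares fits of response vs. nominal standard
concentration with **1/x weighting**; the lower/upper limits of
quantification are the lowest/highest calibrants whose back-calculated
concentration is within ±20 % of nominal (±25 % at the lowest level).

Quality control uses the **adenylate energy charge**
EC = ([ATP] + ½[ADP]) / ([ATP] + [ADP] + [AMP]), which sits in 0.7–0.95 for
physiologically intact sampling, and **Dixon's Q test** for single-replicate
outlier rejection. Downstream statistics follow common metabolomics
practice: >50 % prevalence filtering, minimum-value imputation,
auto-scaling, PCA with 95 % confidence ellipses, pooled two-sample t-tests
with Benjamini–Hochberg FDR control, log₂ fold changes, class-composition
and order-of-magnitude summaries.

Because public raw datasets for this workflow are scarce, the package ships
a **synthetic study generator** with known ground truth (8 biological groups
× 5 replicates over a 68-metabolite central-carbon panel, concentrations
spanning ~7 orders of magnitude, shared multiplicative matrix effects, ~4 %
missingness, occasional single-replicate outliers) so that every stage —
and the isotope-dilution premise itself — is testable end to end.

## Worked example

```r
library(metquant)

config <- study_config(seed = 42)   # 8 groups x 5 replicates, CV 10%,
                                    # matrix SD 30%, 4% missing
run <- run_pipeline(config)
run
#> <metquant_run> 8 groups x 5 replicates, 68 metabolites
#>   median |relative recovery error|: 11.0% (n = 2525 cells)
#>   energy charge in range: 8 / 8 groups
#>   significant (bsub vs scer, FDR 0.05): 54 / 67 metabolites

head(run$qc$ec, 3)
#>   group_id n_replicates   ec_mean       ec_sd ec_in_range
#> 1     bsub            5 0.8150196 0.009754591        TRUE
#> 2     scer            5 0.7983250 0.018930992        TRUE
#> 3     noce            5 0.8795746 0.016319006        TRUE
```

The print method reports: the median absolute relative error of recovered
vs. true intracellular concentrations over all quantified replicate cells
(11 % under the default noise model — dominated by the 10 % CV channel
noise, since the 30 % matrix effect cancels in the isotope ratio); the
per-group energy charge, all within the physiological band; and the number
of metabolites significantly different between the first two groups at
FDR 0.05. Rerunning with `is_correction = FALSE` (no isotope dilution)
roughly doubles the recovery error — the measurable benefit of the internal
standards.

Individual stages are exported: `default_panel()`, `simulate_study()`,
`fit_calibration()`, `quantify_table()`, `normalize_intracellular()`,
`qc_report()`, `dixon_q()`, `energy_charge()`, `prevalence_filter()`,
`impute_min()`, `autoscale()`, `run_pca()`, `ttest_fdr()`,
`class_composition()`, `magnitude_heatmap()`. A thin CLI wrapper lives at
`inst/cli/metquant.R` (`simulate` and `run` subcommands). See the methods
vignette (`vignettes/metquant-methods.Rmd`) for the model and all parameter
choices.

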