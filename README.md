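# fcmodular

Module-level analysis of resting-state functional connectivity and its
coupling to MR-spectroscopy metabolite measures, for two-group
(patient/control) neuroimaging studies.

Functional brain networks organize into modules — groups of regions densely
connected internally and weakly connected across. In disorders such as
schizophrenia, the interesting questions sit at the module level: is
connectivity *within* the frontoparietal module altered, is its coupling *to*
other modules altered, and do those alterations track the neurochemistry
(e.g. NAA in dorsolateral prefrontal cortex) and the clinical picture?
`fcmodular` implements that analysis chain for regional time series:

1. **QC** — exclusion for gross head motion (> 2.5 mm translation or > 2.5°
   rotation), for mean framewise displacement (Jenkinson, 80 mm ball) above
   the group mean + 2 SD, and for spectroscopy that fails the CRLB < 20%
   reliability filter.
2. **Signal conditioning** — Friston-24 motion regression, linear detrend,
   0.01–0.1 Hz band-pass.
3. **Networks** — Fisher-z regional correlations over the 90 cerebral
   parcels; edge-wise one-sample t-tests across subjects with
   Benjamini–Hochberg FDR to retain positive edges; group-average network;
   sparsity threshold chosen as the smallest value in 5–30% keeping every
   subject's network fully connected.
4. **Modularity** — greedy maximization of the weighted modularity

   $$Q^W(p) = \frac{1}{l^W}\sum_{i,j}\Big[w_{ij} - \frac{k_i^W k_j^W}{l^W}\Big]\,\delta_{m_i m_j}$$

   with deterministic tie-breaking and a single-node refinement pass, plus a
   sparsity sweep with integrated (trapezoidal) maximum modularity.
5. **Module metrics** — per subject, intra-module connectivity
   $C_s = \sum_{i,j\in s} k_{i,j}/l_s$ and inter-module connectivity
   $C_{s,t} = \sum_{i\in s,j\in t} k_{i,j}/l_{s,t}$ (mean weight of existing
   edges), evaluated under the healthy-control partition.
6. **Statistics** — Welch t-tests for group contrasts, Pearson correlation of
   CSF-corrected metabolite concentration with module coupling per group,
   Spearman correlations with symptom scores, all preceded by iterative
   Grubbs outlier screening. Summary-statistic inputs (mean ± SD, or r and n)
   are accepted, so printed results can be re-evaluated directly.

Because no raw imaging data accompany the method, the package includes a
fully specified synthetic cohort generator (`generate_cohort()`) that plants
a six-module covariance structure, group differences in specific module
couplings, a metabolite coupled to connectivity in controls only, clinical
scores coupled to module connectivity in patients, and to-be-excluded
motion/CRLB outliers — so the entire pipeline is testable end to end. See the
methods vignette (`vignettes/modular-coupling-methods.Rmd`) for the model,
conventions, and what the generator does and does not emulate.

## Worked example

```r
library(fcmodular)

cohort <- generate_cohort(fc_sim_config(seed = 42))
cohort
#> <fc_cohort> 53 subjects (control: 29, patient: 24), 90 regions x 230 timepoints
#>   planted outliers: P21 P22 P23 P24 C27 C28 C29

analysis <- run_full_analysis(cohort)
analysis
#> <fc_analysis> 26 control, 20 patient included; sparsity 0.20; control Q^W = 0.739 (6 modules)

tidy(analysis)
#>    contrast                        group              method      estimate statistic    df   p.value
#>  1 intra_FP                        patient_vs_control welch_ttest   0.189       9.52  30.9  1.05e-10
#>  2 inter_FP_Central                patient_vs_control welch_ttest  -0.110      -6.36  25    1.19e- 6
#>  3 inter_FP_Hippocampal            patient_vs_control welch_ttest  -0.0852     -5.15  25    2.55e- 5
#>  4 inter_FP_Central_vs_NAA         control            pearson       0.636       4.04  24    4.75e- 4
#>  5 inter_FP_Central_vs_NAA         patient            pearson      NA          NA     18   NA
#>  ...
```

Reading the output: of the recruited pool (24 patients, 29 controls), the
quality filters retain 20 and 26 — the six planted motion outliers and the
one unusable-spectroscopy patient are removed. The control group-average
network at the selected 20% sparsity decomposes into the six planted modules
(Q^W = 0.739). The group contrasts recover the planted effects:
frontoparietal intra-module connectivity is higher in patients (+0.19 z),
FP–Central and FP–Hippocampal coupling lower (−0.11, −0.09 z). NAA tracks
FP–Central connectivity in controls (r = 0.64, p < 0.001) but is undefined
(flagged `constant`) in patients, whose FP–Central edges are entirely
removed by the one-sided FDR mask — the planted decoupling.

Printed summaries can be checked without raw data:

```r
two_sample_ttest(summary = list(mean_a = 0.62, sd_a = 0.14, n_a = 20,
                                mean_b = 0.49, sd_b = 0.09, n_b = 26))$p.value
#> [1] 0.001057  # the published frontoparietal contrast
pearson_corr(r = 0.614, n = 26)$p.value
#> [1] 0.000848
```

Plot helpers: `autoplot()` on connectivity matrices and sparsity sweeps,
`plot_module_metrics()` for group comparisons, `plot_coupling()` for the
metabolite–connectivity scatter.

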