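---
title: "Modular functional connectivity and metabolic coupling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular functional connectivity and metabolic coupling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcmodular)
```

## What the package computes

`fcmodular` implements a module-level analysis of resting-state functional
connectivity and its coupling to single-voxel MR spectroscopy measures, for
two-group (patient vs. control) designs:

1. **Quality control.** Subjects are excluded for gross head motion (any
   translation > 2.5 mm or rotation > 2.5° in any direction), for mean
   framewise displacement above the group mean + 2 SD, or for having no
   metabolite quantification passing the Cramér–Rao lower bound (CRLB < 20%)
   reliability filter.
2. **Signal conditioning.** Per subject, regional time series are
   residualized on the Friston 24-parameter motion design, linearly
   detrended, and band-passed to 0.01–0.1 Hz.
3. **Network construction.** Pearson correlations between all pairs of the
   90 cerebral parcels are Fisher-z transformed. A group-level edge mask
   retains edges whose across-subject z values are significantly positive
   (one-sample t-test, one-sided, Benjamini–Hochberg FDR at q = 0.05):
   the stated goal of this step is to remove weak or negative correlations.
4. **Modularity.** On each group's masked average network, thresholded at a
   sparsity chosen as the smallest value in 5–30% at which every subject's
   network is fully connected, modules are detected by greedy maximization
   of the weighted modularity
   $$Q^W(p) = \frac{1}{l^W}\sum_{i,j}\left[w_{ij} -
     \frac{k^W_i k^W_j}{l^W}\right]\delta_{m_i,m_j},$$
   with node strengths $k^W_i = \sum_j w_{ij}$ and ordered-pair total weight
   $l^W = \sum_{ij} w_{ij}$.
5. **Module-level statistics.** Per subject, intra-module connectivity
   $C_s = \sum_{i,j \in s} k_{i,j}/l_s$ and inter-module connectivity
   $C_{s,t} = \sum_{i\in s, j\in t} k_{i,j}/l_{s,t}$ are computed under the
   healthy-control partition, where $l$ counts the surviving (masked)
   unordered edges — i.e. $C$ is the mean weight of existing edges.
6. **Coupling statistics.** Welch t-tests compare the frontoparietal
   contrasts between groups; Pearson correlation relates the CSF-corrected
   metabolite concentration to FP–Central connectivity per group; Spearman
   correlations relate module metrics to symptom scores in patients. Each
   correlation is preceded by iterative Grubbs outlier screening
   (α = 0.05, at most ⌊n/10⌋ removals).

## Conventions and numerical choices

**Ordered-pair modularity.** $l^W$ sums over ordered pairs (twice the
unordered edge weight) and the $i = j$ terms (which vanish, $w_{ii}=0$) are
included. Under this convention the single-module partition scores exactly
zero, which we regression-test. Statements that the one-module partition
scores 1 (which circulate in the applied literature) are inconsistent with
the formula itself; we follow the formula.

**Greedy detection.** Agglomerative merging of the connected module pair
with the largest modularity gain, with a deterministic single-node refinement
pass (moves that strictly increase $Q^W$ by more than $10^{-12}$, swept in
node order until stable) applied to every partition along the merge path; the
best refined partition is returned. Pure greedy merging is prone to absorbing
small modules that single-node moves cannot later split; refining the whole
merge path recovers them at negligible cost.
All ties break toward the smallest module-index pair, so detection
is reproducible without a seed and invariant to node relabeling (tested via
the adjusted Rand index). On exhaustive enumeration batteries (all set
partitions, n ≤ 8) the detected $Q^W$ never exceeds the true maximum and is
within 0.02 of it in ≥ 95% of random graphs. Disconnected inputs are handled
per connected component with a warning.

**Sparsity.** Sparsity is the retained fraction of all $N(N-1)/2$ edges;
thresholding keeps the largest-weight edges with ties broken by node-index
order, so masks are nested across sparsities. The selection rule scans
5–30% in 1% steps and returns the smallest value at which every subject's
masked network is one connected component; if none qualifies the
maximum-coverage value is returned with a flag.

**Framewise displacement.** The Jenkinson formulation: the RMS displacement
of an 80 mm-radius ball under the relative rigid transform between
consecutive volumes, $\sqrt{\tfrac{1}{5}R^2\,\mathrm{tr}(\Delta A^\top\Delta A)
+ \|\Delta b\|^2}$. The implementation is checked against a Monte-Carlo
oracle that averages displacement over 10,000 points sampled in the ball.
The group FD rule is applied after the hard translation/rotation rules, and
its group statistics are computed over subjects passing those rules, so a
subject with gross motion cannot inflate the group SD and mask an FD
outlier.

**CSF partial-volume correction** divides concentrations by $(1 - f_{CSF})$.
Tissue water-relaxation terms used by some absolute-quantification pipelines
are deliberately not modelled; the correction is a pure visibility-fraction
rescaling, and the tissue-fraction sum is sanity-checked.

**Spearman p-values** use the t-approximation on $n-2$ degrees of freedom
applied to mid-rank correlations. From printed 3-decimal summaries this can
land a rounding boundary away from a published p (e.g. ρ = −0.525, n = 20
gives p = 0.01746, where the unrounded ρ evidently gave 0.0175+); the raw
p-values are reported so no information is lost to rounding.

## The synthetic cohort generator

No raw imaging data accompany this method, so the package ships a generator
(`generate_cohort()`) that emulates the statistical structure the analysis
assumes, making every downstream stage testable end to end:

- **Planted modular covariance.** Six modules (Central 18, default-mode 20,
  frontoparietal 17, occipital 14, subcortical 10, hippocampal 11 regions)
  with within-module correlation 0.5 and between-module correlation 0.1.
  Patients receive −0.15 on FP–Central and FP–Hippocampal coupling and
  +0.15 on FP intra-module coupling — directions matching the reported group
  differences; the magnitudes are design choices since no raw-data effect
  sizes are recoverable. Infeasible combinations are repaired to the nearest
  positive-semidefinite correlation matrix (eigenvalue clipping at $10^{-8}$,
  diagonal renormalization) and the repair is reported; the default
  configuration needs no repair (minimum eigenvalue 0.35).
- **Time series** are multivariate normal (T = 230, i.e. 240 volumes minus
  10 discarded, TR = 2 s) plus white observation noise (SD 0.2). Real BOLD
  data are autocorrelated; the band-pass step imposes the relevant spectral
  structure downstream, and white generation keeps the generator analyzable.
- **Per-subject coupling spread.** Every subject's FP–Central and
  FP–Hippocampal couplings get a random deviation (SD 0.08, clipped at
  2.4 SD). The control-group NAA concentration is linear in the subject's
  planted FP–Central coupling (slope 25 i.u. per z-unit, noise SD 1 i.u.);
  patient NAA is decoupled (slope 0). These magnitudes were calibrated, via
  a pilot power analysis, so that the measured control-group correlation is
  ≈ 0.6 — the approximate strength of the reported coupling — after the two
  attenuations the pipeline itself introduces: band-pass filtering reduces
  the effective temporal degrees of freedom (per-edge z noise ≈ 0.11 rather
  than $1/\sqrt{T-3}$), and the CSF correction adds multiplicative noise.
- **Clinical scores.** Patient PANSS general/total scores decrease with the
  planted FP–Central coupling and increase with the planted FP–Hippocampal
  coupling (standardized weight 0.65), with plausible PANSS means and
  spreads; positive/negative subscales and CGI are uncoupled noise.
- **Planted QC failures.** The recruited pool is 24 patients and 29
  controls: per group one translation-spike, one rotation-spike and one
  high-frequency (mean-FD) motion outlier, plus one patient whose CRLB
  values all exceed 20%. Baseline motion is a bounded AR(1) walk whose
  per-subject amplitude is uniform on (0.8, 1.2) × base — a short-tailed
  across-subject FD distribution, so the mean + 2 SD rule fires only on the
  planted FD outlier. The default quality filters therefore retain exactly
  20 patients and 26 controls.
- **Determinism.** All randomness flows from `config$seed`; identical seeds
  give bit-identical cohorts.

### What the generator does not emulate

Spatially heterogeneous coupling (real between-module connectivity varies
edge by edge and contains distance effects), BOLD autocorrelation and
physiological noise, scanner drift, and any image-space artifacts. Two
consequences matter for interpreting the validation results:

- **Global-signal regression is off by default.** With a spatially flat
  positive background, regressing out the region-mean signal re-centers
  between-module correlations at or below zero; the one-sided edge retention
  then removes every between-module edge and no sparsity below 30% connects
  any subject. Real data, with heterogeneous positive backgrounds, do not
  collapse this way. The regressor is implemented
  (`global_signal = TRUE`) for use on real data, but the synthetic
  validation runs without it.
- **Detected modularity is high.** Homogeneous blocks are cleanly separable,
  so the detected $Q^W$ on the synthetic group-average network at the
  selected sparsity is ≈ 0.65–0.78 (median ≈ 0.74) — mostly above the
  0.3–0.7 band typical of real
  cortical networks, whose modular structure is far messier. Recovery of
  the planted partition (adjusted Rand index), of the planted effect
  directions, and of the coupling/decoupling contrast are the meaningful
  validation quantities; the absolute $Q^W$ level is a property of the
  idealized generator, not of the detection algorithm.

**Module metrics are masked by the FDR mask, not the sparsity mask.** The
module-level assessment applies the healthy-control *partition* as the mask;
sparsity thresholding belongs to the modularity analysis. Restricting the
subject metrics additionally to the group sparsity mask
(`metrics_mask = "fdr_sparsity"`) is available, but top-edge selection can
leave a between-module block with no surviving edges at all, making
$C_{s,t}$ degenerate — measured on default synthetic cohorts it leaves 0–5
FP–Central edges of 306. The FDR-mask default keeps $C_{s,t}$ estimable for
all module pairs.

**Degenerate patient metrics.** Under the planted patient deltas the
FP–Central and FP–Hippocampal blocks have negative expected correlation, so
the patient group's one-sided FDR mask removes them entirely and patient
inter-module $C$ values are exactly 0. Group contrasts remain well-defined
(Welch); the patient-side metabolite correlation is undefined on constant
input and is reported as NA with a `constant` flag — which *is* the
decoupled outcome in this design.

## Parameters at a glance

| Parameter | Default | Units / meaning |
|---|---|---|
| `max_trans_mm`, `max_rot_deg` | 2.5 | hard motion exclusion limits |
| `fd_sd_mult` | 2 | group mean-FD rule multiplier |
| `head_radius_mm` | 80 | FD ball radius |
| `low_hz`, `high_hz` | 0.01, 0.1 | pass band (Hz) |
| `q` | 0.05 | edge-wise FDR level |
| sparsity grid | 0.05–0.30 by 0.01 | connectedness-based selection |
| `max_crlb_percent` | 20 | strict CRLB reliability cut |
| Grubbs α | 0.05 | per-step outlier test level |
| `welch` | TRUE | unequal-variance group test |

Welch is the default reading of "independent two-sample t-test" because it
reproduces the published frontoparietal contrast p-value from the printed
summary statistics (p = 0.00106 → 0.001), while the pooled test gives
0.0004. No multiple-testing correction is applied across the correlation
family, matching the uncorrected reporting convention; a BH option can be
applied by the user on the tidied stats table.

## Problem sizes used in validation

The packaged validation runs the full pipeline on 100 independent synthetic
cohorts (each 24 + 29 recruited subjects, 90 regions, 230 timepoints),
checks the statistics' calibration on 1,000 null replicates at the study's
group sizes (20, 26), the FDR retention on 200 null cohorts of 26 subjects
over 45 edges, and the detection algorithm against exhaustive enumeration on
graphs of up to 8 nodes (4,140 partitions). These sizes make the whole
suite run in minutes while leaving the Monte-Carlo margins (e.g. ≥ 95/100
seeds) interpretable.

## Known limitations

- Image-space preprocessing (slice timing, realignment, segmentation,
  normalization, smoothing) and spectral fitting are out of scope: the
  package consumes regional time series, motion parameters and quantified
  metabolite concentrations.
- The greedy detector is a local optimizer; alternatives (Louvain, spectral,
  consensus clustering) are deliberately not included.
- Negative-weight network analysis is not supported; the one-sided edge
  retention is built around positive coupling.
- The metabolite–clinical correlations reported alongside this kind of
  analysis can imply effective sample sizes smaller than the patient count
  (after CRLB and outlier exclusions); the pipeline always reports the n
  actually used.
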