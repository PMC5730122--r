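---
title: "From labeled spins to cortical thickness: the perfcortex methods"
author: "perfcortex authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From labeled spins to cortical thickness: the perfcortex methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfcortex)
```

`perfcortex` studies whether regional gray-matter (GM) perfusion predicts
regional cortical thickness in unilateral high-grade carotid occlusive
disease. The package covers the full computational chain — partial-volume
corrected quantification of single-delay pseudocontinuous arterial spin
labeling (pCASL), ROI-level hemispheric comparison, and cohort-level
association statistics — plus the synthetic data needed to test each link.
This vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic data do and do not establish.

## 1. The kinetic signal model

pCASL magnetically labels arterial blood for a labeling duration LD,
waits a post-labeling delay PLD, and images. Under the single-compartment
model, a tissue voxel with flow $f$ (ml·100g$^{-1}$·min$^{-1}$) and
equilibrium magnetization $M_0$ contributes a control$-$label difference

$$\Delta M \;=\; \frac{f\,M_0\; 2\alpha\, T_{1b}\,
\bigl(1-e^{-\mathrm{LD}/T_{1b}}\bigr)\,e^{-\mathrm{PLD}/T_{1b}}}{6000\,\lambda},$$

inverted by `cbf_from_ratio()`; `forward_delta_m()` is the exact forward
map, so simulation followed by quantification is an identity by
construction — this round trip, not any one constant, is what the test
suite leans on.

Parameters (all in `acq_params()`, with units and defaults):

| parameter | meaning | default | why |
|---|---|---|---|
| `ld` | labeling duration | 1950 ms | emulated protocol |
| `pld0` | PLD of slice 1 | 1200 ms | emulated protocol |
| `slice_dt` | per-slice PLD increment | 70 ms | 2-D readout timing |
| `alpha` | labeling efficiency | 0.70 | includes background-suppression losses |
| `t1b` | blood $T_1$ | 1650 ms | consensus value at 3T |
| `lambda` | blood–brain partition coefficient | 0.9 ml/g | consensus value |
| `n_pairs` | control/label pairs | 60 | emulated protocol |
| `noise_sd` | additive Gaussian SD | 5 (5% of GM $M_0$) | see §4 |

With a 2-D readout, later slices are acquired later:
`adjusted_pld(k) = (k − 1)·slice_dt + pld0`, slice index 1-based on the
third array axis. Slice 10, where the phantom's motor-cortex ROI sits,
has PLD 1830 ms. The protocol we emulate prints both a 70 ms increment
(in its quantification description) and a 75 ms slice timing (in its
acquisition listing), and effective PLDs of 2.0/2.1 s for slices 10/11
that match neither; we implement the explicit quantification formula
(70 ms) and note the inconsistency rather than resolving it. Quantification
uses each voxel's own slice PLD, not an ROI-average PLD. Background
suppression is not modeled kinetically; its signal cost is folded into
$\alpha$, which is why 0.70 is lower than plain pCASL inversion
efficiency. Arterial transit time is not modeled at all (single-delay
data cannot estimate it); quantified CBF is therefore flow confounded
with transit-time effects, exactly as in any single-delay acquisition.

## 2. Partial-volume correction by local regression

A pCASL voxel (here 3.5×3.5×8 mm) mixes GM, WM and CSF. With tissue
posterior probabilities $p_t$ from structural segmentation, the static
signal model is $\text{control} = \sum_t p_t m_t$ and the difference
signal is $\text{diff} = p_{GM}\,dm_{GM} + p_{WM}\,dm_{WM}$ (CSF is not
perfused). `pvec_correct()`:

1. averages the 60 control frames and the 60 pair differences
   (mean-then-regress; for OLS, regressing per pair and averaging gives
   the same expectation, and mean-first is faster and deterministic);
2. builds the brain mask as $\sum_t p_t \ge 0.30$;
3. at each masked voxel solves a no-intercept OLS of the windowed image
   values on the windowed probabilities over a 7×7×1 kernel, truncated
   at volume edges and restricted to masked voxels. No intercept: the
   mixture model has none, and a free intercept would absorb tissue
   signal.

The implementation accumulates the normal-equation sums with a
moving-window box filter (algebraically identical to per-voxel design
matrices; a brute-force per-voxel solver is kept in the test suite as the
independent oracle, agreement to $10^{-8}$). Where the window is
rank-deficient or ill-conditioned (condition number $>10^6$, e.g. pure-GM
neighborhoods) or has fewer masked voxels than regressors + 1, the
minimum-norm solution is stored and the voxel is flagged `valid = 0`;
downstream ROI means use valid voxels only, so such neighborhoods cannot
bias them. Negative coefficients are kept by default (clipping is an
option) to preserve unbiasedness of ROI means. `quantify_volume()` guards
the ratio $dm_t/m_t$ with a magnetization floor ($10^{-6}$ of the median
masked $|m_t|$): undefined voxels become `NA`, never infinities.

## 3. The digital phantom

`build_probmaps()` is a stand-in for structural segmentation: a
concentric head (WM core, GM band, CSF rim, empty background) per slice,
indicator maps blurred by a Gaussian (SD 1.2 voxels by default), plus a
seeded smooth perturbation redistributing GM/WM mass. This produces what
the PVEc regression needs exercised: pure-GM, pure-WM and mixed windows,
i.e. both well- and ill-conditioned designs, with $\sum_t p_t \le 1$
everywhere. `perfusion_truth()` sets $f_{GM} = 60$, $f_{WM} = 20$
ml·100g$^{-1}$·min$^{-1}$ (textbook resting values) and multiplies GM
flow by `asymmetry_factor` (default 0.9) in the occluded hemisphere,
giving a relative deficit comparable to the ~8–9% hemispheric asymmetry
seen in carotid occlusive disease. `build_roi_atlas()` places
mirror-symmetric M1 (anterior, slices 10–11) and V1 (posterior, lower
slices) GM masks with equal left/right voxel counts, mirroring the
equal ROI volumes reported for such cohorts.

One modeling consequence worth stating: flow is constant within each
hemisphere but steps at the midline, so regression windows straddling the
midline are locally misspecified and voxelwise exactness of the noiseless
round trip holds away from a 7-voxel midline band (and everywhere when
`asymmetry_factor = 1`). ROI means that include near-midline columns are
pulled slightly toward the contralateral level (the phantom's measured
M1 occluded/unoccluded ratio is ≈0.92 for a true 0.90).

## 4. Noise level and what "bias" means here

Noise is i.i.d. Gaussian per voxel per frame on both control and label
images (`noise_sd = 5`, i.e. 5% of GM $M_0$; the per-pair difference then
has SD $5\sqrt2$, verified by simulation in the tests). The GM difference
signal at the M1 slices is only ~0.6% of $M_0$, so the per-voxel,
per-run `dm_GM` estimate carries ~20% median error, and because
neighboring 7×7×1 windows share most of their data, ROI means average
few effectively independent estimates: a single simulated acquisition
yields ROI-mean GM CBF with roughly 20% spread. Per-voxel OLS on
noiseless-regressor designs is exactly unbiased, and we verify the
near-zero bias numerically by averaging the ROI-mean relative error over
simulation seeds (16 seeds × 4 ROIs in the acceptance test, 12 × 4 in the
acceptance script) rather than trusting any single run.

## 5. The synthetic cohort

`simulate_cohort()` generates the tabular side of the study with a known
effect structure at the defaults (`cohort_sim_config()`):

- n = 28 subjects, ages uniform on 50–93; hypertension prevalence 21/28,
  diabetes 6/28, complete occlusion 14/28, collateral status
  15 cross-filling / 6 none / 7 unknown;
- unoccluded-side GM CBF ~ Normal(115.2, 15) in M1 and Normal(112.8, 15)
  in V1; occluded side = unoccluded − offset (9.7 in M1, 6.4 in V1) +
  Normal(0, 9). The side-noise SD of 9 makes the probability of
  occluded-lower asymmetry $\Phi(9.7/9) \approx 0.86$, the observed
  asymmetry-direction rate in the cohorts this emulates;
- M1 thickness $= \beta_0 + 0.0045\,\text{CBF} - 0.0044\,\text{age} +
  \varepsilon$, $\varepsilon \sim$ Normal(0, 0.12) per side, anchored at
  mean 2.15 mm; V1 thickness has both coefficients zero (mean 1.79 mm),
  so any downstream V1 association is a false positive by construction.
  These coefficients were chosen once so the per-side population
  correlations are $r(\text{CBF}, \text{thickness}) \approx 0.45$–$0.50$
  and $r(\text{age}, \text{thickness}) \approx -0.35$, the effect sizes
  typical of this literature;
- hemispheral CBF is the per-side M1/V1 average plus noise; WMH volumes
  are log-normal and independent of thickness (null covariates).

Age and CBF are generated independently, and thickness noise is
independent across sides. Two realistic features are deliberately absent:
an age–CBF correlation (which in real cohorts shrinks the standardized
CBF coefficient below the univariate $r$) and a shared subject-level
thickness component (which in real data makes the paired thickness
comparison far more sensitive than per-side-independent noise allows).
Both would add parameters the emulated structure does not pin down;
their absence means the generator's paired-thickness p-values and
standardized betas are systematically milder than real-data ones, and
tests on the generator cannot validate those two aspects against real
data.

## 6. Statistics

- `paired_t()`: classical paired t, two-sided, $n-1$ df, Bonferroni flag
  at $0.05/2 = 0.025$ for the two regions tested per measure. Identical
  vectors return $t = 0, p = 1$; zero-variance non-zero differences are a
  degenerate-input error. `asymmetry_count()` uses strict inequality —
  ties count against the expected direction (conservative).
- `pearson()` / `variable_screen()`: product-moment $r$ with $t$-based
  two-sided p; candidates enter the multivariable model when $p \le 0.05$
  (inclusive, so a boundary candidate enters). Constant inputs raise an
  error rather than silently yielding `NaN`.
- `fit_ols_standardized()`: OLS on z-scored variables, so coefficients
  are standardized betas (scale-invariant); collinear designs (condition
  number $>10^8$) are an error naming the columns.
- `fit_gee()` / `fit_gee_thickness()`: marginal Gaussian model with
  identity link on the two-rows-per-subject long table, exchangeable
  working correlation estimated by moments, iterated GLS, and robust
  sandwich SEs with normal-reference p-values. This GEE is implemented in
  the package (iterated GLS is a page of linear algebra) and is
  cross-checked in the tests against OLS (independence reduction) and
  against `nlme::gls` with the correlation fixed at the estimated value.
  Working-correlation choice: with clusters of size two, exchangeable is
  the only non-trivial stationary choice; independence is available for
  the reduction test. The "unknown" collateral status is a third factor
  level rather than an exclusion, preserving the full cohort in the GEE.
  With only 28 clusters, sandwich SEs are known to be slightly liberal;
  we keep the standard estimator and note it.
- Missing-data policy: rows missing ASL-derived fields are flagged on
  read (`asl_missing`) and excluded per analysis (complete case), never
  dropped at I/O time.

## 7. What the tests establish, and problem sizes

The suite checks, among others: exact noiseless recovery of
magnetizations, difference components, and both flow maps
($<10^{-6}$ relative, 32×32×12 phantom, 60 pairs); PVEc equality with a
brute-force OLS oracle ($10^{-8}$); the closed-form paired-t/Pearson/
standardized-OLS oracles ($10^{-8}$); seed determinism everywhere; and
the qualitative association pattern (GEE: CBF and age predict M1
thickness, neither predicts V1) across independently seeded 28-subject
cohorts. That pattern is a conjunction of powered tests and 5%-level
null tests, so its per-seed reproduction rate is structurally capped
near ~75–80% at these effect sizes — the acceptance suite reports the
measured rate; a per-seed rate above 95% is not attainable at n = 28
without inflating the generating effects beyond the emulated ones.
Simulation sizes (32×32×12 voxels, 12–16 noise seeds, 60–100 cohort
seeds) were chosen as the smallest that make the Monte-Carlo error
clearly smaller than the tolerances being checked.

## 8. Known limitations

- Single-delay quantification: transit-time effects are inseparable from
  flow; the phantom does not simulate vascular artifacts, motion, or
  distortion.
- The phantom's midline flow step makes near-midline PVEc locally
  misspecified (§3); real deficits are spatially graded.
- The GEE has no small-sample SE correction (§6).
- The `.sav` cohort dialect (for deposited SPSS tables) shares its
  validation and name-mapping path with the CSV dialect, but no SPSS
  writer exists in the test environment, so that branch is exercised only
  through the mapping machinery on CSV fixtures.
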