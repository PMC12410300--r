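---
title: "Image-derived blood normalization for antibody PET: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-derived blood normalization for antibody PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petbloodnorm)
```

## The quantification problem

Antibody radiotracers clear slowly. At a late imaging time point (on the
order of 20 h after injection) the activity concentration in any tissue is
well approximated by two additive components: tracer still circulating in
the tissue's blood volume, and tracer specifically bound to its target.
Between animals, the circulating component varies substantially —
clearance rate, blood volume and organ function all differ — while the
injected dose is known exactly. Dividing by injected dose (%ID/g) therefore
removes none of the blood-level variability; dividing by the animal's own
blood concentration at scan time removes it at the source, and additionally
cancels the blood-borne component's contribution to group differences.
When the control group lacks the target entirely, its blood level is even
systematically *higher* (no target sink), which under %ID/g normalization
shows up as spurious negative group differences in blood-rich,
low-expression organs.

The package estimates the blood concentration from the image itself, so no
terminal blood draw is needed once the method is established: a voxelwise
regression against ex vivo blood measurements (available in the
method-development cohort) defines which voxels track blood, and the mean
over those voxels serves as the per-subject blood level.

## The voxelwise model

For subject $i$ and voxel $v$, the blood-VOI derivation fits

$$y_{iv} = \alpha_v + \beta_v b_i + \varepsilon_{iv},$$

where $b_i$ is the ex vivo blood radioactivity (Bq/g) and
$t_v = \hat\beta_v / \mathrm{SE}(\hat\beta_v)$ with $n-2$ degrees of
freedom. Group contrasts use the pooled-variance two-sample t with
$n_A+n_B-2$ degrees of freedom, positive where group A exceeds group B.
Both maps are computed in closed form, vectorized across the masked
voxels; the test suite checks them against independent scalar per-voxel
oracles at relative tolerance 1e-10.

Thresholding follows the standard uncorrected-p + cluster-extent
convention: voxels with $t$ above the one-sided critical value at
$p$ form connected components (6-, 18- or 26-neighborhood; default 18),
and components strictly larger than `min_size` voxels survive. Defaults
are $p = 0.005$, extent $> 50$ for the blood VOI and $p = 0.05$,
extent $> 50$ for contrast maps. The strict inequality ("more than 50
voxels") is deliberate and parameterized, so the $\ge$ convention is one
argument away.

### Sidedness and numerical edge cases

- The blood-VOI regression is one-sided positive: we seek voxels whose
  uptake *increases* with blood level. Group contrasts are one-sided per
  direction (A &gt; B), matching the directional-contrast convention of
  voxelwise analysis packages; testing the opposite direction means
  swapping the groups, which negates the map exactly.
- Voxels with zero variance across subjects get $t = 0$ and a flag rather
  than being dropped, so map geometry is stable across thresholds.
- Voxels with an *exact* linear fit (zero residual, nonzero slope) arise
  in noiseless simulations; their $t$ is infinite and is clamped to a
  large finite sentinel (1e10) with a flag, preserving the finiteness
  invariant of t-maps without disturbing thresholding.
- No spatial smoothing is applied before the GLM by default; an optional
  Gaussian pre-smoothing argument exists. No grand-mean scaling or global
  normalization happens inside the GLM — normalization is explicit and
  upstream.

## Units and conversions

Volumes carry an explicit unit tag (`Bq/mL`, `Bq/g`, `ratio`, `%ID/g`,
`t_value`, `label`) and every operation checks and propagates it; implicit
coercion is an error. PET activity images are Bq/mL; gamma-counter blood
measurements are Bq/g. The two are made commensurate by dividing image
values by the whole-blood density 1.057 g/mL, applied exactly once when a
blood level is extracted and once in each normalization:

- blood ratio: $(\mathrm{Bq/mL} / 1.057) / \mathrm{blood}_{\mathrm{Bq/g}}$
  — by construction the normalized image averages exactly 1 over its
  defining VOI;
- %ID/g: $(\mathrm{Bq/mL} / 1.057) / \mathrm{dose_{Bq}} \times 100$.

No radioactive-decay correction is applied anywhere: inputs are assumed
decay-corrected to a common reference by the scanner, as is standard for
reconstructed PET.

Voxel indices are 1-based (the R convention) throughout; world coordinates
are millimetres with voxel $(i,j,k)$ at $((i-1)d_x,(j-1)d_y,(k-1)d_z)$,
matching the NIfTI affine the package writes. All cross-subject analyses
require pre-aligned grids; registration is out of scope, so inputs must
share shape and spacing (enforced at load time).

## The digital-mouse phantom

No public dataset exists for this design, so the package ships a
first-class simulator. The atlas places 13 regions (heart blood pool,
myocardium, infarct, carotid, lung, liver, spleen, bone, bone marrow,
cortex, hippocampus, white matter, background) as ellipsoids, shells and
cylinders in anatomically plausible positions; each carries a blood volume
fraction (1 for whole-blood regions) and a target-expression score.

The generative model per subject $i$ and region $r$ is

$$\mathrm{tissue}_{ir} = f_r B_i \;+\; s_g\, e_r\, \mathrm{ID}_i u,
\qquad
B_i = b_0\, \mathrm{ID}_i\, L_i\, m_g,$$

with $f_r$ the blood volume fraction, $e_r$ the expression score,
$s_g \ge 0$ the group binding scale (0 = knockout), $m_g$ the group blood
multiplier, $L_i$ a unit-mean lognormal clearance factor, and $u = 1$ the
expression-to-uptake coupling. The Bq/g map is converted to Bq/mL with the
1.057 density factor, blurred with a separable Gaussian PSF, and Gaussian
noise with SD $= \mathrm{noise\_scale}\sqrt{\max(\mathrm{signal}, 1)}$
(a reconstruction-domain Poisson surrogate) is added. The simulated ex
vivo measurement is $B_i(1 + \mathcal N(0, cv_{\mathrm{assay}}))$.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| design | 11 vs 11, WT vs knockout | the whole-body study design the method targets |
| dose | 34 MBq mean, CV 0.18 | typical injected activities for this tracer class |
| `clearance_cv` | 0.25 | makes %ID normalization visibly confounded by blood variability — the condition under which blood normalization pays off |
| `psf_sigma_mm` | 0.8 | typical small-animal PET resolution; partial volume/spill-over is modeled solely by this blur |
| `noise_scale` | 30 | puts voxel noise at a few percent of organ signal after blur, subordinate to inter-subject variability as in well-counted late static scans |
| `blood_assay_cv` | 0.05 | gamma counting is precise; most error is sample weighing |
| knockout blood multiplier | 1.15 | knockouts lack the target sink, so blood runs modestly higher; kept small enough that group blood differences stay non-significant at n = 11 |
| `base_blood_frac_per_g` | 0.03 g⁻¹ | blood near 3 %ID/g at 20 h, realistic for a slowly clearing antibody |

Expression scores are in units of fractional injected dose per gram
(so $u = 1$); they are chosen once such that specific wild-type uptake is
of the same order as each organ's blood-borne component (0.3–1.5×), which
is the antibody-tracer regime: liver and bone marrow highest, lung and
spleen low, infarct highest of all, blood and background zero. Inter-region
*ratios* are what matter downstream.

The simulator is deterministic given its seed; two calls with the same
spec are bit-identical.

### What the phantom does and does not emulate

It reproduces the statistical structure the analysis assumes —
inter-individual blood variability, genotype-dependent binding, partial
volume, signal-proportional noise — and that is all the validation suite
can show. It does *not* emulate: biological per-organ variability
uncorrelated with blood (every subject's tissue is an exact function of
$B_i$ and $\mathrm{ID}_i$ plus noise), excretion routes (the real liver
signal is partly excretion), soluble-target binding in plasma, anatomical
variation between animals (all subjects share one atlas), or sinogram-level
physics (attenuation, scatter, motion). A practical consequence: because
blood and dose are the only subject-level factors, *every* tissue voxel
correlates with blood, so the data-driven suprathreshold set is one large
connected component spanning the body rather than a sparse vascular tree.
The cluster-seed option (select the component containing a heart or
carotid seed) is therefore the default route in the pipeline, and
absolute agreement slopes of the cluster VOI against ex vivo blood are
diluted by partial-volume voxels — correlation (R²) is the meaningful
agreement readout on phantom data, and the manually positioned heart
sphere is the better absolute estimator.

## The ideal limit and what the tests assert

With zero noise, zero blur and an exact assay, voxels of whole-blood
regions equal $B_i \times 1.057$ Bq/mL exactly. The carotid — surrounded
by background, hence immune to myocardial spill — then survives
thresholding as an isolated pure-blood cluster, and the seed-restricted
VOI recovers true blood with slope 1, intercept 0 and R² = 1 to machine
precision. This exactness is asserted in the acceptance suite. The heart
blood pool cannot serve here because it is anatomically adjacent to the
(also suprathreshold) myocardium — the same spill-in argument that
motivates carotid segmentation in infarct imaging.

Under default noise and blur, the acceptance suite asserts the two
qualitative properties the method stands on, each over 20 simulation
seeds:

- the image-derived blood level tracks true blood with R² ≥ 0.9 in at
  least 18 of 20 seeds;
- the mean peak T over liver and bone marrow in the WT-vs-knockout
  contrast is higher under blood normalization than under %ID
  normalization in at least 18 of 20 seeds.

A permutation check asserts the monotonicity of the thresholding chain:
random relabelings of the pooled cohort never yield more surviving
clusters at p = 0.005 than at p = 0.05 (extent > 50 in both).

Problem sizes used by the test and acceptance code: 24×24×48 to 32×32×64
grids at 0.6–0.8 mm for simulated cohorts and 48×48×96 at 0.5 mm for the
ideal-limit analysis, where the carotid must exceed the 50-voxel extent
threshold at its anatomical proportions.

## Agreement statistics

`linear_fit` (OLS with t-based 95% CI), `pearson` (with the
$t = r\sqrt{(n-2)/(1-r^2)}$ two-sided p), and `bland_altman`. Differences
in the Bland–Altman statistic are `reference − test`, chosen so that a
positive bias reads as "the image underestimates the reference", the
direction partial-volume effects produce. The mean-of-methods axis is
returned for plotting but is not part of the statistic. CIs are
parametric; no bootstrap.

## Design choices that were genuinely open

- **Mean vs peak within VOIs**: blood levels use the arithmetic mean
  (standard VOI reporting); organ summaries report both mean and peak T,
  with mean as the headline.
- **Union vs seeded cluster** for the data-driven blood VOI: union is the
  default of `derive_blood_voi` (the whole vascular tree); the pipeline
  seeds at the heart blood pool centroid, which matches how a data-driven
  heart VOI is used in practice and behaves better on phantom data (see
  above).
- **Density correction direction**: images (Bq/mL) are divided by
  1.057 g/mL to meet gamma-counter units (Bq/g); only this direction makes
  the two methods commensurate.
- **Connectivity 18** by default (the convention of the major voxelwise
  analysis package), 6 and 26 selectable.
- **Dose distribution**: lognormal with the specified mean and CV
  (positivity guaranteed); only mean and CV are meaningful at these CVs.
- **Command surface**: the package exposes R functions
  (`simulate_cohort_to_dir`, `run_pipeline`, `pipeline_config`, YAML
  config via `pipeline_config_from_yaml`) rather than a shell executable;
  an R analysis package's users work from R, and the functions compose.

## Known limitations

- Cross-subject analysis requires a common grid; no registration or
  resampling is provided.
- The GLM is the two-parameter simple regression / two-sample family; no
  covariates of no interest (age, weight) beyond what the user regresses
  out beforehand.
- Cluster-level inference is uncorrected-p + extent only; no familywise
  or FDR correction is claimed, matching the descriptive use of these
  maps.
- NIfTI carries no unit metadata, so unit tags must be supplied when
  reading volumes from disk (the manifest workflow does this
  automatically).
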