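---
title: "Functional connectivity strength mapping: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional connectivity strength mapping: models, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcstrength)
```

# The analysis this package implements

Resting-state fMRI studies of cervical spondylotic myelopathy (CSM) ask how
chronic spinal cord compression reorganises the cortical sensory-motor
network (SMN). One way to quantify that reorganisation is **functional
connectivity strength (FCS)** — the weighted degree centrality of each voxel
in the voxel-level functional network:

$$k(i) \;=\; \sum_{j \ne i,\; r_{ij} > r_0} r_{ij},$$

where $r_{ij}$ is the Pearson correlation between the band-passed,
noise-regressed time series of voxels $i$ and $j$ inside the analysis mask,
and $r_0$ is a connection threshold that removes weak and negative
correlations. Each subject's map is divided by its own global mean $k_0$
over the mask, so maps average exactly 1 and are comparable across subjects,
then standardised for group comparison. Group differences are tested with a
voxel-wise GLM (a two-group ANCOVA with age and sex as covariates; with two
groups the ANCOVA $F$ and the group-indicator $t$ satisfy $t^2 = F$, so the
post-hoc two-sample $t$ is read directly off the GLM). Multiple comparisons
are handled by Monte Carlo **cluster-extent** correction: only contiguous
supra-threshold clusters at least as large as a simulated critical size
$k_\mathrm{crit}$ are declared significant. Regions that survive are then
used two ways: their mean normalised FCS is correlated with clinical scores
(JOA myelopathy score, Neck Disability Index, cervical-cord fractional
anisotropy) controlling for age and sex with Bonferroni correction, and
their peaks seed a spherical-ROI resting-state connectivity (rsFC) analysis
whose group networks, union mask, contrast and cluster correction follow the
same machinery.

Because no patient imaging data are available, the package is organised
around a **synthetic cohort generator with planted ground truth**: every
stage of the pipeline is validated by recovering structure the generator is
known to contain.

# The synthetic cohort

`cohort_spec()` describes a two-group study emulating the cohort design this
analysis family targets: 31 patients and 31 controls, 230 retained volumes
at TR = 2 s, a 3-mm isotropic grid. The default grid is 24 x 24 x 18 voxels
with a box-shaped 1,568-voxel analysis mask standing in for an SMN template,
containing six 4 x 4 x 4 ROI blocks placed in the mask corners. Corner
placement is deliberate: the 6-mm smoothing kernel spreads each block's
signal into a halo, and at a mask corner most of that halo falls outside the
mask and is clipped, which keeps planted effects spatially compact. The
corner vertically adjacent to the first ROI is left empty for the same
reason.

Each subject's image is built as follows:

* **Latent ROI signals.** White Gaussian series are restricted to the
  0.01–0.08 Hz band by DFT bin selection — the same bins the preprocessing
  filter retains, so planted structure passes through the pipeline's
  band-pass essentially unchanged — and mixed through the symmetric matrix
  square root of the subject's ROI correlation matrix. A matrix that is not
  positive semi-definite is rejected with the offending eigenvalue named.
* **Subject variability.** A per-subject factor $f \sim N(1, 0.12)$ scales
  the off-diagonal of the group's ROI matrix, giving the between-subject
  connectivity variation that the clinical link needs.
* **Voxel noise.** Independent Gaussian noise (`noise_sd`, default 0.5) is
  added to ROI voxels; non-ROI voxels receive variance-matched noise.
* **Nuisance structure.** Two global confound series (white-matter- and
  CSF-like, band-limited, amplitude 0.4) and a motion-coupled component
  (random-walk translations and rotations, step 0.02 mm / 0.02 degrees per
  volume, coupling 0.1) are added everywhere; the true series are emitted as
  the subject's nuisance table so regression can remove exactly what was
  injected.

The planted group difference is focal: in the patient group the first ROI's
correlations with every other ROI drop from 0.50 to 0.15. After attenuation
by voxel noise, 0.15 sits well below the reference connection threshold
$r_0 = 0.25$ while 0.50 sits well above it, so the patient group loses that
ROI's cross-ROI contribution to $k$ entirely — a strong, localised FCS
decrease. Division by $k_0$ makes the unaffected ROIs rise slightly in
normalised units and the background rise a little as well, so the synthetic
contrast reproduces the qualitative pattern of focal decreases coexisting
with diffuse increases.

Clinical scores are linear in the subject's **planted strength** (the
analytic normalised FCS of the linked ROI under that subject's ROI matrix)
plus Gaussian noise, parameterised by a target correlation: JOA
11.45 ± 2.45 with link 0.6, NDI 0.316 ± 0.114 with link −0.3, C2-level FA
0.613 ± 0.050 with link 0.35 in patients; controls sit at the JOA ceiling
of 17 with FA 0.673 ± 0.052. Ages are drawn at 51.4 ± 6.3 / 50.9 ± 6.3
years, sex is fixed at 22 male / 9 female per group, and the two symptom
indicators are planted as exact counts (12/31 and 20/31), so the cohort's
categorical summaries are reproduced exactly. A link of 0.6 gives roughly
93% power for a two-sided test at $n = 31$, comfortably above the 80%
recovery rate the validation suite demands over repeated cohorts.

What the generator does **not** emulate: hemodynamic response shapes,
scanner drift or spike artifacts, anatomy (the mask is a box, the ROIs are
blocks), spatial normalisation error, and genuinely distance-dependent
noise correlation. Passing tests therefore demonstrate that the pipeline's
statistics behave correctly on data with known correlation structure — not
that the pipeline is robust to every artifact of real acquisitions.

# Preprocessing choices

Stages run in the order smoothing → temporal filtering → nuisance
regression (configurable; the filtering-versus-regression order debate is
noted, not resolved — each stage is linear, so the suite checks
composability directly).

* **Motion QC** reads the exclusion limits strictly: a subject fails only
  when a translation exceeds 2 mm or a rotation exceeds 2.0 degrees;
  boundary values pass. Rotations are compared in raw degrees, without
  conversion to arc length at an assumed head radius.
* **Smoothing** is a separable Gaussian with
  $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis in mm (6 mm → 2.548 mm),
  honouring anisotropic voxel sizes, with reflective boundaries so constant
  images are unchanged and kernel mass is conserved.
* **Band-pass** is an ideal DFT-bin filter (the convention of the REST
  toolbox family) rather than an IIR design. One subtlety: "detrend, then
  select bins" composed literally is not idempotent, because in-band Fourier
  vectors are not orthogonal to a linear trend. The filter is therefore
  implemented as the exact orthogonal projection onto the intersection of
  the in-band span and the trend complement — bin selection followed by
  removal of the band-limited component of the trend. The output is
  band-limited, mean- and trend-free, and applying the filter twice equals
  applying it once to machine precision.
* **Nuisance regression** fits an intercept plus the eight regressors
  (white matter, CSF, six motion parameters) per voxel by OLS; a
  rank-deficient design is rejected naming the collinear columns.

# FCS mapping

`voxel_fcs()` computes $k$ in column blocks of the correlation matrix, so
memory stays flat for large masks; the suite proves block-size invariance
against dense thresholded row sums at $10^{-10}$. Voxels whose variance does
not exceed `min_variance` are removed from the valid set entirely (not
zeroed), keeping $k_0$ meaningful; their count is recorded on the map
object. Negative correlations never contribute (the threshold is one-sided
above $r_0 > 0$) and self-connections are excluded.

For the group-comparison transform, the default mode is map-wise
z-standardisation — the convention of the degree-centrality toolchain this
package follows. A literal Fisher $\operatorname{atanh}$ mode exists but is
guarded: normalised FCS averages 1, so values at or above 1 are
mathematically outside the domain of $\operatorname{atanh}$ and the literal
mode errors with a pointer to the z-score mode. One consequence of the
subject-wise standardisation worth knowing: it is scale-free per subject, so
a planted decrease is recoverable only while it perturbs a small share of
the map's distribution (the default design affects one ROI of six), and
between-subject variation in overall connectivity is deliberately damped —
which also attenuates clinical associations measured on pipeline output
relative to the planted link (see below).

The threshold sweep (`fcs_sweep()`, $r_0 = 0.10$–$0.40$ in steps of 0.05)
exists because the choice of $r_0$ is conventional; the suite checks that
the spatial pattern of normalised FCS is rank-stable (Spearman > 0.9)
between adjacent thresholds on synthetic cohorts. At 230 retained volumes
the reference $r_0 = 0.25$ corresponds to a per-connection two-tailed
$p \approx 1.3 \times 10^{-4}$, below the 0.001 significance convention —
`r_to_p()` makes that correspondence explicit.

# Seed-based rsFC

Seed spheres take the stated 8-mm **diameter** literally (radius 4 mm; at
3-mm voxels that is the centre plus its six face neighbours). Much of the
literature quotes a radius instead; the diameter is a parameter, not an
assumption. Correlations are clipped to $\pm(1 - 10^{-7})$ before
$\operatorname{atanh}$ so self-correlated voxels stay finite. Group
networks keep voxels with *positive* one-sample $t$ surviving both a
voxel-wise $p < 0.001$ screen and Benjamini–Hochberg FDR at $q < 0.001$;
the source convention's pairing of "cluster-wise FDR" language with
voxel-level thresholds is ambiguous, and this voxel-level reading is the
interpretation adopted. The two group networks are combined by union into
the comparison mask.

# Monte Carlo cluster-extent correction

The correction re-implements the classic simulation recipe from scratch:
per iteration, an iid Gaussian field on the mask bounding box is smoothed at
the assumed FWHM, restricted to the mask, thresholded at the z quantile of
the voxel-level $p$ (two-sided by default, matching the two-tailed group
contrasts; the historic one-sided mode is available), and the maximum
cluster size under the `rmm` neighbourhood is recorded. The critical size
at corrected level $\alpha$ is the smallest $k$ whose exceedance fraction
is at most $\alpha$. The `rmm = 5` mm radius at 3-mm voxels yields the
18-neighbourhood — faces (3.0 mm) and edges (4.24 mm) connect, corners
(5.196 mm) do not.

Two numerical choices deserve emphasis:

* **Voxel-wise field standardisation.** Reflective-boundary smoothing
  leaves edge voxels of the bounding box with more than twice the interior
  standard deviation. A single global rescaling would concentrate null
  exceedances at mask edges — where clusters clip small — and underestimate
  $k_\mathrm{crit}$. The null field is therefore standardised voxel-wise
  using the exact per-voxel variance of the smoothing operator (the product
  over axes of the kernel-matrix row sums of squares), which matches the
  pointwise self-normalisation of the $t$ statistic the null stands in for.
* **Signed labelling.** Positive and negative excursions are labelled
  separately, in the null and in the real contrast alike, so
  opposite-signed voxels never merge into one cluster.

`fwer_calibration()` closes the loop: it estimates $k_\mathrm{crit}$ for a
mask, then simulates hundreds of null two-group cohorts and runs the full
covariate-adjusted contrast plus cluster thresholding on each, reporting
the fraction of replicates with any surviving cluster. The null cohorts are
simulated **at the map level** — each subject receives an independent
smoothed, voxel-wise standardised Gaussian field. This is the group-level
extension of the correction's own null model, and it is what makes hundreds
of replicates tractable (regenerating and preprocessing full 4D cohorts per
replicate would cost roughly three orders of magnitude more). The
calibration therefore tests the inferential chain (GLM → $t$ → threshold →
clusters → extent rule) under the smoothness the correction assumes, not
the BOLD generator itself; the generator's own recovery properties are
tested separately at full scale. A residual mild over-rejection (empirical
rates slightly above the nominal 0.05) is expected and observed: the
single-field null cannot capture the extra spatial coherence a group $t$
field inherits from its smooth variance-estimate denominator, a
well-documented property of cluster-extent inference at lenient
voxel-level thresholds. The acceptance script reports the empirical rate
as computed.

# Validation problem sizes

The suite exercises the defaults where the property being checked requires
them and reduced sizes elsewhere, as the package's own choices: unit tests
use 12–14-voxel grids with three to six ROI blocks and full-length
(230-volume) series wherever FCS structure matters, because shorter series
leave too few in-band DFT bins for $r_0 = 0.25$ to separate planted from
incidental correlations; the study-scale recovery test runs the complete
default cohort (31 + 31 subjects) once; link-recovery rates use 50 repeated
clinical draws at $n = 31$; the family-wise calibration uses 200–400 null
replicates with a 1000-iteration critical-size estimate.

# Known limitations

* The clinical link is planted on ground-truth strength; associations
  measured on pipeline output are attenuated by the global-mean
  normalisation and map standardisation, so the package demonstrates link
  *recovery* with the planted strength and treats measured-level
  associations descriptively.
* Cluster-extent correction calibrates mildly above nominal for group $t$
  contrasts (see above); users wanting exact control should treat the
  reported critical sizes as lower bounds.
* The generator's idealisations (box mask, block ROIs, white noise, exact
  band-limited signals) mean the suite cannot speak to registration error,
  physiological noise spectra, or anatomy-dependent smoothness.
* Smoothness for the correction is taken as configured (the applied kernel),
  not estimated from residuals.
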