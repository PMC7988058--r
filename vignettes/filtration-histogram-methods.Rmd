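---
title: "Filtration-histogram CT texture analysis and its prognostic evaluation"
author: "filtrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filtration-histogram CT texture analysis and its prognostic evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filtrad)
```

## The method

Filtration-histogram texture analysis characterises a CT lesion in two
steps. First, every axial slice is passed through a Laplacian-of-Gaussian
(LoG) band-pass filter whose spatial scale filter (SSF) parameter, in mm,
selects the approximate size of the image structures that survive
filtration: SSF 2 is conventionally called *fine*, 3--4 *medium*, 5--6
*coarse* texture, and SSF 0 means no filtration at all. Second, the filtered
(or raw, at SSF 0) intensities of all voxels inside the segmented volume of
interest (VOI) are pooled into a single histogram, and six first-order
statistics are read off it: mean, standard deviation, entropy, kurtosis,
skewness, and the mean of positive pixels (MPP) --- the average of the
strictly positive values only, which isolates the brightness of the
structures the filter highlighted from the dark background they sit in. A
standard run uses the six scales {0, 2, 3, 4, 5, 6} mm, i.e. 36 features
per lesion.

These features are then evaluated as prognostic biomarkers with the chain
clinical studies in this area use: ROC analysis of each feature against a
binary progression label (screening at p < 0.05), an optimal-threshold
Kaplan--Meier split with a log-rank test for overall and progression-free
survival, and univariate Cox proportional-hazards regression with the
feature as a continuous covariate.

## The LoG kernel and its conventions

The widely used commercial implementation of this method does not publish
its SSF-to-kernel mapping, so two conventions had to be fixed here; both are
exposed as parameters so alternatives can be swapped in.

**SSF to sigma.** SSF is read as the approximate *diameter* (in mm) of the
structures to highlight. The LoG response to a Gaussian blob is maximal when
the blob's radius is $\sigma\sqrt{2}$, which gives
$\sigma_{mm} = \mathrm{SSF} / (2\sqrt{2})$ (`sigma_per_ssf` in
`build_log_kernel()`). One consequence worth stating plainly: because the
true mapping is unpublished, absolute feature values --- and therefore
published cut-offs such as an MPP threshold of 56.22 HU --- cannot be
expected to transfer numerically between implementations. Directions of
effect, scale orderings and the statistical machinery do transfer.

**Normalisation.** Coefficients are the sign-inverted, scale-normalised LoG
sampled in physical mm on a square support of half-width
$\lceil 4\,\sigma_{px}\rceil$ pixels:

$$ w(u,v) \;\propto\; \frac{p_r\,p_c}{\sigma^2}\,
   \Big(1 - \frac{u^2+v^2}{2\sigma^2}\Big)\,
   e^{-(u^2+v^2)/2\sigma^2}, $$

with $p_r, p_c$ the pixel spacings. The $1/\sigma^2$ scale normalisation
makes the discrete sum approximate the continuous scale-normalised response,
which buys two properties the tests verify: a Gaussian blob of matched size
produces the maximal response across scales (so fine filters really do
prefer fine structure), and filtering the same anatomy sampled at 0.7 mm or
1.0 mm pixels gives responses agreeing within a few percent. The
sign inversion makes bright structures yield positive responses, so MPP
reads as "average brightness of highlighted structures". After sampling,
the mean is subtracted so the coefficients sum to exactly zero and uniform
regions filter to zero (up to round-off; a constant 50 HU slice leaves
residuals below $10^{-12}$ HU, which is why features of an exactly constant
lesion report MPP as a $10^{-13}$-scale number rather than as missing).

**Boundary and geometry.** Filtration is strictly 2D per axial slice,
matching the in-plane filtration step of the original method; pooling
across slices happens only at the histogram stage. Each slice is filtered
*whole* and the mask is applied afterwards, so lesion-edge voxels see
genuine image context instead of a cropped border. Slice borders use
mirror (reflect) padding; lesions are interior structures, so this choice
is second-order. Anisotropic pixels are handled by sampling the kernel in
mm. The correlation is evaluated by FFT on the reflect-padded slice, which
is exact to round-off (verified against a nested-loop oracle at $10^{-10}$
relative) and fast enough that a full 36-feature extraction of a lesion
takes tens of milliseconds.

## Feature definitions and the missing-value policy

For a pooled sample $x_1,\dots,x_n$ with central moments $m_k$:
mean is arithmetic; SD uses the $n-1$ denominator (0 when $n = 1$);
skewness is the biased ratio $m_3/m_2^{3/2}$ and kurtosis the *excess*
$m_4/m_2^2 - 3$ (a normal histogram scores 0 --- reported cut-offs for
kurtosis straddle zero, which raw Pearson kurtosis cannot do); entropy is
Shannon entropy in bits of the normalised histogram over 256 equal-width
bins spanning the sample's own [min, max] (0 for a constant sample); MPP is
the mean of values strictly greater than zero. The 256-bin base-2
convention is not documented by the commercial tool either, so both knobs
are parameters (`entropy_bins`, `sd_denominator`).

Whatever is undefined stays an explicit `NA`, never a silent zero: MPP with
no positive values, and both shape moments on zero-variance samples.

Whether voxels should be pooled volumetrically per lesion or features
computed per slice and averaged is not documented by the reference tool;
volumetric pooling is the default here and the per-slice average is
available as `pooling = "slice_mean"`, without any claim that it reproduces
a particular tool's behaviour.

## The statistics chain

**ROC.** AUC uses the rank (Mann--Whitney) identity with half credit for
ties, which equals the trapezoidal area under the empirical ROC curve
exactly. If the raw AUC is below 0.5, the reported direction flips to "low
values indicate the positive class" and the AUC is reported as its
complement. The cut-off maximises Youden's J over observed values, ties
broken toward higher specificity, and subjects *at* the cut-off fall on the
low side, matching the "$\le$ cut-off" reporting convention. The p-value
against AUC = 0.5 comes from the tie-corrected normal approximation to the
Mann--Whitney statistic --- adequate for univariate screening and simple to
verify; DeLong's variance could be added but is not required for a screen.

**Kaplan--Meier and log-rank.** Textbook product-limit estimator and 1-df
log-rank with hypergeometric variance, both verified to machine precision
against independent implementations and hand tallies, with the log-rank
test's type-I error simulated at nominal level.

**Optimal cut-off.** The threshold grid is the midpoints between
consecutive sorted unique feature values, subject to both groups keeping at
least 10% of subjects (configurable), and the returned threshold minimises
the log-rank p-value. Two honesty notes are built into the result object.
First, the p-value is flagged *exploratory* in the output: a searched
minimum is optimistically biased relative to a pre-specified split, no
multiplicity adjustment is applied (mirroring the exploratory stance such
studies state), and the suite demonstrates the bias by comparison with a
median split on null data. Second, for perfectly ordered data the log-rank
statistic is typically maximised by an *extreme* admissible split, not the
balanced one --- a known instability of minimum-p cut-point selection that
users should expect to see. Exact ties in p are broken toward the lowest
threshold.

**Cox.** Single-covariate partial likelihood maximised by Newton--Raphson
with step-halving; tied event times (inevitable with day-granular
follow-up) use Efron's correction, which dominates Breslow's in accuracy.
Convergence requires the score to fall below `tol` (default $10^{-8}$)
relative to the observed information, the form that rule has to take for
covariates measured in raw HU units where the information is of order
$10^3$ and the double-precision score plateau sits above any absolute
$10^{-8}$. A log-hazard exceeding 10 per covariate standard deviation is
treated as a monotone likelihood (perfect separation): the score also
vanishes in the flat tail of a monotone partial likelihood, so divergence
must be detected on the coefficient scale; the coefficient is capped there
and the fit flagged `converged = FALSE` rather than silently returned.
Estimates, standard errors and Efron handling agree with
`survival::coxph()` to $10^{-7}$ on tied data.

**OS/PFS conventions.** Both clocks start at first drug administration;
patients alive (or progression-free) at the end of follow-up are censored.
The Cox covariate is continuous, the natural reading of a per-unit hazard
ratio.

## The synthetic cohort generator

No imaging from the motivating study is deposited, so the package ships a
generator that stands in for the cohort: it is first-class, tested code,
not a fixture.

**Phantoms.** A lesion is an ellipsoid (a sphere in mm) centred in the
grid: lesion voxels carry a mean enhancement plus a stationary Gaussian
texture field (white noise smoothed to a controllable correlation length,
rescaled to a controllable amplitude) plus white acquisition noise;
background voxels carry a soft-tissue level plus noise. Defaults emulate a
contrast-enhanced chest CT at 1.25 mm reconstruction: 20 mm lesion, 60 HU
lesion mean over a 20 HU surround, 15 HU texture at 3 mm correlation
length, 5 HU noise.

**Outcomes.** Each patient's event time is exponential with hazard
$h_0 \exp(\beta \cdot \mathrm{MPP}_i)$, where $\mathrm{MPP}_i$ is the
*true* MPP measured on the noiseless-pipeline side at a reference scale of
3 mm (a medium filter). Defaults: $\beta = -0.117$ per MPP unit (hazard
ratio $\approx 0.89$, higher MPP protective) and $h_0 = 0.043$/day, chosen
so a lesion at the cohort-typical true MPP of about 24 has a *latent*
median survival near 270 days (observed medians are shorter, since uniform
censoring truncates follow-up). Censoring is independent uniform on $[0, \tau]$ with $\tau$
calibrated by root-finding so the expected censoring fraction matches the
target (default 0.57, about 43% deaths); the realised fraction is verified
within $\pm 0.1$ at $n \ge 200$. PFS is a fixed fraction of the OS time
(default 0.45, putting median PFS near 120 days) with its own event flag
--- a deterministic coupling, not a multistate model, because the pipeline
only needs ordered correlated endpoints with PFS $\le$ OS. The progression
label is "progression observed by 180 days". Times are rounded up to whole
days to produce the ties real follow-up data has.

**Reproducibility.** One master seed; per-patient substreams come from a
stable hash of (seed, patient index), so cohorts are bit-reproducible and
patients could be generated in any order.

**What the generator does not model** --- and hence what passing tests do
not show about real data: lung anatomy and air-tissue interfaces,
respiratory motion, scanner reconstruction kernels and dose, inter-reader
segmentation variability, non-stationary tumour biology (necrosis, hypoxia
gradients), and any mechanistic link between texture and outcome beyond the
imposed exponential hazard. Pipeline-level claims verified on this cohort
are directional and statistical, never claims about clinical effect sizes.

## Problem sizes and numerical tolerances used by the test suite

The suite checks filter output against a brute-force correlation oracle on
100 random 32x32 slices (relative $10^{-10}$), feature formulas on 200
random samples up to $n = 10^4$ (relative $10^{-10}$), log-rank size with
1000 null replicates of 30 + 30 subjects, Cox recovery of $\beta = -0.117$
with 200 replicates of 200 subjects at 40% censoring (bias within 0.03,
Wald coverage within (0.90, 0.99)), and the end-to-end direction of effect
on 50 replicate cohorts of 200 patients with compact phantom grids
(14x40x40 at 2.5x1x1 mm) so a full replicate costs seconds. The packaged
demo config uses 12 patients and reruns byte-identically.

## Known limitations

Absolute feature values depend on the unpublished SSF-to-sigma convention
and entropy binning of the reference tool, so published cut-off values are
not numerically transferable (directions and orderings are). Only
first-order features are implemented --- no co-occurrence or run-length
statistics, no 3D filtration, and no full IBSI compliance. The cut-point
search is deliberately left unadjusted for multiplicity and labelled
exploratory. DICOM support covers uncompressed little-endian single-frame
CT series only; RTSTRUCT contours and registration are out of scope, and
masks must be voxel-aligned to their volumes.
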