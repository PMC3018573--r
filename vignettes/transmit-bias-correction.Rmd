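---
title: "Estimating and removing transmit-field bias in variable flip-angle R1 maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and removing transmit-field bias in variable flip-angle R1 maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(unicort)
```

## The model

Variable flip-angle (VFA) R1 mapping estimates the longitudinal relaxation
rate from two spoiled gradient-echo volumes, a PDw image ($S_1$, low flip
angle) and a T1w image ($S_2$, high flip angle).  In the small-angle,
short-TR regime the Ernst signal
$S = PD\,\sin\alpha\,(1-E)/(1-\cos\alpha\,E)$, $E = e^{-TR \cdot R1}$, is
well approximated by the rational form
$S \approx PD\,\alpha\,TR\,R1/(\alpha^2/2 + TR\,R1)$, which the two-point
estimator implemented in `r1AppMap()` inverts exactly:

$$R1_{app} = \frac{1}{2}\,
  \frac{S_2\alpha_2/TR_2 - S_1\alpha_1/TR_1}{S_1/\alpha_1 - S_2/\alpha_2}.$$

Receive-coil sensitivity cancels in this ratio; transmit (B1⁺)
inhomogeneity does not.  Writing $\psi$ for the ratio of the local to the
nominal flip angle, both signals are acquired at $\psi\alpha_n$, and under
the rational model the estimate is biased exactly multiplicatively:
$R1_{app} = R1/\psi^2$.  Since $\psi$ varies smoothly over the head at 3 T
(deviations up to roughly 30%, a central brightening plus a weaker
left–right asymmetry), $R1_{app}$ is the true map times a smooth
multiplicative field $\eta = 1/\psi^2$.

`fitBiasField()` estimates $\eta$ from the masked $R1_{app}$ map alone.
The generative model assumes head voxels fall into four classes — GM, WM,
CSF and non-brain tissue — whose corrected intensities follow a mixture of
Gaussians (several components per class), while the log of the bias field
is a linear combination of separable low-frequency cosine (DCT-II-type)
basis functions over the mask bounding box.  With $\beta_i = 1/\eta(x_i)$
the penalized log-likelihood is

$$\sum_i \Big[\log \sum_k w_k\, N(\beta_i y_i;\, \mu_k, \sigma_k^2)
  + \log \beta_i\Big] \;-\; \kappa N_{vox}\, \Omega(c),$$

where the $\log\beta_i$ term is the change-of-variables Jacobian of
treating the bias as a data correction, and $\Omega$ is the bending energy
of the log-bias.  The corrected map and the intrinsic transmit-field
estimate follow algebraically: $R1_{corr} = R1_{app}/\eta$ and
$\psi_{est} = 1/\sqrt\eta$.

Two assumptions matter in practice.  First, the tissue classes must be
separable in intensity — the method fails on data whose class distributions
collapse.  Second, the overall scale of $\eta$ is not identifiable from the
likelihood (a constant bias trades exactly against the mixture means), so
the constant basis coefficient is fixed by the scanner-calibration
assumption that the *mean* flip angle over the head equals the nominal one:
after convergence the constant term is shifted so
$\mathrm{mean}(1/\sqrt\eta) = 1$ over the fitted voxels, and `runUnicort()`
re-anchors the same constant over the full head mask so that
$\mathrm{mean}(\psi_{est}\,|\,\mathrm{head}) = 1$ exactly.

## Tunable parameters

* `fwhm` (mm, default 60): the shortest spatial period the bias basis can
  represent.  The per-axis basis count is
  $n_k = \max(1, \lfloor 2L_k/\mathrm{fwhm}\rfloor + 1)$ with $L_k$ the
  mask bounding-box extent in mm — a Nyquist-style cutoff, so
  `fwhm` $\geq 2L$ leaves only the constant.  Smaller values buy
  flexibility at the price of overfitting anatomy into the field.
* `kappa` (dimensionless, default $10^{-3}$): weight of the bending-energy
  penalty, scaled by the number of fitted voxels.  $\kappa \to \infty$
  forces a flat field (no correction); very small values admit rough,
  overfitted fields.  The defaults are the operating point found optimal
  for 3 T brain data; at other field strengths, with other coils, or for
  fields rougher than a body-coil transmit pattern both should be
  re-optimized, e.g. with `gridSearch()` on a phantom emulating the
  acquisition.
* `nPerClass` (GM 2, WM 2, CSF 2, other 3): Gaussian components per class.
  Brain classes are reasonably unimodal on phantom data; the non-brain
  class is deliberately richer because it pools scalp, skull and partial
  volumes.  The counts are configurable; results on well-separated data
  are insensitive to moderate changes.
* `maxIter` (64) and `tol` ($10^{-5}$ relative): the outer loop stops when
  the penalized objective stalls or the iteration budget is exhausted.
* Acquisition parameters are taken in console units (degrees,
  milliseconds) by `acquisitionParams()` and stored in radians and seconds,
  the only units in which the estimator is dimensionally consistent.

## The synthetic-data generator

`generatePhantom()` provides ground-truthed inputs in place of acquired
data.  It emulates: a nested-ellipsoid head (outer non-brain shell, CSF
layer, GM cortex, WM core; presets add enlarged ventricles or an off-centre
CSF cyst), literature-typical 3 T tissue parameters (R1 in 1/s: WM 1.18,
GM 0.77, CSF 0.25, other 0.50; relative PD: WM 0.70, GM 0.80, CSF 1.00,
other 0.90), Ernst-equation signals at the validated protocol (PDw
TR 23.7 ms/6°, T1w 18.7 ms/20°), and a transmit field built from a centred
Gaussian-shaped bump (peak deviation `b1PeakDeviation`, default 0.25) plus
a left–right linear tilt (`b1Asymmetry`, default 0.05), both zero-mean over
the head and renormalized so $\mathrm{mean}(\psi) = 1$ exactly.  Optional
noise is additive Gaussian with $\sigma = \mathrm{mean(head\ signal)}/SNR$
per volume (a Rician flag exists for stress tests; at the high SNR of the
protocol the Gaussian approximation is adequate).  The generator is a pure
function of its spec: identical specs give bitwise-identical volumes.

What it does *not* emulate — real cortical folding and partial-volume
mixing, within-class R1 dispersion, imperfect RF spoiling, k-space/EPI
artifacts, slice profiles, and registration error between the two
acquisitions.  Passing tests on the phantom therefore demonstrate that the
estimator and the bias model are implemented correctly and recover known
smooth fields under the stated conditions; they do not by themselves
establish accuracy on acquired data, where within-class dispersion and
anatomy–field interactions set the attainable floor.

The sign convention follows the estimator algebra: $R1_{app} = R1/\psi^2$,
so a central transmit *excess* ($\psi > 1$) depresses apparent R1 centrally.
The phantom's field polarity is configurable (`b1Sign`) for users who wish
to emulate the opposite pattern.

## Numerical choices

* **Penalty form and scale.**  $\Omega$ is the thin-plate bending energy of
  the log-bias — the integral over the mask bounding box of all squared
  second derivatives — computed analytically from the basis frequencies
  (the cosine basis diagonalizes it).  Lengths are measured in units of
  100 mm, i.e. head scale, which makes $\kappa$ dimensionless and places
  the interesting regime in the $10^{-5}$–$10^{-1}$ decades: at the default
  $\kappa = 10^{-3}$ the penalty on a realistic field is orders of
  magnitude below the likelihood gain of correcting it, while at
  $\kappa = 10^{-1}$ it overwhelms that gain and the fitted field stays
  essentially flat.  The absolute correspondence with any particular
  segmentation package's internal regularization scale is not claimed.
* **Optimization.**  Outer iterations alternate (a) EM sweeps on the
  mixture until its log-likelihood stalls, (b) up to eight Gauss–Newton
  coefficient updates, each solved matrix-free by diagonally preconditioned
  conjugate gradients (the Hessian-vector product uses the separable basis
  transforms) and safeguarded by a step-halving line search, and (c) an
  over-relaxation probe along the net coefficient displacement of the
  iteration, accepted only if it improves the objective.  Every accepted
  move is non-decreasing, so the objective trace is monotone by
  construction (asserted in the fit result's validity).
* **Initialization and determinism.**  The mixture starts from fixed
  quantiles of the masked $R1_{app}$ distribution (CSF low, GM middle, WM
  high, non-brain spread), equal weights, variances from the inter-quantile
  spread.  There is no randomness anywhere in the fit; reruns are
  bit-identical.
* **Degenerate inputs.**  Voxels where the estimator's denominator
  vanishes or the estimate leaves $[0, 10]$ 1/s are zeroed and excluded
  from the likelihood via the validity mask (noise can drive the algebraic
  estimator anywhere).  Component variances are floored at $10^{-6}$ times
  the data variance; component weights at $10^{-10}$.  Constant images,
  empty masks and masks below 1000 voxels raise errors rather than
  producing silent nonsense.
* **Head mask.**  The PDw intensities are histogrammed into 256 equal-width
  bins on $[0, \max]$; the threshold is five times the centre of the modal
  bin and the mask keeps voxels strictly above it, optionally pruned to the
  largest 6-connected component.  The modal bin is searched over the full
  histogram including the lowest bin: on acquired data the modal bin is the
  background-noise peak either way, while on noiseless synthetic data the
  zero-background bin *is* the mode and yields a threshold that separates
  background from head exactly.  Excluding the lowest bin — tempting to
  guard against zero-filled voxels — would instead put the mode on tissue
  and empty the mask on clean data.
* **Mixture bookkeeping.**  EM can make component means cross; components
  are relabelled to keep means sorted within class (a pure relabelling,
  invisible to the likelihood).  After the final calibration shift the
  mixture means and variances are rescaled to the corrected intensity
  scale, so the reported mixture describes the corrected map.
* **Iteration budget.**  On noiseless phantoms the bias field plateaus
  within a few tens of iterations, but the objective keeps creeping as
  redundant mixture components slowly exchange weight; runs then end at the
  64-iteration cap with `converged = FALSE` and a fully usable field.  The
  flag reports the optimizer's state honestly rather than papering over it.

## Design decisions

* **No deformable registration or spatial tissue priors.**  Mixing
  proportions are stationary scalars.  The component exercised and
  validated here is bias estimation; spatial priors mainly sharpen the
  *segmentation*, and on phantom geometry the intensity model alone
  separates the classes.  This is the main structural simplification
  relative to full unified segmentation.
* **Bias as data correction.**  The bias enters as $\beta_i y_i$ with the
  $+\log\beta_i$ Jacobian term, the generative convention that makes the
  mean/variance M-steps closed-form on corrected data.
* **Calibration convention.**  Unit mean of $\psi$ (not zero-mean
  log-bias) over the head, because that is the physical statement the
  scanner's transmitter adjustment makes.
* **Aggregation.**  The symmetric deviation $D = 2(a-b)/(a+b)$ is reported
  as the median of $|D|$ in percent; a `signed` flag exists.  R1 aggregates
  use the brain mask (GM+WM+CSF posterior > 0.5 within the head mask),
  B1⁺ aggregates the head mask.
* **Problem sizes.**  The package's validation runs use a 64³ lattice at
  3 mm (192 mm field of view) for the reference phantom and single-run
  checks, and the same field of view on coarser lattices — 48³ at 4 mm for
  the atypical-anatomy presets, 40³ at 4.8 mm (with a 32-iteration cap)
  for the 5×5 κ × FWHM grid — where many pipeline runs are tabulated.
  The physical field-of-view is kept fixed because the basis counts and
  penalty depend on extents in mm, not on voxel counts.

## Known limitations

* The rational-approximation residual (under 3% over R1 ∈ [0.2, 2] 1/s at
  the default protocol) is inherited by the corrected map; it is not a
  bias-field error and a measured-B1⁺ correction shares it.
* Fields rougher than the basis cutoff (e.g. surface-coil transmit
  patterns, very high field strengths) violate the smoothness assumption;
  lowering `fwhm` helps only as far as the segmentation stays stable.
* Severe anatomy (large lesions, resections) can break the mixture model
  and with it the concomitant bias estimate; inspect the segmentation
  posteriors when in doubt.
* The histogram head mask assumes a background/foreground intensity gap;
  pre-masked or cropped data should supply their own mask via the `mask`
  argument of `runUnicort()`.
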