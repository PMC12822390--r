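---
title: "Methods: correlative Brillouin-Raman analysis of spheroids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlative Brillouin-Raman analysis of spheroids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brmspheroid)
```

This vignette documents the physical model behind `brmspheroid`, the
numerical choices made in each stage, and the assumptions and limits of
the synthetic-data generator used for validation.

## 1. The measurement model

A Brillouin spectrometer probing a spheroid voxel records inelastic
scattering from acoustic phonons. The spectral density of a single damped
acoustic mode is the damped harmonic oscillator (DHO):

$$ I(\nu) \;=\; B + A\,\frac{\Gamma\,\omega_B^2}
{\left(\nu^2-\omega_B^2\right)^2 + \Gamma^2\nu^2}, $$

which is even in $\nu$ and therefore produces a symmetric Stokes /
anti-Stokes doublet at $\pm\omega_B$ once the frequency axis is centered
on the elastic line. The shift $\omega_B$ reports the longitudinal
modulus at GHz frequencies; the linewidth $\Gamma$ reports the acoustic
loss.

A voxel at the spheroid scale is not a pure material: it averages cells
and extracellular matrix (ECM). When the component shifts are closer than
roughly a quarter linewidth, the composite spectrum is experimentally
indistinguishable from a single DHO whose fitted shift is the
volume-fraction-weighted mean of the component shifts:

$$ \omega_B \;=\; \omega_{cell}\,\Phi_{cell} +
\omega_{ECM}\,\Phi_{ECM}, \qquad \Phi_{cell}+\Phi_{ECM}=1.
\tag{Eq. 1} $$

`forward_omega()` and `invert_omega_ecm()` / `invert_omega_cell()`
implement this mixture and its inversions; the linearization itself is a
tested property of the fitting code, not an assumption (see the
two-component sweep in the test suite: for separations
$\le \Gamma/4$ the single-DHO fit matches Eq. 1 within 0.02 GHz).

## 2. Brillouin fitting protocol

`fit_brillouin()` runs the full protocol on a two-sided spectrum:

1. **Peak location.** Each side is scanned for its most prominent local
   maximum outside the elastic-line exclusion zone ($|\nu| < 2$ GHz by
   default). Prominence is measured against the robust noise level
   (median absolute deviation of the high-frequency residual), so flat or
   pathological spectra fail loudly instead of "fitting" noise.
2. **Symmetry calibration.** Stokes and anti-Stokes sides are fitted
   separately with one-sided DHO models that carry a free axis-offset
   parameter. Half the fitted asymmetry is the axis miscalibration; if it
   exceeds 0.01 GHz the axis is recentered (offsets beyond 0.5 GHz are
   treated as gross miscalibration and raise an error rather than being
   silently "corrected").
3. **Joint fit.** A single two-sided DHO (parameters $A$, $B$,
   $\omega_B$, $\Gamma$) is fitted to all points outside the exclusion
   zone with Levenberg-Marquardt (`minpack.lm::nls.lm`), with seeded
   multistart restarts if the first attempt fails to converge. Standard
   errors come from the residual variance and the local curvature.

Numerical notes: the fit is exactly scale-equivariant (intensity
rescaling moves only $A$ and $B$) and shift-equivariant after
recentering; a warning is raised when $\Gamma$ pins at its lower bound or
when the fitted separation approaches $\Gamma/4$, where Eq. 1 starts to
lose validity.

## 3. Raman composition chain

The high-wavenumber window (2400-4000 cm$^{-1}$) contains the CH stretch
band (2800-3020 cm$^{-1}$, organic/dry matter) and the OH stretch band
(3020-3700 cm$^{-1}$, water). The processing order matters and is fixed:

1. **Fluorescence baseline.** A smoothing spline is fitted through two
   anchor regions that contain no bands (2600-2750 and 3750-3900
   cm$^{-1}$) and subtracted. Anchors overlapping an integration window
   raise an error; large anchor residuals raise a warning.
2. **Factor optimization and PDMS subtraction.** The chip's PDMS doublet
   (2905/2965 cm$^{-1}$) leaks into the CH window. See §4 for how the
   subtraction factors are determined. The scaled PDMS reference is
   subtracted.
3. **OH integration.** $A_{OH}$ is integrated *before* medium
   subtraction, because the medium reference is itself an OH band: the
   subtraction in the next step removes the *entire* OH contribution
   (the spheroid's own water included), isolating CH. $A_{OH}$ therefore
   measures all water in the probed volume, which is exactly what the
   biphasic model needs.
4. **Medium subtraction and CH integration.** The scaled medium
   reference is subtracted and $A_{CH}$ is integrated on the isolated CH
   band. Trapezoidal integration with a zero floor is used throughout.

Consequence for the "true" factors: the optimal PDMS factor equals the
PDMS contamination level, but the optimal medium factor is the
contamination level *plus* the sample's own OH amplitude relative to the
medium reference. The synthetic generator records both
(`alpha_pdms_true`, `alpha_medium_true`) and recovery is tested against
these.

## 4. Design of `optimize_factors()`

Matching the sample's CH area to an off-chip reference spectrum with a
single scalar criterion cannot determine two factors
$(\alpha_{PDMS}, \alpha_{medium})$, and enforcing it exactly per sample
would clamp every sample's CH area to the reference's, erasing the
composition differences between conditions that the study is about. The
implemented objective is a shape-based least squares:

- in the OH window, the residual after medium subtraction (pins
  $\alpha_{medium}$, since nothing else has OH intensity there);
- in the CH window, the residual against the reference CH *shape* with a
  free amplitude (pins $\alpha_{PDMS}$, because PDMS's doublet shape is
  distinct from the biological CH envelope, while leaving each sample's
  dry-mass amplitude free).

Because both factors and the free CH amplitude enter linearly, the
optimum has a closed form; `optimize_factors()` solves it by QR and
accepts the solution when it is inside the $[0, 2]$ bounds, falling back
to a seeded multistart bounded L-BFGS-B search otherwise. The closed
form makes the resulting CH/OH ratio exactly invariant under global
intensity rescaling (tested to $10^{-9}$). The CH-area agreement with
the reference is still reported (`ch_area_mismatch`) as the diagnostic
the area-matching criterion intended.

## 5. Biphasic composition model

Cells are roughly 70% water / 30% dry matter by volume
($w_{cell} = 0.70$); the interstitial ECM is predominantly aqueous
($w_{ECM} = 1.0$) because collagen at the mg/ml scale contributes
negligible dry volume. With $d_{cell} = 1 - w_{cell}$, the measured
CH/OH area ratio of a voxel is

$$ R \;=\; \kappa\,
\frac{d_{cell}\,\Phi_{cell}}
{w_{cell}\,\Phi_{cell} + w_{ECM}\,\Phi_{ECM}}, $$

where $\kappa$ absorbs the relative Raman cross sections and
instrumental response of the CH and OH bands. $\kappa$ is not assumed:
`calibrate_kappa()` determines it from a reference measurement of known
composition — compressed spheroids, whose interstitial space is squeezed
out ($\Phi_{ECM} = 0$), give $\kappa = R_{ref}\, w_{cell}/d_{cell}$.
Inverting for $\Phi_{ECM}$ is closed-form (`estimate_phi()`), with a
first-order standard error, a small-negative clamp for estimates within
sampling error of zero, and hard errors for ratios incompatible with the
model. Fractions below 0.02 are treated as negligible
(`is_negligible_ecm()`), and Eq.-1 inversion refuses to divide by
fractions that small (`phi_min`), where it is ill-conditioned.

Note a deliberate robustness property of the calibration: multiplicative
biases common to sample and reference (objective, laser power, band
windows) cancel in $R/\kappa$. Additive contamination does not cancel
exactly — medium OH leakage inflates $A_{OH}$ slightly more in
ECM-rich samples than in the compressed reference — which is why
end-to-end recovery at the default contamination level is specified at
the two-percentage-point tolerance rather than the noiseless one.

## 6. Morphometry

Nuclear label images are summarized by the moment-equivalent ellipse
(`nucleus_shapes()`, via `EBImage::computeFeatures`); the aspect ratio
is major/minor axis with minor $= \text{major}\sqrt{1-e^2}$. Zones are
assigned by Euclidean distance from the spheroid boundary
(`EBImage::distmap`; centroids within `band` pixels of the boundary are
"periphery"). Marker positivity normalizes intensities to the control
mean and thresholds at control mean $+ k\,\mathrm{SD}$ ($k = 2$).
Invasion is quantified as (total $-$ core)/core area on binary masks,
which is resolution-invariant by construction. All of these have
analytic oracles in the test suite (disk, axis-aligned and rotated
ellipses, annuli, two-population mixtures).

## 7. The synthetic generator: realism and limits

`make_brillouin()` renders the two-component DHO mixture plus an elastic
Lorentzian tail and a flat background, with Poisson counting noise whose
peak signal-to-noise is `noise_snr` (counts scaled so that
$\sqrt{\text{peak counts}} = \mathrm{SNR}$). `make_raman()` builds the
CH envelope (three Gaussians), the OH band (two Gaussians), PDMS and
medium contamination, and a cubic fluorescence pedestal, with Gaussian
noise. `make_nuclei_image()`, `make_invasion_masks()`,
`make_marker_intensities()` and `make_dextran_image()` provide
morphometry fixtures with recorded ground truth; `make_dataset()` writes
a complete on-disk tree (spectra, references, truth sidecars, manifest).

Default parameters and their rationale:

- $\omega_{cell}$: control 8.20 GHz, ROCK-inhibited 8.10 (softened
  cortex), RhoA-activated 8.28, cyclic-compression 8.30; $\omega_{ECM}$
  8.00 GHz (dilute collagen is nearly water-like); $\Gamma$ 1.2 GHz
  (1.5 for RhoA). The cell-ECM separation (0.2 GHz) is well under
  $\Gamma/4 = 0.3$, so Eq. 1 applies.
- $\Phi_{ECM}$: 0.15 control, 0.24 ROCK, 0 compressed.
- `noise_snr = 50`: a realistic per-voxel acquisition.
- Contamination `pdms_level = medium_level = 0.2`: modest confocal
  leakage of chip and medium signal into the probed volume. These are
  artifact-model choices, deliberately nonzero so the subtraction stages
  are exercised, and deliberately moderate so that their known residual
  bias (see §5) stays within the study's reporting tolerance.

Limits, stated plainly: the generator is a validation instrument, not an
instrument simulator. It does not model detector nonlinearity, cosmic
spikes, spectrometer drift within an acquisition, spatial maps (each
"sample" is one voxel-average spectrum), or real collagen Raman
signatures; band shapes are Gaussian idealizations and finite
integration windows clip a few percent of their tails (tests compare
like with like where that matters). Conclusions about real instruments
require real calibration data.

## 8. Problem sizes and runtime

Spectra are ~800 points; a full Brillouin protocol fit takes ~15 ms and
a full Raman chain ~5 ms, so the 20-sample recovery studies and the
whole test suite run in seconds on one CPU. Statistical comparisons
(`compare_groups()`) gate on Shapiro-Wilk normality ($\alpha = 0.05$)
and use Student's t / Mann-Whitney for two groups, ANOVA with Tukey or
Dunnett (`multcomp`) for more.

## 9. Reproducibility

Every stochastic routine takes an explicit integer seed, restores the
caller's RNG state, and derives per-sample seeds deterministically from
a master seed, so a dataset is a pure function of its seed:
`make_dataset()` trees are byte-identical across runs. `run_pipeline()`
echoes its full effective configuration (plus the package version) next
to its outputs.
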