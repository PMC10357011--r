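---
title: "The ospra measurement chain: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ospra measurement chain: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ospra)
```

## What this package models

`ospra` is a hardware-free implementation of the measurement chain of a
low-cost spectroradiometer built around a 288-photosite CMOS line sensor,
a 10-bit ADC and a servo-driven shutter head with closed, radiance and
irradiance apertures. The instrument class targets sensory-ecology and
light-pollution work: spectral radiance and irradiance from daylight down
to night-time levels, with photometric summaries (luminance in cd m⁻²,
illuminance in lux).

Everything downstream of the photons is implemented: dark-frame
subtraction, exposure planning, count linearisation, spectral-sensitivity
calibration, cosine-corrector evaluation, radiometric conversion,
low-light dark-offset correction and photometry. Upstream of that sits a
generative sensor simulator, so that every processing stage can be tested
as a round trip against a known ground truth instead of against hardware.

## The sensor model

A `sensor_config()` describes one simulated unit. The ADC offers 1024
linear levels, of which the sensor's output voltage range makes roughly
900 usable; counts at or above this ceiling are saturated and
underestimate flux, so 900 counts is both the saturation flag threshold
and the instrument's theoretical single-exposure dynamic range (900:1).
Wavelength is mapped from photosite index by a degree-5 polynomial
(shorter coefficient vectors are zero-padded); the default spans roughly
320–850 nm with mild curvature. A photosite's spectral bin width
$B_p$ is the midpoint difference of its neighbours' wavelengths
(one-sided at the ends), so that per-nm spectral densities convert to
per-bin energy by multiplication with $B$.

With the shutter open, the expected linear photo-signal at photosite $p$
for a scene $L(\lambda)$ and integration time $T$ (ms) is
$S_p \, L(\lambda_p) \, B_p \, T$ counts, where $S_p$ is the
responsivity (counts ms⁻¹ per spectral-flux unit per nm). The default
responsivity curve is a bilobed Gaussian peaking near 560 nm with about
two-thirds relative sensitivity at 320 nm and low near-infrared
sensitivity, emulating the combined optics/grating/CMOS response of this
sensor class. The count nonlinearity (below) is applied in the generative
direction, a stray-light pedestal (optional, off by default) proportional
to the band-summed signal is spread uniformly across photosites, and
noise is added: Poisson shot noise on the photo-signal, Gaussian dark and
read noise, then rounding to integer ADC counts and clipping to
[0, 1023]. The noise law is not part of the instrument's published
description (only that longer exposures are noisier); Poisson + Gaussian
is standard CMOS behaviour and is sufficient to exercise the averaging
logic. The stray pedestal is deliberately present only with the shutter
open, so closed-shutter darks cannot remove it — this reproduces the
low-light near-infrared artefact that the fixed dark-offset correction
targets.

Defaults chosen where the instrument description is silent: mean dark
level 30 counts, dark noise 1 count, read noise 0.5 counts, responsivity
scale 1000 counts ms⁻¹ per (W sr⁻¹ m⁻² nm⁻¹) nm. These put a desk-lamp
scene at convenient integration times (tens of ms to saturation) and are
fixed once here, not tuned per test.

## Acquisition

The controller averages up to 50 exposures per measurement; when 50
exposures would exceed 1 s in total, the count is reduced so that
$n \cdot T$ stays strictly under 1 s ("less than" is read strictly),
down to a minimum of 3. Each measurement is followed by an identical
shutter-closed regime, and the dark-subtracted counts are
$c_p = \bar{l}_p - \bar{d}_p$. Beyond 1 s integration, dark frames are
strictly alternated with light frames (the exact interleaving pattern is
not prescribed; strict alternation is the closest temporal matching).
Saturation is judged on raw light counts only — after subtraction it can
no longer be detected — and the number of saturated photosites travels
with every measurement.

Auto-exposure doubles a test exposure from the 1 ms minimum until any
photosite reaches the ceiling, then rescales the *preceding* unsaturated
exposure to put the peak at 0.8 of saturation:
$T = T_\text{last} \times 0.8 \times 900 / \text{peak}(T_\text{last})$,
clamped to [1 ms, 30 s]. The peak used for targeting is taken above the
dark mean estimate, while saturation detection uses raw counts. The
one-shot rescale is exact only when raw counts scale linearly with
integration time, which is why the default configuration models a
well-linearised sensor; with a strongly nonlinear response the rescale is
a first-order approximation, as it is in the firmware it emulates.

## Linearisation

The sensor responds almost linearly except at low counts, where counts
underestimate flux — precisely the regime that matters for night-time
measurements. Calibration ramps a stable broadband source (an AMOLED
screen on the bench) through one-octave integration steps from the
saturation point down to 1 ms and back up, sums the dark-subtracted
counts over the source's 380–780 nm emission band (inclusive endpoints),
and pairs each band sum with the expected linear rate $r \propto T$,
both axes scaled to max = 1. Saturated steps are excluded before
normalisation.

The response is modelled with the two-coefficient family

$$ r = f(c; a, b) = \frac{\log(1 + c^b / a)}{\log(1 + 1/a)}, \qquad a, b > 0. $$

The functional form is this package's own choice within the published
constraints on the correction's behaviour: it is strictly increasing,
tends to zero with vanishing slope as counts approach zero for $b > 1$
(so it does not amplify low-count noise the way gamma-variate or
log-linear corrections do, which also dive negative below one count), is
asymptotically log-linear in $c$, and is anchored at $f(1) = 1$ so that
fitting max-normalised data is exactly identifiable and invariant to the
overall count scale. In the large-$a$ limit the family reduces to the
power law $c^b$, so an identity response is representable
($a = 10^{12}, b = 1$) and a perfectly linear ramp fits as the identity.
The coefficients recommended for otherwise-uncalibrated units,
$a = 0.14231$, $b = 1.06125$, are interpreted in this parametrisation
throughout; every recovery test is a round trip through the same family,
so the results are self-consistent by construction.

Fitting is nonlinear least squares (Levenberg–Marquardt via
`minpack.lm`), with $a$ optimised on the log scale, started at the
recommended coefficients and falling back to a coarse multi-start grid.
A ramp must contribute at least 4 unsaturated observations spanning at
least 3 octaves.

Per-photosite linearisation applies the fitted response to counts
expressed as a fraction of the 900-count ceiling,
$c_\text{lin} = 900 \, f(c/900)$, keeping linearised counts on the raw
count scale. Negative dark-subtracted counts follow an odd extension
(sign switched, function applied, sign restored), so noise around zero
is never systematically amplified, and zero maps exactly to zero.

## Spectral sensitivity and radiometric conversion

Relative sensitivity divides the linearised count rate per nm by a
reference spectrum of known shape, resampled to photosite wavelengths by
linear interpolation (the instrument's ~9 nm resolution makes
higher-order interpolation immaterial), smooths with a Gaussian of
σ = 3 — in photosite-index units, the native grid — and rescales to
peak 1. Absolute calibration transfers units with a single least-squares
scalar from a measurement of a standard of known absolute spectrum;
because calibrated values scale as $1/S$, a brighter standard lowers the
scalar. Photosites below 2 % of peak sensitivity are excluded from the
scale fit (the spectral ends carry no information and much noise).

The radiometric conversion is
$\text{value}_p = c_{\text{lin},p} / (S_p \, T \, B_p)$, giving
W sr⁻¹ m⁻² nm⁻¹ (radiance sensitivity $S_r$) or W m⁻² nm⁻¹ (irradiance
sensitivity $S_i$). Negative values are retained, never clipped:
unfiltered noise statistics are exactly what makes post-hoc averaging of
low-light spectra honest. Raw counts are stored with every measurement,
so re-calibration after the fact is lossless and bit-exact.

For extreme low light, a fixed dark offset (0.5 counts radiance,
0.2 counts irradiance, configurable) compensates the stray-light
pedestal that closed-shutter darks cannot see. Relative spectral shape
across light levels is compared after scaling to unit area over
425–650 nm, using bin-width-weighted sums (not trapezoids) to stay
consistent with the bin semantics of the conversion; smoothing, when
applied, happens before area normalisation (the order is not prescribed
elsewhere; it is fixed and documented here).

## Cosine corrector and photometry

The irradiance port's diffuser is evaluated by sweeping a stable
narrowband LED from 0° to 80° in 10° steps and comparing the normalised
signal with cos θ. The simulator degrades an imperfect diffuser as
$q \cos\theta + (1-q)\cos^2\theta$, so the expected deviation-from-cosine
is the closed form $q + (1-q)\cos\theta$ — a known ground truth for the
evaluation code.

Luminance/illuminance integrate the spectrum against an analytic
photopic luminous-efficiency curve generated on each unit's own
wavelength grid (a bilobed-Gaussian approximation peaking at ~555 nm,
zero outside 360–830 nm) with $K_m = 683$ lm W⁻¹. Whether a
CIE-2006-adjusted efficacy constant should replace 683 is left
configurable; 683 is the default convention.

## What the simulator does and does not emulate

Emulated: ADC quantisation and clipping, the ~900-count usable range,
per-site dark level with Gaussian noise, Poisson shot noise, a
count nonlinearity identifiable with the calibration family, a
non-dark-correctable stray-light pedestal, shutter states, and
sub-Lambertian diffuser degradation. Not emulated: thermal drift and
voltage collapse beyond 30 s exposures, second-order diffraction from
strongly near-IR sources, servo mechanics and timing, real lamp spectra
(synthetic smooth references are used), and wavelength-calibration error.
Passing round-trip tests therefore demonstrate the correctness and
self-consistency of the processing chain, not field accuracy of any
physical unit; the published field floors (≈0.001 cd m⁻² radiance,
≈0.005 lx irradiance) depend on hardware and are out of scope here.

## Numerical choices and problem sizes

Degenerate inputs are rejected early with named diagnostics (empty bands,
non-monotone wavelength maps, zero in-band areas, missing CSV columns,
out-of-range angles and integration times). Gaussian smoothing uses a
discrete kernel of radius 4σ with symmetric-reflection boundaries.
CSV numerics are serialised with 17 significant digits, making every
round trip bit-exact. Exact-division edges in the scan-count rule back
off by one ("strictly under 1 s"), and ties in the auto-exposure
doubling stop at the first saturated test exposure.

The shipped tests and the acceptance script run entirely on simulated
data at desk scale: 1000-frame Monte-Carlo means, 150–200-repetition
averaging-law checks, and 100 replicate noisy ramp fits (octave steps,
1–128 ms, down-and-up), sizes chosen to give comfortable statistical
margins at interactive runtimes.

## A worked example

```{r example}
cfg <- sensor_config()            # a simulated, well-linearised unit
calib <- default_calibration(cfg) # calibration matching its ground truth
scene <- scene_amoled(0.005)      # a white AMOLED-like test scene

set.seed(1)
plan <- auto_expose(function(t) simulate_frame(scene, t, "radiance", cfg), cfg)
plan
cs <- acquire(scene, plan, cfg)
sp <- counts_to_spectrum(cs, calib, "radiance", label = "demo")
sp
lf <- luminosity_on_grid(wavelength_map(cfg$wavelength_coeffs, cfg$n_photosites))
luminance(sp, lf)   # cd m^-2
```

```{r plot, fig.width = 6, fig.height = 3.5}
plot(sp$lambda, sp$values, type = "l", xlab = "wavelength (nm)",
     ylab = expression(L[e] ~ (W ~ sr^-1 ~ m^-2 ~ nm^-1)),
     main = "Recovered spectral radiance of the simulated scene")
lines(sp$lambda, scene_value_at(scene, sp$lambda), col = 2, lty = 2)
legend("topright", c("recovered", "true scene"), col = 1:2, lty = 1:2, bty = "n")
```
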