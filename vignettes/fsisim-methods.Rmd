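---
title: "Methods: simulating structured-detection Fourier single-pixel imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating structured-detection Fourier single-pixel imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsisim)
```

## The measurement model

Fourier single-pixel imaging (FSI) forms an image without a pixelated
sensor. In the structured-detection variant simulated here, the image of
the scene is relayed onto a digital micromirror device (DMD), the DMD
displays a sequence of patterns, and a bucket detector (a photomultiplier)
integrates the modulated light into one scalar per pattern. Each Fourier
coefficient `F(u, v)` of the `M x N` scene `I` is probed with the three
phase-shifted sinusoidal patterns

```
P_phi(x, y; u, v) = 1/2 + 1/2 cos(2 pi u x / M + 2 pi v y / N + phi),
phi in {0, 2pi/3, 4pi/3},
```

giving responses `D_phi = sum_xy I(x, y) P_phi(x, y) + n` with a noise
term `n`. The three-step combination

```
F(u, v) = (2 D_0 - D_{2pi/3} - D_{4pi/3}) + sqrt(3) j (D_{2pi/3} - D_{4pi/3})
```

has weights `(2, -1, -1)` and `(0, 1, -1)` that each sum to zero, so any
offset common to a triplet — ambient light, detector pedestal — cancels
identically. Writing the bucket sums out shows the combination equals
`(3/2) sum_xy I(x, y) exp(-j 2 pi (u x / M + v y / N))`, i.e. 3/2 times
the unnormalized forward DFT coefficient. `assemble_spectrum()` divides
this factor out so spectra are directly comparable to `stats::fft()`
output, and `reconstruct_image()` applies the inverse DFT with `1/(M N)`
normalization. Unmeasured coefficients are zero-filled; no regularized or
learned completion is attempted.

Because the scene is real, the spectrum is Hermitian
(`F(-u, -v) = conj(F(u, v))`), so only one member of each conjugate pair
is acquired and its mirror is filled in by conjugation. Self-conjugate
cells (DC and the half-band frequencies on even-sized grids) must be real;
any imaginary part they acquire from noise is discarded at assembly.
`reconstruct_image()` verifies Hermitian symmetry and checks that the
imaginary residue of the inverse transform stays below `1e-9` of the image
peak before discarding it.

### Conventions fixed for bit-exactness

Several choices the measurement model leaves open are fixed once so that
results are deterministic and testable:

- **Coordinates.** Pixels and frequencies are 0-based; `x` indexes the
  `M` rows, `y` the `N` columns. This matches the DFT kernel used at
  reconstruction.
- **Conjugate canonical half-plane.** A coordinate `(u, v)` represents its
  pair when its column lies in the lower half-band (`v < N - v mod N`),
  with ties on the self-mirrored columns broken by `u <= M - u mod M`.
  Every pair, including self-conjugate points, has exactly one canonical
  representative.
- **Circular sampling.** Coefficients are ordered by the wrap-around
  ("centered") radius `r(u, v) = sqrt(min(u, M-u)^2 + min(v, N-v)^2)`,
  ties broken lexicographically by `(u, v)`. The plan for a smaller ratio
  is therefore an exact prefix of the plan for a larger one, which makes
  truncation experiments meaningful. Coverage counts a self-conjugate
  selection once and any other selection twice (itself plus its implied
  conjugate) against the `M N` total, the convention under which a ratio
  of 1 is exactly the full spectrum. Counting only displayed coefficients
  is available behind `count_conjugates = FALSE` for comparison with
  reports that use the other convention. DC has radius 0 and is always
  acquired first; the simulation acquires it like any other coefficient
  rather than estimating it separately.
- **Dithering.** Binary-modulator patterns are produced by
  Floyd–Steinberg error diffusion with the classic 7/16, 3/16, 5/16, 1/16
  kernel in a serpentine scan (left-to-right on even rows, right-to-left
  on odd rows), the common anti-streak choice; the kernel mirrors with the
  scan direction, diffusion error falling outside the grid is dropped, and
  a pixel turns on at accumulated value `>= 0.5`. The procedure is
  deterministic, idempotent on binary input, and conserves the pattern
  mean up to a border-leakage term bounded by `(M + N) / (M N)`.

## The virtual instrument

The instrument module synthesizes every scene used by the built-in
experiments, so nothing external is required.

- **Wire phantom (x-ray).** A straight absorbing cylinder of diameter
  0.4 mm (default) crossing the field on a uniform bright background.
  Transmission follows Beer–Lambert through the circular cross-section:
  at perpendicular distance `rho` the optical depth scales as the chord
  `sqrt(1 - (2 rho / d)^2)` of its center value (default 4.6, i.e. ~1%
  transmission through the center, appropriate for metal). Pixels are
  rendered by 4x4 Gauss–Legendre quadrature over the pixel footprint,
  giving the sub-pixel accuracy that resolution estimates need; a 10x
  supersampled rendering agrees within 1% in integrated absorption. The
  wire can be offset from the field center; a wire entirely outside the
  field degrades to a warning and a uniform background.
- **Dilution phantom (fluorescence).** Six circular wells on a dark
  background holding the serial 2x dilution 11.86, 5.93, 2.97, 1.48,
  0.74 nmol/ml and a pure-water blank, each filled at
  `gain x concentration` with linear-coverage antialiased rims. The
  default layout places the blank leftmost with concentration ascending to
  the right. Overlapping or out-of-field wells are configuration errors.
- **Depth phantom (fluorescence).** A 1 mm emissive stripe at depth `d`
  in a diffusive medium characterized by `mu_a = 0.03 cm^-1` and
  `mu_s' = 12.3 cm^-1`. No radiative-transport solver is warranted for a
  detectability experiment, so the depth dependence uses the
  diffusion-regime effective attenuation
  `mu_eff = sqrt(3 mu_a (mu_a + mu_s')) ~ 1.053 cm^-1`: the tube emission
  is scaled by `exp(-mu_eff d)` and, to emulate scattering broadening,
  spread laterally by a Gaussian of `sigma = 0.5 d` mm. The blur is
  normalized to conserve integrated emission, so depth reduces both the
  peak (attenuation and spreading) and the apparent sharpness, which is
  what makes deep tubes sink below the detection threshold.
- **Noise.** The single additive term `n` of the response model is split
  into the parts that matter for three-step phase shifting: an ambient
  offset constant across the three measurements of a triplet (held
  constant across the whole acquisition here — exactly the component the
  triplet weights cancel), independent zero-mean Gaussian read noise per
  measurement, and optional Poisson shot noise on the signal. Per-noise
  magnitudes are configuration, not claims about any physical detector.
  Seeded acquisitions are bit-reproducible.

The acquisition loop (pattern synthesis, optional dithering, bucket
summation over ~12k pixels for up to ~18k patterns per full acquisition)
is implemented in compiled code; a cosine rotation recurrence replaces
per-pixel trigonometric calls. Everything downstream is plain R on top of
`stats::fft`, `stats::lm` and `minpack.lm::nlsLM`.

## Evaluation procedures

- **Resolution.** `line_profile()` samples the reconstruction by bilinear
  interpolation at unit-pixel spacing perpendicular to the wire;
  `fit_gaussian_fwhm()` fits `A exp(-(t - mu)^2 / (2 sigma^2)) + b` by
  Levenberg–Marquardt least squares and reports
  `FWHM = 2 sqrt(2 ln 2) sigma x pitch` in mm. Initialization is
  deterministic: baseline = profile median, amplitude = extremum minus
  baseline, center = extremum location, sigma = half the width above half
  excursion. Dips and peaks are auto-detected by which polarity has the
  larger excursion from the median (an absorbing wire dips, so the negated
  profile is fitted). Flat profiles and non-convergent fits raise errors
  carrying the initial guess. Note that at the default 0.52 mm pitch a
  0.4 mm wire spans less than one pixel, so the fitted sigma of a
  noiseless *fully sampled* rendering is ill-conditioned; the estimate is
  meaningful for reconstructions whose passband widens the profile, which
  is the regime the procedure is designed for.
- **Sensitivity.** `roi_mean()` averages a 5x5 pixel window at each well
  center; `fit_calibration()` regresses ROI mean on concentration by
  ordinary least squares and reports `R² = 1 - SS_res / SS_tot` (defined
  as 0 for a flat response). The detection limit is operationalized as the
  lowest concentration whose ROI mean exceeds the blank mean by three
  blank-level standard deviations.
- **Imaging depth.** `depth_detectability()` computes the
  contrast-to-noise ratio `CNR = (mean_tube - mean_bg) / sd_bg` between
  disjoint masks and applies the Rose criterion, CNR >= 5, as the
  detectability threshold; "clearly distinguishable" is qualitative, so
  the criterion is explicit and configurable. The background band is kept
  four blur sigmas clear of the tube. CNR is invariant to affine intensity
  rescaling of the reconstruction.

### The depth operating point

The depth preset fixes a reference operating point found once by a
calibration sweep of the virtual instrument: tube emission 100 detector
units at zero depth and Gaussian read noise of 250 detector units. At the
default 14% dithered acquisition this places the 2 mm and 4 mm tubes above
the Rose threshold (CNR ~ 16 and ~ 6.6) and the 6 mm and 8 mm tubes below
it (CNR ~ 3.6 and ~ 2.1), so the simulated system's imaging depth is 4 mm.
The flags are stable across acquisition seeds; the sweep is frozen as a
regression fixture, not re-run.

## The smooth-phantom suite

Fidelity-versus-sampling experiments use `phantom_suite()`: reproducible
scenes built by low-pass filtering seeded white Gaussian noise with a
Gaussian transfer function and rescaling to `[0, 1]`. The cutoff radius
defaults to `min(M, N) / 8` cycles (12 cycles at 96 x 128). The choice is
deliberate: the suite's spectral energy must span the radial range that the
sampling-ratio ladder {5, 10, 14, 25, 50, 100}% probes. A much smoother
suite leaves the truncation error at 50% sampling below the floating-point
noise floor of the bucket sums, and the measured PSNR then saturates at an
arbitrary round-off level instead of reflecting sampling fidelity. With
the default cutoff the grayscale PSNR curve is strictly increasing in the
ratio, as Parseval's identity requires of a prefix-nested plan (the energy
in unmeasured cells can only shrink).

Two regimes behave differently and both are tested:

- **Grayscale patterns, no noise**: reconstruction error is pure spectrum
  truncation, so fidelity is monotone in the sampling ratio.
- **Dithered patterns**: binarization injects a roughly flat error
  spectrum. Low-frequency coefficients carry strong scene signal and are
  barely affected, but beyond the scene's spectral support each additional
  coefficient contributes mostly dither noise, so the PSNR-versus-ratio
  curve peaks near the scene bandwidth and then declines gently. The
  dither-fidelity regression gate (mean PSNR of the suite at full sampling
  with dithered patterns) was computed once from this fixture — 28.9 dB —
  and is asserted as a floor of 28.5 dB thereafter; it is a regression
  gate for this synthetic suite, not a claim about hardware.

What the suite does *not* emulate: detector nonlinearity and afterpulsing,
scene motion, DMD timing and tilt geometry, spectral (energy-dependent)
x-ray response, or real photon-transport in tissue. Passing these tests
therefore demonstrates the correctness of the sampling, binarization,
recovery and evaluation machinery — not hardware-level image quality.

## Numerical tolerances and problem sizes

Exact algebraic identities (triplet-to-DFT equivalence, pipeline identity
at full sampling, offset rejection) are asserted at `1e-8`–`1e-9`
relative, the level double precision supports after ~12k-term summations.
Offset rejection is exercised with offsets up to `1e6` times the scene
intensity scale; offsets of `1e6` times the *summed response* would push
the stored responses' rounding error itself above the assertion level, a
floating-point bound rather than a property of the method. Monte-Carlo
checks (noise propagation through the triplet combination, estimator
recovery) use 10^2–10^4 seeded trials. End-to-end suites run at the
reference 96 x 128 geometry; algebraic identities are verified on grids up
to 16 x 16, including odd sizes, where brute-force double-loop oracles are
cheap. These sizes are the package's validation design: large enough to
exercise every code path (odd/even Hermitian boundaries, serpentine rows,
partial plans), small enough that the whole suite runs in about a minute.

## Known limitations

- The forward model is monochromatic and linear; the scintillator is a
  fixed gain, and x-ray transmission is single-energy Beer–Lambert.
- The depth phantom's diffusion closed form is a detectability
  surrogate, not a solution of the transport equation; absolute CNR values
  at depth should not be read as tissue predictions.
- Zero-filled inverse-DFT reconstruction is the only recovery method;
  compressed-sensing or learned completion would change the
  fidelity-versus-ratio trade-off substantially.
- The absolute radiometric scale of reconstructions follows the DFT
  convention fixed here (the 3/2 triplet factor divided out at assembly);
  instruments that rescale post hoc will differ by a constant.
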