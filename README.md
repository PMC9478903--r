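# fsisim

Simulation and evaluation toolkit for **structured-detection Fourier
single-pixel imaging (FSI)**, the architecture in which a dual-modality
(x-ray transmission / fluorescence emission) scene is imaged with a single
bucket detector: a digital micromirror device (DMD) modulates the scene's
image with sinusoidal basis patterns and a photomultiplier integrates the
result, one scalar per pattern.

The package provides everything needed to study the method end to end with
no hardware:

- **Pattern synthesis.** Three-step phase-shifting Fourier basis patterns
  `P_phi(x,y;u,v) = 1/2 + 1/2 cos(2 pi u x / M + 2 pi v y / N + phi)` with
  `phi in {0, 2pi/3, 4pi/3}`, and serpentine Floyd–Steinberg error
  diffusion to binarize them for a binary modulator.
- **Sampling plans.** Circular (low-radial-frequency-first) undersampling
  of the Fourier plane with Hermitian-pair accounting, so a 14% ratio
  covers 14% of the `M x N` spectrum counting implied conjugates.
- **A virtual instrument.** Bucket-detector forward model
  `D_phi = sum_xy I(x,y) P_phi(x,y) + n` with ambient-offset, Gaussian and
  Poisson noise components, plus three built-in phantoms: a 0.4 mm
  absorbing wire on a bright field (Beer–Lambert transmission), a serial
  2x dilution well row (11.86 … 0.74 nmol/ml plus blank), and a 1 mm
  emissive tube at depth in a diffusive medium
  (`mu_a = 0.03 cm^-1`, `mu_s' = 12.3 cm^-1`).
- **Reconstruction.** The triplet combination
  `F(u,v) = (2 D_0 - D_{2pi/3} - D_{4pi/3}) + sqrt(3) j (D_{2pi/3} - D_{4pi/3})`,
  which equals 3/2 times the unnormalized DFT coefficient and cancels any
  offset common to a triplet; Hermitian spectrum assembly; inverse DFT.
- **Evaluation procedures.** Line-profile Gaussian fits reported as
  `FWHM = 2 sqrt(2 ln 2) sigma * pitch` (spatial resolution), 5x5 ROI means
  with linear calibration and R² (sensitivity), and contrast-to-noise depth
  detectability against the Rose criterion (CNR >= 5).

Defaults reproduce the reference operating point of the simulated
instrument: 96 x 128 pixels, 0.52 mm object-space pitch, 14% circular
sampling, dithered binary patterns.

## Worked example

Simulate the imaging-depth experiment: a 1 mm fluorescent tube 4 mm deep in
a scattering medium, acquired at 14% sampling with dithered patterns and
calibrated read noise, then reconstructed and scored:

```r
library(fsisim)

cfg <- preset_config("depth", depth = 4, seed = 5)
res <- run_experiment(cfg)
str(res$report, give.attr = FALSE)
#> List of 9
#>  $ experiment     : chr "depth"
#>  $ depth_mm       : num 4
#>  $ contrast       : num 6.65
#>  $ detectable     : logi TRUE
#>  $ mean_tube      : num 12.8
#>  $ mean_background: num -0.0678
#>  $ sd_background  : num 1.93
#>  $ threshold      : num 5
#>  $ psnr_db        : num 16.4
```

The tube at 4 mm yields a contrast-to-noise ratio of 6.65, above the Rose
threshold of 5, so it is flagged detectable; repeating with `depth = 6`
drops the CNR to about 3.4 and the flag turns off — the simulated system's
imaging depth is 4 mm. The same `run_experiment()` call with
`preset_config("wire")` or `preset_config("dilution")` performs the
resolution and sensitivity experiments and reports a Gaussian-fit FWHM in
mm, or per-well ROI means with calibration slope, R² and a 3-sigma
detection limit.

Lower-level building blocks are exported too:

```r
plan <- circular_sampling_plan(c(96, 128), 0.14)   # 861 coefficients
tr   <- triplet_for(3, 5, c(96, 128))              # 3 grayscale + 3 binary patterns
scene <- make_wire_scene(wire_phantom(), c(96, 128))
ms    <- acquire(scene, plan, use_binary = TRUE, noise = noise_model(seed = 1))
rec   <- reconstruct_image(assemble_spectrum(ms))
```

A thin command-line front end ships in `inst/cli/fsi`
(`fsi preset wire|dilution|depth`, `fsi simulate`, `fsi reconstruct`,
`fsi evaluate`).

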