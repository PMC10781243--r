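# pwbeam

Beamforming for multi-angle plane-wave (PW) ultrasound in R: from raw
channel data to B-mode images and image-quality metrics.

In PW imaging a whole field of view is insonified by a single unfocused
transmission, and image quality is recovered by *coherently compounding*
several transmissions at different steering angles (CPWC). `pwbeam`
implements CPWC and a family of data-adaptive beamformers that improve on
it, for engineers and researchers working on ultrasound image
reconstruction:

* **CPWC** — delay-and-sum over the per-pixel echo matrix
  `X(n)` (M transmit angles x N receive elements), with a dynamic receive
  aperture (F-number 1.75 by default):
  `y_CPWC(n) = w_T^H Z(n) = w_R^H V(n)`, where `Z(n)` (Tx-angle array) and
  `V(n)` (Rx-channel array) are the channel- and angle-compounded
  reductions of `X(n)`.
* **Minimum-variance (Capon) beamforming** in either dimension — RxMV on
  `V(n)`, TxMV on `Z(n)`: weights `w = R⁻¹a / (aᴴR⁻¹a)` minimizing output
  power under the unity-gain constraint, with subarray (spatial) averaging,
  temporal averaging over ~5.4 wavelengths, forward–backward averaging
  `R_FB = (R + J Rᵀ J)/2` and diagonal loading `Δ·tr(R)/L`. A
  leave-one-channel-out full-covariance comparison beamformer (DCR-MVDR)
  is included.
* **DMAS coherence imaging** — magnitudes taken to the `1/p` power with
  phase kept, compounded, then restored with the `p` power, so the output
  is weighted by the signal coherence across transmit angles; `p = 1`
  recovers DAS. Combined with TxMV as `TxMV-DMAS`.
* **Adaptive coherence order (ADMAS)** — a per-pixel `p` driven by the
  generalized coherence factor `GCF` and the angular variance `Var` of
  `Z(n)`: low-quality pixels (off-axis clutter, uncorrelated noise,
  low-coherence cyst clutter) are categorized by thresholds on the two
  maps and pushed toward `p_max`, while fully developed speckle stays at
  `p_min`, via `α = GCF^(Var^(1/m))`, the inverse S-curve
  `γ = 1 − 1/(1 + exp(−(18α − 9)))`, median filtering, and
  `p = γ(p_max − 1) + p_min`.
* **Metrics** — lateral FWHM of point targets, contrast ratio
  `CR = 20·log10(μ_bck/μ_cyst)`, contrast-to-noise ratio
  `CNR = 20·log10(|μ_cyst − μ_bck| / sqrt((σ²_cyst + σ²_bck)/2))`, and the
  generalized CNR `gCNR = 1 − ∫ min(p_cyst, p_bck)`, all on the linear
  envelope.
* **Synthetic data** — a single-scattering PW simulator (point phantoms,
  speckle slabs, anechoic/hyperechoic cysts, 2.5-cycle Hann pulse) so the
  full chain is testable without datasets, plus HDF5 I/O for PICMUS-style
  files.

## Worked example

Simulate a 64-element, 15-angle acquisition of a single 30 mm point
target and compare lateral resolution across beamformers:

```r
library(pwbeam)

geom  <- transducer_geometry(n_elements = 64, pitch = 0.3e-3,
                             center_frequency = 5.2e6,
                             sampling_frequency = 20.8e6)
seq15 <- plane_wave_angles(15, 7.5)        # -7.5..+7.5 degrees
cube  <- simulate_cube(make_point_phantom(0, 30e-3), geom, seq15)
grid  <- image_grid(geom, c(-2.5e-3, 2.5e-3), c(29e-3, 31e-3),
                    dx = wavelength(geom) / 8)

for (img in list(beamform_cpwc(cube, grid),
                 beamform_txmv(cube, grid, L = 5),
                 beamform_txmv_dmas(cube, grid, p = 2, L = 5)))
  print(metrics_report(img, point_targets = data.frame(x = 0, z = 30e-3)))
#> cpwc         FWHM 0.598 mm
#> txmv         FWHM 0.403 mm
#> txmv-dmas    FWHM 0.308 mm
```

The main lobe narrows from 0.60 mm (plain compounding) to 0.40 mm with
transmit-dimension MV weighting and 0.31 mm once coherence weighting
(`p = 2`) is added.

On an anechoic-cyst phantom the same comparison shows the
contrast/speckle trade-off and its adaptive resolution:

```r
cyst  <- roi_circle(0, 27e-3, 2.5e-3)
ccube <- simulate_cube(make_cyst_phantom(c(-7e-3, 7e-3), c(22e-3, 32e-3),
                                         cysts = list(cyst), seed = 1),
                       geom, seq15)
cgrid <- image_grid(geom, c(-6.2e-3, 6.2e-3), c(24.5e-3, 29.5e-3))
cy    <- roi_circle(0, 27e-3, 1.75e-3)
bck   <- list(roi_circle(-4.3e-3, 27e-3, 1.75e-3, "background"))

for (img in list(beamform_cpwc(ccube, cgrid),
                 beamform_txmv_dmas(ccube, cgrid, p = 2, L = 5),
                 beamform_txmv_admas(ccube, cgrid,
                                     thresholds = admas_thresholds(p_max = 2),
                                     L = 5)))
  print(metrics_report(img, cyst_rois = list(cy), bck_rois = bck))
#> cpwc         CR  22.4 dB  CNR 5.975  gCNR 0.962
#> txmv-dmas    CR 27.25 dB  CNR 5.896  gCNR 0.966
#> txmv-admas   CR 22.49 dB  CNR  6.02  gCNR 0.962
```

Fixed-`p` DMAS buys ~5 dB of contrast at the cost of CNR (degraded
speckle); the adaptive order restores the CNR to the delay-and-sum level.
`beamform_txmv_admas()` also returns the intermediate `GCF`, `Var`, `α`,
`γ` and `p` maps in `$maps`.

A thin command-line interface over the same functions lives at
`inst/cli/pwbeam.R` with verbs `simulate`, `beamform`, `evaluate` and
`bench` (YAML configuration, see `?run_pipeline`).

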