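---
title: "Adaptive-coherence beamforming for multi-angle plane-wave imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive-coherence beamforming for multi-angle plane-wave imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Multi-angle plane-wave imaging transmits `M` unfocused plane waves at
steering angles $\theta_1 < \dots < \theta_M$ and records the echoes on an
`N`-element linear array. For an image pixel at $(x, z)$ the package
time-compensates every channel of every transmission with the two-way
delay

$$\tau_{ij} = \frac{z\cos\theta_i + x\sin\theta_i}{c} +
  \frac{\sqrt{z^2 + (x - x_j)^2}}{c},$$

with the transmitted wavefront referenced to the array center at $t = 0$
(the convention of the public plane-wave challenge datasets, so that their
`initial_time` metadata applies unchanged). The compensated samples form
the per-pixel echo matrix $X(n) \in \mathbb{C}^{M \times N}$. Averaging
over receive channels gives the Tx-angle array $Z(n) \in \mathbb{C}^M$;
averaging over angles gives the Rx-channel array $V(n) \in \mathbb{C}^N$;
uniform compounding of either is CPWC, and both routes coincide exactly.

A dynamic receive aperture keeps element $j$ active only while
$|x_j - x| \le z / (2 F_\#)$ (default $F_\# = 1.75$), with a floor of the
two nearest elements so that every pixel keeps a valid (if tiny)
aperture. Averages over receive channels are normalized by the *active*
count: a fixed $1/N$ would dim shallow and lateral-border pixels for no
physical reason, and the difference is only an overall magnitude scale.

### Minimum-variance weighting

The MV (Capon) beamformer replaces uniform compounding weights by
$w = R^{-1}a / (a^H R^{-1} a)$, the minimizer of the output power
$w^H R w$ under $w^H a = 1$. Because the data are already delay-aligned,
the steering vector $a$ is all-ones. The covariance $R$ is estimated with:

* **subarray averaging** over all forward sub-vectors of length `L`;
* **temporal averaging** over $2T+1$ depth samples, truncated (never
  zero-padded) at the image edges and normalized by the actual count, so
  the covariance scale stays unbiased near borders;
* **forward–backward averaging** $R_{FB} = (R + J R^T J)/2$;
* **diagonal loading** $R + \Delta\,\mathrm{tr}(R)/L \cdot I$.

The weight solve is a Hermitian linear solve (never an explicit inverse);
a numerically singular pixel falls back to uniform weights with a warning
rather than aborting the image — isolated dark pixels should not kill a
frame.

Applied along the receive dimension this is RxMV (subarray length one
third of the active aperture, minimum 2, no temporal averaging because
the aperture itself changes with depth); along the transmit dimension it
is TxMV (fixed `L`, default 25 at the 75-angle full scale, i.e. `L = M/3`;
temporal window $2T+1 \approx 5.4$ wavelengths of fast time, rounded to
the nearest odd number of samples — 21 samples, $T = 10$, at 5.2 MHz
center and 20.8 MHz sampling). The DCR-MVDR comparison method instead
builds a full $M \times M$ covariance from `N_active` leave-one-channel-out
compounding snapshots with no subarray averaging and a stronger loading
($\Delta = 1$ point targets / $\Delta = 5$ speckle).

### Coherence weighting (DMAS) and its adaptive order

DMAS scales magnitudes to their $1/p$ power keeping phase,
$\hat z_i = |z_i|^{1/p} e^{j\angle z_i}$, compounds, and restores
dimensionality with the $p$ power. In `TxMV-DMAS` both the covariance and
the weights are computed from the root-scaled array and each subarray dot
product is restored before the subarray average. The restoration power of
a complex scalar is applied to the magnitude with the phase kept — the
same convention as the forward scaling — which keeps envelope detection
well defined. With $p = 1$ the entire pipeline reduces *exactly* to TxMV
(and TxMV with `L = 1` to CPWC); these degeneracies are regression-tested
to $10^{-10}$.

A global $p$ trades speckle quality for contrast. The adaptive variant
computes, per pixel, from $Z(n)$:

* the **generalized coherence factor**: the fraction of the length-`M`
  DFT energy within DC $\pm M_0$ bins (default $M_0 = 1$, so 3 of `M`
  bins);
* the **angular variance** of the depth-gain-compensated magnitudes
  $|z_i|$, normalized by the image maximum so the thresholds live on
  $[0, 1]$.

Pixels are then categorized (precedence I > II > III): region I,
off-axis clutter, `var > thv2`; region II, uncorrelated noise,
`gcf < thg1`; region III, low-coherence cyst clutter, `gcf < thg2` and
`var < thv1`. All three get their GCF reset to zero. The maps are fused by
$\alpha = \mathrm{GCF}^{\mathrm{Var}^{1/m}}$ (so speckle, whose variance
collapses, gets $\alpha \to 1$ however noisy its raw GCF is), passed
through the inverse S-curve $\gamma = 1 - 1/(1 + e^{-(18\alpha - 9)})$
(exactly $0.5$ at $\alpha = 0.5$), median-filtered, and mapped affinely to
$p = \gamma (p_{max} - 1) + p_{min}$. The per-pixel $p$ is used both for
the forward root scaling and for the restoration.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `f_number` | 1.75 | receive aperture growth with depth |
| `L` | 25 (TxMV family, full scale) | covariance subarray length; `M/3` is the reference ratio |
| `T` | from 5.4 wavelengths | temporal half-window in depth samples |
| `delta` | 0.1 (MV), 1/5 (DCR-MVDR) | diagonal loading factor |
| `p`, `p_min`/`p_max` | 2 / [1, 2] | coherence order (fixed / adaptive range) |
| `thg1, thg2` | 0.1, 0.2 | GCF categorization bounds |
| `thv1, thv2` | 0.001, 0.15 | variance categorization bounds |
| `M0`, `m` | 1, 4 | GCF cutoff; contrast root of the α map |
| `median_kernel` | 5 | map smoothing window, in lateral pixels |

The categorization thresholds are tied to the transmit-angle set: the GCF
of speckle rises as the angles get fewer and closer (3 of 15 DFT bins in
band instead of 3 of 75), so with a small-angle configuration the bounds
should be re-optimized. They are configuration, not constants, and one
test demonstrates a re-optimized set for 15 angles.

## What the synthetic generator emulates — and what it does not

`simulate_cube()` is a single-scattering superposition model: every
scatterer contributes a delayed 2.5-cycle sinusoid under a Hann envelope
(symmetric about its two-way delay, so envelope peaks land exactly on the
scatterer) to every angle/element pair, sampled at `fs`, optionally with
white Gaussian noise at a stated dB level below the RF peak. Phantoms
provide isolated points, uniform speckle slabs (uniform positions,
standard-normal amplitudes) and anechoic or hyperechoic circular
inclusions.

The default speckle density is 60 scatterers/mm². The resolution cell at
the reference settings (lateral $\lambda F_\#$, axial $1.25\lambda$) is
about 0.22 mm², so this is ~13 scatterers per cell nominally; with
Gaussian amplitudes the *effective* per-cell count is a third of that
(the amplitude kurtosis triples the required density), which is what it
takes for the CPWC envelope to be Rayleigh to within ~10% in envelope
SNR. The test suite checks that invariant on a slab holding several
hundred independent speckle cells, since the SNR estimator itself has
~10% spread on fields of only ~100 cells.

Not modeled: element directivity, elevation focusing, attenuation and
dispersion, multiple scattering, reverberation. Passing tests therefore
show the reconstruction chain is correct under the stated wave model —
they do not certify performance against tissue effects such as aberration
or reverberation clutter, which is precisely where fixed thresholds and
MV weights are known to be stressed.

## Numerical choices

* **Analytic signal** by the FFT one-sided-spectrum construction; linear
  interpolation of complex analytic samples at the delay (phase-safe at
  4x carrier oversampling). Out-of-window delays contribute exact zeros,
  not clamped edge samples, to avoid spurious coherence at borders.
* **Grids**: images are `[z, x]` matrices; the default grid is λ/2
  lateral and one RF sample (`c/2fs`) axial, so the temporal covariance
  window is a window of image rows.
* **Median filter geometry**: the kernel is stated in lateral pixels and
  applied over a *physically square* window — on the default grid the
  axial pixel is ~4x finer than the lateral one, so the axial arm widens
  by `dx/dz`. A pixel-square window on an anisotropic grid cannot remove
  speckle-null pinholes, which span about a pulse length axially.
* **Variance normalization** (the quantity is stated only up to a
  convention): magnitudes are compensated by the inverse of the smoothed
  mean CPWC envelope per depth (a time-gain compensation), the sample
  variance is taken over angles, and the map is normalized by its image
  maximum. In images that contain a bright reflector the maximum is set by
  its off-axis clutter and the thresholds behave as intended; in
  reflector-free speckle images the maximum is a noisy extreme of the
  speckle field itself, so isolated background patches can cross `thv2`.
  For that reason summaries of the adaptive-`p` map report medians — the
  typical pixel — rather than means.
* **Degenerate inputs**: all-zero pixels skip the MV solve and return 0;
  an all-zero GCF input is defined as 0; $\alpha(0, 0)$ is defined as 0
  (the region reset dominates); singular covariances fall back to uniform
  weights.

## Problem sizes

The bundled tests and the acceptance script run a reduced study: 64
elements, 15 angles spanning ±7.5°, `L = 5` (the same `L = M/3` ratio as
the full scale), single point target at 30 mm, one 2.5 mm anechoic cyst
at 27 mm in a 14 × 10 mm slab, and a 16 × 11 mm pure-speckle slab. These
sizes keep the full simulate–beamform–evaluate chain to tens of seconds
while leaving every algorithmic path (aperture growth, temporal
truncation, region categorization, adaptive restoration) exercised. The
full 128-element / 75-angle scale is supported by the same code paths and
the PICMUS-style HDF5 reader.

At the reduced angle count the in-cyst clutter is more coherent than at
75 angles, so with the default (75-angle) thresholds the adaptive map
elevates `p` inside the cyst only mildly and TxMV-ADMAS behaves close to
TxMV — which is already the point of the method: contrast comparable to
the fixed-`p` beamformer wherever categorization fires, speckle left at
`p = p_min`. With bounds re-optimized for 15 angles
(`thg = [0.2, 0.5]`, `thv1 = 0.01`) the in-cyst order approaches
`p_max` and the contrast of fixed-`p` DMAS is matched within ~1 dB at
higher CNR; the suite contains both configurations.

## Known limitations

* Demodulated IQ input with a nonzero carrier is rejected; supply RF or
  analytic data.
* The DCR-MVDR comparison builds one echo matrix per pixel and is the
  slowest path; it is intended for method comparison on modest grids.
* RxMV ignores temporal averaging by design (depth-varying aperture);
  its resolution is bounded by the shallow-depth aperture.
* Thresholds are not auto-tuned to the transmit sequence (see above).
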