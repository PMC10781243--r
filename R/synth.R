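# Synthetic plane-wave channel-data generator. Single-scattering
# superposition: every scatterer contributes a delayed, Hann-windowed
# 2.5-cycle tone to every (angle, element) channel. No attenuation,
# directivity or multiple scattering; the phantoms carry the structural
# features (isolated points, fully developed speckle, anechoic and
# hyperechoic inclusions) the beamformers and the adaptive-p machinery
# assume.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Transmit pulse model
#'
#' A sinusoid of `n_cycles` cycles at the center frequency under a Hann
#' (or rectangular) envelope; the reference excitation is a 2.5-cycle tone.
#'
#' @param center_frequency Hz.
#' @param n_cycles Number of cycles (> 0, default 2.5).
#' @param window `"hann"` or `"rect"`.
#' @return Object of class `pw_pulse` with a `waveform(t)` evaluator.
#' @export
pulse_model <- function(center_frequency, n_cycles = 2.5, window = c("hann", "rect")) {
  stopifnot(center_frequency > 0, n_cycles > 0)
  window <- match.arg(window)
  D <- n_cycles / center_frequency
  # symmetric about t = 0 so the envelope peaks exactly at the scatterer delay
  wf <- function(t) {
    inside <- abs(t) <= D / 2
    u <- t + D / 2
    w <- if (window == "hann") 0.5 * (1 - cos(2 * pi * u / D)) else 1
    ifelse(inside, sin(2 * pi * center_frequency * u) * w, 0)
  }
  structure(list(center_frequency = center_frequency, n_cycles = n_cycles,
                 window = window, duration = D, waveform = wf),
            class = "pw_pulse")
}

.phantom <- function(x, z, amplitude, label) {
  stopifnot(length(x) == length(z), length(x) == length(amplitude),
            all(z > 0))
  structure(list(x = x, z = z, amplitude = amplitude, label = label),
            class = "pw_phantom")
}

#' @export
print.pw_phantom <- function(x, ...) {
  cat(sprintf("<pw_phantom> '%s', %d scatterers\n", x$label, length(x$x)))
  invisible(x)
}

#' Point-target phantom
#'
#' Default layout emulates the standard resolution phantom: a vertical
#' column at `x = 0` from 10 to 45 mm depth in 5 mm steps (8 points) plus
#' horizontal rows at 20 and 40 mm depth at lateral positions -15..15 mm in
#' 5 mm steps excluding 0 (12 points), 20 unit-amplitude targets in all.
#'
#' @param x,z Optional explicit scatterer positions in meters (equal
#'   lengths); when given they override the default layout.
#' @return A `pw_phantom`.
#' @export
make_point_phantom <- function(x = NULL, z = NULL) {
  if (is.null(x) != is.null(z)) stop("give both x and z, or neither")
  if (is.null(x)) {
    zc <- seq(10e-3, 45e-3, by = 5e-3)
    xr <- setdiff(seq(-15e-3, 15e-3, by = 5e-3), 0)
    x <- c(rep(0, length(zc)), xr, xr)
    z <- c(zc, rep(20e-3, length(xr)), rep(40e-3, length(xr)))
  }
  .phantom(x, z, rep(1, length(x)), "points")
}

#' Speckle / cyst phantom
#'
#' Uniformly random sub-resolution scatterers with standard-normal random
#' amplitudes over a rectangular slab; scatterers inside anechoic circles
#' are removed and those inside hyperechoic circles are amplitude-scaled.
#' Deterministic for a given seed.
#'
#' @param x_range,z_range Slab extents in meters.
#' @param density Scatterers per square millimeter. The default, 60/mm^2,
#'   puts about 13 scatterers in a resolution cell (lateral `lambda F#` x
#'   axial 1.25 `lambda` at the reference 5.2 MHz / F1.75 settings). With
#'   Gaussian amplitudes the effective per-cell count is a third of the
#'   nominal one, so this density is what it takes for fully developed
#'   (Rayleigh) speckle; the generator requires at least 5 per cell.
#' @param cysts List of [roi_circle()] inclusions (anechoic).
#' @param hyper List of [roi_circle()] inclusions scaled by `hyper_scale`.
#' @param hyper_scale Amplitude factor inside `hyper` circles (default 3).
#' @param seed Integer seed (restores the caller's RNG state).
#' @return A `pw_phantom`.
#' @export
make_cyst_phantom <- function(x_range, z_range, density = 60,
                              cysts = list(), hyper = list(),
                              hyper_scale = 3, seed = 1) {
  area_mm2 <- diff(range(x_range)) * diff(range(z_range)) * 1e6
  n <- max(1L, round(density * area_mm2))
  .with_seed(seed, {
    x <- stats::runif(n, x_range[1], x_range[2])
    z <- stats::runif(n, z_range[1], z_range[2])
    a <- stats::rnorm(n)
    for (cy in cysts) {
      inside <- (x - cy$x)^2 + (z - cy$z)^2 <= cy$radius^2
      x <- x[!inside]; z <- z[!inside]; a <- a[!inside]
    }
    for (hy in hyper) {
      inside <- (x - hy$x)^2 + (z - hy$z)^2 <= hy$radius^2
      a[inside] <- a[inside] * hyper_scale
    }
    .phantom(x, z, a, if (length(cysts) || length(hyper)) "cysts" else "speckle")
  })
}

#' Simulate a multi-angle plane-wave channel-data cube
#'
#' For each transmit angle and element, sums the pulse contributions of all
#' scatterers at their two-way delays (plane-wave transmit delay plus
#' element receive delay), digitizes at the geometry's sampling rate,
#' optionally adds white Gaussian noise at `noise_db` relative to the RF
#' peak, and converts to the analytic signal.
#'
#' @param phantom A `pw_phantom` (may be empty only if noise is enabled).
#' @param geometry A `pw_geometry` (`fs > 2 f0` required).
#' @param sequence A `pw_sequence`.
#' @param pulse A [pulse_model()]; default 2.5-cycle Hann at the geometry's
#'   center frequency.
#' @param noise_db Noise level in dB relative to the RF peak (e.g. -40), or
#'   `NULL` for noise-free data.
#' @param t_max Recorded window end in seconds (default: covers the deepest
#'   scatterer plus the pulse).
#' @param seed Seed for the noise (ignored when `noise_db` is `NULL`).
#' @return A `pw_cube` of analytic channel data.
#' @export
simulate_cube <- function(phantom, geometry, sequence, pulse = NULL,
                          noise_db = NULL, t_max = NULL, seed = 1) {
  if (geometry$sampling_frequency <= 2 * geometry$center_frequency)
    stop("sampling frequency must exceed twice the center frequency")
  if (length(phantom$x) == 0 && is.null(noise_db))
    stop("empty phantom with no noise would produce an empty cube")
  if (is.null(pulse)) pulse <- pulse_model(geometry$center_frequency)
  fs <- geometry$sampling_frequency
  c0 <- geometry$sound_speed
  M <- length(sequence$angles)
  N <- geometry$n_elements
  if (is.null(t_max)) {
    zmax <- if (length(phantom$z)) max(phantom$z) else 40e-3
    xspan <- max(abs(geometry$element_x)) +
      (if (length(phantom$x)) max(abs(phantom$x)) else 0)
    t_max <- (zmax + sqrt(zmax^2 + xspan^2)) / c0 + pulse$duration + 8 / fs
  }
  nt <- as.integer(ceiling(t_max * fs))
  if (nt < 8) stop("recorded window too short")
  rf <- array(0, dim = c(M, N, nt))
  P <- as.integer(ceiling(pulse$duration * fs)) + 2L
  MN <- M * N
  ij_i <- rep(seq_len(M), times = N)
  ij_j <- rep(seq_len(N), each = M)
  t0_flat <- sequence$t0[ij_i]
  for (s in seq_along(phantom$x)) {
    xs <- phantom$x[s]; zs <- phantom$z[s]; as_ <- phantom$amplitude[s]
    if (as_ == 0) next
    txd <- tx_delay(sequence$angles, xs, zs, c0)
    rxd <- rx_delay(geometry$element_x, xs, zs, c0)
    tau <- txd[ij_i] + rxd[ij_j]                    # length MN
    n0 <- floor((tau - pulse$duration / 2 - t0_flat) * fs) + 1
    nn <- rep(n0, P) + rep(seq_len(P) - 1L, each = MN)
    tt <- (nn - 1) / fs + rep(t0_flat, P) - rep(tau, P)
    val <- as_ * pulse$waveform(tt)
    keep <- nn >= 1 & nn <= nt & val != 0
    if (!any(keep)) next
    idx <- (nn[keep] - 1) * MN + (rep(ij_j, P)[keep] - 1) * M + rep(ij_i, P)[keep]
    rf[idx] <- rf[idx] + val[keep]
  }
  if (!is.null(noise_db)) {
    pk <- max(abs(rf))
    if (pk == 0) pk <- 1
    sd <- pk * 10^(noise_db / 20)
    rf <- rf + .with_seed(seed, array(stats::rnorm(length(rf), sd = sd), dim(rf)))
  }
  analytic_cube(to_analytic(rf), geometry, sequence)
}
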