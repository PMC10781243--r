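#' Linear-array transducer geometry
#'
#' Describes a 1D linear array with uniform pitch, centered on the lateral
#' origin: element `j` sits at `x = (j - (N+1)/2) * pitch`.
#'
#' @param n_elements Number of elements `N` (>= 2).
#' @param pitch Element pitch in meters.
#' @param center_frequency Transmit center frequency in Hz.
#' @param sampling_frequency Fast-time sampling frequency in Hz.
#' @param sound_speed Speed of sound in m/s (default 1540).
#' @return An object of class `pw_geometry` with fields `element_x`, `pitch`,
#'   `n_elements`, `center_frequency`, `sampling_frequency`, `sound_speed`.
#' @examples
#' geom <- transducer_geometry(128, 0.3e-3, 5.2e6, 20.8e6)
#' range(geom$element_x)  # symmetric about 0
#' @export
transducer_geometry <- function(n_elements, pitch, center_frequency,
                                sampling_frequency, sound_speed = 1540) {
  stopifnot(n_elements >= 2, pitch > 0, center_frequency > 0,
            sampling_frequency > 0, sound_speed > 0)
  n_elements <- as.integer(n_elements)
  structure(list(
    element_x = (seq_len(n_elements) - (n_elements + 1) / 2) * pitch,
    pitch = pitch,
    n_elements = n_elements,
    center_frequency = center_frequency,
    sampling_frequency = sampling_frequency,
    sound_speed = sound_speed
  ), class = "pw_geometry")
}

#' @export
print.pw_geometry <- function(x, ...) {
  cat(sprintf("<pw_geometry> %d elements, pitch %.3g mm, f0 %.3g MHz, fs %.3g MHz, c %.4g m/s\n",
              x$n_elements, 1e3 * x$pitch, 1e-6 * x$center_frequency,
              1e-6 * x$sampling_frequency, x$sound_speed))
  invisible(x)
}

#' Acoustic wavelength of a geometry
#' @param geometry A `pw_geometry`.
#' @return Wavelength `c / f0` in meters.
#' @export
wavelength <- function(geometry) geometry$sound_speed / geometry$center_frequency

#' Plane-wave transmit sequence
#'
#' @param angles Transmit steering angles in radians, sorted ascending,
#'   each within (-pi/2, pi/2).
#' @param t0 Time of the first recorded sample for each angle, seconds
#'   (scalar recycled or length `M`).
#' @return Object of class `pw_sequence` with fields `angles`, `t0`.
#' @export
plane_wave_sequence <- function(angles, t0 = 0) {
  stopifnot(length(angles) >= 1, all(is.finite(angles)),
            all(angles > -pi / 2), all(angles < pi / 2))
  if (is.unsorted(angles, strictly = FALSE))
    stop("plane-wave angles must be sorted ascending")
  t0 <- rep_len(t0, length(angles))
  stopifnot(all(is.finite(t0)))
  structure(list(angles = as.numeric(angles), t0 = as.numeric(t0)),
            class = "pw_sequence")
}

#' Evenly spread plane-wave angles
#'
#' Convenience constructor for `M` angles spanning `[-span, +span]` degrees.
#' @param n_angles Number of transmit angles `M`.
#' @param span_deg Half-span in degrees (e.g. 16 for -16..+16 degrees).
#' @param t0 Per-angle start time, seconds.
#' @export
plane_wave_angles <- function(n_angles, span_deg, t0 = 0) {
  ang <- if (n_angles == 1) 0 else seq(-span_deg, span_deg, length.out = n_angles)
  plane_wave_sequence(ang * pi / 180, t0 = t0)
}

#' Multi-angle analytic channel-data cube
#'
#' Bundles complex (analytic or IQ-at-zero-carrier) channel data indexed
#' `[angle, element, fast-time sample]` with its acquisition metadata.
#'
#' @param data Complex array of dimension `M x N x n_samples`.
#' @param geometry A `pw_geometry` with `n_elements == N`.
#' @param sequence A `pw_sequence` with `length(angles) == M`.
#' @return Object of class `pw_cube`.
#' @export
analytic_cube <- function(data, geometry, sequence) {
  stopifnot(inherits(geometry, "pw_geometry"), inherits(sequence, "pw_sequence"))
  d <- dim(data)
  if (is.null(d) || length(d) != 3)
    stop("cube data must be a 3D array [angle, element, sample]")
  if (d[1] != length(sequence$angles))
    stop("first cube dimension must equal the number of transmit angles")
  if (d[2] != geometry$n_elements)
    stop("second cube dimension must equal the number of elements")
  if (!is.complex(data)) data <- data + 0i
  if (anyNA(data) || !all(is.finite(Re(data))) || !all(is.finite(Im(data))))
    stop("cube data must be finite")
  structure(list(data = data, geometry = geometry, sequence = sequence),
            class = "pw_cube")
}

#' @export
print.pw_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<pw_cube> %d angles x %d elements x %d samples\n", d[1], d[2], d[3]))
  invisible(x)
}

#' Rectangular image pixel grid
#'
#' @param lateral_x Monotone, regularly spaced lateral positions (m).
#' @param axial_z Monotone, regularly spaced axial depths (m), all > 0.
#' @return Object of class `pw_grid`. Image arrays built on this grid are
#'   indexed `[z, x]`.
#' @export
pixel_grid <- function(lateral_x, axial_z) {
  .check_regular <- function(v, name) {
    if (length(v) > 1) {
      dv <- diff(v)
      if (any(dv <= 0)) stop(name, " must be strictly increasing")
      if (diff(range(dv)) > 1e-9 * max(abs(dv)) + 1e-15)
        stop(name, " must be regularly spaced")
    }
  }
  .check_regular(lateral_x, "lateral_x")
  .check_regular(axial_z, "axial_z")
  stopifnot(all(axial_z > 0))
  structure(list(lateral_x = as.numeric(lateral_x), axial_z = as.numeric(axial_z)),
            class = "pw_grid")
}

#' Default imaging grid for a geometry
#'
#' Lateral spacing defaults to half a wavelength and axial spacing to one
#' fast-time sample (`c / (2 fs)`), so that one image row corresponds to one
#' RF depth sample (the temporal-averaging convention of the MV beamformers).
#'
#' @param geometry A `pw_geometry`.
#' @param x_range,z_range Length-2 extents in meters.
#' @param dx,dz Spacings in meters (defaults as above).
#' @export
image_grid <- function(geometry, x_range, z_range,
                       dx = wavelength(geometry) / 2,
                       dz = geometry$sound_speed / (2 * geometry$sampling_frequency)) {
  pixel_grid(seq(x_range[1], x_range[2], by = dx),
             seq(z_range[1], z_range[2], by = dz))
}

#' Analytic-signal conversion along fast time
#'
#' Converts real RF data to its analytic signal (real part preserved,
#' imaginary part the quadrature component) using the one-sided-spectrum
#' construction: negative frequencies are zeroed and positive frequencies
#' doubled. Operates along the last array dimension.
#'
#' @param rf Real vector, matrix or array; the last dimension is fast time
#'   (length >= 8).
#' @return Complex object of the same shape.
#' @export
to_analytic <- function(rf) {
  if (anyNA(rf) || !all(is.finite(rf))) stop("RF data must be finite")
  d <- dim(rf)
  if (is.null(d)) d <- length(rf)
  nt <- d[length(d)]
  if (nt < 8) stop("fast-time axis must have at least 8 samples")
  m <- matrix(as.numeric(rf), nrow = prod(d) / nt, ncol = nt)
  h <- numeric(nt)
  if (nt %% 2 == 0) {
    h[c(1, nt / 2 + 1)] <- 1
    h[2:(nt / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((nt + 1) / 2)] <- 2
  }
  a <- stats::mvfft(stats::mvfft(t(m)) * h, inverse = TRUE) / nt
  out <- t(a)
  dim(out) <- if (is.null(dim(rf))) NULL else d
  out
}

#' Plane-wave transmit delay
#'
#' Propagation time of a steered plane wave from the array center to a pixel,
#' with the wavefront referenced to cross `x = 0` at `t = 0` (PICMUS
#' convention): `(z cos(theta) + x sin(theta)) / c`.
#'
#' @param angle Steering angle in radians.
#' @param x,z Pixel lateral position and depth in meters (`z >= 0`).
#' @param c Sound speed in m/s.
#' @return Delay in seconds (vectorized over pixels).
#' @export
tx_delay <- function(angle, x, z, c) {
  stopifnot(all(z >= 0))
  (z * cos(angle) + x * sin(angle)) / c
}

#' Receive delay from a pixel to an element
#'
#' `sqrt(z^2 + (x - element_x)^2) / c`.
#'
#' @param element_x Element lateral position (m).
#' @inheritParams tx_delay
#' @export
rx_delay <- function(element_x, x, z, c) {
  stopifnot(all(z >= 0))
  sqrt(z^2 + (x - element_x)^2) / c
}

#' Dynamic receive-aperture mask
#'
#' Element `j` is active for a pixel iff `|element_x[j] - x| <= z / (2 F#)`.
#' At least two elements (the nearest to the pixel) are always kept active,
#' mirroring the minimum subarray size of the receive-dimension MV beamformer.
#'
#' @param x,z Pixel position (m).
#' @param geometry A `pw_geometry`.
#' @param f_number Receive F-number (> 0).
#' @return Logical vector of length `n_elements`.
#' @export
rx_aperture_mask <- function(x, z, geometry, f_number) {
  stopifnot(f_number > 0)
  d <- abs(geometry$element_x - x)
  mask <- d <= z / (2 * f_number) + 1e-12
  if (sum(mask) < 2) {
    mask[] <- FALSE
    mask[order(d)[1:2]] <- TRUE
  }
  mask
}

#' Per-pixel echo matrix
#'
#' Builds the `M x N` matrix of time-compensated analytic samples for one
#' pixel: entry `(i, j)` is the cube sample at
#' `t = tx_delay(angle_i) + rx_delay(element_j) - t0_i`, obtained by linear
#' interpolation of the complex samples. Delays falling outside the recorded
#' window contribute exact zeros; elements outside the dynamic receive
#' aperture are zeroed and flagged in `rx_mask`.
#'
#' @param cube A `pw_cube`.
#' @param pixel Numeric `c(x, z)` in meters.
#' @param f_number Receive F-number.
#' @return Object of class `pw_echo`: list with `values` (`M x N` complex),
#'   `rx_mask` (logical length `N`) and `out_of_range` (TRUE when every delay
#'   missed the recorded window).
#' @export
build_echo_matrix <- function(cube, pixel, f_number) {
  geom <- cube$geometry
  sq <- cube$sequence
  M <- length(sq$angles)
  N <- geom$n_elements
  nt <- dim(cube$data)[3]
  fs <- geom$sampling_frequency
  x <- pixel[1]; z <- pixel[2]
  txd <- tx_delay(sq$angles, x, z, geom$sound_speed)
  rxd <- rx_delay(geom$element_x, x, z, geom$sound_speed)
  # fractional sample index per (i, j)
  s <- outer(txd - sq$t0, rxd, "+") * fs + 1
  s0 <- floor(s)
  w <- s - s0
  vals <- matrix(0i, M, N)
  ok <- s0 >= 1 & s0 <= nt - 1
  if (any(ok)) {
    ii <- row(s)[ok]; jj <- col(s)[ok]
    li <- (s0[ok] - 1) * (M * N) + (jj - 1) * M + ii
    vals[ok] <- cube$data[li] * (1 - w[ok]) + cube$data[li + M * N] * w[ok]
  }
  last <- s0 == nt & w < 1e-9
  if (any(last)) {
    ii <- row(s)[last]; jj <- col(s)[last]
    vals[last] <- cube$data[(nt - 1) * (M * N) + (jj - 1) * M + ii]
  }
  mask <- rx_aperture_mask(x, z, geom, f_number)
  vals[, !mask] <- 0i
  out_of_range <- !any(ok | last)
  if (out_of_range) warning("all delays outside the recorded time window; echo matrix is zero")
  structure(list(values = vals, rx_mask = mask, out_of_range = out_of_range),
            class = "pw_echo")
}
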