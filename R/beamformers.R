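# Whole-image beamformers. Each returns a `pw_image`: the complex pixel
# grid plus the method tag and effective parameters, consumed by the
# envelope/metrics functions.

.pw_image <- function(data, grid, method, params = list()) {
  structure(list(data = data, grid = grid, method = method, params = params),
            class = "pw_image")
}

#' @export
print.pw_image <- function(x, ...) {
  cat(sprintf("<pw_image> %s, %d x %d pixels\n", x$method,
              nrow(x$data), ncol(x$data)))
  invisible(x)
}

.field_to_image <- function(field, stack, method, params) {
  .pw_image(matrix(field, stack$nz, stack$nx), stack$grid, method, params)
}

#' Coherent plane-wave compounding (CPWC)
#'
#' Delay-and-sum reference beamformer: uniform-weight compounding of the
#' echo matrix over receive channels and transmit angles at every pixel.
#'
#' @param cube A `pw_cube`.
#' @param grid A `pw_grid`.
#' @param f_number Receive F-number (default 1.75).
#' @return A `pw_image` (complex, indexed `[z, x]`).
#' @export
beamform_cpwc <- function(cube, grid, f_number = 1.75) {
  st <- .delay_stack(cube, grid, f_number)
  field <- as.vector(st$Z %*% rep(1 / ncol(st$Z), ncol(st$Z)))
  .field_to_image(field, st, "cpwc", list(f_number = f_number))
}

#' Receive-dimension minimum-variance beamforming (RxMV)
#'
#' MV estimation on the receive-channel array restricted to the active
#' aperture. The subarray length is one third of the active-aperture size
#' with a minimum of 2 (no temporal averaging, since the active aperture
#' changes with depth), followed by forward-backward averaging and diagonal
#' loading.
#'
#' @inheritParams beamform_cpwc
#' @param delta Diagonal-loading factor (default 0.1).
#' @param L Optional fixed subarray length overriding the one-third rule.
#' @export
beamform_rxmv <- function(cube, grid, f_number = 1.75, delta = 0.1, L = NULL) {
  st <- .delay_stack(cube, grid, f_number)
  npix <- nrow(st$V)
  field <- rep(0i, npix)
  for (pix in seq_len(npix)) {
    v <- st$V[pix, st$active[pix, ]]
    if (all(Mod(v) == 0)) next
    Nact <- length(v)
    Lr <- if (is.null(L)) max(2L, floor(Nact / 3)) else min(L, Nact)
    K <- Nact - Lr + 1
    S <- matrix(v[outer(seq_len(Lr), seq_len(K) - 1L, "+")], Lr, K)
    if (Lr == 1) {
      field[pix] <- mean(v)
      next
    }
    R <- fb_average(S %*% Conj(t(S)) / K)
    R <- diagonal_load(R, delta, Lr)
    w <- suppressWarnings(mv_weights(R))
    field[pix] <- sum(Conj(w) * (S %*% rep(1 / K, K)))
  }
  .field_to_image(field, st, "rxmv",
                  list(f_number = f_number, delta = delta, L = L))
}

#' Transmit-dimension minimum-variance beamforming (TxMV)
#'
#' MV estimation on the transmit-angle array with spatial subarray averaging
#' (length `L`), temporal averaging over `2T+1` depth samples,
#' forward-backward averaging and diagonal loading; output averaged over
#' forward subarrays.
#'
#' @inheritParams beamform_rxmv
#' @param L Subarray length (default 25, the paper-scale value for M = 75;
#'   must not exceed the number of angles).
#' @param T Temporal half-window in depth samples; default from
#'   [temporal_halfwidth()] (about 5.4 wavelengths of fast time).
#' @export
beamform_txmv <- function(cube, grid, f_number = 1.75, L = 25, T = NULL,
                          delta = 0.1) {
  beamform_txmv_dmas(cube, grid, f_number = f_number, p = 1, L = L, T = T,
                     delta = delta)
}

#' p-th-root magnitude scaling (the DMAS forward transform)
#'
#' Scales magnitudes to their `1/p` power while preserving phase:
#' `|z|^(1/p) * exp(j arg z)`; zero maps to zero. `p = 1` is the identity
#' and reduces DMAS to conventional delay-and-sum.
#'
#' @param z Complex vector or matrix.
#' @param p Coherence order (>= 1), scalar.
#' @export
dmas_root_scale <- function(z, p) {
  stopifnot(all(p >= 1))
  .root_scale(z, p)
}

#' TxMV-DMAS beamforming
#'
#' DMAS integrated into the transmit-dimension MV estimation: the
#' transmit-angle array is root-scaled ([dmas_root_scale()]), covariance and
#' MV weights are computed from the scaled array, each subarray dot product
#' is restored to signal dimensionality by the magnitude `p`-power (phase
#' preserved), and the restored outputs are averaged over subarrays.
#' `p` may be a scalar or a per-pixel `nz x nx` map (the adaptive variant).
#'
#' @inheritParams beamform_txmv
#' @param p Coherence order (scalar >= 1, or a matrix matching the grid).
#' @export
beamform_txmv_dmas <- function(cube, grid, f_number = 1.75, p = 2, L = 25,
                               T = NULL, delta = 0.1) {
  stopifnot(all(p >= 1))
  if (is.null(T)) T <- temporal_halfwidth(cube$geometry)
  st <- .delay_stack(cube, grid, f_number)
  pvec <- if (length(p) == 1) p else as.vector(p)
  field <- .txmv_field(st$Z, st$nz, st$nx, L = L, T = T, delta = delta,
                       p = pvec)
  method <- if (all(p == 1)) "txmv" else "txmv-dmas"
  .field_to_image(field, st, method,
                  list(f_number = f_number, L = L, T = T, delta = delta,
                       p = if (length(p) == 1) p else "per-pixel"))
}

#' Transmit-dimension DMAS without MV (Tx-DMAS)
#'
#' The MV-free variant: root-scale the transmit-angle array, compound with
#' uniform weights, restore with the magnitude `p`-power. `p = 1` equals
#' CPWC; a per-pixel `p` map gives Tx-ADMAS.
#'
#' @inheritParams beamform_txmv_dmas
#' @export
beamform_tx_dmas <- function(cube, grid, f_number = 1.75, p = 2) {
  stopifnot(all(p >= 1))
  st <- .delay_stack(cube, grid, f_number)
  pvec <- if (length(p) == 1) p else as.vector(p)
  Zs <- .root_scale(st$Z, pvec)
  y <- as.vector(Zs %*% rep(1 / ncol(Zs), ncol(Zs)))
  field <- .power_restore(y, pvec)
  .field_to_image(field, st, "tx-dmas",
                  list(f_number = f_number,
                       p = if (length(p) == 1) p else "per-pixel"))
}

#' Leave-one-channel-out compounding snapshots (DCR-MVDR)
#'
#' For each active channel `j`, the snapshot is the echo matrix compounded
#' over the receive channels excluding `j`, giving `N_active` transmit-angle
#' vectors used to estimate a full `M x M` covariance without subarray
#' averaging.
#'
#' @param X A `pw_echo`.
#' @return Complex `M x N_active` matrix, one snapshot per column.
#' @export
dcr_snapshots <- function(X) {
  stopifnot(inherits(X, "pw_echo"))
  act <- which(X$rx_mask)
  n_act <- length(act)
  if (n_act < 2) stop("leave-one-out snapshots need at least 2 active channels")
  Xa <- X$values[, act, drop = FALSE]
  tot <- as.vector(Xa %*% rep(1 + 0i, n_act))
  (tot - Xa) / (n_act - 1)
}

#' DCR-MVDR beamforming
#'
#' Comparison beamformer: the covariance of the leave-one-channel-out
#' compounding snapshots (no subarray averaging) is diagonally loaded and
#' inverted for MV weights applied to the fully compounded transmit-angle
#' vector. Loading factors of 1 (point targets) and 5 (speckle) are the
#' reference settings.
#'
#' @inheritParams beamform_cpwc
#' @param delta Diagonal-loading factor.
#' @export
beamform_dcr_mvdr <- function(cube, grid, f_number = 1.75, delta = 1) {
  xg <- grid$lateral_x; zg <- grid$axial_z
  nz <- length(zg); nx <- length(xg)
  img <- matrix(0i, nz, nx)
  for (ix in seq_len(nx)) for (iz in seq_len(nz)) {
    X <- suppressWarnings(build_echo_matrix(cube, c(xg[ix], zg[iz]), f_number))
    if (all(Mod(X$values) == 0)) next
    S <- dcr_snapshots(X)
    z_full <- channel_sum(X)
    R <- diagonal_load(S %*% Conj(t(S)) / ncol(S), delta, nrow(S))
    w <- suppressWarnings(mv_weights(R))
    img[iz, ix] <- sum(Conj(w) * z_full)
  }
  .pw_image(img, grid, "dcr-mvdr", list(f_number = f_number, delta = delta))
}

#' Beamformer registry
#'
#' Dispatches a cube to one of the named beamformers:
#' `"cpwc"`, `"rxmv"`, `"txmv"`, `"dcr-mvdr"`, `"txmv-dmas"`, `"tx-dmas"`,
#' `"txmv-admas"`.
#'
#' @inheritParams beamform_cpwc
#' @param method Method name (see above).
#' @param ... Passed to the method-specific beamformer.
#' @return A `pw_image` (for `"txmv-admas"` it carries a `$maps` field).
#' @export
beamform <- function(cube, grid, method, f_number = 1.75, ...) {
  switch(match.arg(method, c("cpwc", "rxmv", "txmv", "dcr-mvdr", "txmv-dmas",
                             "tx-dmas", "txmv-admas")),
         "cpwc" = beamform_cpwc(cube, grid, f_number),
         "rxmv" = beamform_rxmv(cube, grid, f_number, ...),
         "txmv" = beamform_txmv(cube, grid, f_number, ...),
         "dcr-mvdr" = beamform_dcr_mvdr(cube, grid, f_number, ...),
         "txmv-dmas" = beamform_txmv_dmas(cube, grid, f_number, ...),
         "tx-dmas" = beamform_tx_dmas(cube, grid, f_number, ...),
         "txmv-admas" = beamform_txmv_admas(cube, grid, f_number, ...))
}
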