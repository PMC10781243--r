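# Minimum-variance (Capon) core: covariance estimation with subarray,
# temporal and forward-backward averaging, diagonal loading, and the MV
# weight solution under the unity-gain constraint w^H a = 1 with a = ones.

.as_cov <- function(R, n_subarrays = NA_integer_, loading = 0) {
  structure(list(R = R, n_subarrays = n_subarrays, loading_applied = loading),
            class = "pw_cov")
}

.cov_matrix <- function(x) if (inherits(x, "pw_cov")) x$R else x

#' Forward subarray-averaged covariance
#'
#' Averages outer products of all length-`L` forward subarrays of a data
#' vector, optionally over a temporal window of `2T+1` snapshots. The window
#' is truncated (not zero-padded) at the data edges and the normalization
#' uses the actual number of subarrays averaged.
#'
#' @param arr Complex vector (single snapshot), or a complex matrix whose
#'   rows are fast-time snapshots of the vector.
#' @param L Subarray length (`1 <= L <= length`).
#' @param T Temporal half-window in snapshots (rows of `arr`); ignored for a
#'   vector input.
#' @param n Center row for the temporal window (default: middle row).
#' @return A `pw_cov`: `L x L` Hermitian matrix `R`, `n_subarrays` averaged,
#'   `loading_applied = 0`.
#' @export
covariance_forward <- function(arr, L, T = 0, n = NULL) {
  if (is.null(dim(arr))) arr <- matrix(arr, nrow = 1)
  len <- ncol(arr)
  stopifnot(L >= 1, T >= 0)
  if (L > len) stop("subarray length L exceeds the data vector length")
  if (is.null(n)) n <- (nrow(arr) + 1) %/% 2
  rows <- max(1, n - T):min(nrow(arr), n + T)
  K <- len - L + 1
  idx <- outer(seq_len(L), seq_len(K) - 1L, "+")
  R <- matrix(0i, L, L)
  for (r in rows) {
    S <- matrix(arr[r, idx], L, K)
    R <- R + S %*% Conj(t(S))
  }
  n_sub <- length(rows) * K
  .as_cov(R / n_sub, n_sub)
}

#' Forward-backward averaging
#'
#' `R_FB = (R + J R^T J) / 2` with `J` the exchange (anti-identity) matrix.
#' The result is Hermitian and persymmetric; the operation is idempotent.
#'
#' @param R A `pw_cov` or a square complex matrix.
#' @return Same type as the input.
#' @export
fb_average <- function(R) {
  Rm <- .cov_matrix(R)
  L <- nrow(Rm)
  Rfb <- (Rm + t(Rm)[L:1, L:1, drop = FALSE]) / 2  # J R^T J = flipped transpose
  if (inherits(R, "pw_cov")) .as_cov(Rfb, R$n_subarrays, R$loading_applied) else Rfb
}

#' Diagonal loading
#'
#' Adds `delta * trace(R) / L` to the diagonal, the standard robustification
#' before inversion.
#'
#' @param R A `pw_cov` or square complex matrix.
#' @param delta Loading factor (>= 0); the paper-scale default elsewhere is 0.1.
#' @param L Divisor for the trace (default: matrix size).
#' @export
diagonal_load <- function(R, delta, L = nrow(.cov_matrix(R))) {
  stopifnot(delta >= 0)
  Rm <- .cov_matrix(R)
  load <- delta * Re(sum(diag(Rm))) / L
  Rl <- Rm + diag(load, nrow(Rm))
  if (inherits(R, "pw_cov")) .as_cov(Rl, R$n_subarrays, R$loading_applied + load) else Rl
}

#' Minimum-variance weights
#'
#' Solves `min w^H R w` subject to `w^H a = 1` with the steering vector
#' simplified to ones (the data are already delay-aligned to the main lobe):
#' `w = R^{-1} a / (a^H R^{-1} a)`, computed as a linear solve, never an
#' explicit inverse. A numerically singular `R` falls back to uniform
#' weights `a / L` with a warning.
#'
#' @param R A `pw_cov` or square complex matrix (after loading).
#' @return Complex weight vector of length `L` satisfying `w^H a = 1`.
#' @export
mv_weights <- function(R) {
  Rm <- .cov_matrix(R)
  L <- nrow(Rm)
  y <- tryCatch(solve(Rm, rep(1 + 0i, L)), error = function(e) NULL)
  s <- if (is.null(y)) 0i else sum(y)
  bad <- is.null(y) || anyNA(y) || !all(is.finite(Re(y)) & is.finite(Im(y))) ||
    Mod(s) < .Machine$double.eps * L
  if (bad) {
    warning("singular covariance matrix; falling back to uniform weights")
    return(rep(1 / L + 0i, L))
  }
  y / s
}

#' Subarray-averaged beamformer output
#'
#' Applies `w^H` to every length-`L` forward subarray of `arr` and averages:
#' `y = 1/(len - L + 1) * sum_k w^H arr[k:(k+L-1)]`.
#'
#' @param arr Complex data vector.
#' @param w MV weight vector of length `L`.
#' @param L Subarray length (default `length(w)`).
#' @return Complex scalar.
#' @export
mv_output <- function(arr, w, L = length(w)) {
  stopifnot(length(w) == L, L <= length(arr))
  K <- length(arr) - L + 1
  # mean over subarrays of w^H Z_k  ==  w^H (mean subarray)
  sub_mean <- vapply(seq_len(L), function(a) mean(arr[a:(a + K - 1)]), 0i)
  sum(Conj(w) * sub_mean)
}

#' Default temporal half-window
#'
#' The temporal covariance window spans about `wavelengths` acoustic
#' wavelengths of fast time: `2T+1` is `wavelengths * fs / f0` rounded to the
#' nearest odd integer (21 samples, `T = 10`, at 5.2 MHz / 20.8 MHz rates).
#'
#' @param geometry A `pw_geometry`.
#' @param wavelengths Window extent in wavelengths (default 5.4).
#' @export
temporal_halfwidth <- function(geometry, wavelengths = 5.4) {
  w <- wavelengths * geometry$sampling_frequency / geometry$center_frequency
  max(0L, as.integer(round((w - 1) / 2)))
}
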