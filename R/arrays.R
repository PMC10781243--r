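# Reductions of the per-pixel echo matrix into the transmit-angle array,
# the receive-channel array, and the CPWC pixel value.

#' Transmit-angle array (channel sum)
#'
#' Compounds the echo matrix over receive channels: `z_i` is the mean of
#' row `i` over the elements inside the dynamic receive aperture, giving one
#' complex value per transmit angle. Normalizing by the active-element count
#' (rather than the full element count) keeps border pixels unbiased.
#'
#' @param X A `pw_echo` from [build_echo_matrix()].
#' @return Complex vector of length `M`.
#' @export
channel_sum <- function(X) {
  stopifnot(inherits(X, "pw_echo"))
  n_act <- sum(X$rx_mask)
  if (n_act == 0) stop("empty receive-aperture mask")
  as.vector(X$values[, X$rx_mask, drop = FALSE] %*% rep(1 / n_act, n_act))
}

#' Receive-channel array (angle sum)
#'
#' Compounds the echo matrix over all `M` transmit angles: `v_j` is the mean
#' of column `j`. Masked-out channels stay exactly zero.
#'
#' @param X A `pw_echo`.
#' @return Complex vector of length `N` with attribute `rx_mask`.
#' @export
angle_sum <- function(X) {
  stopifnot(inherits(X, "pw_echo"))
  M <- nrow(X$values)
  v <- as.vector(rep(1 / M, M) %*% X$values)
  v[!X$rx_mask] <- 0i
  attr(v, "rx_mask") <- X$rx_mask
  v
}

#' CPWC value of one pixel
#'
#' Uniform-weight compounding of the echo matrix: the mean of the
#' transmit-angle array, identical (to rounding) to the mean of the
#' receive-channel array over active channels.
#'
#' @param X A `pw_echo`.
#' @return Complex scalar.
#' @export
cpwc_pixel <- function(X) {
  mean(channel_sum(X))
}
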