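# Adaptive coherence order (ADMAS): per-pixel maps of the generalized
# coherence factor and the angular variance of the transmit-angle array
# drive a pixel-wise p value for DMAS, so clutter is suppressed with a high
# coherence order while fully developed speckle keeps p near its minimum.

#' ADMAS thresholds and parameters
#'
#' Region-categorization thresholds and map parameters. Defaults are the
#' reference values tuned for 75-angle acquisitions: `[thg1 thg2] =
#' [0.1 0.2]` on the GCF, `[thv1 thv2] = [0.001 0.15]` on the normalized
#' angular variance, GCF cutoff `M0 = 1`, contrast root `m = 4`. The
#' thresholds should be re-optimized when the transmit-angle set changes.
#'
#' @param thg1,thg2 Lower/upper GCF thresholds (`0 <= thg1 < thg2 <= 1`).
#' @param thv1,thv2 Lower/upper variance thresholds (`0 <= thv1 < thv2`).
#' @param M0 GCF spectral cutoff in DFT bins (band is DC +/- M0).
#' @param m Root applied to the variance in the alpha map (>= 1).
#' @param p_min,p_max Coherence-order range mapped from the gamma map.
#' @param median_kernel Odd square kernel size (pixels) for smoothing gamma.
#' @return Object of class `pw_admas_thresholds`.
#' @export
admas_thresholds <- function(thg1 = 0.1, thg2 = 0.2, thv1 = 0.001,
                             thv2 = 0.15, M0 = 1, m = 4,
                             p_min = 1, p_max = 2, median_kernel = 5) {
  stopifnot(thg1 >= 0, thg1 < thg2, thg2 <= 1, thv1 >= 0, thv1 < thv2,
            m >= 1, p_min >= 1, p_min <= p_max, M0 >= 0,
            median_kernel >= 1, median_kernel %% 2 == 1)
  structure(list(thg1 = thg1, thg2 = thg2, thv1 = thv1, thv2 = thv2,
                 M0 = as.integer(M0), m = m, p_min = p_min, p_max = p_max,
                 median_kernel = as.integer(median_kernel)),
            class = "pw_admas_thresholds")
}

#' Generalized coherence factor of a transmit-angle array
#'
#' Ratio of the spectral energy within DC +/- `M0` bins of the length-`M`
#' DFT of `z` to the total spectral energy; 1 for a perfectly coherent
#' (constant) array, 0 for an all-zero array.
#'
#' @param z Complex vector (one pixel's transmit-angle array).
#' @param M0 Spectral cutoff in bins (`M0 < M/2`).
#' @return Scalar in `[0, 1]`.
#' @export
gcf_pixel <- function(z, M0 = 1) {
  M <- length(z)
  stopifnot(M0 >= 0, M0 < M / 2)
  E <- Mod(stats::fft(z))^2
  tot <- sum(E)
  if (tot == 0) return(0)
  band <- c(seq_len(M0 + 1), if (M0 > 0) seq.int(M - M0 + 1, M))
  sum(E[band]) / tot
}

#' Angular variance of a transmit-angle array
#'
#' Sample variance of the depth-gain-compensated magnitudes `|z_i| * g`.
#' Within a map the variance image is subsequently normalized by its maximum
#' (see [coherence_maps()]) so the thresholds live on a `[0, 1]` scale.
#'
#' @param z Complex vector.
#' @param depth_gain Positive attenuation-compensation gain for this depth.
#' @return Non-negative scalar.
#' @export
var_pixel <- function(z, depth_gain = 1) {
  stopifnot(depth_gain > 0)
  stats::var(Mod(z) * depth_gain)
}

#' Region categorization from GCF and variance maps
#'
#' Pixels with low focusing quality are split into three regions, applied
#' with precedence I > II > III:
#' region I (off-axis clutter): `var > thv2`;
#' region II (uncorrelated noise): `gcf < thg1`;
#' region III (low-coherence cyst clutter): `gcf < thg2` and `var < thv1`.
#' All three get their GCF reset to 0; remaining pixels are background and
#' keep their GCF.
#'
#' @param gcf_map,var_map Equal-shaped numeric maps (variance normalized).
#' @param th An [admas_thresholds()] object.
#' @return List with `region` (integer map: 0 background, 1..3 regions
#'   I..III) and `gcf_reset` (the GCF map after the reset).
#' @export
categorize_regions <- function(gcf_map, var_map, th = admas_thresholds()) {
  stopifnot(identical(dim(gcf_map), dim(var_map)) ||
              length(gcf_map) == length(var_map))
  r1 <- var_map > th$thv2
  r2 <- !r1 & gcf_map < th$thg1
  r3 <- !r1 & !r2 & gcf_map < th$thg2 & var_map < th$thv1
  region <- array(0L, dim = if (is.null(dim(gcf_map))) length(gcf_map) else dim(gcf_map))
  region[r1] <- 1L; region[r2] <- 2L; region[r3] <- 3L
  gcf_reset <- gcf_map
  gcf_reset[region > 0L] <- 0
  list(region = region, gcf_reset = gcf_reset)
}

#' Alpha map: variance-tempered coherence
#'
#' `alpha = gcf_reset ^ (var ^ (1/m))`. In speckle the variance approaches
#' zero, so the exponent vanishes and alpha approaches 1 regardless of the
#' raw GCF fluctuation; a reset GCF of 0 forces alpha to 0 (the `0^0` case
#' is defined as 0: the region reset dominates).
#'
#' @param gcf_reset GCF values after region reset, in `[0, 1]`.
#' @param var Normalized variance values (>= 0).
#' @param m Contrast root (default 4).
#' @export
alpha_pixel <- function(gcf_reset, var, m = 4) {
  stopifnot(all(gcf_reset >= 0), all(gcf_reset <= 1), all(var >= 0), m >= 1)
  out <- ifelse(gcf_reset <= 0, 0, gcf_reset^(var^(1 / m)))
  if (!is.null(dim(gcf_reset))) dim(out) <- dim(gcf_reset)
  out
}

#' Gamma map: inverse S-curve
#'
#' `gamma = 1 - 1 / (1 + exp(-(18 alpha - 9)))`, a strictly decreasing
#' logistic ramp with `gamma(0.5) = 0.5` exactly, mapping low coherence to a
#' high coherence order.
#'
#' @param alpha Values in `[0, 1]`.
#' @export
gamma_pixel <- function(alpha) {
  stopifnot(all(alpha >= 0), all(alpha <= 1))
  stats::plogis(9 - 18 * alpha)
}

#' Sliding median filter with replicated edges
#'
#' Per-pixel median over an odd rectangular kernel, used to remove pinholes
#' from the gamma map before the p mapping.
#'
#' @param map Numeric matrix.
#' @param kernel Odd kernel size in pixels: a scalar for a square window or
#'   `c(rows, cols)` (default 5 x 5).
#' @export
median_filter_map <- function(map, kernel = 5) {
  kernel <- rep_len(as.integer(kernel), 2)
  stopifnot(is.matrix(map), all(kernel >= 1), all(kernel %% 2 == 1))
  if (all(kernel == 1)) return(map)
  kr <- (kernel[1] - 1) / 2; kc <- (kernel[2] - 1) / 2
  nz <- nrow(map); nx <- ncol(map)
  vals <- matrix(0, nz * nx, kernel[1] * kernel[2])
  col <- 1L
  for (dr in -kr:kr) {
    ri <- pmin(pmax(seq_len(nz) + dr, 1L), nz)
    for (dc in -kc:kc) {
      ci <- pmin(pmax(seq_len(nx) + dc, 1L), nx)
      vals[, col] <- map[ri, ci]
      col <- col + 1L
    }
  }
  matrix(apply(vals, 1, stats::median), nz, nx)
}

#' Adaptive coherence-order map
#'
#' Affine mapping of the gamma map onto the coherence-order range:
#' `p = gamma * (p_max - 1) + p_min`, so `gamma = 0` gives `p_min` and
#' (with `p_min = 1`) `gamma = 1` gives `p_max`.
#'
#' @param gamma_map Values in `[0, 1]`.
#' @param p_min,p_max Coherence-order range.
#' @export
adaptive_p_map <- function(gamma_map, p_min = 1, p_max = 2) {
  stopifnot(p_min >= 1, p_max >= p_min)
  gamma_map * (p_max - 1) + p_min
}

# shared map computation from a delay stack
.maps_from_stack <- function(st, th) {
  M <- ncol(st$Z)
  nz <- st$nz; nx <- st$nx
  # GCF from the unpadded length-M DFT of each pixel's Z
  E <- Mod(stats::mvfft(t(st$Z)))^2            # M x npix
  tot <- colSums(E)
  band <- c(seq_len(th$M0 + 1), if (th$M0 > 0) seq.int(M - th$M0 + 1, M))
  g <- colSums(E[band, , drop = FALSE]) / ifelse(tot > 0, tot, 1)
  g[tot == 0] <- 0
  gcf <- matrix(g, nz, nx)

  # depth gain: inverse of the smoothed mean CPWC envelope per depth (TGC)
  env <- matrix(Mod(st$Z %*% rep(1 / M, M)), nz, nx)
  prof <- rowMeans(env)
  kw <- min(31, if (nz %% 2 == 1) nz else nz - 1)
  if (kw >= 3) {
    sm <- stats::filter(prof, rep(1 / kw, kw), sides = 2)
    prof <- ifelse(is.na(sm), prof, as.numeric(sm))
  }
  prof <- pmax(prof, max(prof) * 1e-3)
  if (max(prof) == 0) prof[] <- 1
  gain <- 1 / prof

  Xm <- Mod(st$Z) * gain[rep(seq_len(nz), nx)]
  rs <- rowSums(Xm)
  v <- (rowSums(Xm^2) - rs^2 / M) / (M - 1)
  v <- pmax(v, 0)
  if (max(v) > 0) v <- v / max(v)
  var_map <- matrix(v, nz, nx)

  cat_ <- categorize_regions(gcf, var_map, th)
  alpha <- alpha_pixel(cat_$gcf_reset, var_map, th$m)
  gam <- gamma_pixel(alpha)
  # physically square median window: the kernel size is stated in lateral
  # pixels; on a finer axial grid the axial arm widens to the same extent
  kz <- th$median_kernel
  if (nz > 1 && nx > 1) {
    dxs <- diff(st$grid$lateral_x[1:2]); dzs <- diff(st$grid$axial_z[1:2])
    kz <- as.integer(round(th$median_kernel * dxs / dzs))
    kz <- min(max(kz, 1L), nz)
    if (kz %% 2 == 0) kz <- kz + 1L
  }
  gam_f <- median_filter_map(gam, c(kz, th$median_kernel))
  p_ad <- adaptive_p_map(gam_f, th$p_min, th$p_max)
  structure(list(gcf = gcf, var = var_map, region = cat_$region,
                 gcf_reset = cat_$gcf_reset, alpha = alpha, gamma = gam_f,
                 p_adaptive = p_ad, thresholds = th),
            class = "pw_maps")
}

#' Coherence maps for adaptive DMAS
#'
#' Computes the per-pixel GCF, normalized angular variance, region labels,
#' alpha, gamma (median-filtered) and adaptive-p maps for a cube on a grid.
#'
#' @inheritParams beamform_cpwc
#' @param thresholds An [admas_thresholds()] object.
#' @return Object of class `pw_maps` (a list of `nz x nx` maps).
#' @export
coherence_maps <- function(cube, grid, f_number = 1.75,
                           thresholds = admas_thresholds()) {
  st <- .delay_stack(cube, grid, f_number)
  .maps_from_stack(st, thresholds)
}

#' TxMV-ADMAS beamforming
#'
#' The adaptive-coherence pipeline: transmit-angle arrays -> GCF and
#' variance maps -> region reset -> alpha -> gamma -> median filter ->
#' per-pixel p map, then the TxMV-DMAS pipeline with each pixel's own p used
#' both for the root scaling and for the dimensionality restoration.
#'
#' @inheritParams beamform_txmv
#' @param thresholds An [admas_thresholds()] object (carries `p_min`,
#'   `p_max` and the categorization thresholds).
#' @return A `pw_image` with an extra `$maps` field holding the `pw_maps`.
#' @export
beamform_txmv_admas <- function(cube, grid, f_number = 1.75,
                                thresholds = admas_thresholds(), L = 25,
                                T = NULL, delta = 0.1) {
  if (is.null(T)) T <- temporal_halfwidth(cube$geometry)
  st <- .delay_stack(cube, grid, f_number)
  maps <- .maps_from_stack(st, thresholds)
  field <- .txmv_field(st$Z, st$nz, st$nx, L = L, T = T, delta = delta,
                       p = as.vector(maps$p_adaptive))
  img <- .field_to_image(field, st, "txmv-admas",
                         list(f_number = f_number, L = L, T = T,
                              delta = delta, p_min = thresholds$p_min,
                              p_max = thresholds$p_max))
  img$maps <- maps
  img
}
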