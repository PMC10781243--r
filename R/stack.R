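# Whole-image delay engine. For every pixel of the grid this computes the
# transmit-angle array Z (pixels x M) and the receive-channel array V
# (pixels x N) by delaying and compounding the analytic cube, with the
# dynamic receive aperture applied. Pixels are stored column-major over the
# [z, x] image, i.e. pix = iz + (ix - 1) * nz, so an axial shift of one image
# row equals one fast-time sample on the default grid.

.delay_stack <- function(cube, grid, f_number) {
  geom <- cube$geometry
  sq <- cube$sequence
  M <- length(sq$angles)
  N <- geom$n_elements
  nt <- dim(cube$data)[3]
  fs <- geom$sampling_frequency
  c0 <- geom$sound_speed
  xg <- grid$lateral_x
  zg <- grid$axial_z
  nz <- length(zg); nx <- length(xg)
  npix <- nz * nx
  X <- rep(xg, each = nz)
  Z <- rep(zg, times = nx)

  # dynamic aperture: |element - x| <= z / (2 F#), nearest-2 fallback
  dist <- abs(outer(X, geom$element_x, "-"))           # npix x N
  active <- dist <= Z / (2 * f_number) + 1e-12
  n_act <- rowSums(active)
  short <- which(n_act < 2)
  if (length(short)) {
    for (p in short) {
      active[p, ] <- FALSE
      active[p, order(dist[p, ])[1:2]] <- TRUE
    }
    n_act[short] <- 2L
  }

  rxs <- sqrt(Z^2 + dist^2) * (fs / c0)                # rx delay in samples
  Zs <- matrix(0i, npix, M)
  Vs <- matrix(0i, npix, N)
  for (i in seq_len(M)) {
    txs <- (Z * cos(sq$angles[i]) + X * sin(sq$angles[i])) * (fs / c0) -
      sq$t0[i] * fs
    acc <- numeric(npix) + 0i
    for (j in seq_len(N)) {
      s <- txs + rxs[, j] + 1
      s0 <- floor(s)
      w <- s - s0
      ok <- s0 >= 1 & s0 <= nt - 1
      v <- rep(0i, npix)
      if (any(ok)) {
        series <- cube$data[i, j, ]
        v[ok] <- series[s0[ok]] * (1 - w[ok]) + series[s0[ok] + 1] * w[ok]
      }
      Vs[, j] <- Vs[, j] + v
      v[!active[, j]] <- 0i
      acc <- acc + v
    }
    Zs[, i] <- acc / n_act
  }
  Vs <- (Vs / M) * active
  list(Z = Zs, V = Vs, active = active, n_act = n_act,
       nz = nz, nx = nx, grid = grid)
}

# p-th-root magnitude scaling, phase preserved; p may be a scalar or a
# per-pixel vector recycled down the columns of a pixels x M matrix.
.root_scale <- function(Z, p) {
  mag <- Mod(Z)
  ph <- Z
  nz <- mag > 0
  ph[nz] <- Z[nz] / mag[nz]
  ph[!nz] <- 0i
  mag^(1 / p) * ph
}

# magnitude p-power with phase preserved (the restoration step)
.power_restore <- function(Y, p) {
  mag <- Mod(Y)
  ph <- Y
  nz <- mag > 0
  ph[nz] <- Y[nz] / mag[nz]
  ph[!nz] <- 0i
  mag^p * ph
}

# Vectorized transmit-dimension MV / MV-DMAS kernel over all pixels.
#
# Zstack: pixels x M transmit-angle arrays (pix = iz + (ix-1) nz).
# p: scalar or per-pixel coherence order; p = 1 is plain TxMV.
# Temporal averaging uses the 2T+1 axial image rows centered on each pixel
# (truncated at the image edges, normalized by the actual count).
.txmv_field <- function(Zstack, nz, nx, L, T, delta, p = 1,
                        forward_backward = TRUE) {
  M <- ncol(Zstack)
  if (L > M) stop("subarray length L exceeds the number of transmit angles")
  npix <- nrow(Zstack)
  Zs <- if (all(p == 1)) Zstack else .root_scale(Zstack, p)
  K <- M - L + 1
  iz <- rep(seq_len(nz), times = nx)

  if (L == 1) {
    W <- matrix(1 + 0i, npix, 1)
  } else {
    # covariance accumulation via lag products:
    # R[a, a+d] = sum_k Zt[, k+a-1] Conj(Zt[, k+a-1+d])
    Rflat <- matrix(0i, npix, L * L)
    cnt <- numeric(npix)
    for (t in seq.int(-T, T)) {
      valid <- iz + t >= 1 & iz + t <= nz
      if (!any(valid)) next
      Zt <- matrix(0i, npix, M)
      Zt[valid, ] <- Zs[which(valid) + t, , drop = FALSE]
      cnt <- cnt + valid * K
      for (d in 0:(L - 1)) {
        Pd <- Zt[, seq_len(M - d), drop = FALSE] *
          Conj(Zt[, seq_len(M - d) + d, drop = FALSE])
        cs <- Pd
        for (m in seq_len(M - d)[-1]) cs[, m] <- cs[, m - 1] + cs[, m]
        for (a in seq_len(L - d)) {
          b <- a + d
          seg <- cs[, a + K - 1] - if (a > 1) cs[, a - 1] else 0i
          Rflat[, (b - 1) * L + a] <- Rflat[, (b - 1) * L + a] + seg
        }
      }
    }
    Rflat <- Rflat / cnt
    # fill lower triangle (Hermitian)
    for (a in seq_len(L)) for (b in seq_len(a - 1)) {
      Rflat[, (b - 1) * L + a] <- Conj(Rflat[, (a - 1) * L + b])
    }
    if (forward_backward) {
      # (J R^T J)[a, b] = R[L+1-b, L+1-a]
      perm <- as.vector(outer(seq_len(L), seq_len(L), function(a, b) {
        ((L + 1 - a) - 1) * L + (L + 1 - b)
      }))
      Rflat <- (Rflat + Rflat[, perm, drop = FALSE]) / 2
    }
    dcols <- (seq_len(L) - 1) * L + seq_len(L)
    tr <- rowSums(Re(Rflat[, dcols, drop = FALSE]))
    load <- delta * tr / L
    for (dc in dcols) Rflat[, dc] <- Rflat[, dc] + load

    W <- matrix(0i, npix, L)
    a1 <- rep(1 + 0i, L)
    dead <- rowSums(Mod(Zs)) == 0
    W[dead, ] <- 1 / L
    for (pix in which(!dead)) {
      Rm <- matrix(Rflat[pix, ], L, L)
      y <- tryCatch(solve(Rm, a1), error = function(e) NULL)
      s <- if (is.null(y)) 0i else sum(y)
      if (is.null(y) || anyNA(y) || Mod(s) < .Machine$double.eps * L) {
        W[pix, ] <- 1 / L
      } else {
        W[pix, ] <- y / s
      }
    }
  }

  # per-subarray dot products, p-power restoration, subarray average
  Y <- matrix(0i, npix, K)
  for (k in seq_len(K)) {
    yk <- rep(0i, npix)
    for (a in seq_len(L)) yk <- yk + Conj(W[, a]) * Zs[, k + a - 1]
    Y[, k] <- yk
  }
  if (!all(p == 1)) Y <- .power_restore(Y, p)
  as.vector(Y %*% rep(1 / K, K))
}
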