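# Shared fixtures. Heavy synthetic cubes are built once per test run and
# memoized here; all fixtures are generated in code, nothing is stored.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(name, builder) {
  if (!exists(name, .fx, inherits = FALSE)) assign(name, builder(), .fx)
  get(name, .fx, inherits = FALSE)
}

# --- small unit-test scale -------------------------------------------------

fx_geom <- function(n = 32) transducer_geometry(n, 0.3e-3, 5.2e6, 20.8e6)

# single point scatterer at (0, 20 mm), M = 7 angles, N = 32 elements
fx_point_cube <- function() fx_memo("point_cube", function() {
  simulate_cube(make_point_phantom(0, 20e-3), fx_geom(), plane_wave_angles(7, 7.5))
})

fx_point_grid <- function() fx_memo("point_grid", function() {
  image_grid(fx_geom(), c(-2e-3, 2e-3), c(19e-3, 21e-3))
})

# a synthetic per-pixel echo matrix with a given aperture mask
fx_echo <- function(values, rx_mask = rep(TRUE, ncol(values))) {
  values[, !rx_mask] <- 0i
  structure(list(values = values, rx_mask = rx_mask, out_of_range = FALSE),
            class = "pw_echo")
}

fx_random_echo <- function(M, N, n_masked = 0, seed = 1) {
  set.seed(seed)
  vals <- matrix(complex(real = rnorm(M * N), imaginary = rnorm(M * N)), M, N)
  mask <- rep(TRUE, N)
  if (n_masked > 0) mask[sample.int(N, n_masked)] <- FALSE
  fx_echo(vals, mask)
}

rand_cplx <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  complex(real = rnorm(n), imaginary = rnorm(n))
}

# --- study scale (the package's reduced synthetic conditions) --------------
# N = 64 elements, M = 15 angles spanning -7.5..+7.5 degrees, PICMUS-like
# probe rates; phantoms sized so the full MV/ADMAS chain stays fast.

acc_geom <- function() transducer_geometry(64, 0.3e-3, 5.2e6, 20.8e6)
acc_seq <- function() plane_wave_angles(15, 7.5)

acc_point_cube <- function() fx_memo("acc_point_cube", function() {
  simulate_cube(make_point_phantom(0, 30e-3), acc_geom(), acc_seq())
})

acc_point_grid <- function() fx_memo("acc_point_grid", function() {
  g <- acc_geom()
  image_grid(g, c(-2.5e-3, 2.5e-3), c(29e-3, 31e-3), dx = wavelength(g) / 8)
})

acc_cyst <- function() roi_circle(0, 27e-3, 2.5e-3)

acc_cyst_cube <- function() fx_memo("acc_cyst_cube", function() {
  simulate_cube(
    make_cyst_phantom(c(-7e-3, 7e-3), c(22e-3, 32e-3),
                      cysts = list(acc_cyst()), seed = 7),
    acc_geom(), acc_seq())
})

acc_cyst_grid <- function() fx_memo("acc_cyst_grid", function() {
  image_grid(acc_geom(), c(-6.2e-3, 6.2e-3), c(24.5e-3, 29.5e-3))
})

# pure speckle: a slab large enough to hold several hundred independent
# speckle cells, so envelope statistics are measurable
acc_speckle_cube <- function() fx_memo("acc_speckle_cube", function() {
  simulate_cube(
    make_cyst_phantom(c(-8e-3, 8e-3), c(21.5e-3, 32.5e-3), seed = 11),
    acc_geom(), acc_seq())
})

acc_speckle_grid <- function() fx_memo("acc_speckle_grid", function() {
  image_grid(acc_geom(), c(-6e-3, 6e-3), c(23e-3, 31e-3))
})

# ROI pair for contrast metrics: cyst ROI concentric at 70% radius,
# equal-area background circles flanking the cyst at the same depth
acc_cyst_roi <- function() roi_circle(0, 27e-3, 1.75e-3, "cyst")
acc_bck_rois <- function() list(roi_circle(-4.3e-3, 27e-3, 1.75e-3, "background"),
                                roi_circle(4.3e-3, 27e-3, 1.75e-3, "background"))

# memoized beamformed images of the cyst cube (shared by admas + acceptance)
acc_cyst_image <- function(method, p = NULL) {
  key <- paste0("cyst_img_", method, "_", if (is.null(p)) "na" else p)
  fx_memo(key, function() {
    cube <- acc_cyst_cube(); grid <- acc_cyst_grid()
    switch(method,
           cpwc = beamform_cpwc(cube, grid),
           txmv = beamform_txmv(cube, grid, L = 5),
           "txmv-dmas" = beamform_txmv_dmas(cube, grid, p = p, L = 5),
           "txmv-admas" = beamform_txmv_admas(
             cube, grid, thresholds = admas_thresholds(p_max = p), L = 5))
  })
}
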