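# HDF5 input/output. Two layouts are supported: a simple native layout for
# synthetic cubes (flat datasets /data_real, /data_imag, /angles, /fs, /f0,
# /c, /element_x, /t0, /pitch) and PICMUS-style files, located by probing
# dataset basenames across the known group spellings of the public releases.

#' Write a cube in the native HDF5 layout
#'
#' @param cube A `pw_cube`.
#' @param path Output file path (overwritten).
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll())
  rhdf5::h5write(Re(cube$data), path, "data_real")
  rhdf5::h5write(Im(cube$data), path, "data_imag")
  rhdf5::h5write(cube$sequence$angles, path, "angles")
  rhdf5::h5write(cube$sequence$t0, path, "t0")
  rhdf5::h5write(cube$geometry$sampling_frequency, path, "fs")
  rhdf5::h5write(cube$geometry$center_frequency, path, "f0")
  rhdf5::h5write(cube$geometry$sound_speed, path, "c")
  rhdf5::h5write(cube$geometry$element_x, path, "element_x")
  rhdf5::h5write(cube$geometry$pitch, path, "pitch")
  invisible(path)
}

.h5_read_required <- function(path, name, listing) {
  if (!name %in% listing$name[listing$otype == "H5I_DATASET"])
    stop(sprintf("HDF5 file '%s' is missing required dataset '/%s'", path, name))
  rhdf5::h5read(path, name)
}

#' Read a cube from the native HDF5 layout
#'
#' @param path HDF5 file written by [write_cube()].
#' @return A `pw_cube`.
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  listing <- tryCatch(rhdf5::h5ls(path),
                      error = function(e) stop("not a readable HDF5 file: ",
                                               path, " (", conditionMessage(e), ")"))
  on.exit(rhdf5::h5closeAll())
  re <- .h5_read_required(path, "data_real", listing)
  im <- .h5_read_required(path, "data_imag", listing)
  angles <- as.numeric(.h5_read_required(path, "angles", listing))
  fs <- as.numeric(.h5_read_required(path, "fs", listing))
  f0 <- as.numeric(.h5_read_required(path, "f0", listing))
  c0 <- as.numeric(.h5_read_required(path, "c", listing))
  ex <- as.numeric(.h5_read_required(path, "element_x", listing))
  pitch <- as.numeric(.h5_read_required(path, "pitch", listing))
  t0 <- as.numeric(.h5_read_required(path, "t0", listing))
  geom <- transducer_geometry(length(ex), pitch, f0, fs, c0)
  sq <- plane_wave_sequence(angles, t0)
  analytic_cube(complex(real = re, imaginary = im) |> array(dim = dim(re)),
                geom, sq)
}

# locate a dataset whose basename matches any of `names`; returns its full
# path or NULL
.h5_find <- function(listing, names) {
  ds <- listing[listing$otype == "H5I_DATASET", , drop = FALSE]
  hit <- ds[ds$name %in% names, , drop = FALSE]
  if (!nrow(hit)) return(NULL)
  paste0(sub("^/$", "", hit$group[1]), "/", hit$name[1])
}

#' Read a PICMUS-style plane-wave dataset
#'
#' Reads multi-angle plane-wave channel data from the HDF5 layout of the
#' public plane-wave imaging challenge datasets (dataset names are probed
#' across the known group spellings). RF data are converted to the analytic
#' signal; analytic (zero-carrier IQ) data pass through. Demodulated IQ
#' with a nonzero modulation frequency is rejected.
#'
#' @param path HDF5 file.
#' @return A `pw_cube`.
#' @export
read_picmus <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  listing <- tryCatch(rhdf5::h5ls(path),
                      error = function(e) stop("not a readable HDF5 file: ",
                                               path, " (", conditionMessage(e), ")"))
  on.exit(rhdf5::h5closeAll())
  need <- function(names, what) {
    p <- .h5_find(listing, names)
    if (is.null(p))
      stop(sprintf("PICMUS file '%s' is missing the %s dataset (looked for: %s)",
                   path, what, paste(names, collapse = ", ")))
    rhdf5::h5read(path, p)
  }
  angles <- as.numeric(need(c("angles", "angle"), "transmit-angle"))
  fs <- as.numeric(need(c("sampling_frequency", "fs"), "sampling-frequency"))[1]
  c0 <- as.numeric(need(c("sound_speed", "c0", "c"), "sound-speed"))[1]
  probe <- need(c("probe_geometry", "element_x"), "probe-geometry")
  # probe_geometry is stored as (x, y, z) per element, in either orientation
  ex <- if (!is.matrix(probe)) as.numeric(probe)
        else if (nrow(probe) <= 3 && ncol(probe) > 3) probe[1, ]
        else probe[, 1]
  f0p <- .h5_find(listing, c("center_frequency", "f0", "transmit_frequency"))
  f0 <- if (!is.null(f0p)) as.numeric(rhdf5::h5read(path, f0p))[1] else 5.2e6
  t0p <- .h5_find(listing, c("initial_time", "t0"))
  t0 <- if (!is.null(t0p)) as.numeric(rhdf5::h5read(path, t0p)) else 0
  modp <- .h5_find(listing, "modulation_frequency")
  if (!is.null(modp)) {
    fm <- as.numeric(rhdf5::h5read(path, modp))[1]
    if (is.finite(fm) && fm != 0)
      stop("demodulated IQ data (nonzero modulation frequency) are not supported; ",
           "use the RF variant of the dataset")
  }
  re <- need(c("real", "data_real"), "channel-data (real part)")
  imp <- .h5_find(listing, c("imag", "data_imag"))
  im <- if (!is.null(imp)) rhdf5::h5read(path, imp) else NULL

  M <- length(angles)
  N <- length(ex)
  d <- dim(re)
  if (is.null(d) || length(d) != 3)
    stop("channel data must be a 3D array; got dimensions: ",
         paste(dim(re), collapse = " x "))
  di_m <- which(d == M); di_n <- which(d == N)
  if (length(di_m) < 1 || length(di_n) < 1)
    stop(sprintf(paste0("cannot match data dimensions (%s) to %d angles and ",
                        "%d elements"), paste(d, collapse = " x "), M, N))
  # tie-break duplicated matches: fast time is the remaining (largest) axis
  di_m <- di_m[1]
  di_n <- setdiff(di_n, di_m)[1]
  if (is.na(di_n)) stop("ambiguous channel-data dimensions")
  di_t <- setdiff(1:3, c(di_m, di_n))
  perm <- c(di_m, di_n, di_t)
  re <- aperm(re, perm)
  if (!is.null(im)) im <- aperm(im, perm)

  pitch <- if (N > 1) stats::median(diff(sort(ex))) else 0.3e-3
  geom <- transducer_geometry(N, pitch, f0, fs, c0)
  geom$element_x <- as.numeric(sort(ex))  # honor file positions
  ord <- order(angles)
  sq <- plane_wave_sequence(angles[ord], rep_len(t0, M)[ord])
  data <- if (is.null(im) || all(im == 0)) to_analytic(re)
          else complex(real = re, imaginary = im) |> array(dim = dim(re))
  analytic_cube(data[ord, , , drop = FALSE], geom, sq)
}
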