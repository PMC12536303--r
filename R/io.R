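# File formats: multi-page 32-bit TIFF for volumes and angiograms
# (page order = repeat index for frame series), YAML sidecar for scan
# metadata, CSV for reports.

#' Write / read an OCT frame series as per-position TIFF stacks
#'
#' Each slow-axis position is stored as one multi-page 32-bit TIFF
#' (`pos_0001.tif`, ...; page order = repeat index). TIFF samples are
#' limited to \[0, 1\], so amplitudes are divided by their maximum and
#' the scale recorded, together with the scan metadata, in a
#' `meta.yaml` sidecar. The IBDV statistic is amplitude-scale invariant,
#' so the rescaling does not affect downstream results.
#'
#' @param series An [oct_frame_series()].
#' @param dir Directory to create/fill.
#' @return `write_frame_series()` returns `dir` invisibly;
#'   `read_frame_series()` returns an `oct_frame_series`.
#' @export
write_frame_series <- function(series, dir) {
  stopifnot(inherits(series, "oct_frame_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(series$amplitude)
  scale <- max(series$amplitude, 1e-12)
  for (y in seq_len(d[4])) {
    pages <- lapply(seq_len(d[3]), function(j)
      t(series$amplitude[, , j, y]) / scale)   # rows = depth for display
    tiff::writeTIFF(pages, file.path(dir, sprintf("pos_%04d.tif", y)),
                    bits.per.sample = 32L, compression = "none")
  }
  yaml::write_yaml(list(J = d[3], n_positions = d[4], dt = series$dt,
                        lateral_spacing_um = series$lateral_spacing_um,
                        slow_spacing_um = series$slow_spacing_um,
                        axial_spacing_um = series$axial_spacing_um,
                        amplitude_scale = scale),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_frame_series
#' @export
read_frame_series <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  files <- sort(list.files(dir, pattern = "^pos_\\d+\\.tif$",
                           full.names = TRUE))
  if (!length(files)) stop("no pos_*.tif stacks found in ", dir)
  first <- tiff::readTIFF(files[1], all = TRUE)
  nx <- ncol(first[[1]]); nz <- nrow(first[[1]])
  amp <- array(0, dim = c(nx, nz, meta$J, length(files)))
  for (y in seq_along(files)) {
    pages <- if (y == 1) first else tiff::readTIFF(files[y], all = TRUE)
    for (j in seq_len(meta$J)) amp[, , j, y] <- t(pages[[j]])
  }
  oct_frame_series(amp * meta$amplitude_scale, J = meta$J, dt = meta$dt,
                   lateral_spacing_um = meta$lateral_spacing_um,
                   slow_spacing_um = meta$slow_spacing_um,
                   axial_spacing_um = meta$axial_spacing_um)
}

#' Write a Doppler-variance volume as a multi-page TIFF
#'
#' One 32-bit page per slow-axis position; masked (`NaN`) voxels are
#' written as 0 and recorded in a companion `*_mask.tif`.
#'
#' @param volume A `doppler_variance_volume`.
#' @param path Output path (`.tif`).
#' @export
write_volume_tiff <- function(volume, path) {
  stopifnot(inherits(volume, "doppler_variance_volume"))
  d <- dim(volume$sigma2)
  pages <- lapply(seq_len(d[3]), function(y) {
    m <- t(volume$sigma2[, , y]); m[is.nan(m)] <- 0; m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  maskp <- lapply(seq_len(d[3]), function(y) t(volume$mask[, , y]) * 1)
  tiff::writeTIFF(maskp, sub("\\.tiff?$", "_mask.tif", path),
                  bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Write an en-face angiogram as 32-bit TIFF
#'
#' @param angiogram An `enface_angiogram` (values already in \[0, 1\]).
#' @param path Output path.
#' @export
write_angiogram_tiff <- function(angiogram, path) {
  stopifnot(inherits(angiogram, "enface_angiogram"))
  tiff::writeTIFF(t(clamp01(angiogram$image)), path, bits.per.sample = 32L,
                  compression = "none")
  invisible(path)
}

#' Read an en-face angiogram written by [write_angiogram_tiff()]
#'
#' @param path TIFF path.
#' @param lateral_spacing_um,slow_spacing_um Pixel spacings to attach.
#' @return An `enface_angiogram`.
#' @export
read_angiogram_tiff <- function(path, lateral_spacing_um = 1,
                                slow_spacing_um = lateral_spacing_um) {
  img <- t(tiff::readTIFF(path))
  structure(list(image = img, depth_range = NA, projection = "max",
                 lateral_spacing_um = lateral_spacing_um,
                 slow_spacing_um = slow_spacing_um),
            class = "enface_angiogram")
}
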