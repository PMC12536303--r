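# Inter-frame intensity-based Doppler variance (IBDV) angiography.

#' Compute an IBDV Doppler-variance B-scan from repeated frames
#'
#' For J repeated B-scans acquired at the same slow-axis position, the
#' intensity-based Doppler variance at each voxel is
#'
#' \deqn{\sigma^2 = 1 - \frac{\sum_{j=1}^{J-1} |A_j||A_{j+1}|}
#'   {\sum_{j=1}^{J-1} (|A_j|^2 + |A_{j+1}|^2)/2}}
#'
#' i.e. one minus the normalized correlation of consecutive-frame
#' amplitudes. Static tissue (identical frames) gives 0; fully
#' decorrelated speckle (flow) approaches 1. Numerator and denominator
#' are each averaged over a lateral window of `2*window + 1` A-lines
#' (and optionally `2*depth_window + 1` depth pixels) before taking the
#' ratio, which suppresses speckle noise in the estimate. The result is
#' clamped to \[0, 1\] and is invariant under global amplitude scaling.
#' Voxels with zero denominator (no signal) are defined as 0.
#'
#' @param frames Numeric 3-D array `[x, z, j]` of non-negative
#'   amplitudes (complex input is accepted; the modulus is taken), or a
#'   `J x 1 x ...`-compatible matrix list. `J = dim(frames)[3] >= 2`.
#' @param window Lateral averaging half-width in A-lines (>= 0;
#'   default 2, i.e. 5 A-lines).
#' @param depth_window Depth averaging half-width in pixels (default 0).
#' @return Numeric matrix `[x, z]` of sigma-squared values in \[0, 1\].
#' @examples
#' a <- array(rexp(2 * 3 * 4), dim = c(2, 3, 4))
#' s2 <- compute_ibdv(a, window = 0)
#' range(s2)
#' @export
compute_ibdv <- function(frames, window = 2, depth_window = 0) {
  if (is.complex(frames)) frames <- Mod(frames)
  d <- dim(frames)
  if (length(d) != 3) stop("frames must be a 3-D array [x, z, j]")
  J <- d[3]
  if (J < 2) stop("need at least two repeated frames")
  if (window < 0 || depth_window < 0) stop("window must be >= 0")
  num <- matrix(0, d[1], d[2])
  den <- matrix(0, d[1], d[2])
  for (j in seq_len(J - 1)) {
    a <- frames[, , j]; b <- frames[, , j + 1]
    num <- num + a * b
    den <- den + (a * a + b * b) / 2
  }
  num <- boxsum2(num, window, depth_window)
  den <- boxsum2(den, window, depth_window)
  s2 <- 1 - num / den
  s2[den == 0] <- 0
  clamp01(s2)
}

#' Mask low-signal voxels of a frame series
#'
#' Decorrelation in the noise floor reads as spurious flow, so voxels
#' whose mean amplitude (over the J repeats) does not exceed a quantile
#' of the volume-wide mean-amplitude distribution are flagged for
#' removal. `threshold_quantile = 0` keeps every voxel; otherwise a
#' voxel is kept iff its mean amplitude is strictly above the quantile.
#'
#' @param series An [oct_frame_series()].
#' @param threshold_quantile Fraction in \[0, 1); default 0.25.
#' @return Logical array `[x, z, y]`; `TRUE` = keep.
#' @export
intensity_mask <- function(series, threshold_quantile = 0.25) {
  stopifnot(inherits(series, "oct_frame_series"))
  if (threshold_quantile < 0 || threshold_quantile >= 1)
    stop("threshold_quantile must lie in [0, 1)")
  mean_amp <- apply(series$amplitude, c(1, 2, 4), mean)
  if (threshold_quantile == 0)
    return(array(TRUE, dim = dim(mean_amp)))
  thr <- stats::quantile(mean_amp, threshold_quantile, names = FALSE)
  mean_amp > thr
}

#' Assemble a Doppler-variance volume from a frame series
#'
#' Applies [compute_ibdv()] at every slow-axis position and then the
#' intensity mask: masked voxels become `NaN` so they are ignored by the
#' en-face projection.
#'
#' @inheritParams intensity_mask
#' @inheritParams compute_ibdv
#' @return Object of class `doppler_variance_volume`: list with `sigma2`
#'   (`[x, z, y]`, values in \[0, 1\] or `NaN` where masked), the
#'   intensity `mask`, and scan metadata.
#' @export
assemble_volume <- function(series, window = 2, depth_window = 1,
                            threshold_quantile = 0.25) {
  stopifnot(inherits(series, "oct_frame_series"))
  d <- dim(series$amplitude)
  sigma2 <- array(NA_real_, dim = d[c(1, 2, 4)])
  for (y in seq_len(d[4]))
    sigma2[, , y] <- compute_ibdv(series$amplitude[, , , y, drop = TRUE],
                                  window = window,
                                  depth_window = depth_window)
  mask <- intensity_mask(series, threshold_quantile)
  sigma2[!mask] <- NaN
  structure(list(sigma2 = sigma2, mask = mask,
                 lateral_spacing_um = series$lateral_spacing_um,
                 slow_spacing_um = series$slow_spacing_um,
                 axial_spacing_um = series$axial_spacing_um,
                 window = window, depth_window = depth_window,
                 threshold_quantile = threshold_quantile),
            class = "doppler_variance_volume")
}

#' @export
print.doppler_variance_volume <- function(x, ...) {
  d <- dim(x$sigma2)
  cat(sprintf("Doppler variance volume: %d x %d x %d (x, z, y)\n",
              d[1], d[2], d[3]))
  cat(sprintf("  masked: %.1f%%; window = %d, depth_window = %d\n",
              100 * mean(!x$mask), x$window, x$depth_window))
  invisible(x)
}

#' En-face angiogram by maximum intensity projection
#'
#' Reslices the Doppler-variance volume along depth and takes, for every
#' `(x, y)`, the maximum sigma-squared over `depth_range` (1-based,
#' inclusive), ignoring masked (`NaN`) voxels. Columns that are entirely
#' masked project to 0.
#'
#' @param volume A `doppler_variance_volume`.
#' @param depth_range Integer `c(z_lo, z_hi)`, `1 <= z_lo <= z_hi <=
#'   n_depth`; default the full depth.
#' @return Object of class `enface_angiogram`: list with `image` (matrix
#'   `[x, y]` of values in \[0, 1\]), `depth_range`, `projection =
#'   "max"`, and the en-face pixel spacings.
#' @export
enface_mip <- function(volume, depth_range = NULL) {
  stopifnot(inherits(volume, "doppler_variance_volume"))
  nz <- dim(volume$sigma2)[2]
  depth_range <- depth_range %||% c(1L, nz)
  if (length(depth_range) != 2 || depth_range[1] > depth_range[2])
    stop("depth_range must be c(z_lo, z_hi) with z_lo <= z_hi")
  if (depth_range[1] < 1 || depth_range[2] > nz)
    stop("depth_range out of volume bounds")
  zs <- seq(depth_range[1], depth_range[2])
  slab <- volume$sigma2[, zs, , drop = FALSE]
  img <- apply(slab, c(1, 3), function(v) {
    v <- v[!is.nan(v)]
    if (!length(v)) 0 else max(v)
  })
  structure(list(image = img, depth_range = depth_range, projection = "max",
                 lateral_spacing_um = volume$lateral_spacing_um,
                 slow_spacing_um = volume$slow_spacing_um),
            class = "enface_angiogram")
}

#' @export
print.enface_angiogram <- function(x, ...) {
  cat(sprintf(
    "En-face angiogram: %d x %d (x, y), max projection over z = [%d, %d]\n",
    nrow(x$image), ncol(x$image), x$depth_range[1], x$depth_range[2]))
  invisible(x)
}

#' Resample an en-face angiogram to isotropic pixels
#'
#' The slow axis is usually sampled more coarsely than the fast axis;
#' skeleton-based diameter measurement assumes square pixels, so the
#' image is linearly interpolated along the slow axis to the fast-axis
#' spacing.
#'
#' @param angiogram An `enface_angiogram`.
#' @return An `enface_angiogram` with equal pixel spacings.
#' @export
resample_isotropic <- function(angiogram) {
  stopifnot(inherits(angiogram, "enface_angiogram"))
  sx <- angiogram$lateral_spacing_um; sy <- angiogram$slow_spacing_um
  if (isTRUE(all.equal(sx, sy))) return(angiogram)
  img <- angiogram$image
  ny <- ncol(img)
  y_old <- (seq_len(ny) - 1) * sy
  ny_new <- max(2L, as.integer(round(y_old[ny] / sx)) + 1L)
  y_new <- (seq_len(ny_new) - 1) * (y_old[ny] / (ny_new - 1))
  out <- t(apply(img, 1, function(row)
    stats::approx(y_old, row, xout = y_new, rule = 2)$y))
  angiogram$image <- out
  angiogram$slow_spacing_um <- y_old[ny] / (ny_new - 1)
  angiogram
}
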