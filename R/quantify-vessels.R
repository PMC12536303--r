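# Vessel enhancement, binarization and morphometry on en-face angiograms.

# Mexican-hat (negated Laplacian-of-Gaussian) kernel, possibly
# anisotropic in pixels; scale-normalized by sigma^2 so ridges of
# different widths respond comparably under a multi-scale maximum.
mexican_hat_kernel <- function(sigma_x, sigma_y) {
  hx <- max(1L, ceiling(3 * sigma_x)); hy <- max(1L, ceiling(3 * sigma_y))
  x <- seq(-hx, hx); y <- seq(-hy, hy)
  gx <- exp(-x^2 / (2 * sigma_x^2)); gy <- exp(-y^2 / (2 * sigma_y^2))
  g <- outer(gx, gy); g <- g / sum(g)
  lap <- outer(x^2 / sigma_x^4 - 1 / sigma_x^2,
               rep(1, length(y))) +
         outer(rep(1, length(x)), y^2 / sigma_y^4 - 1 / sigma_y^2)
  k <- -g * lap * prod(c(sigma_x, sigma_y))  # -LoG, scale-normalized
  k - mean(k)                                 # exact zero DC response
}

#' Enhance tubular vessels in an en-face angiogram
#'
#' Mexican-hat (negated Laplacian-of-Gaussian) filtering at one or more
#' scales, taking the per-pixel maximum of the scale-normalized
#' responses. `scales_um` are the vessel diameters to enhance; the
#' Gaussian sigma used for a scale is `0.75 * scale` (chosen so that the
#' half-maximum width of the response to an ideal ridge matches the
#' ridge width; see the package vignette). Negative (flank) responses
#' are clipped to zero and the result is rescaled to \[0, 1\]. The
#' response is invariant to adding a constant to the image.
#'
#' @param angiogram An `enface_angiogram`, or a plain numeric matrix
#'   (then `spacing_um` supplies the pixel size).
#' @param scales_um Positive vessel diameters (micrometres) to enhance.
#' @param spacing_um Pixel spacing when `angiogram` is a bare matrix.
#' @return An `enface_angiogram` whose `image` is the filtered response
#'   in \[0, 1\], with a `provenance` field recording the scales.
#' @export
enhance_vessels <- function(angiogram, scales_um = c(160, 240),
                            spacing_um = NULL) {
  if (is.matrix(angiogram))
    angiogram <- structure(list(image = angiogram,
                                depth_range = NA, projection = "max",
                                lateral_spacing_um = spacing_um %||% 1,
                                slow_spacing_um = spacing_um %||% 1),
                           class = "enface_angiogram")
  stopifnot(inherits(angiogram, "enface_angiogram"))
  if (!length(scales_um) || any(scales_um <= 0))
    stop("scales_um must be non-empty and positive")
  sx <- angiogram$lateral_spacing_um; sy <- angiogram$slow_spacing_um
  img <- angiogram$image
  if (diff(range(img)) == 0) {           # constant image: zero response
    angiogram$image <- matrix(0, nrow(img), ncol(img))
    angiogram$provenance <- list(filter = "mexican_hat",
                                 scales_um = scales_um)
    return(angiogram)
  }
  resp <- matrix(-Inf, nrow(img), ncol(img))
  for (s in scales_um) {
    sig_x <- 0.75 * s / sx
    sig_y <- 0.75 * s / sy
    if (sig_x < 0.5 || sig_y < 0.5)
      stop(sprintf("scale %g um is below one pixel at this spacing", s))
    k <- mexican_hat_kernel(sig_x, sig_y)
    r <- EBImage::filter2(img, k, boundary = "replicate")
    resp <- pmax(resp, r)
  }
  resp <- pmax(resp, 0)
  mx <- max(resp)
  if (mx > 0) resp <- resp / mx
  angiogram$image <- resp
  angiogram$provenance <- list(filter = "mexican_hat", scales_um = scales_um)
  angiogram
}

#' Binarize a vessel-enhanced angiogram
#'
#' Thresholds the enhanced image (pixels strictly above the threshold
#' become vessel) and removes connected components smaller than
#' `min_area_px`. With `method = "otsu"` the threshold is Otsu's on a
#' 256-bin histogram of the \[0, 1\] response; a degenerate constant
#' image yields an all-background mask with a warning. `method =
#' "fixed"` uses `fixed_threshold` directly.
#'
#' @param filtered An `enface_angiogram` (from [enhance_vessels()]) or a
#'   numeric matrix with values in \[0, 1\].
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_threshold Threshold in (0, 1) when `method = "fixed"`.
#' @param min_area_px Minimum connected-component area kept (default 5).
#' @param roi Optional `c(x1, x2, y1, y2)` (1-based, inclusive)
#'   analysis region; default the whole image.
#' @return Object of class `vessel_binary_mask`: list with logical
#'   `mask` `[x, y]`, `roi`, pixel spacings, and `provenance`.
#' @export
binarize_vessels <- function(filtered, method = c("otsu", "fixed"),
                             fixed_threshold = NULL, min_area_px = 5,
                             roi = NULL) {
  method <- match.arg(method)
  if (is.matrix(filtered)) img <- filtered
  else { stopifnot(inherits(filtered, "enface_angiogram")); img <- filtered$image }
  if (method == "fixed") {
    if (is.null(fixed_threshold) || fixed_threshold <= 0 ||
        fixed_threshold >= 1)
      stop("fixed_threshold must lie in (0, 1) when method = 'fixed'")
    thr <- fixed_threshold
  } else {
    if (diff(range(img)) == 0) {
      warning("constant image: Otsu threshold undefined, returning empty mask")
      thr <- Inf
    } else {
      thr <- EBImage::otsu(EBImage::Image(clamp01(img)), range = c(0, 1))
    }
  }
  mask <- img > thr
  if (min_area_px > 1 && any(mask)) {
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    labm <- EBImage::imageData(lab)
    sizes <- tabulate(labm[labm > 0])
    small <- which(sizes < min_area_px)
    if (length(small)) mask[labm %in% small] <- FALSE
  }
  roi <- roi %||% c(1L, nrow(img), 1L, ncol(img))
  if (roi[1] < 1 || roi[3] < 1 || roi[2] > nrow(img) || roi[4] > ncol(img) ||
      roi[1] > roi[2] || roi[3] > roi[4])
    stop("roi out of image bounds")
  sp <- if (is.matrix(filtered)) list(lateral_spacing_um = 1, slow_spacing_um = 1)
        else filtered[c("lateral_spacing_um", "slow_spacing_um")]
  structure(list(mask = mask, roi = as.integer(roi),
                 lateral_spacing_um = sp$lateral_spacing_um,
                 slow_spacing_um = sp$slow_spacing_um,
                 provenance = list(method = method, threshold = thr,
                                   min_area_px = min_area_px)),
            class = "vessel_binary_mask")
}

#' Vessel density within the analysis region
#'
#' The percentage of region pixels occupied by binarized vasculature.
#'
#' @param mask A `vessel_binary_mask` (or logical matrix).
#' @param roi Optional region override, `c(x1, x2, y1, y2)`.
#' @return Density in percent, a single number in \[0, 100\].
#' @export
vessel_density <- function(mask, roi = NULL) {
  if (is.matrix(mask)) mask <- list(mask = mask,
                                    roi = c(1L, nrow(mask), 1L, ncol(mask)))
  roi <- roi %||% mask$roi
  sub <- mask$mask[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  if (!length(sub)) stop("empty roi")
  100 * sum(sub) / length(sub)
}

#' Measure vessel diameters from a binary mask
#'
#' Automates multi-point calliper measurement: the mask is skeletonized
#' (Zhang-Suen thinning) and at every `sample_step_px`-th skeleton pixel
#' the local diameter is `2 * D * spacing_um`, where `D` is the
#' Euclidean distance-transform value (distance to the nearest
#' background pixel). Skeleton pixels closer to a skeleton endpoint than
#' their own radius are excluded, so tapering tube ends do not bias the
#' estimate. Assumes approximately square pixels (see
#' [resample_isotropic()]).
#'
#' @param mask A `vessel_binary_mask` or logical matrix.
#' @param spacing_um Pixel spacing in micrometres.
#' @param sample_step_px Sampling stride along the skeleton (default 10).
#' @return List of class `vessel_metrics`: `diameter_mean_um`,
#'   `diameter_sd_um`, `n_measurements`, and the individual
#'   `diameters_um`.
#' @export
measure_diameters <- function(mask, spacing_um = NULL, sample_step_px = 10) {
  if (inherits(mask, "vessel_binary_mask")) {
    spacing_um <- spacing_um %||% mask$lateral_spacing_um
    mask <- mask$mask
  }
  spacing_um <- spacing_um %||% 1
  if (!any(mask)) stop("no vessels to measure")
  skel <- skeletonize(mask)
  dt <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
  pts <- which(skel, arr.ind = TRUE)
  # endpoints: skeleton pixels with at most one 8-connected skeleton
  # neighbour
  nb <- neighbor_count(skel)
  ends <- which(skel & nb <= 1, arr.ind = TRUE)
  keep <- rep(TRUE, nrow(pts))
  if (nrow(ends)) {
    for (i in seq_len(nrow(pts))) {
      r <- dt[pts[i, 1], pts[i, 2]]
      d2 <- (ends[, 1] - pts[i, 1])^2 + (ends[, 2] - pts[i, 2])^2
      if (any(d2 <= r * r)) keep[i] <- FALSE
    }
  }
  pts <- pts[keep, , drop = FALSE]
  if (!nrow(pts)) stop("no vessels to measure")
  pts <- pts[order(pts[, 2], pts[, 1]), , drop = FALSE]
  sel <- seq(1, nrow(pts), by = max(1L, as.integer(sample_step_px)))
  diam <- 2 * dt[pts[sel, , drop = FALSE]] * spacing_um
  structure(list(diameter_mean_um = mean(diam),
                 diameter_sd_um = if (length(diam) > 1) stats::sd(diam) else 0,
                 n_measurements = length(diam),
                 diameters_um = diam),
            class = "vessel_metrics")
}

#' @export
print.vessel_metrics <- function(x, ...) {
  cat(sprintf("Vessel diameter: %.2f +/- %.2f um (n = %d samples)\n",
              x$diameter_mean_um, x$diameter_sd_um, x$n_measurements))
  invisible(x)
}

# 8-connected neighbour count of TRUE pixels
neighbor_count <- function(m) {
  p <- matrix(FALSE, nrow(m) + 2, ncol(m) + 2)
  p[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  n <- matrix(0L, nrow(m), ncol(m))
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    n <- n + p[(2 + di):(nrow(m) + 1 + di), (2 + dj):(ncol(m) + 1 + dj)]
  }
  n
}

#' Skeletonize a binary mask (Zhang-Suen thinning)
#'
#' Iterative morphological thinning to a 1-pixel-wide, 8-connected
#' centerline.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of the same size.
#' @export
skeletonize <- function(mask) {
  m <- mask
  nr <- nrow(m); nc <- ncol(m)
  shift <- function(p, di, dj)
    p[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p <- matrix(FALSE, nr + 2, nc + 2)
      p[2:(nr + 1), 2:(nc + 1)] <- m
      # neighbours clockwise from north (P2..P9), rows = x, cols = y
      p2 <- shift(p, 0, -1); p3 <- shift(p, 1, -1); p4 <- shift(p, 1, 0)
      p5 <- shift(p, 1, 1);  p6 <- shift(p, 0, 1);  p7 <- shift(p, -1, 1)
      p8 <- shift(p, -1, 0); p9 <- shift(p, -1, -1)
      bn <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      an <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
            (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (pass == 1)
        cond <- (!p2 | !p4 | !p6) & (!p4 | !p6 | !p8)
      else
        cond <- (!p2 | !p4 | !p8) & (!p2 | !p6 | !p8)
      del <- m & bn >= 2 & bn <= 6 & an == 1 & cond
      if (any(del)) { m[del] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}
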