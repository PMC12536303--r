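# Epithelial thickness: surface and dermal-epidermal junction (DEJ)
# detection on structural B-scans.

#' Detect the tissue surface on a B-scan
#'
#' Per A-scan, the surface is the first depth at which the (trailing
#' running-mean smoothed) amplitude exceeds a noise threshold of
#' `background mean + k * SD`, with the background statistics estimated
#' from the shallowest `bg_rows` depth pixels of the whole B-scan. The
#' per-A-scan estimates are then median-filtered laterally, making the
#' detector robust to isolated speckle outliers. A-scans with no
#' crossing are reported missing (`NA`).
#'
#' For speckle suppression, pass the mean over the J repeated frames as
#' the B-scan.
#'
#' @param bscan Non-negative numeric matrix `[x, z]`.
#' @param k Threshold in background standard deviations (default 4).
#' @param bg_rows Number of shallow depth pixels treated as background.
#' @param smooth_z Trailing-mean window along depth (pixels).
#' @param median_x Lateral median-filter width (odd; default 5).
#' @return Numeric vector of surface depths (pixels, 1-based) per
#'   A-scan, `NA` where undetected.
#' @export
detect_surface <- function(bscan, k = 4, bg_rows = 10, smooth_z = 3,
                           median_x = 5) {
  stopifnot(is.matrix(bscan), min(bscan) >= 0)
  bg_rows <- min(bg_rows, ncol(bscan))
  bg <- bscan[, seq_len(bg_rows)]
  thr <- mean(bg) + k * stats::sd(as.vector(bg))
  if (!is.finite(thr)) thr <- mean(bg)
  surf <- apply(bscan, 1, function(a) {
    sm <- trailing_mean(a, smooth_z)
    i <- which(sm > thr)
    if (!length(i)) NA_real_ else i[1]
  })
  ok <- !is.na(surf)
  if (sum(ok) >= 3 && median_x >= 3) {
    width <- min(median_x, sum(ok) - (sum(ok) + 1) %% 2)
    if (width %% 2 == 0) width <- width - 1
    if (width >= 3) surf[ok] <- stats::runmed(surf[ok], width)
  }
  surf
}

#' Detect the dermal-epidermal junction below a detected surface
#'
#' Log-amplitude A-scan profiles are first aligned to the detected
#' surface (surface-relative depth), so that lateral averaging over
#' `2*lateral_avg + 1` neighbouring A-scans does not smear the boundary
#' even on strongly undulating tissue. The averaged profile is smoothed
#' along depth and detrended by the attenuation slope estimated from a
#' clean stretch below the search range; the DEJ candidate at
#' surface-relative depth d is scored by the step statistic -- the
#' difference between mean detrended log-amplitude over `step_w` pixels
#' below and above d, leaving a `smooth_z`-wide guard gap so the
#' smoothed transition does not dilute the step. The best candidate is
#' refined to the local extremum of the depth gradient (the centre of
#' the smoothed edge). If its step is weaker than `min_contrast`
#' (log-amplitude units) the DEJ is reported missing for that A-scan --
#' the expected behaviour in sclerotic tissue where dermal contrast
#' vanishes.
#'
#' @param bscan Non-negative numeric matrix `[x, z]` (mean over repeats
#'   recommended).
#' @param surface_z Per-A-scan surface depths from [detect_surface()].
#' @param min_contrast Minimum normalized boundary contrast
#'   (log-amplitude step) to accept a DEJ; default 0.4, about half
#'   the full epithelium/dermis log-amplitude step of healthy tissue.
#' @param min_offset_px Minimum epithelium depth searched below the
#'   surface (default 8).
#' @param max_offset_px Maximum search depth below the surface
#'   (default 90).
#' @param smooth_z Centered depth-smoothing half-width (default 3).
#' @param lateral_avg Lateral averaging half-width for the
#'   surface-aligned profile (default 6, i.e. 13 A-scans).
#' @param step_w Step-window width in pixels (default 6).
#' @return List of class `dej_detection`: `dej_z` (per A-scan, `NA`
#'   where missing), `contrast` (per A-scan step magnitude), and
#'   `dej_found_fraction` over A-scans with a defined surface.
#' @export
detect_dej <- function(bscan, surface_z, min_contrast = 0.4,
                       min_offset_px = 8, max_offset_px = 90,
                       smooth_z = 3, lateral_avg = 6, step_w = 6) {
  stopifnot(is.matrix(bscan), nrow(bscan) == length(surface_z))
  nx <- nrow(bscan); nz <- ncol(bscan)
  logb <- log(pmax(bscan, 1e-12))
  gap <- smooth_z
  # surface-aligned profiles: row d+1 holds log amplitude at depth
  # round(surface) + d of each A-scan
  si <- round(surface_z)
  nd <- max_offset_px + step_w + gap + 26
  aligned <- matrix(NA_real_, nd + 1, nx)
  for (j in seq_len(nx)) {
    if (is.na(si[j])) next
    ds <- 0:min(nd, nz - si[j])
    aligned[ds + 1, j] <- logb[j, si[j] + ds]
  }
  dej <- rep(NA_real_, nx)
  contrast <- rep(NA_real_, nx)
  for (i in seq_len(nx)) {
    if (is.na(si[i])) next
    cols <- max(1, i - lateral_avg):min(nx, i + lateral_avg)
    block <- aligned[, cols, drop = FALSE]
    p <- rowMeans(block, na.rm = TRUE)
    navail <- rowSums(!is.na(block))
    p[navail == 0] <- NA
    p <- centered_mean_na(p, smooth_z)
    # surface rounding can leave residual air in the first pixels
    valid_lo <- smooth_z + 2
    lo <- max(min_offset_px, valid_lo + gap + 1)
    hi <- min(max(which(!is.na(p))) - step_w - gap, max_offset_px)
    if (!is.finite(hi) || hi - lo < 2) next
    # attenuation slope from a clean stretch below the search range
    # (the DEJ, if any, lies within max_offset_px); fall back to the
    # median gradient when the scan is too shallow
    deep <- seq(hi + step_w + gap + 1,
                min(max(which(!is.na(p))) - smooth_z, hi + step_w + gap + 25))
    deep <- deep[!is.na(p[deep])]
    if (length(deep) >= 10) {
      zc <- deep - mean(deep)
      slope0 <- sum(zc * p[deep]) / sum(zc * zc)
    } else {
      slope0 <- stats::median(diff(p[valid_lo:hi]), na.rm = TRUE)
    }
    q <- p - slope0 * seq_along(p)
    ds <- lo:hi
    step <- vapply(ds, function(d) {
      below <- q[(d + 1 + gap):(d + gap + step_w) + 1]
      ab_lo <- max(valid_lo, d - gap - step_w)
      above <- q[ab_lo:(d - 1 - gap) + 1]
      mean(below, na.rm = TRUE) - mean(above, na.rm = TRUE)
    }, 0)
    j <- which.max(abs(step))
    contrast[i] <- abs(step[j])
    if (contrast[i] >= min_contrast) {
      # refine to the gradient-weighted centroid of the smoothed edge;
      # the centroid averages speckle noise that an argmax would chase
      d0 <- ds[j]
      win <- max(valid_lo, d0 - gap - 2):min(nd - 1, d0 + gap + 2)
      gd <- (p[win + 2] - p[win + 1]) * sign(step[j])
      w <- pmax(gd, 0)
      d_edge <- if (sum(w) > 0) sum(win * w) / sum(w) else d0
      dej[i] <- si[i] + d_edge + 0.5
    }
  }
  # lateral median filter over detected positions removes isolated
  # refinement outliers (the true boundary is laterally smooth)
  found <- !is.na(dej)
  if (sum(found) >= 3) {
    width <- min(5L, sum(found) - (sum(found) + 1L) %% 2L)
    if (width %% 2L == 0L) width <- width - 1L
    if (width >= 3) dej[found] <- stats::runmed(dej[found], width)
  }
  ok <- !is.na(surface_z)
  structure(list(dej_z = dej, contrast = contrast,
                 dej_found_fraction =
                   if (any(ok)) mean(!is.na(dej[ok])) else NA_real_),
            class = "dej_detection")
}

#' Epithelial thickness from surface and DEJ depths
#'
#' Per A-scan optical thickness `(dej_z - surface_z) * axial_spacing_um`
#' divided by the tissue group refractive index (`group_index = 1`
#' reports raw optical thickness; 1.4 is a typical epithelial value for
#' geometric thickness). The summary statistic is the median over
#' A-scans with a defined DEJ, which is robust to residual boundary
#' outliers. A-scans where the DEJ does not lie below the surface are
#' set missing with a warning.
#'
#' @param surface_z,dej_z Per-A-scan depths in pixels (`NA` allowed in
#'   `dej_z`).
#' @param axial_spacing_um Axial pixel spacing, micrometres (> 0).
#' @param group_index Tissue group refractive index (>= 1, default 1).
#' @param site Optional site label, e.g. `"labia_minora"`.
#' @return List of class `thickness_result`: per-A-scan `thickness_um`,
#'   summary `thickness_median_um`, `dej_found_fraction`, `site`, and
#'   the input depth vectors.
#' @export
epithelial_thickness <- function(surface_z, dej_z, axial_spacing_um,
                                 group_index = 1, site = NULL) {
  if (inherits(dej_z, "dej_detection")) dej_z <- dej_z$dej_z
  stopifnot(length(surface_z) == length(dej_z))
  if (!is.numeric(axial_spacing_um) || axial_spacing_um <= 0)
    stop("axial_spacing_um must be > 0")
  if (group_index < 1) stop("group_index must be >= 1")
  bad <- !is.na(dej_z) & !is.na(surface_z) & dej_z <= surface_z
  if (any(bad)) {
    warning(sprintf("DEJ at or above surface at %d A-scan(s); set missing",
                    sum(bad)))
    dej_z[bad] <- NA
  }
  thickness <- (dej_z - surface_z) * axial_spacing_um / group_index
  ok_surf <- !is.na(surface_z)
  structure(list(
    surface_z = surface_z, dej_z = dej_z, thickness_um = thickness,
    thickness_median_um = if (all(is.na(thickness))) NA_real_
      else stats::median(thickness, na.rm = TRUE),
    dej_found_fraction = if (any(ok_surf))
      mean(!is.na(dej_z[ok_surf])) else NA_real_,
    site = site, group_index = group_index),
    class = "thickness_result")
}

#' @export
print.thickness_result <- function(x, ...) {
  med <- if (is.na(x$thickness_median_um)) "-" else
    sprintf("%.1f um", x$thickness_median_um)
  cat(sprintf("Epithelial thickness%s: median %s (DEJ found in %.0f%% of A-scans)\n",
              if (is.null(x$site)) "" else paste0(" [", x$site, "]"),
              med, 100 * x$dej_found_fraction))
  invisible(x)
}
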