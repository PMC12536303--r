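# Synthetic OCT phantom: geometry, speckle generation, ground truth.

# Deterministic geometry shared by the generator and ground_truth():
# continuous surface / DEJ depth maps [x, y] (in pixels) and the boolean
# vessel mask [x, z, y].
phantom_geometry <- function(spec) {
  nx <- spec$n_lateral; nz <- spec$n_depth; ny <- spec$n_positions
  x_um <- (seq_len(nx) - 1) * spec$lateral_spacing_um
  y_um <- (seq_len(ny) - 1) * spec$slow_spacing_um
  sp <- spec$surface
  surface_z <- 1 + (sp$base_depth_um +
    sp$amplitude_um * outer(sin(2 * pi * x_um / sp$period_um),
                            cos(2 * pi * y_um / sp$period_um))) /
    spec$axial_spacing_um
  dej_z <- surface_z + spec$epithelium_thickness_um / spec$axial_spacing_um
  mask <- array(FALSE, dim = c(nx, nz, ny))
  for (v in spec$vessels) mask <- mark_tube(mask, v, spec)
  list(surface_z = surface_z, dej_z = dej_z, vessel_mask = mask)
}

# Mark voxels whose centres lie within radius_um of the vessel polyline.
# Distances use the anisotropic physical spacings; voxel (i, k, j) sits at
# ((i-1)*lat, (j-1)*slow, (k-1)*axial) um, matching continuous 1-based
# voxel coordinates for the centerline.
mark_tube <- function(mask, vessel, spec) {
  d <- dim(mask)
  sx <- spec$lateral_spacing_um; sy <- spec$slow_spacing_um
  sz <- spec$axial_spacing_um
  r <- vessel$radius_um
  cl <- vessel$centerline
  for (s in seq_len(nrow(cl) - 1)) {
    p <- (cl[s, ] - 1) * c(sx, sy, sz)
    q <- (cl[s + 1, ] - 1) * c(sx, sy, sz)
    lo <- pmax(1, floor(pmin(cl[s, ], cl[s + 1, ]) - r / c(sx, sy, sz) - 1))
    hi <- pmin(d[c(1, 3, 2)], ceiling(pmax(cl[s, ], cl[s + 1, ]) +
                                        r / c(sx, sy, sz) + 1))
    if (any(lo > hi)) next
    xs <- seq(lo[1], hi[1]); ys <- seq(lo[2], hi[2]); zs <- seq(lo[3], hi[3])
    g <- expand.grid(x = xs, z = zs, y = ys)
    pt <- cbind((g$x - 1) * sx, (g$y - 1) * sy, (g$z - 1) * sz)
    # point-to-segment distance
    v <- q - p
    L2 <- sum(v * v)
    t <- if (L2 == 0) rep(0, nrow(pt)) else
      clamp01(((pt[, 1] - p[1]) * v[1] + (pt[, 2] - p[2]) * v[2] +
                 (pt[, 3] - p[3]) * v[3]) / L2)
    dx <- pt[, 1] - (p[1] + t * v[1])
    dy <- pt[, 2] - (p[2] + t * v[2])
    dz <- pt[, 3] - (p[3] + t * v[3])
    inside <- (dx * dx + dy * dy + dz * dz) <= r * r
    idx <- cbind(g$x, g$z, g$y)[inside, , drop = FALSE]
    mask[idx] <- TRUE
  }
  mask
}

#' Generate a repeated-B-scan OCT frame series from a phantom
#'
#' Simulates fully developed speckle: each voxel carries a circular
#' complex Gaussian field whose consecutive-frame correlation is
#' `static_correlation` in static tissue and the vessel's
#' `flow_correlation` inside vessels (AR(1) mixing of the complex field).
#' The recorded amplitude is
#' `|field| * reflectivity * exp(-attenuation_per_um * depth_below_surface_um)`
#' plus an independent Rayleigh noise amplitude of scale `noise_floor`.
#' Above the surface the reflectivity is zero, so only the noise floor
#' remains. Output is bit-reproducible for a fixed spec (including seed).
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `oct_frame_series`: list with `amplitude`,
#'   a 4-D array indexed `[x, z, j, y]` (fast axis, depth, repeat,
#'   slow position), plus the scan metadata (`J`, `dt`, pixel spacings).
#' @seealso [ground_truth()], [assemble_volume()]
#' @export
generate_speckle_frames <- function(spec) {
  validate_phantom_spec(spec)
  geom <- phantom_geometry(spec)
  nx <- spec$n_lateral; nz <- spec$n_depth; ny <- spec$n_positions
  J <- spec$frames_per_position
  dermis_eff <- spec$epithelium_reflectivity + spec$dej_contrast *
    (spec$dermis_reflectivity - spec$epithelium_reflectivity)
  zidx <- matrix(seq_len(nz), nx, nz, byrow = TRUE)
  # per-voxel inter-frame correlation; later vessels win on overlap
  rho_vol <- array(spec$static_correlation, dim = c(nx, nz, ny))
  for (v in spec$vessels) {
    vm <- mark_tube(array(FALSE, dim = c(nx, nz, ny)), v, spec)
    rho_vol[vm] <- v$flow_correlation
  }
  amp <- array(0, dim = c(nx, nz, J, ny))
  with_local_seed(spec$seed, {
    for (y in seq_len(ny)) {
      surf <- geom$surface_z[, y]
      dej <- geom$dej_z[, y]
      depth_px <- zidx - surf              # recycled down columns
      tissue <- depth_px >= 0
      refl <- matrix(0, nx, nz)
      refl[tissue] <- spec$epithelium_reflectivity
      refl[zidx >= dej] <- dermis_eff
      gain <- refl * exp(-spec$attenuation_per_um * spec$axial_spacing_um *
                           pmax(depth_px, 0))
      rho <- rho_vol[, , y]
      mix <- sqrt(pmax(0, 1 - rho^2))
      n <- nx * nz
      field <- complex_speckle(n)
      for (j in seq_len(J)) {
        if (j > 1) field <- rho * field + mix * complex_speckle(n)
        noise <- spec$noise_floor * Mod(complex_speckle(n))
        amp[, , j, y] <- Mod(field) * gain + noise
      }
    }
  })
  oct_frame_series(amp, J = J, dt = spec$dt,
                   lateral_spacing_um = spec$lateral_spacing_um,
                   slow_spacing_um = spec$slow_spacing_um,
                   axial_spacing_um = spec$axial_spacing_um)
}

# unit-power circular complex Gaussian draws (|.| is Rayleigh, E|.|^2 = 1)
complex_speckle <- function(n) {
  complex(real = stats::rnorm(n, 0, sqrt(0.5)),
          imaginary = stats::rnorm(n, 0, sqrt(0.5)))
}

#' Ground truth of a phantom
#'
#' Returns the exact geometry the generator used: the boolean vessel
#' mask, continuous surface and DEJ depth maps, the en-face vessel area
#' fraction by exact voxel counting, the per-vessel true diameters
#' (`2 * radius_um`), and the true thickness map
#' `(dej_z - surface_z) * axial_spacing_um`.
#'
#' @param spec A [phantom_spec()].
#' @return List of class `oct_ground_truth` with elements `vessel_mask`
#'   (`[x, z, y]`), `surface_z`, `dej_z`, `true_thickness_um` (`[x, y]`),
#'   `enface_footprint` (`[x, y]`), `true_density_pct`,
#'   `true_diameters_um`.
#' @export
ground_truth <- function(spec) {
  validate_phantom_spec(spec)
  geom <- phantom_geometry(spec)
  footprint <- apply(geom$vessel_mask, c(1, 3), any)
  structure(list(
    vessel_mask = geom$vessel_mask,
    surface_z = geom$surface_z,
    dej_z = geom$dej_z,
    true_thickness_um = (geom$dej_z - geom$surface_z) * spec$axial_spacing_um,
    enface_footprint = footprint,
    true_density_pct = 100 * mean(footprint),
    true_diameters_um = vapply(spec$vessels, function(v) 2 * v$radius_um,
                               numeric(1))),
    class = "oct_ground_truth")
}

#' Construct an OCT frame series
#'
#' Container for repeated-B-scan amplitude data: a 4-D array indexed
#' `[x, z, j, y]` with J repeats per slow-axis position, plus scan
#' metadata. All amplitudes must be non-negative and J >= 2.
#'
#' @param amplitude 4-D non-negative array `[x, z, j, y]`.
#' @param J Repeats per position; must equal `dim(amplitude)[3]`.
#' @param dt Inter-frame interval, seconds.
#' @param lateral_spacing_um,slow_spacing_um,axial_spacing_um Pixel
#'   spacings in micrometres.
#' @return An `oct_frame_series`.
#' @export
oct_frame_series <- function(amplitude, J = dim(amplitude)[3], dt = 0.005,
                             lateral_spacing_um = 40,
                             slow_spacing_um = lateral_spacing_um,
                             axial_spacing_um = 5) {
  if (length(dim(amplitude)) != 4)
    stop("amplitude must be a 4-D array [x, z, j, y]")
  if (J != dim(amplitude)[3])
    stop("J must match dim(amplitude)[3]")
  if (J < 2) stop("need at least two repeated frames")
  if (min(amplitude) < 0) stop("amplitudes must be non-negative")
  structure(list(amplitude = amplitude, J = as.integer(J), dt = dt,
                 lateral_spacing_um = lateral_spacing_um,
                 slow_spacing_um = slow_spacing_um,
                 axial_spacing_um = axial_spacing_um),
            class = "oct_frame_series")
}

#' @export
print.oct_frame_series <- function(x, ...) {
  d <- dim(x$amplitude)
  cat(sprintf(
    "OCT frame series: %d A-lines x %d depth x J = %d repeats x %d positions\n",
    d[1], d[2], d[3], d[4]))
  cat(sprintf("  dt = %g s; spacing %g x %g x %g um (lat, slow, axial)\n",
              x$dt, x$lateral_spacing_um, x$slow_spacing_um,
              x$axial_spacing_um))
  invisible(x)
}
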