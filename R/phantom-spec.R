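#' Surface topography parameters for a synthetic phantom
#'
#' Describes the air/tissue interface as a smooth undulating sheet,
#' `z_surface(x, y) = base_depth_um + amplitude_um * sin(2*pi*x_um/period_um)
#' * cos(2*pi*y_um/period_um)`, expressed in micrometres and converted to
#' axial pixels by the generator. An `amplitude_um` of 0 gives a flat
#' surface.
#'
#' @param base_depth_um Mean depth of the surface below the top of the
#'   scan, in micrometres.
#' @param amplitude_um Peak undulation amplitude, micrometres.
#' @param period_um Lateral period of the undulation, micrometres.
#' @return A list of class `surface_profile`.
#' @export
surface_profile <- function(base_depth_um = 150, amplitude_um = 40,
                            period_um = 2000) {
  stopifnot(base_depth_um >= 0, amplitude_um >= 0, period_um > 0)
  structure(list(base_depth_um = base_depth_um, amplitude_um = amplitude_um,
                 period_um = period_um),
            class = "surface_profile")
}

#' Specify a tubular vessel embedded in the phantom
#'
#' A vessel is a tube of radius `radius_um` around a 3-D polyline
#' `centerline` given in continuous 1-based voxel coordinates
#' `(x, y, z)` = (fast axis, slow axis, depth). Voxels whose centres lie
#' within the radius of the polyline (using the physical pixel spacings)
#' belong to the vessel; between repeated frames their speckle
#' decorrelates to the inter-frame amplitude correlation
#' `flow_correlation` (0 = fully decorrelated, i.e. fast flow).
#'
#' @param centerline Numeric matrix with columns `x`, `y`, `z` (voxel
#'   coordinates); at least two rows.
#' @param radius_um Tube radius in micrometres, > 0.
#' @param flow_correlation Inter-frame correlation inside the vessel, in
#'   \[0, 1\].
#' @return A list of class `vessel_spec`.
#' @seealso [vessel_line()] for the common straight-tube case.
#' @export
vessel_spec <- function(centerline, radius_um, flow_correlation = 0) {
  centerline <- as.matrix(centerline)
  if (ncol(centerline) != 3 || nrow(centerline) < 2)
    stop("vessel_spec: 'centerline' must be an n x 3 matrix with n >= 2")
  if (!is.numeric(radius_um) || length(radius_um) != 1 || radius_um <= 0)
    stop("vessel_spec: 'radius_um' must be a single positive number")
  if (flow_correlation < 0 || flow_correlation > 1)
    stop("vessel_spec: 'flow_correlation' must lie in [0, 1]")
  colnames(centerline) <- c("x", "y", "z")
  structure(list(centerline = centerline, radius_um = radius_um,
                 flow_correlation = flow_correlation),
            class = "vessel_spec")
}

#' @rdname vessel_spec
#' @param from,to Numeric length-3 vectors `(x, y, z)` giving the tube
#'   end points in voxel coordinates.
#' @export
vessel_line <- function(from, to, radius_um, flow_correlation = 0) {
  vessel_spec(rbind(from, to), radius_um, flow_correlation)
}

default_vessels <- function(n_lateral, n_positions, n_depth) {
  # A sparse plexus of horizontal tubes at dermal depths; radii chosen so
  # vessels span a few lateral pixels at the default 40 um spacing.
  zs <- round(n_depth * c(0.45, 0.50, 0.55, 0.60, 0.65))
  ys <- round(n_positions * c(0.2, 0.35, 0.5, 0.65, 0.8))
  radii <- c(60, 80, 100, 80, 60)
  mapply(function(y, z, r)
    vessel_line(c(1, y, z), c(n_lateral, y, z), radius_um = r),
    ys, zs, radii, SIMPLIFY = FALSE)
}

#' Parameters of the synthetic OCT phantom
#'
#' Defines a volumetric OCT acquisition of a two-layer tissue (epithelium
#' over dermis) with fully developed speckle, an undulating surface,
#' exponential depth attenuation, embedded tubular vessels and an
#' additive noise floor. The defaults mirror an inter-frame OCTA
#' protocol over a square field of view: J = 6 repeated B-scans per
#' slow-axis position at 5 ms spacing, 40 um lateral sampling.
#'
#' Temporal speckle dynamics are an AR(1) process on the complex field:
#' frame j is `rho * frame_{j-1} + sqrt(1 - rho^2) * fresh`, with
#' `rho = static_correlation` in static tissue and the per-vessel
#' `flow_correlation` inside vessels.
#'
#' @param n_lateral A-lines per B-scan (fast axis).
#' @param n_depth Pixels per A-line (depth).
#' @param n_positions Slow-axis positions.
#' @param frames_per_position Repeated B-scans per position (J, >= 2).
#' @param dt Inter-frame interval in seconds.
#' @param lateral_spacing_um Fast-axis pixel spacing, micrometres.
#' @param slow_spacing_um Slow-axis spacing; defaults to a square field
#'   of view (`n_lateral * lateral_spacing_um / n_positions`).
#' @param axial_spacing_um Depth pixel spacing, micrometres.
#' @param surface A [surface_profile()].
#' @param epithelium_thickness_um True epithelial thickness, micrometres.
#' @param epithelium_reflectivity,dermis_reflectivity Mean backscatter of
#'   the two layers (dimensionless).
#' @param attenuation_per_um Exponential amplitude decay per micrometre
#'   of depth below the surface.
#' @param dej_contrast Scale in \[0, 1\] on the epithelium/dermis
#'   reflectivity step; 0 emulates sclerotic tissue with no detectable
#'   dermal-epidermal junction.
#' @param vessels List of [vessel_spec()] objects.
#' @param noise_floor Scale of the additive (Rayleigh-amplitude) noise.
#' @param static_correlation Inter-frame correlation of static tissue.
#' @param seed Integer RNG seed; the generator is fully reproducible.
#' @return A validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(n_lateral = 128L, n_depth = 256L, n_positions = 64L,
                         frames_per_position = 6L, dt = 0.005,
                         lateral_spacing_um = 40, slow_spacing_um = NULL,
                         axial_spacing_um = 5,
                         surface = surface_profile(),
                         epithelium_thickness_um = 200,
                         epithelium_reflectivity = 0.45,
                         dermis_reflectivity = 1,
                         attenuation_per_um = 0.002,
                         dej_contrast = 1,
                         vessels = NULL,
                         noise_floor = 0.03,
                         static_correlation = 0.99,
                         seed = 1L) {
  slow_spacing_um <- slow_spacing_um %||%
    (n_lateral * lateral_spacing_um / n_positions)
  if (is.null(vessels))
    vessels <- default_vessels(n_lateral, n_positions, n_depth)
  spec <- structure(list(
    n_lateral = as.integer(n_lateral), n_depth = as.integer(n_depth),
    n_positions = as.integer(n_positions),
    frames_per_position = as.integer(frames_per_position), dt = dt,
    lateral_spacing_um = lateral_spacing_um,
    slow_spacing_um = slow_spacing_um, axial_spacing_um = axial_spacing_um,
    surface = surface, epithelium_thickness_um = epithelium_thickness_um,
    epithelium_reflectivity = epithelium_reflectivity,
    dermis_reflectivity = dermis_reflectivity,
    attenuation_per_um = attenuation_per_um, dej_contrast = dej_contrast,
    vessels = vessels, noise_floor = noise_floor,
    static_correlation = static_correlation, seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' Validate a phantom specification
#'
#' Checks every invariant of [phantom_spec()]; errors name the offending
#' field.
#'
#' @param spec A `phantom_spec`.
#' @return `spec`, invisibly, if valid.
#' @export
validate_phantom_spec <- function(spec) {
  fail <- function(field, why)
    stop(sprintf("invalid phantom_spec: field '%s' %s", field, why),
         call. = FALSE)
  pos1 <- function(field) {
    v <- spec[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      fail(field, "must be a single positive number")
  }
  for (f in c("n_lateral", "n_depth", "n_positions", "dt",
              "lateral_spacing_um", "slow_spacing_um", "axial_spacing_um",
              "epithelium_thickness_um", "dermis_reflectivity"))
    pos1(f)
  if (spec$frames_per_position < 2)
    fail("frames_per_position", "must be >= 2")
  if (spec$epithelium_reflectivity <= 0)
    fail("epithelium_reflectivity", "must be > 0")
  if (spec$attenuation_per_um < 0) fail("attenuation_per_um", "must be >= 0")
  if (spec$noise_floor < 0) fail("noise_floor", "must be >= 0")
  if (spec$dej_contrast < 0 || spec$dej_contrast > 1)
    fail("dej_contrast", "must lie in [0, 1]")
  if (spec$static_correlation < 0 || spec$static_correlation > 1)
    fail("static_correlation", "must lie in [0, 1]")
  if (!inherits(spec$surface, "surface_profile"))
    fail("surface", "must be a surface_profile")
  for (v in spec$vessels) {
    if (!inherits(v, "vessel_spec")) fail("vessels", "must hold vessel_spec objects")
    if (v$flow_correlation > spec$static_correlation)
      fail("vessels", "has flow_correlation above static_correlation")
  }
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "OCT phantom spec: %d x %d x %d (x, z, y), J = %d, dt = %g s\n",
    x$n_lateral, x$n_depth, x$n_positions, x$frames_per_position, x$dt))
  cat(sprintf("  spacing %g x %g x %g um (lat, slow, axial); %d vessel(s)\n",
              x$lateral_spacing_um, x$slow_spacing_um, x$axial_spacing_um,
              length(x$vessels)))
  cat(sprintf("  epithelium %g um, DEJ contrast %g, seed %d\n",
              x$epithelium_thickness_um, x$dej_contrast, x$seed))
  invisible(x)
}

#' Read or write a phantom specification as YAML
#'
#' Vessels serialize as a list of `{from, to, radius_um,
#' flow_correlation}` line segments or explicit `centerline` point lists.
#'
#' @param spec A `phantom_spec`.
#' @param path File path.
#' @return `read_phantom_spec()` returns a `phantom_spec`;
#'   `write_phantom_spec()` returns `path` invisibly.
#' @export
write_phantom_spec <- function(spec, path) {
  validate_phantom_spec(spec)
  x <- unclass(spec)
  x$surface <- unclass(x$surface)
  x$vessels <- lapply(spec$vessels, function(v) {
    list(centerline = apply(unname(v$centerline), 1, as.list),
         radius_um = v$radius_um, flow_correlation = v$flow_correlation)
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  vessels <- lapply(x$vessels, function(v) {
    cl <- if (!is.null(v$centerline))
      do.call(rbind, lapply(v$centerline, unlist))
    else rbind(unlist(v$from), unlist(v$to))
    vessel_spec(cl, v$radius_um, v$flow_correlation %||% 0)
  })
  surface <- do.call(surface_profile, x$surface)
  x$surface <- NULL
  x$vessels <- NULL
  do.call(phantom_spec, c(x, list(surface = surface, vessels = vessels)))
}
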