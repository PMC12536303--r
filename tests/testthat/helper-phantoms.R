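# Shared fixture builders; everything is generated in code at test time.

# flat-surface, vessel-free spec with convenient overrides
flat_spec <- function(...) {
  args <- list(n_lateral = 64, n_depth = 160, n_positions = 2,
               vessels = list(),
               surface = surface_profile(amplitude_um = 0))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_spec, args)
}

# isotropic-grid phantom with five axis-aligned tubes of known radii,
# used for density / Dice / diameter recovery
recovery_spec <- function(seed = 42) {
  nl <- 96; np <- 96
  vess <- mapply(function(y, z, r)
    vessel_line(c(1, y, z), c(nl, y, z), radius_um = r),
    c(14, 30, 48, 66, 84), c(100, 96, 104, 100, 98),
    c(60, 80, 100, 120, 140), SIMPLIFY = FALSE)
  phantom_spec(n_lateral = nl, n_depth = 160, n_positions = np,
               slow_spacing_um = 40, vessels = vess, seed = seed)
}

# horizontal bar of a given width in a logical image
draw_bar <- function(width, len = 60, nx = 80, ny = 40, x0 = 10,
                     row0 = floor((ny - width) / 2)) {
  m <- matrix(FALSE, nx, ny)
  m[x0:(x0 + len), (row0 + 1):(row0 + width)] <- TRUE
  m
}

# 8-connected binary dilation by one pixel
dilate1 <- function(m) {
  p <- matrix(FALSE, nrow(m) + 2, ncol(m) + 2)
  p[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (di in -1:1) for (dj in -1:1)
    out <- out | p[(2 + di):(nrow(m) + 1 + di), (2 + dj):(ncol(m) + 1 + dj)]
  out
}

# structural B-scan: mean over the J repeats at one position
mean_bscan <- function(series, y = 1)
  apply(series$amplitude[, , , y, drop = FALSE], c(1, 2), mean)

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
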