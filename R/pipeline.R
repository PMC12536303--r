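# End-to-end pipeline: phantom (or stored frames) -> Doppler variance
# volume -> en-face angiogram -> vessel morphometry, plus per-site
# epithelial thickness, assembled into a morphometry report.

#' Default pipeline configuration
#'
#' A single nested list mirroring the YAML config accepted by
#' [run_pipeline()]: sections `phantom` (shared spec overrides),
#' `sites` (per-site spec overrides; thickness defaults step down from
#' keratinized labia majora to the labia minora), `angiography`,
#' `vessels`, `thickness` and `output`. One master `seed` drives every
#' stage; per-site seeds are derived by fixed offsets.
#'
#' @return Named list of defaults.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    subject_id = "phantom-01",
    group = "control",
    phantom = list(),
    sites = list(
      labia_majora = list(phantom = list(epithelium_thickness_um = 300)),
      interlabial_sulci = list(phantom = list(epithelium_thickness_um = 180)),
      labia_minora = list(phantom = list(epithelium_thickness_um = 120))),
    angiography = list(window = 2, depth_window = 1,
                       threshold_quantile = 0.25),
    vessels = list(sites = "labia_minora",
                   scales_um = c(160, 240),
                   method = "otsu", fixed_threshold = NULL,
                   min_area_px = 5, sample_step_px = 10),
    thickness = list(k = 4, min_contrast = 0.4, group_index = 1,
                     min_offset_px = 8, max_offset_px = 90),
    output = list(dir = NULL, write_volumes = FALSE))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

site_spec <- function(config, site, offset) {
  overrides <- merge_config(config$phantom %||% list(),
                            config$sites[[site]]$phantom %||% list())
  overrides$seed <- (config$seed %||% 1L) + offset
  if (!is.null(overrides$surface) && !inherits(overrides$surface,
                                               "surface_profile"))
    overrides$surface <- do.call(surface_profile, overrides$surface)
  if (!is.null(overrides$vessels) && length(overrides$vessels) &&
      !inherits(overrides$vessels[[1]], "vessel_spec"))
    overrides$vessels <- lapply(overrides$vessels, function(v)
      vessel_line(unlist(v$from), unlist(v$to), v$radius_um,
                  v$flow_correlation %||% 0))
  do.call(phantom_spec, overrides)
}

#' Run the full OCTA morphometry pipeline
#'
#' For every configured anatomical site: generate (or read) the repeated
#' B-scan series, assemble the IBDV Doppler-variance volume, detect the
#' tissue surface, project the en-face angiogram over the tissue depth,
#' and measure epithelial thickness on the central B-scan. For sites
#' listed in `config$vessels$sites`, additionally enhance, binarize and
#' measure the vasculature (density and diameter). Results are returned
#' as a [morphometry_report()] with one row per site; any stage failure
#' leaves that row's cells missing and is recorded in the log.
#'
#' When an output directory is configured (or given), the report CSV,
#' per-site angiogram TIFFs and a YAML log of every effective parameter
#' are written there. Reruns with the same config are byte-identical.
#'
#' @param config Path to a YAML config or a nested list; see
#'   [default_pipeline_config()] for structure and defaults.
#' @param output_dir Optional override of `config$output$dir`.
#' @return The `morphometry_report`, invisibly; attributes `details`
#'   (per-site intermediate results) and `paths` (written files).
#' @export
run_pipeline <- function(config = list(), output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  out_dir <- output_dir %||% cfg$output$dir
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sites <- names(cfg$sites)
  rows <- list()
  details <- list()
  paths <- character()
  log_lines <- c(sprintf("subject %s (%s), master seed %d",
                         cfg$subject_id, cfg$group, cfg$seed))
  for (i in seq_along(sites)) {
    site <- sites[i]
    res <- list(density_pct = NA_real_, diameter_mean_um = NA_real_,
                diameter_sd_um = NA_real_, vuet_um = NA_real_)
    det <- list()
    tryCatch({
      spec <- site_spec(cfg, site, offset = i)
      log_lines <- c(log_lines,
                     sprintf("[%s] phantom seed %d, thickness %g um, DEJ contrast %g",
                             site, spec$seed, spec$epithelium_thickness_um,
                             spec$dej_contrast))
      series <- generate_speckle_frames(spec)
      vol <- assemble_volume(series,
                             window = cfg$angiography$window,
                             depth_window = cfg$angiography$depth_window,
                             threshold_quantile = cfg$angiography$threshold_quantile)
      # structural B-scans: mean over the J repeats
      struct <- apply(series$amplitude, c(1, 2, 4), mean)
      surf_map <- apply(struct, 3, detect_surface, k = cfg$thickness$k)
      z_lo <- max(1L, floor(min(surf_map, na.rm = TRUE)))
      ang <- enface_mip(vol, c(z_lo, dim(vol$sigma2)[2]))
      det$spec <- spec; det$angiogram <- ang
      # thickness on the central B-scan
      mid <- ceiling(dim(struct)[3] / 2)
      bscan <- struct[, , mid]
      surf <- surf_map[, mid]
      dej <- detect_dej(bscan, surf,
                        min_contrast = cfg$thickness$min_contrast,
                        min_offset_px = cfg$thickness$min_offset_px,
                        max_offset_px = cfg$thickness$max_offset_px)
      th <- epithelial_thickness(surf, dej, series$axial_spacing_um,
                                 group_index = cfg$thickness$group_index,
                                 site = site)
      det$thickness <- th
      res$vuet_um <- th$thickness_median_um
      log_lines <- c(log_lines,
                     sprintf("[%s] VuET median %s um, DEJ found fraction %.2f",
                             site,
                             if (is.na(res$vuet_um)) "--" else
                               sprintf("%.1f", res$vuet_um),
                             th$dej_found_fraction))
      if (site %in% cfg$vessels$sites) {
        iso <- resample_isotropic(ang)
        enh <- enhance_vessels(iso, scales_um = cfg$vessels$scales_um)
        bin <- binarize_vessels(enh, method = cfg$vessels$method,
                                fixed_threshold = cfg$vessels$fixed_threshold,
                                min_area_px = cfg$vessels$min_area_px)
        det$mask <- bin
        res$density_pct <- vessel_density(bin)
        dm <- tryCatch(measure_diameters(bin,
                                         sample_step_px = cfg$vessels$sample_step_px),
                       error = function(e) NULL)
        if (!is.null(dm)) {
          res$diameter_mean_um <- dm$diameter_mean_um
          res$diameter_sd_um <- dm$diameter_sd_um
        }
        log_lines <- c(log_lines,
                       sprintf("[%s] vessel density %.2f%%, diameter %.1f um",
                               site, res$density_pct,
                               res$diameter_mean_um))
      }
      if (!is.null(out_dir)) {
        p <- file.path(out_dir, sprintf("angiogram_%s.tif", site))
        write_angiogram_tiff(ang, p)
        paths <- c(paths, p)
        if (isTRUE(cfg$output$write_volumes)) {
          p <- file.path(out_dir, sprintf("sigma2_%s.tif", site))
          write_volume_tiff(vol, p)
          paths <- c(paths, p)
        }
      }
    }, error = function(e) {
      log_lines <<- c(log_lines, sprintf("[%s] FAILED: %s", site,
                                         conditionMessage(e)))
    })
    details[[site]] <- det
    rows[[site]] <- morphometry_report(cfg$subject_id, cfg$group, site,
                                       res$density_pct,
                                       res$diameter_mean_um,
                                       res$diameter_sd_um, res$vuet_um)
  }
  report <- validate_report(do.call(rbind, rows))
  if (!is.null(out_dir)) {
    p <- file.path(out_dir, "report.csv")
    write_report(report, p)
    paths <- c(paths, p)
    cfg_log <- cfg; cfg_log$output$dir <- NULL
    yaml::write_yaml(list(parameters = prune_for_yaml(cfg_log),
                          log = as.list(log_lines)),
                     file.path(out_dir, "pipeline_log.yaml"))
    paths <- c(paths, file.path(out_dir, "pipeline_log.yaml"))
  }
  attr(report, "details") <- details
  attr(report, "paths") <- paths
  attr(report, "log") <- log_lines
  invisible(report)
}

# strip non-serializable objects before logging the parameter set
prune_for_yaml <- function(x) {
  if (inherits(x, "vessel_spec"))
    return(list(centerline = apply(unname(x$centerline), 1, as.list),
                radius_um = x$radius_um,
                flow_correlation = x$flow_correlation))
  if (is.list(x)) return(lapply(x, prune_for_yaml))
  x
}
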