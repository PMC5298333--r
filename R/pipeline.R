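#' Pipeline configuration
#'
#' Bundles every constant and setting of the end-to-end analysis:
#' simulator populations and mesocosm design, the FSC-to-ESD calibration
#' coefficients, the net-tow sampling geometry and scan resolution, the
#' size-spectrum binning, the tissue density, and the test settings. The
#' defaults are the conventional constants of the measurement protocol:
#' calibration `ESD = 0.0064 * FSC^0.5262`, density 1.060 g cm^-3, a
#' 0.17 m x 17 m net tow subsampled 20/500 mL, 2400 dpi scans, a 150 um
#' minimum classifiable size, an instrument crossover gap of 60-150 um and
#' alpha = 0.05.
#'
#' @param populations list of [population_spec()].
#' @param mesocosms list of [mesocosm_spec()].
#' @param days sampling days to simulate and analyse.
#' @param seed integer simulation seed.
#' @param calib a [calibration_curve()].
#' @param geometry a [sampling_geometry()].
#' @param dpi scan resolution.
#' @param fcm_volume_l analysed flow-cytometry volume, litres.
#' @param fcm_noise_cv FSC measurement noise (CV) used when emitting
#'   simulated event tables.
#' @param fcm_esd_range_um trusted ESD range of flow cytometry, um.
#' @param min_esd_um minimum classifiable imaged-object size, um.
#' @param s_min_um,s_max_um,bins_per_decade spectrum bin grid settings.
#' @param crossover_um instrument gap (upper FCM limit, lower imaging
#'   limit), um.
#' @param density_g_cm3 tissue density for wet weight.
#' @param alpha significance threshold.
#' @param compare_day day on which treatments are compared.
#' @param reference_day baseline day for temporal contrasts.
#' @return object of class `"pipeline_config"` (a named list).
#' @export
pipeline_config <- function(populations = default_populations(),
                            mesocosms = default_mesocosms(),
                            days = c(1L, 57L),
                            seed = 1L,
                            calib = calibration_curve(),
                            geometry = sampling_geometry(),
                            dpi = 2400,
                            fcm_volume_l = 5e-4,
                            fcm_noise_cv = 0.05,
                            fcm_esd_range_um = c(0.5, 60),
                            min_esd_um = 150,
                            s_min_um = 0.5, s_max_um = 2500,
                            bins_per_decade = 12L,
                            crossover_um = c(60, 150),
                            density_g_cm3 = 1.060,
                            alpha = 0.05,
                            compare_day = 57L,
                            reference_day = 1L) {
  if (!length(mesocosms))
    stop("configuration has zero mesocosms", call. = FALSE)
  if (!length(populations))
    stop("configuration has zero populations", call. = FALSE)
  if (!all(c(compare_day, reference_day) %in% days))
    stop("'compare_day' and 'reference_day' must be among 'days'",
         call. = FALSE)
  structure(list(populations = populations, mesocosms = mesocosms,
                 days = as.integer(days), seed = as.integer(seed),
                 calib = calib, geometry = geometry, dpi = dpi,
                 fcm_volume_l = fcm_volume_l, fcm_noise_cv = fcm_noise_cv,
                 fcm_esd_range_um = fcm_esd_range_um,
                 min_esd_um = min_esd_um, s_min_um = s_min_um,
                 s_max_um = s_max_um,
                 bins_per_decade = as.integer(bins_per_decade),
                 crossover_um = crossover_um,
                 density_g_cm3 = density_g_cm3, alpha = alpha,
                 compare_day = as.integer(compare_day),
                 reference_day = as.integer(reference_day)),
            class = "pipeline_config")
}

#' Run the full mesocosm size-spectrum pipeline
#'
#' Executes every stage end to end: simulate the community, emit and
#' re-process instrument tables (flow-cytometry events through the size
#' calibration; imaged objects through the size filter and concentration
#' scaling), merge the instrument domains, build per-(mesocosm, day)
#' size spectra, fit spectrum slopes on treatment-mean control spectra,
#' tabulate per-group biomass, and compare treatments per size class and
#' per group on the comparison day. Deterministic given the config seed.
#'
#' @param config a [pipeline_config()].
#' @param output_dir optional directory; when given, all tables are written
#'   as CSV (spectra per mesocosm and day, biomass tables, comparisons,
#'   slope fits) together with a plain-text run log recording the seed and
#'   every configuration value. On failure the partially written directory
#'   is removed.
#' @return (invisibly) a list with elements `particles`, `spectra` (named
#'   list per mesocosm x day), `mean_control_spectra`, `slopes`,
#'   `biomass_table`, `biomass_summary`, `class_comparisons`,
#'   `group_comparisons`, `percent_changes`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(output_dir)) {
    created <- !dir.exists(output_dir)
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    on.exit(if (!is.null(output_dir)) {
      # reached only on error: drop partial outputs
      if (created) unlink(output_dir, recursive = TRUE)
    }, add = TRUE)
  }

  imaging_volume <- effective_subsample_volume(config$geometry)
  community <- simulate_community(config$populations, config$mesocosms,
                                  config$days, seed = config$seed,
                                  fcm_volume_l = config$fcm_volume_l,
                                  imaging_volume_l = imaging_volume)

  # instrument round trips --------------------------------------------------
  events <- community_fcm_events(community, config$calib,
                                 noise_cv = config$fcm_noise_cv)
  fcm_particles <- events_to_particles(events, config$calib,
                                       analyzed_volume_l = config$fcm_volume_l,
                                       esd_range_um = config$fcm_esd_range_um,
                                       density_g_cm3 = config$density_g_cm3)
  objects <- community_objects(community, dpi = config$dpi)
  objects <- apply_min_size_filter(objects, config$min_esd_um)
  objects <- remove_disturbances(objects)
  img_particles <- objects_to_particles(objects, imaging_volume,
                                        density_g_cm3 = config$density_g_cm3)
  particles <- merge_instruments(fcm_particles, img_particles,
                                 crossover_um = config$crossover_um)

  # spectra ------------------------------------------------------------------
  bins <- build_bins(config$s_min_um, config$s_max_um,
                     config$bins_per_decade)
  design <- data.frame(
    mesocosm = vapply(config$mesocosms, `[[`, character(1), "mesocosm_id"),
    treatment = vapply(config$mesocosms, `[[`, character(1), "treatment"),
    stringsAsFactors = FALSE)
  gap <- config$crossover_um
  spectra <- list()
  for (d in config$days) {
    for (m in design$mesocosm) {
      sel <- particles$mesocosm == m & particles$day == d
      spectra[[paste0(m, "_t", d)]] <-
        compute_spectrum(particles[sel, , drop = FALSE], bins, gap_um = gap)
    }
  }

  # treatment-mean control spectra and their slopes -------------------------
  control_ids <- design$mesocosm[design$treatment == "control"]
  mean_control <- list(); slopes <- list()
  for (d in config$days) {
    keys <- paste0(control_ids, "_t", d)
    avg <- spectra[[keys[1]]]
    for (col in c("count", "conc_l", "pss_l_mm", "wbs_mg_l"))
      avg[[col]] <- rowMeans(sapply(keys, function(k) spectra[[k]][[col]]))
    avg$mean_biomass_mg <- ifelse(avg$conc_l > 0,
                                  avg$wbs_mg_l / avg$conc_l, 0)
    key <- paste0("t", d)
    mean_control[[key]] <- avg
    slopes[[key]] <- fit_slope(avg)
  }

  # biomass tables -----------------------------------------------------------
  biomass <- group_biomass_table(particles)
  biomass <- merge(biomass, design, by = "mesocosm", sort = FALSE)
  known <- vapply(config$populations, `[[`, character(1), "name")
  summ <- aggregate(list(mean_biomass_mg_l = biomass$biomass_mg_l,
                         mean_biovolume_mm3_l = biomass$biovolume_mm3_l),
                    by = list(day = biomass$day, treatment = biomass$treatment,
                              group = biomass$group),
                    FUN = mean)
  ses <- aggregate(list(se_biomass_mg_l = biomass$biomass_mg_l),
                   by = list(day = biomass$day, treatment = biomass$treatment,
                             group = biomass$group),
                   FUN = function(x) sd(x) / sqrt(length(x)))
  summ <- merge(summ, ses)
  summ <- summ[order(summ$day, summ$treatment, summ$group), ]
  rownames(summ) <- NULL

  # temporal contrasts in the control arm ------------------------------------
  ctl <- summ[summ$treatment == "control", ]
  pick <- function(d, g) {
    v <- ctl$mean_biomass_mg_l[ctl$day == d & ctl$group == g]
    if (length(v)) v else NA_real_
  }
  pct <- data.frame(
    quantity = c("copepod_total_biomass", "total_biomass"),
    reference_day = config$reference_day, value_day = config$compare_day,
    reference = c(pick(config$reference_day, "Copepod_total"),
                  pick(config$reference_day, "Total")),
    value = c(pick(config$compare_day, "Copepod_total"),
              pick(config$compare_day, "Total")))
  pct$percent_change <- percent_change(pct$reference, pct$value)

  # treatment comparisons on the comparison day ------------------------------
  cmp_day <- config$compare_day
  wbs_long <- do.call(rbind, lapply(design$mesocosm, function(m) {
    sp <- spectra[[paste0(m, "_t", cmp_day)]]
    data.frame(mesocosm = m, class = sp$mid_um, value = sp$wbs_mg_l)
  }))
  class_cmp <- compare_size_classes(wbs_long, design, alpha = config$alpha)
  grp_day <- biomass[biomass$day == cmp_day, ]
  grp_long <- data.frame(mesocosm = grp_day$mesocosm, class = grp_day$group,
                         value = grp_day$biomass_mg_l)
  group_cmp <- compare_size_classes(grp_long, design, alpha = config$alpha)

  result <- list(particles = particles, spectra = spectra,
                 mean_control_spectra = mean_control, slopes = slopes,
                 biomass_table = biomass, biomass_summary = summ,
                 class_comparisons = class_cmp,
                 group_comparisons = group_cmp,
                 percent_changes = pct, config = config)

  if (!is.null(output_dir)) {
    write_pipeline_outputs(result, output_dir)
    output_dir <- NULL  # success: disarm the cleanup handler
  }
  invisible(result)
}

# internal: serialize a pipeline result as CSV tables plus a run log
write_pipeline_outputs <- function(result, output_dir) {
  cfg <- result$config
  for (key in names(result$spectra))
    write_spectrum(result$spectra[[key]],
                   file.path(output_dir, paste0("spectrum_", key, ".csv")))
  for (key in names(result$mean_control_spectra))
    write_spectrum(result$mean_control_spectra[[key]],
                   file.path(output_dir,
                             paste0("spectrum_control_mean_", key, ".csv")))
  slope_df <- do.call(rbind, lapply(names(result$slopes), function(k) {
    s <- result$slopes[[k]]
    data.frame(day = k, slope = s$slope, intercept = s$intercept,
               r_squared = s$r_squared, n_bins_used = s$n_bins_used)
  }))
  write.csv(slope_df, file.path(output_dir, "slopes.csv"), row.names = FALSE)
  write.csv(result$biomass_table,
            file.path(output_dir, "biomass_per_mesocosm.csv"),
            row.names = FALSE)
  write.csv(result$biomass_summary,
            file.path(output_dir, "biomass_treatment_means.csv"),
            row.names = FALSE)
  write.csv(result$class_comparisons,
            file.path(output_dir, "class_comparisons.csv"),
            row.names = FALSE)
  write.csv(result$group_comparisons,
            file.path(output_dir, "group_comparisons.csv"),
            row.names = FALSE)
  write.csv(result$percent_changes,
            file.path(output_dir, "percent_changes.csv"), row.names = FALSE)

  log <- c(
    paste0("run: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("package: mesospectra ",
           as.character(utils::packageVersion("mesospectra"))),
    paste0("R: ", R.version.string),
    paste0("seed: ", cfg$seed),
    paste0("days: ", paste(cfg$days, collapse = ", ")),
    paste0("mesocosms: ",
           paste(vapply(cfg$mesocosms, `[[`, character(1), "mesocosm_id"),
                 vapply(cfg$mesocosms, `[[`, character(1), "treatment"),
                 sep = "=", collapse = ", ")),
    paste0("populations: ",
           paste(vapply(cfg$populations, `[[`, character(1), "name"),
                 collapse = ", ")),
    sprintf("calibration: a=%.6g b=%.6g", cfg$calib$a, cfg$calib$b),
    sprintf("geometry: net=%.3g m, depth=%.3g m, madeup=%.3g mL, sub=%.3g mL",
            cfg$geometry$net_diameter_m, cfg$geometry$tow_depth_m,
            cfg$geometry$madeup_volume_ml, cfg$geometry$subsample_volume_ml),
    sprintf("fcm: volume=%.3g L, noise_cv=%.3g, range=%.3g-%.3g um",
            cfg$fcm_volume_l, cfg$fcm_noise_cv, cfg$fcm_esd_range_um[1],
            cfg$fcm_esd_range_um[2]),
    sprintf("imaging: dpi=%d, min_esd=%.3g um", as.integer(cfg$dpi),
            cfg$min_esd_um),
    sprintf("bins: %.3g-%.3g um, %d per decade; crossover %.3g-%.3g um",
            cfg$s_min_um, cfg$s_max_um, cfg$bins_per_decade,
            cfg$crossover_um[1], cfg$crossover_um[2]),
    sprintf("density: %.4g g cm^-3; alpha: %.3g", cfg$density_g_cm3,
            cfg$alpha),
    sprintf("contrast days: t%d vs t%d", cfg$reference_day, cfg$compare_day))
  writeLines(log, file.path(output_dir, "run_log.txt"))
  invisible(output_dir)
}
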