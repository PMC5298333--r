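#' Population specification for the community simulator
#'
#' One plankton population with a lognormal body-size distribution and a
#' piecewise-linear abundance trajectory. Together with the mesocosm
#' specifications these define the ground truth that the simulator draws
#' from: expected counts per (population, mesocosm, day) are the
#' interpolated concentration times sampled volume, times the treatment
#' multiplier in the high-CO2 arm, times a lognormal replicate factor;
#' realized counts are Poisson.
#'
#' @param name population label (becomes the particle `group`).
#' @param log_esd_mean log10 of the median ESD in micrometres.
#' @param log_esd_sd spread of log10 ESD (>= 0).
#' @param abundance_knots data.frame with columns `day` and `conc_l`
#'   (# L^-1, all >= 0); concentrations are interpolated linearly between
#'   knots and held constant beyond the first/last knot.
#' @param treatment_multiplier factor (> 0) applied to the concentration in
#'   the high-CO2 treatment.
#' @param instrument which instrument observes the population: `"fcm"`,
#'   `"imaging"` or `"both"`.
#' @return object of class `"population_spec"`.
#' @export
population_spec <- function(name, log_esd_mean, log_esd_sd, abundance_knots,
                            treatment_multiplier = 1,
                            instrument = c("fcm", "imaging", "both")) {
  instrument <- match.arg(instrument)
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(log_esd_mean), length(log_esd_mean) == 1L,
            is.numeric(log_esd_sd), length(log_esd_sd) == 1L)
  if (log_esd_sd < 0) stop("'log_esd_sd' must be >= 0", call. = FALSE)
  if (!is.data.frame(abundance_knots) ||
      !all(c("day", "conc_l") %in% names(abundance_knots)) ||
      nrow(abundance_knots) < 1L)
    stop("'abundance_knots' must be a data.frame with columns day, conc_l",
         call. = FALSE)
  if (any(!is.finite(abundance_knots$conc_l) | abundance_knots$conc_l < 0))
    stop("knot concentrations must be finite and >= 0", call. = FALSE)
  if (is.unsorted(abundance_knots$day, strictly = TRUE))
    stop("knot days must be strictly increasing", call. = FALSE)
  if (!is.finite(treatment_multiplier) || treatment_multiplier <= 0)
    stop("'treatment_multiplier' must be > 0", call. = FALSE)
  structure(list(name = name, log_esd_mean = log_esd_mean,
                 log_esd_sd = log_esd_sd,
                 abundance_knots = abundance_knots[c("day", "conc_l")],
                 treatment_multiplier = treatment_multiplier,
                 instrument = instrument),
            class = "population_spec")
}

#' Mesocosm specification for the community simulator
#'
#' @param mesocosm_id label, e.g. `"M1"`.
#' @param treatment `"control"` or `"high_co2"`.
#' @param replicate_noise_sd standard deviation, on the natural-log scale,
#'   of the mean-one lognormal replicate factor applied per
#'   (population, day); models between-mesocosm variability.
#' @param seed optional integer seeding this mesocosm's random stream; if
#'   `NA`, a stream is derived deterministically from the simulation seed.
#' @return object of class `"mesocosm_spec"`.
#' @export
mesocosm_spec <- function(mesocosm_id, treatment = c("control", "high_co2"),
                          replicate_noise_sd = 0.15, seed = NA_integer_) {
  treatment <- match.arg(treatment)
  stopifnot(is.character(mesocosm_id), length(mesocosm_id) == 1L,
            is.numeric(replicate_noise_sd), replicate_noise_sd >= 0)
  structure(list(mesocosm_id = mesocosm_id, treatment = treatment,
                 replicate_noise_sd = replicate_noise_sd,
                 seed = as.integer(seed)),
            class = "mesocosm_spec")
}

#' Expected individual wet weight of a lognormal-size population
#'
#' For ESD distributed as `10^N(log_esd_mean, log_esd_sd^2)` um, the mean
#' individual biovolume is `(pi/6) * median_esd^3 * exp(4.5 * sigma_ln^2)`
#' with `sigma_ln = log_esd_sd * ln(10)` (the third-moment factor of the
#' lognormal). Multiplying by tissue density gives the expected wet weight
#' in mg. Used to translate biomass-based population trajectories into the
#' number concentrations the simulator needs.
#'
#' @param log_esd_mean,log_esd_sd lognormal size parameters (log10 um).
#' @param density_g_cm3 tissue density.
#' @return expected individual biomass in mg.
#' @export
expected_individual_biomass_mg <- function(log_esd_mean, log_esd_sd,
                                           density_g_cm3 = 1.060) {
  sigma_ln <- log_esd_sd * log(10)
  (pi / 6) * (10^log_esd_mean / 1000)^3 * exp(4.5 * sigma_ln^2) * density_g_cm3
}

# internal: population whose knots are given as biomass (mg L^-1)
biomass_population <- function(name, log_esd_mean, log_esd_sd, days,
                               biomass_mg_l, treatment_multiplier = 1,
                               instrument = "imaging") {
  m <- expected_individual_biomass_mg(log_esd_mean, log_esd_sd)
  population_spec(name, log_esd_mean, log_esd_sd,
                  data.frame(day = days, conc_l = biomass_mg_l / m),
                  treatment_multiplier, instrument)
}

#' Default synthetic community
#'
#' The packaged population set emulates the structure of a 113-day
#' winter-to-summer plankton succession in a fjord mesocosm experiment:
#' a picoplankton wave peaking near day 57-65 at 3-4 times its initial
#' abundance; a broad background of 5-40 um phytoplankton; two
#' nanophytoplankton bloom waves (a broad 2-15 um peak near day 33 and a
#' narrower 4-8 um peak near day 57); a large centric diatom
#' (*Coscinodiscus*-like, 200-500 um ESD) blooming between days 40 and 65;
#' a copepod community dominated by one calanoid species that shifts from
#' medium/large adults (600-1000 um, declining from day 1) to a cohort of
#' copepodites and nauplii (200-600 um, peaking near day 57); and sparse
#' hydromedusae above 1 mm appearing from day 33. Copepod and diatom
#' trajectories are anchored to the treatment-mean biomass a comparable
#' mesocosm study reports on its initial (t1) and bloom-peak (t57) days;
#' high-CO2 multipliers encode the published effect directions: +60 %
#' picoeukaryotes, +30 % *Coscinodiscus*, +40 % small/medium copepods and
#' nauplii, -20 % hydromedusae.
#'
#' @return list of [population_spec()] objects.
#' @seealso [default_mesocosms()], [simulate_community()]
#' @export
default_populations <- function() {
  list(
    population_spec(
      "picoplankton", log_esd_mean = log10(0.95), log_esd_sd = 0.10,
      abundance_knots = data.frame(
        day = c(1, 33, 45, 57, 65, 81, 113),
        conc_l = 8.6e7 * c(1, 1.3, 2.0, 3.5, 3.5, 2.0, 1.5)),
      treatment_multiplier = 1.6, instrument = "fcm"),
    biomass_population(
      "background_nano", log10(12), 0.20,
      days = c(1, 33, 57, 113),
      biomass_mg_l = c(1.73, 1.40, 1.00, 0.80), instrument = "fcm"),
    biomass_population(
      "nano_bloom_1", log10(5.5), 0.22,
      days = c(1, 20, 33, 45, 57, 70, 113),
      biomass_mg_l = c(0, 0.5, 5.0, 1.5, 0.5, 0.2, 0), instrument = "fcm"),
    biomass_population(
      "nano_bloom_2", log10(5.7), 0.065,
      days = c(1, 40, 57, 70, 113),
      biomass_mg_l = c(0, 0.3, 2.34, 1.0, 0.2), instrument = "fcm"),
    biomass_population(
      "coscinodiscus", log10(300), 0.08,
      days = c(1, 25, 33, 40, 57, 65, 81, 113),
      biomass_mg_l = c(0.05, 0.3, 1.5, 5.0, 6.02, 5.0, 1.5, 0.5),
      treatment_multiplier = 1.3, instrument = "imaging"),
    biomass_population(
      "nauplii", log10(210), 0.07,
      days = c(1, 33, 57, 70, 113),
      biomass_mg_l = c(0.029, 0.20, 0.809, 0.60, 0.30),
      treatment_multiplier = 1.4, instrument = "imaging"),
    biomass_population(
      "copepod_S", log10(450), 0.07,
      days = c(1, 33, 57, 81, 113),
      biomass_mg_l = c(0.371, 0.45, 0.921, 0.70, 0.50),
      treatment_multiplier = 1.4, instrument = "imaging"),
    biomass_population(
      "copepod_M", log10(780), 0.05,
      days = c(1, 25, 41, 57, 81, 113),
      biomass_mg_l = c(2.85, 2.60, 1.80, 0.84, 0.50, 0.40),
      treatment_multiplier = 1.4, instrument = "imaging"),
    biomass_population(
      "copepod_L", log10(1150), 0.03,
      days = c(1, 33, 49, 113),
      biomass_mg_l = c(0.18, 0.10, 0, 0), instrument = "imaging"),
    biomass_population(
      "hydromedusae", log10(1600), 0.06,
      days = c(1, 33, 57, 113),
      biomass_mg_l = c(0, 0.01, 0.12, 0.08),
      treatment_multiplier = 0.8, instrument = "imaging"))
}

#' Default mesocosm design
#'
#' Ten mesocosms in two arms of five: an untreated control (M1, M3, M5,
#' M9, M10) and a high-CO2 "ocean acidification" arm (M2, M4, M6, M7, M8).
#'
#' @param replicate_noise_sd between-mesocosm lognormal noise, natural-log
#'   scale.
#' @return list of [mesocosm_spec()] objects.
#' @export
default_mesocosms <- function(replicate_noise_sd = 0.15) {
  control <- c("M1", "M3", "M5", "M9", "M10")
  high <- c("M2", "M4", "M6", "M7", "M8")
  c(lapply(control, mesocosm_spec, treatment = "control",
           replicate_noise_sd = replicate_noise_sd),
    lapply(high, mesocosm_spec, treatment = "high_co2",
           replicate_noise_sd = replicate_noise_sd))
}

# internal: interpolate a knot table at given days (constant beyond ends)
interp_knots <- function(knots, days) {
  if (nrow(knots) == 1L) return(rep(knots$conc_l, length(days)))
  approx(knots$day, knots$conc_l, xout = days, rule = 2)$y
}

#' Simulate a mesocosm community
#'
#' Draws particle tables for every (population, mesocosm, day): the
#' expected count is the interpolated concentration, times the treatment
#' multiplier for high-CO2 mesocosms, times a mean-one lognormal replicate
#' factor (one per population x mesocosm x day), times the volume sampled
#' by the population's instrument; the realized count is Poisson and each
#' particle's ESD is drawn from the population's lognormal size
#' distribution. Output is fully reproducible from `seed`.
#'
#' @param populations list of [population_spec()]; non-empty.
#' @param mesocosms list of [mesocosm_spec()]; non-empty.
#' @param days integer vector of sampling days, sorted increasing.
#' @param seed integer seed for the whole simulation.
#' @param fcm_volume_l analysed flow-cytometry volume per sample, litres.
#' @param imaging_volume_l effective volume represented by one imaged
#'   subsample, litres (default: 4 % of a 17 cm x 17 m net tow).
#' @return object of class `"community_table"`: a data.frame with columns
#'   `mesocosm`, `treatment`, `day`, `group`, `instrument`, `esd_um`, with
#'   attributes `volumes` (data.frame of per-instrument sampled volume) and
#'   `seed`.
#' @export
simulate_community <- function(populations, mesocosms, days, seed = 1L,
                               fcm_volume_l = 5e-4,
                               imaging_volume_l =
                                 effective_subsample_volume()) {
  if (!length(populations)) stop("no populations given", call. = FALSE)
  if (!length(mesocosms)) stop("no mesocosms given", call. = FALSE)
  stopifnot(all(vapply(populations, inherits, logical(1), "population_spec")),
            all(vapply(mesocosms, inherits, logical(1), "mesocosm_spec")))
  if (is.unsorted(days)) stop("'days' must be sorted", call. = FALSE)
  stopifnot(is.finite(fcm_volume_l), fcm_volume_l > 0,
            is.finite(imaging_volume_l), imaging_volume_l > 0)
  vols <- c(fcm = fcm_volume_l, imaging = imaging_volume_l)

  pieces <- list()
  for (mi in seq_along(mesocosms)) {
    meso <- mesocosms[[mi]]
    mseed <- if (!is.na(meso$seed)) meso$seed else
      (as.integer(seed) %% 49999L) * 40009L + mi * 7919L
    set.seed(mseed %% .Machine$integer.max)
    for (pop in populations) {
      conc <- interp_knots(pop$abundance_knots, days)
      if (meso$treatment == "high_co2")
        conc <- conc * pop$treatment_multiplier
      noise <- if (meso$replicate_noise_sd > 0)
        rlnorm(length(days), meanlog = -meso$replicate_noise_sd^2 / 2,
               sdlog = meso$replicate_noise_sd)
      else rep(1, length(days))
      instruments <- if (pop$instrument == "both") c("fcm", "imaging")
                     else pop$instrument
      for (instr in instruments) {
        lambda <- conc * noise * vols[[instr]]
        n <- rpois(length(days), lambda)
        tot <- sum(n)
        if (tot == 0L) next
        esd <- 10^rnorm(tot, mean = pop$log_esd_mean, sd = pop$log_esd_sd)
        pieces[[length(pieces) + 1L]] <- data.frame(
          mesocosm = meso$mesocosm_id, treatment = meso$treatment,
          day = rep(as.integer(days), n), group = pop$name,
          instrument = instr, esd_um = esd, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(mesocosm = character(), treatment = character(),
               day = integer(), group = character(), instrument = character(),
               esd_um = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "volumes") <- data.frame(instrument = names(vols),
                                     volume_l = unname(vols))
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("community_table", "data.frame")
  out
}

#' Expected counts of the community simulator
#'
#' Deterministic part of the simulation model: the Poisson mean for every
#' (population, mesocosm, day, instrument), i.e. interpolated concentration
#' times treatment multiplier times sampled volume, before replicate noise.
#'
#' @inheritParams simulate_community
#' @return data.frame with columns `mesocosm`, `treatment`, `day`, `group`,
#'   `instrument`, `lambda`.
#' @export
expected_counts <- function(populations, mesocosms, days,
                            fcm_volume_l = 5e-4,
                            imaging_volume_l = effective_subsample_volume()) {
  vols <- c(fcm = fcm_volume_l, imaging = imaging_volume_l)
  out <- list()
  for (meso in mesocosms) {
    for (pop in populations) {
      conc <- interp_knots(pop$abundance_knots, days)
      if (meso$treatment == "high_co2") conc <- conc * pop$treatment_multiplier
      instruments <- if (pop$instrument == "both") c("fcm", "imaging")
                     else pop$instrument
      for (instr in instruments)
        out[[length(out) + 1L]] <- data.frame(
          mesocosm = meso$mesocosm_id, treatment = meso$treatment,
          day = as.integer(days), group = pop$name, instrument = instr,
          lambda = conc * vols[[instr]], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Emit flow-cytometry events from a simulated community
#'
#' Converts the FCM-domain rows of a community table into a
#' fluorescence-triggered event table by inverting the size calibration,
#' optionally with multiplicative lognormal scatter noise.
#'
#' @param community a [simulate_community()] table.
#' @param calib a [calibration_curve()].
#' @param noise_cv coefficient of variation of the FSC measurement noise.
#' @return data.frame of events: `mesocosm`, `day`, `group`, `fsc`,
#'   `fluorescent`.
#' @export
community_fcm_events <- function(community, calib = calibration_curve(),
                                 noise_cv = 0) {
  stopifnot(inherits(community, "community_table"))
  fc <- community[community$instrument == "fcm", , drop = FALSE]
  data.frame(mesocosm = fc$mesocosm, day = fc$day, group = fc$group,
             fsc = fsc_from_esd(fc$esd_um, calib, noise_cv),
             fluorescent = TRUE, stringsAsFactors = FALSE)
}

#' Emit an imaged-object table from a simulated community
#'
#' Converts the imaging-domain rows of a community table into an object
#' table of the same shape that scan-plate measurement produces. Simulated
#' organisms are spherical, so major and minor axes equal the ESD and the
#' biovolume is `(pi/6) * ESD^3`.
#'
#' @param community a [simulate_community()] table.
#' @param dpi nominal scan resolution used to fill the pixel-area column.
#' @return imaged-object data.frame (see [read_objects()] for columns).
#' @export
community_objects <- function(community, dpi = 2400) {
  stopifnot(inherits(community, "community_table"))
  im <- community[community$instrument == "imaging", , drop = FALSE]
  ps <- pixel_size_from_dpi(dpi)
  data.frame(id = seq_len(nrow(im)), mesocosm = im$mesocosm, day = im$day,
             area_px = round(pi / 4 * (im$esd_um / ps)^2),
             esd_um = im$esd_um, major_um = im$esd_um, minor_um = im$esd_um,
             biovolume_mm3 = sphere_biovolume_mm3(im$esd_um),
             category = im$group, stringsAsFactors = FALSE)
}

#' Render a synthetic scan plate
#'
#' Draws filled ellipses (grey `particle_grey`) on a uniform background
#' (`background_grey`), mimicking organisms spread on a flatbed-scanner
#' glass plate. Objects must lie fully inside the canvas and must not
#' overlap: the laboratory protocol separates objects by hand before
#' scanning, and the renderer enforces the same guarantee.
#'
#' @param objects data.frame with columns `x_px`, `y_px` (ellipse centre,
#'   pixels), `major_um`, `minor_um` (full axis lengths), and optionally
#'   `orientation_rad`; may have zero rows.
#' @param width_px,height_px canvas size in pixels.
#' @param dpi scan resolution (sets the um-per-pixel scale).
#' @param background_grey,particle_grey grey levels 0-255; must differ.
#' @return a `scan_image`: integer grey-level matrix (rows = y) with a
#'   `dpi` attribute.
#' @export
render_scan_plate <- function(objects, width_px = 600, height_px = 600,
                              dpi = 2400, background_grey = 230,
                              particle_grey = 60) {
  if (background_grey == particle_grey)
    stop("particle and background grey levels must differ", call. = FALSE)
  img <- matrix(as.integer(background_grey), nrow = height_px,
                ncol = width_px)
  painted <- matrix(0L, height_px, width_px)
  ps <- pixel_size_from_dpi(dpi)
  if (!is.null(objects) && nrow(objects)) {
    if (!all(c("x_px", "y_px", "major_um", "minor_um") %in% names(objects)))
      stop("'objects' need columns x_px, y_px, major_um, minor_um",
           call. = FALSE)
    for (k in seq_len(nrow(objects))) {
      a <- objects$major_um[k] / 2 / ps   # semi-axes in pixels
      b <- objects$minor_um[k] / 2 / ps
      th <- if ("orientation_rad" %in% names(objects))
        objects$orientation_rad[k] else 0
      cx <- objects$x_px[k]; cy <- objects$y_px[k]
      r <- ceiling(max(a, b))
      if (cx - r < 1 || cx + r > width_px || cy - r < 1 || cy + r > height_px)
        stop("object ", k, " extends beyond the canvas", call. = FALSE)
      xs <- floor(cx - r):ceiling(cx + r)
      ys <- floor(cy - r):ceiling(cy + r)
      gx <- outer(rep(1, length(ys)), xs) - cx
      gy <- outer(ys, rep(1, length(xs))) - cy
      u <- gx * cos(th) + gy * sin(th)
      v <- -gx * sin(th) + gy * cos(th)
      inside <- (u / a)^2 + (v / b)^2 <= 1
      idx <- cbind(rep(ys, times = length(xs))[as.vector(inside)],
                   rep(xs, each = length(ys))[as.vector(inside)])
      painted[idx] <- painted[idx] + 1L
      img[idx] <- as.integer(particle_grey)
    }
    if (any(painted > 1L))
      stop("overlapping objects on the plate; the scan protocol requires ",
           "non-touching objects", call. = FALSE)
  }
  structure(img, dpi = dpi, class = c("scan_image", class(img)))
}
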