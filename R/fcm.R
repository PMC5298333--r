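#' Assign phytoplankton size classes
#'
#' Classifies ESD values into the conventional picoplankton (< 2 um),
#' nanoplankton (2-20 um) and microplankton (> 20 um) classes. Boundaries
#' are half-open `[lower, upper)`, so 2 um is nano and 20 um is micro.
#'
#' @param esd numeric vector of ESD in micrometres, all positive.
#' @return factor with levels `pico`, `nano`, `micro`.
#' @export
#' @examples
#' assign_phyto_class(c(0.8, 2, 15, 20, 45))
assign_phyto_class <- function(esd) {
  if (length(esd) && (!is.numeric(esd) || any(!is.finite(esd) | esd <= 0)))
    stop("all ESD values must be positive and finite", call. = FALSE)
  cut(esd, breaks = c(0, 2, 20, Inf), labels = c("pico", "nano", "micro"),
      right = FALSE)
}

#' Convert flow-cytometry events to particle records
#'
#' Retains fluorescence-triggered events with positive forward scatter,
#' converts FSC to ESD through the calibration power law, derives spherical
#' biovolume and wet-weight biomass, and weights each event by
#' `1 / analyzed_volume_l` so that summed weights give concentration in
#' individuals per litre. Events whose converted ESD falls outside
#' `esd_range_um` (the trustworthy domain of the instrument) are dropped and
#' tallied in the `discarded` attribute; events outside the FSC range the
#' calibration was fitted on (widened by one decade on each side) are kept
#' but flagged `extrapolated`.
#'
#' @param events data.frame with columns `fsc` and (optionally)
#'   `fluorescent` (logical; non-fluorescent events are discarded, matching
#'   a fluorescence-triggered acquisition). Columns `mesocosm`, `day` and
#'   `group` are passed through when present.
#' @param calib a [calibration_curve()].
#' @param analyzed_volume_l analysed sample volume in litres; positive.
#' @param esd_range_um retained ESD range in micrometres
#'   (default 0.5-60 um).
#' @param density_g_cm3 tissue density used for the wet-weight conversion.
#' @return particle records (see [particle-records]) with an extra logical
#'   column `extrapolated`, and an attribute `discarded`: a named count of
#'   events removed per reason.
#' @export
events_to_particles <- function(events, calib = calibration_curve(),
                                analyzed_volume_l,
                                esd_range_um = c(0.5, 60),
                                density_g_cm3 = 1.060) {
  if (!is.data.frame(events) || !"fsc" %in% names(events))
    stop("'events' must be a data.frame with an 'fsc' column", call. = FALSE)
  stopifnot(is.numeric(analyzed_volume_l), length(analyzed_volume_l) == 1L)
  if (!is.finite(analyzed_volume_l) || analyzed_volume_l <= 0)
    stop("'analyzed_volume_l' must be positive", call. = FALSE)
  stopifnot(length(esd_range_um) == 2L, esd_range_um[1] < esd_range_um[2])

  n0 <- nrow(events)
  disc <- c(non_fluorescent = 0L, nonpositive_fsc = 0L, out_of_size_range = 0L)
  if ("fluorescent" %in% names(events)) {
    keep <- as.logical(events$fluorescent)
    disc[["non_fluorescent"]] <- sum(!keep)
    events <- events[keep, , drop = FALSE]
  }
  ok <- is.finite(events$fsc) & events$fsc > 0
  disc[["nonpositive_fsc"]] <- sum(!ok)
  events <- events[ok, , drop = FALSE]

  esd <- esd_from_fsc(events$fsc, calib)
  in_range <- esd >= esd_range_um[1] & esd <= esd_range_um[2]
  disc[["out_of_size_range"]] <- sum(!in_range)
  events <- events[in_range, , drop = FALSE]
  esd <- esd[in_range]

  out <- empty_particles()
  if (nrow(events)) {
    bv <- sphere_biovolume_mm3(esd)
    out <- data.frame(
      mesocosm = if ("mesocosm" %in% names(events)) events$mesocosm else NA_character_,
      day = if ("day" %in% names(events)) events$day else NA_integer_,
      group = if ("group" %in% names(events)) events$group else "unclassified",
      instrument = "fcm",
      esd_um = esd,
      biovolume_mm3 = bv,
      biomass_mg = biomass_from_biovolume(bv, density_g_cm3),
      weight_l = 1 / analyzed_volume_l,
      stringsAsFactors = FALSE)
  }
  fr <- calib$fsc_range
  if (all(is.finite(fr))) {
    out$extrapolated <- nrow(out) > 0 &
      (events$fsc < fr[1] / 10 | events$fsc > fr[2] * 10)
  } else {
    out$extrapolated <- logical(nrow(out))
  }
  attr(out, "discarded") <- disc
  attr(out, "n_input_events") <- n0
  out
}

#' Read / write flow-cytometry event tables
#'
#' Event tables are plain comma-separated text with at least the columns
#' `fsc` and `fluorescent`; any additional columns (e.g. `mesocosm`, `day`,
#' `group`) round-trip unchanged. Native FCS parsing is deliberately out of
#' scope: exporting listmode data to delimited text is assumed upstream.
#'
#' @param path file path.
#' @param events data.frame of events to write.
#' @return `read_events()` returns the event data.frame; `write_events()`
#'   returns `path` invisibly.
#' @export
read_events <- function(path) {
  ev <- read.csv(path, stringsAsFactors = FALSE)
  if (!"fsc" %in% names(ev))
    stop("event table has no 'fsc' column: ", path, call. = FALSE)
  if ("fluorescent" %in% names(ev))
    ev$fluorescent <- as.logical(ev$fluorescent)
  ev
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  write.csv(events, path, row.names = FALSE)
  invisible(path)
}
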