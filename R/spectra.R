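#' Wet-weight biomass from biovolume
#'
#' Converts biovolume to wet weight assuming a constant tissue density of
#' organic matter (default 1.060 g cm^-3). Since 1 g cm^-3 = 1 mg mm^-3,
#' biovolume in mm^3 times density gives biomass in mg.
#'
#' @param biovolume_mm3 biovolume in cubic millimetres, non-negative.
#' @param density_g_cm3 tissue density in g cm^-3.
#' @return biomass (wet weight) in milligrams.
#' @export
#' @examples
#' biomass_from_biovolume(1)        # 1 mm^3 -> 1.06 mg
biomass_from_biovolume <- function(biovolume_mm3, density_g_cm3 = 1.060) {
  if (length(biovolume_mm3) &&
      (!is.numeric(biovolume_mm3) || any(biovolume_mm3 < 0, na.rm = TRUE)))
    stop("biovolume must be non-negative", call. = FALSE)
  stopifnot(is.numeric(density_g_cm3), density_g_cm3 > 0)
  biovolume_mm3 * density_g_cm3
}

#' Logarithmically spaced size-class grid
#'
#' Builds the binning backbone of the size spectrum: bin edges placed at
#' `s_min * 10^(k / bins_per_decade)` until `s_max` is covered. Bins are
#' half-open `[lower, upper)` on ESD. Each bin carries its linear width in
#' millimetres (the normalisation denominator of the PSS) and its geometric
#' midpoint in micrometres (the abscissa for slope fits).
#'
#' @param s_min_um,s_max_um size range to cover, in micrometres;
#'   `0 < s_min_um < s_max_um`.
#' @param bins_per_decade number of bins per factor-of-ten in size. The
#'   default 12 (bin width ~0.083 decades) resolves the 100-um-scale class
#'   bands in which treatment effects are typically reported.
#' @return object of class `"bin_grid"`: a data.frame with columns
#'   `lower_um`, `upper_um`, `mid_um`, `width_mm`.
#' @export
#' @examples
#' build_bins(0.5, 2000, bins_per_decade = 12)
build_bins <- function(s_min_um, s_max_um, bins_per_decade = 12L) {
  stopifnot(is.numeric(s_min_um), is.numeric(s_max_um))
  if (!is.finite(s_min_um) || !is.finite(s_max_um) || s_min_um <= 0 ||
      s_min_um >= s_max_um)
    stop("need 0 < s_min_um < s_max_um", call. = FALSE)
  if (bins_per_decade < 1)
    stop("'bins_per_decade' must be >= 1", call. = FALSE)
  n_dec <- log10(s_max_um / s_min_um)
  k <- 0:ceiling(n_dec * bins_per_decade - 1e-9)
  edges <- s_min_um * 10^(k / bins_per_decade)
  if (edges[length(edges)] < s_max_um)
    edges <- c(edges, s_min_um * 10^(length(edges) / bins_per_decade))
  lower <- edges[-length(edges)]
  upper <- edges[-1]
  structure(data.frame(lower_um = lower, upper_um = upper,
                       mid_um = sqrt(lower * upper),
                       width_mm = (upper - lower) / 1000),
            bins_per_decade = bins_per_decade,
            class = c("bin_grid", "data.frame"))
}

# internal: bin index for each particle (NA = outside grid)
bin_index <- function(esd_um, bins) {
  edges <- c(bins$lower_um, bins$upper_um[nrow(bins)])
  i <- findInterval(esd_um, edges, rightmost.closed = FALSE)
  i[i < 1L | i > nrow(bins)] <- NA_integer_
  i
}

#' Particle size spectrum and weighted biomass spectrum
#'
#' Bins particle records into a logarithmic size grid and computes, per
#' bin i:
#' \describe{
#'   \item{PSS}{the normalized abundance spectrum: total concentration of
#'     particles in the bin divided by the bin's linear width,
#'     `pss_l_mm = sum(weight_l) / width_mm`, in # L^-1 mm^-1. The division
#'     by the linear width corrects the distortion introduced by
#'     logarithmic binning, in which class width grows with size.}
#'   \item{WBS}{the weighted biomass spectrum: the absolute biomass
#'     concentration in the bin, `wbs_mg_l = sum(biomass_mg * weight_l)`,
#'     in mg L^-1. This equals PSS x (mean individual biomass) x (bin
#'     width), and sums over bins to the total biomass concentration.}
#' }
#' `compute_pss()` and `compute_wbs()` are aliases of `compute_spectrum()`
#' provided for code that addresses one spectrum at a time; all three
#' return the full per-bin table.
#'
#' @param particles particle records (see [particle-records]).
#' @param bins a [build_bins()] grid covering the particles. Particles
#'   outside the grid are dropped and tallied in the `n_dropped` attribute.
#' @param gap_um optional numeric length-2: size interval not observed by
#'   any instrument; bins wholly inside it are flagged
#'   `coverage = "unobserved_gap"`, bins straddling one of its edges (and
#'   hence sampled over part of their width only) `"partial_coverage"`;
#'   both kinds are excluded from slope fits. Defaults
#'   to the `instrument_gap` attribute left by [merge_instruments()].
#' @return object of class `"size_spectrum"`: the bin grid with extra
#'   columns `count` (raw particles), `conc_l` (# L^-1), `pss_l_mm`
#'   (# L^-1 mm^-1), `wbs_mg_l` (mg L^-1), `mean_biomass_mg` and `coverage`
#'   (`"observed"` / `"partial_coverage"` / `"unobserved_gap"`).
#' @export
compute_spectrum <- function(particles, bins, gap_um = NULL) {
  stopifnot(inherits(bins, "bin_grid"))
  check_particles(particles)
  if (is.null(gap_um)) gap_um <- attr(particles, "instrument_gap")
  i <- bin_index(particles$esd_um, bins)
  dropped <- sum(is.na(i)) - sum(is.na(particles$esd_um))
  ok <- !is.na(i)
  nb <- nrow(bins)
  count <- tabulate(i[ok], nbins = nb)
  conc <- as.vector(rowsum_safe(particles$weight_l[ok], i[ok], nb))
  wbs <- as.vector(rowsum_safe(particles$biomass_mg[ok] *
                               particles$weight_l[ok], i[ok], nb))
  pss <- conc / bins$width_mm
  meanb <- ifelse(conc > 0, wbs / conc, 0)
  # the product form of the WBS definition must agree with the direct sum
  stopifnot(all(abs(pss * meanb * bins$width_mm - wbs) <=
                1e-12 * pmax(wbs, 1e-300)))
  coverage <- rep("observed", nb)
  if (!is.null(gap_um)) {
    stopifnot(length(gap_um) == 2L)
    overlaps <- bins$upper_um > gap_um[1] & bins$lower_um < gap_um[2]
    inside <- bins$lower_um >= gap_um[1] & bins$upper_um <= gap_um[2]
    # bins straddling a gap edge are sampled over part of their width only,
    # which biases their PSS low; they are flagged and kept out of slope fits
    coverage[overlaps] <- "partial_coverage"
    coverage[inside] <- "unobserved_gap"
  }
  out <- cbind(as.data.frame(bins), count = count, conc_l = conc,
               pss_l_mm = pss, wbs_mg_l = wbs, mean_biomass_mg = meanb,
               coverage = coverage)
  attr(out, "n_dropped") <- dropped
  attr(out, "bins_per_decade") <- attr(bins, "bins_per_decade")
  class(out) <- c("size_spectrum", "data.frame")
  out
}

# internal: rowsum that returns a dense length-nb vector
rowsum_safe <- function(x, index, nb) {
  out <- numeric(nb)
  if (length(x)) {
    s <- rowsum(x, index)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' @rdname compute_spectrum
#' @export
compute_pss <- function(particles, bins, gap_um = NULL) {
  compute_spectrum(particles, bins, gap_um)
}

#' @rdname compute_spectrum
#' @export
compute_wbs <- function(particles, bins, gap_um = NULL) {
  compute_spectrum(particles, bins, gap_um)
}

#' Slope of the normalized abundance spectrum
#'
#' Ordinary least squares of `log10(PSS)` on `log10(size)` over bins that
#' are observed (not inside an instrument gap), contain at least one
#' particle, and fall inside `size_range_um`. Empty bins are excluded
#' because their log-PSS is undefined; no pseudo-counts are added. Size
#' spectra of aquatic communities typically have slopes near -2 on this
#' scale, with steeper (more negative) slopes indicating relatively more
#' small particles.
#'
#' @param spectrum a [compute_spectrum()] result.
#' @param size_range_um optional ESD interval (um) restricting the fit.
#' @param weights `"none"` (default) gives every non-empty bin equal
#'   weight — the convention under which published spectrum slopes
#'   (including the canonical -2) are defined; `"count"` weights each bin
#'   by its raw particle count, i.e. by the inverse Poisson sampling
#'   variance of its log-PSS, the better estimator when a single
#'   instrument with uniform counting effort samples the spectrum and
#'   tail bins hold only a handful of particles. For spectra merged
#'   across instruments of very different sampled volume, count weights
#'   would concentrate all leverage in the best-counted instrument, so
#'   they are not the default.
#' @return object of class `"slope_fit"`: list with `slope`, `intercept`
#'   (of log10 PSS on log10 ESD in mm), `r_squared`, `n_bins_used`.
#' @export
fit_slope <- function(spectrum, size_range_um = NULL,
                      weights = c("none", "count")) {
  stopifnot(inherits(spectrum, "size_spectrum"))
  weights <- match.arg(weights)
  use <- spectrum$coverage == "observed" & spectrum$count > 0 &
    spectrum$pss_l_mm > 0
  if (!is.null(size_range_um)) {
    stopifnot(length(size_range_um) == 2L)
    use <- use & spectrum$mid_um >= size_range_um[1] &
      spectrum$mid_um <= size_range_um[2]
  }
  if (sum(use) < 3L)
    stop("fewer than 3 usable bins for the slope fit", call. = FALSE)
  x <- log10(spectrum$mid_um[use] / 1000)  # ESD in mm
  y <- log10(spectrum$pss_l_mm[use])
  w <- if (weights == "count") spectrum$count[use] else rep(1, sum(use))
  fit <- lm(y ~ x, weights = w)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 n_bins_used = sum(use)),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("size-spectrum slope: %.3f (R^2 = %.3f, %d bins)\n",
              x$slope, x$r_squared, x$n_bins_used))
  invisible(x)
}

#' Merge flow-cytometry and imaging particle records
#'
#' The two instruments cover disjoint size domains: flow cytometry up to
#' ~60 um and scan imaging from ~150 um. Merging concatenates the records
#' and annotates the unobserved interval in between so that spectra built
#' from the merged table mark the gap bins and slope fits exclude them.
#' Records violating their instrument's domain (e.g. an FCM event converted
#' to 80 um) are flagged `out_of_domain`, not silently dropped.
#'
#' @param fcm,imaging particle records from the respective instruments.
#' @param crossover_um numeric length-2: upper trusted limit of flow
#'   cytometry and lower trusted limit of imaging, in micrometres.
#' @return combined particle records with a logical `out_of_domain` column
#'   and attribute `instrument_gap = crossover_um`.
#' @export
merge_instruments <- function(fcm, imaging, crossover_um = c(60, 150)) {
  stopifnot(length(crossover_um) == 2L, crossover_um[1] < crossover_um[2])
  check_particles(fcm); check_particles(imaging)
  pad <- function(x) {
    if (!"out_of_domain" %in% names(x))
      x$out_of_domain <- rep(FALSE, nrow(x))
    x
  }
  fcm <- pad(fcm); imaging <- pad(imaging)
  if (nrow(fcm)) fcm$out_of_domain <- fcm$esd_um > crossover_um[1]
  if (nrow(imaging)) imaging$out_of_domain <- imaging$esd_um < crossover_um[2]
  shared <- intersect(names(fcm), names(imaging))
  out <- rbind(fcm[shared], imaging[shared])
  rownames(out) <- NULL
  attr(out, "instrument_gap") <- crossover_um
  out
}

#' Biomass concentration per taxon group and copepod size class
#'
#' Sums `biomass_mg * weight_l` (mg L^-1) per mesocosm, day and group.
#' Groups listed in `copepod_labels` are re-classed by body size via
#' [assign_copepod_class()] into `Copepod_S_nauplii` (with `nauplii_label`
#' merged in, as nauplii fall in the S size range), `Copepod_M` and
#' `Copepod_L`; a `Copepod_total` and a grand `Total` row are appended per
#' (mesocosm, day). Unknown group labels are kept as their own rows and
#' listed in the `unknown_groups` attribute rather than dropped.
#'
#' @param particles particle records with `group` labels.
#' @param copepod_labels group labels to be size-classed as copepods.
#' @param nauplii_label group label of copepod nauplii.
#' @param known_groups optional character vector of expected labels; others
#'   are reported via the `unknown_groups` attribute.
#' @return data.frame with columns `mesocosm`, `day`, `group`,
#'   `biomass_mg_l`, `biovolume_mm3_l`. Biomass (wet weight, density
#'   applied) and raw biovolume per litre are both reported because
#'   published tables differ in which of the two units they print.
#' @export
group_biomass_table <- function(particles,
                                copepod_labels = c("copepod_S", "copepod_M",
                                                   "copepod_L"),
                                nauplii_label = "nauplii",
                                known_groups = NULL) {
  check_particles(particles, require = c("esd_um", "biomass_mg", "weight_l",
                                         "group", "mesocosm", "day"))
  p <- particles
  if (!"biovolume_mm3" %in% names(p))
    p$biovolume_mm3 <- p$biomass_mg / 1.060
  is_cop <- p$group %in% c(copepod_labels, nauplii_label)
  lab <- p$group
  if (any(is_cop)) {
    cls <- as.character(assign_copepod_class(pmax(p$esd_um[is_cop], 150)))
    lab[is_cop] <- paste0("Copepod_", cls)
    lab[is_cop & lab == "Copepod_S"] <- "Copepod_S_nauplii"
  }
  p$lab <- lab
  agg <- function(val, labels) {
    a <- aggregate(list(v = val),
                   by = list(mesocosm = p$mesocosm, day = p$day,
                             group = labels), FUN = sum)
    a
  }
  bm <- aggregate(list(biomass_mg_l = p$biomass_mg * p$weight_l,
                       biovolume_mm3_l = p$biovolume_mm3 * p$weight_l),
                  by = list(mesocosm = p$mesocosm, day = p$day,
                            group = p$lab),
                  FUN = sum)
  # copepod total and grand total per (mesocosm, day)
  totals <- function(sel, label) {
    if (!any(sel)) return(NULL)
    aggregate(list(biomass_mg_l = p$biomass_mg[sel] * p$weight_l[sel],
                   biovolume_mm3_l = p$biovolume_mm3[sel] * p$weight_l[sel]),
              by = list(mesocosm = p$mesocosm[sel], day = p$day[sel],
                        group = rep(label, sum(sel))),
              FUN = sum)
  }
  out <- rbind(bm, totals(is_cop, "Copepod_total"),
               totals(rep(TRUE, nrow(p)), "Total"))
  out <- out[order(out$mesocosm, out$day, out$group), ]
  rownames(out) <- NULL
  if (!is.null(known_groups)) {
    attr(out, "unknown_groups") <-
      setdiff(unique(particles$group),
              c(known_groups, copepod_labels, nauplii_label))
  }
  out
}

#' Percent change relative to a reference
#'
#' `(reference - value) / reference * 100`: positive for a decrease from
#' the reference, negative for an increase. The sign convention follows the
#' habit of reporting declines as positive percentages ("biomass decreased
#' by 25 %").
#'
#' @param reference reference (earlier / control) value; non-zero.
#' @param value comparison value.
#' @return percent change (positive = decrease).
#' @export
#' @examples
#' percent_change(3.43, 2.58)  # ~25 % decrease
percent_change <- function(reference, value) {
  if (any(!is.finite(reference) | reference == 0))
    stop("'reference' must be finite and non-zero", call. = FALSE)
  (reference - value) / reference * 100
}

#' Read / write spectrum tables
#'
#' Spectra are written as comma-separated text with unit-bearing column
#' names, and re-read into `size_spectrum` objects.
#'
#' @param path file path.
#' @param spectrum a `size_spectrum`.
#' @return `read_spectrum()` returns a `size_spectrum`; `write_spectrum()`
#'   returns `path` invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  write.csv(as.data.frame(spectrum), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("size_spectrum", "data.frame")
  out
}
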