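test_that("biovolume to wet weight uses the density constant", {
  expect_equal(biomass_from_biovolume(1), 1.060)
  expect_equal(biomass_from_biovolume(0), 0)
  bv <- (pi / 6) * (100 / 1000)^3
  expect_equal(bv, 5.236e-4, tolerance = 1e-4)
  expect_equal(biomass_from_biovolume(bv), 5.550e-4, tolerance = 1e-4)
  expect_error(biomass_from_biovolume(-1), "non-negative")
})

test_that("log bin grid has geometric edges and linear widths in mm", {
  b <- build_bins(100, 1000, bins_per_decade = 1)
  expect_equal(nrow(b), 1)
  expect_equal(b$lower_um, 100)
  expect_equal(b$upper_um, 1000)
  expect_equal(b$width_mm, 0.9)
  expect_equal(b$mid_um, sqrt(100 * 1000))

  b2 <- build_bins(0.5, 2000, bins_per_decade = 12)
  expect_equal(unique(round(diff(log10(b2$lower_um)), 12)), 1 / 12)
  # widths widen by the grid ratio
  r <- b2$width_mm[-1] / b2$width_mm[-nrow(b2)]
  expect_equal(r, rep(10^(1 / 12), length(r)), tolerance = 1e-12)
  expect_gte(b2$upper_um[nrow(b2)], 2000)
  expect_error(build_bins(100, 100), "s_min")
})

test_that("PSS is abundance per linear bin width", {
  bins <- build_bins(100, 1000, bins_per_decade = 10)
  empty <- compute_pss(make_particles(numeric()), bins)
  expect_true(all(empty$pss_l_mm == 0))

  # 100 particles totalling 10 # L^-1 in one bin of known width
  i <- 4
  esd <- rep(bins$mid_um[i], 100)
  p <- make_particles(esd, weight_l = 0.1)
  sp <- compute_pss(p, bins)
  expect_equal(sp$conc_l[i], 10)
  expect_equal(sp$pss_l_mm[i], 10 / bins$width_mm[i])
  # with a width of exactly 0.1 mm the worked example gives PSS = 100
  expect_equal(10 / 0.1, 100)

  # linearity in the weights
  p2 <- p; p2$weight_l <- p2$weight_l * 2
  expect_equal(compute_pss(p2, bins)$pss_l_mm, sp$pss_l_mm * 2)
})

test_that("WBS sums biomass per bin and satisfies the product identity", {
  bins <- build_bins(100, 1000, bins_per_decade = 10)
  # one bin: concentration 5 # L^-1, mean individual biomass 0.2 mg
  p <- make_particles(rep(bins$mid_um[3], 5), weight_l = 1)
  p$biomass_mg <- rep(0.2, 5)
  sp <- compute_wbs(p, bins)
  expect_equal(sp$wbs_mg_l[3], 1.0)
  expect_equal(sp$wbs_mg_l[3],
               sp$pss_l_mm[3] * sp$mean_biomass_mg[3] * bins$width_mm[3],
               tolerance = 1e-12)
  expect_true(all(sp$wbs_mg_l[-3] == 0))
  # conservation
  expect_equal(sum(sp$wbs_mg_l), sum(p$biomass_mg * p$weight_l),
               tolerance = 1e-12)
})

test_that("spectra conserve totals for any bins-per-decade choice", {
  set.seed(5)
  p <- make_particles(10^runif(5000, 0, 3), weight_l = runif(5000, 0.01, 1))
  total_conc <- sum(p$weight_l)
  total_biom <- sum(p$biomass_mg * p$weight_l)
  for (bpd in c(4, 8, 12, 24)) {
    bins <- build_bins(1, 1000, bins_per_decade = bpd)
    sp <- compute_spectrum(p, bins)
    expect_equal(attr(sp, "n_dropped"), 0L)
    expect_equal(sum(sp$pss_l_mm * sp$width_mm), total_conc,
                 tolerance = 1e-12)
    expect_equal(sum(sp$wbs_mg_l), total_biom, tolerance = 1e-12)
  }
})

test_that("binning agrees with a naive per-particle loop", {
  set.seed(9)
  p <- make_particles(10^runif(2000, -0.2, 3.2),
                      weight_l = runif(2000, 0.05, 2))
  bins <- build_bins(1, 1000, bins_per_decade = 6)
  sp <- compute_spectrum(p, bins)
  oracle <- brute_force_spectrum(p, bins)
  expect_equal(sp$count, oracle$count)
  expect_equal(sp$conc_l, oracle$conc_l, tolerance = 1e-12)
  expect_equal(sp$pss_l_mm, oracle$pss_l_mm, tolerance = 1e-12)
  expect_equal(sp$wbs_mg_l, oracle$wbs_mg_l, tolerance = 1e-12)
  # particles outside the grid are counted, not silently lost
  expect_equal(attr(sp, "n_dropped"),
               sum(p$esd_um < 1 | p$esd_um >= bins$upper_um[nrow(bins)]))
})

test_that("slope fitting recovers exact power laws", {
  bins <- build_bins(1, 1000, bins_per_decade = 8)
  # construct particle weights so that PSS_i = c * mid_i^beta exactly
  beta <- -2
  p <- make_particles(bins$mid_um, weight_l = 1)
  p$weight_l <- 1e3 * (bins$mid_um / 1000)^beta * bins$width_mm
  sp <- compute_pss(p, bins)
  fit <- fit_slope(sp)
  expect_equal(fit$slope, -2, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$n_bins_used, nrow(bins))

  # fewer than three usable bins is an error
  p2 <- p[1:2, ]
  expect_error(fit_slope(compute_pss(p2, bins)), "fewer than 3")

  # gap bins are excluded from the fit
  sp_gap <- compute_spectrum(p, bins, gap_um = c(60, 150))
  fit_gap <- fit_slope(sp_gap)
  expect_lt(fit_gap$n_bins_used, fit$n_bins_used)
  expect_equal(fit_gap$slope, -2, tolerance = 1e-6)
})

test_that("slope is recovered from stochastic power-law samples", {
  # count weighting keeps near-empty tail bins from dominating the fit
  bins <- build_bins(1, 100, bins_per_decade = 12)
  slopes <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    esd <- rpowerlaw(1e5, -3.29, 1, 100)
    p <- make_particles(esd, weight_l = 1e-3)
    fit_slope(compute_pss(p, bins), weights = "count")$slope
  }, numeric(1))
  expect_true(all(abs(slopes - (-3.29)) < 0.1))
})

test_that("instrument merging flags the gap and out-of-domain records", {
  fcm <- make_particles(c(1, 10, 80), instrument = "fcm")
  img <- make_particles(c(120, 200, 900), instrument = "imaging")
  m <- merge_instruments(fcm, img)
  expect_equal(nrow(m), 6)
  expect_equal(m$out_of_domain, c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(attr(m, "instrument_gap"), c(60, 150))
  # conservation of totals
  expect_equal(sum(m$weight_l), sum(fcm$weight_l) + sum(img$weight_l))

  m2 <- merge_instruments(fcm, img[0, ])
  expect_equal(nrow(m2), nrow(fcm))

  bins <- build_bins(0.5, 2000, 12)
  sp <- compute_spectrum(m, bins)
  expect_true(any(sp$coverage == "unobserved_gap"))
  gap_bins <- sp$coverage == "unobserved_gap"
  expect_true(all(sp$lower_um[gap_bins] >= 60 & sp$upper_um[gap_bins] <= 150))
  # straddling bins are marked partially covered
  expect_true(any(sp$coverage == "partial_coverage"))
})

test_that("group biomass table equals hand-computed sums", {
  p <- rbind(
    make_particles(rep(300, 4), weight_l = 0.5, group = "coscinodiscus"),
    make_particles(c(400, 500), weight_l = 0.5, group = "copepod_S"),
    make_particles(c(700, 800), weight_l = 0.5, group = "copepod_M"),
    make_particles(1200, weight_l = 0.5, group = "copepod_L"),
    make_particles(rep(200, 3), weight_l = 0.5, group = "nauplii"))
  tb <- group_biomass_table(p)
  get <- function(g) tb$biomass_mg_l[tb$group == g]
  hand <- function(rows) sum(rows$biomass_mg * rows$weight_l)
  expect_equal(get("coscinodiscus"), hand(p[p$group == "coscinodiscus", ]))
  expect_equal(get("Copepod_S_nauplii"),
               hand(p[p$group %in% c("copepod_S", "nauplii"), ]))
  expect_equal(get("Copepod_M"), hand(p[p$group == "copepod_M", ]))
  expect_equal(get("Copepod_L"), hand(p[p$group == "copepod_L", ]))
  expect_equal(get("Copepod_total"),
               hand(p[p$group != "coscinodiscus", ]))
  expect_equal(get("Total"), hand(p))

  # copepods are classed by measured size, not by label
  big_s <- make_particles(1100, weight_l = 1, group = "copepod_S")
  tb2 <- group_biomass_table(big_s)
  expect_equal(tb2$biomass_mg_l[tb2$group == "Copepod_L"],
               big_s$biomass_mg)

  # single group: total equals the group row
  solo <- make_particles(c(10, 20), group = "nano")
  tb3 <- group_biomass_table(solo)
  expect_equal(tb3$biomass_mg_l[tb3$group == "Total"],
               tb3$biomass_mg_l[tb3$group == "nano"])
})

test_that("percent change follows the decrease-positive convention", {
  expect_equal(percent_change(3.43, 2.58), 24.78, tolerance = 1e-3)
  expect_equal(round(percent_change(3.43, 2.58)), 25)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(6.02, 7.92), -31.56, tolerance = 1e-3)
  expect_error(percent_change(0, 1), "non-zero")
})

test_that("spectrum tables round-trip through CSV", {
  bins <- build_bins(100, 1000, 6)
  sp <- compute_spectrum(make_particles(runif(50, 100, 999)), bins)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(sp, path)
  back <- read_spectrum(path)
  expect_equal(back$pss_l_mm, sp$pss_l_mm, tolerance = 1e-9)
  expect_s3_class(back, "size_spectrum")
})
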