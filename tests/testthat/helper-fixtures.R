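# fixture builders shared across test files

# particle records built directly (no simulator), spherical biomass
make_particles <- function(esd_um, weight_l = 1, group = "g",
                           mesocosm = "M1", day = 1L,
                           instrument = "imaging", density = 1.060) {
  bv <- (pi / 6) * (esd_um / 1000)^3
  n <- length(esd_um)
  data.frame(mesocosm = rep_len(mesocosm, n), day = rep_len(day, n),
             group = rep_len(group, n), instrument = rep_len(instrument, n),
             esd_um = esd_um, biovolume_mm3 = bv, biomass_mg = bv * density,
             weight_l = rep_len(weight_l, n), stringsAsFactors = FALSE)
}

# a single-population, single-mesocosm configuration with constant
# concentration and no replicate noise
flat_population <- function(conc_l, name = "pop", log_mean = log10(300),
                            log_sd = 0.05, instrument = "imaging",
                            multiplier = 1) {
  population_spec(name, log_mean, log_sd,
                  data.frame(day = 1, conc_l = conc_l),
                  treatment_multiplier = multiplier, instrument = instrument)
}

quiet_mesocosm <- function(id = "M1", treatment = "control") {
  mesocosm_spec(id, treatment, replicate_noise_sd = 0)
}

# ESD sampler with an exact power-law density f(s) ~ s^beta on [lo, hi]
rpowerlaw <- function(n, beta, lo, hi) {
  u <- stats::runif(n)
  k <- beta + 1
  (lo^k + u * (hi^k - lo^k))^(1 / k)
}

# naive per-particle binning: loop over bins, no vectorised tricks;
# independent oracle for compute_spectrum
brute_force_spectrum <- function(particles, bins) {
  nb <- nrow(bins)
  pss <- wbs <- conc <- numeric(nb)
  count <- integer(nb)
  for (i in seq_len(nb)) {
    for (j in seq_len(nrow(particles))) {
      s <- particles$esd_um[j]
      if (s >= bins$lower_um[i] && s < bins$upper_um[i]) {
        count[i] <- count[i] + 1L
        conc[i] <- conc[i] + particles$weight_l[j]
        wbs[i] <- wbs[i] + particles$biomass_mg[j] * particles$weight_l[j]
      }
    }
    pss[i] <- conc[i] / bins$width_mm[i]
  }
  list(count = count, conc_l = conc, pss_l_mm = pss, wbs_mg_l = wbs)
}

# exhaustive two-sample permutation test for 5-vs-5 designs (126 splits)
permutation_p <- function(x, y) {
  all_v <- c(x, y)
  n <- length(x)
  idx <- utils::combn(length(all_v), n)
  obs <- abs(mean(x) - mean(y))
  diffs <- apply(idx, 2, function(i) {
    abs(mean(all_v[i]) - mean(all_v[-i]))
  })
  mean(diffs >= obs - 1e-12)
}
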