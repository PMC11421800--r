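test_that("hydrograph endpoints and closed-form recession are exact", {
  cfg <- simulationConfig(recession_shape = 0.5)
  h <- generateHydrograph(cfg)
  expect_equal(max(h$discharge_cms), 1.8)
  expect_equal(min(h$discharge_cms), 0.25)
  # baseflow through the onset day
  expect_equal(h$discharge_cms[seq_len(cfg$event_start_day)],
               rep(0.25, cfg$event_start_day))
  # peak on day event_start_day + rise_days = 8, then geometric recession
  peak <- cfg$event_start_day + cfg$rise_days
  expect_equal(which.max(h$discharge_cms), peak)
  for (k in 1:5)
    expect_equal(h$discharge_cms[peak + k], 0.25 + (1.8 - 0.25) * 0.5^k)
  expect_true(all(h$discharge_cms >= 0.25))
  # precipitation only on event days
  expect_true(all(h$precip_mm[-(cfg$event_start_day:peak)] == 0))
  expect_true(all(h$precip_mm[cfg$event_start_day:peak] > 0))
})

test_that("a storm starting on the last possible day elevates exactly one day", {
  cfg <- simulationConfig(n_days = 10, event_start_day = 9)
  h <- generateHydrograph(cfg)
  expect_equal(sum(h$discharge_cms > cfg$q_base), 1)
  expect_equal(which(h$discharge_cms > cfg$q_base), 10L)
})

test_that("invalid generator configurations are rejected", {
  expect_error(simulationConfig(q_base = -1), "q_peak > q_base > 0")
  expect_error(simulationConfig(q_base = 2, q_peak = 1), "q_peak > q_base")
  expect_error(simulationConfig(n_days = 2), "n_days")
  expect_error(simulationConfig(event_start_day = 17), "event_start_day")
  expect_error(simulationConfig(class_probabilities = c(0.5, 0.5, 0.5)),
               "class_probabilities")
  expect_error(simulationConfig(library_size_range = c(0, 10)),
               "library_size_range")
  expect_error(simulationConfig(delta_old = -40, delta_new = -40), "differ")
  expect_error(simulationConfig(recession_shape = 1.5), "recession_shape")
})

test_that("community columns are exact multinomial draws at the drawn depth", {
  cfg <- simulationConfig(rng_seed = 11)
  h <- generateHydrograph(cfg)
  comm <- generateCommunity(h, cfg)
  expect_true(all(comm$counts >= 0))
  expect_true(all(comm$counts == round(comm$counts)))
  expect_equal(unname(colSums(comm$counts)), unname(comm$truth$library_sizes))
  expect_true(all(comm$truth$library_sizes >= 4333 &
                  comm$truth$library_sizes <= 37740))
  # every taxon has exactly one class
  expect_setequal(rownames(comm$counts), names(comm$truth$taxon_class))
  expect_true(all(comm$truth$taxon_class %in%
                  c("mobilized", "diluted", "static", "event-only")))
  # coupling signs follow the class
  b <- comm$truth$beta; k <- comm$truth$taxon_class
  expect_true(all(b[k == "mobilized"] > 0))
  expect_true(all(b[k == "diluted"] < 0))
  expect_true(all(b[k %in% c("static", "event-only")] == 0))
})

test_that("event-only taxa create a richness spike at peak discharge", {
  hits <- vapply(1:12, function(s) {
    sim <- default_sim(seed = 100 + s, n_event_taxa = 50L)
    rar <- rarefyCounts(sim$experiment, seed = s)
    a <- alphaDiversity(rar)
    peak <- which.max(discharge(rar))
    a$richness[peak] > mean(a$richness[1:4])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("isotope series follows two-endmember mixing with recorded fractions", {
  cfg <- simulationConfig(isotope_noise_sd = 0, d18O_noise_sd = 0, phi = 1)
  h <- generateHydrograph(cfg)
  iso <- generateIsotopes(h, cfg)
  f <- iso$event_water_fraction
  # pre-event days are pure old water
  pre <- seq_len(cfg$event_start_day)
  expect_equal(unname(f[pre]), rep(0, length(pre)))
  expect_equal(iso$isotopes$d2H[pre], rep(cfg$delta_old, length(pre)))
  # Q = 2 * q_base with phi = 1 gives the midpoint of the endmembers
  iso2 <- generateIsotopes(data.frame(date = h$date,
                                      discharge_cms = rep(2 * cfg$q_base, 17),
                                      precip_mm = 0), cfg)
  expect_equal(unname(iso2$event_water_fraction), rep(0.5, 17))
  expect_equal(iso2$isotopes$d2H, rep((cfg$delta_old + cfg$delta_new) / 2, 17))
  # event_water_fraction is zero exactly on pre-event days
  expect_true(all(f[h$discharge_cms > cfg$q_base] > 0))
})

test_that("mixing estimator round-trips the generator exactly at zero noise", {
  cfg <- simulationConfig(isotope_noise_sd = 0, d18O_noise_sd = 0)
  h <- generateHydrograph(cfg)
  iso <- generateIsotopes(h, cfg)
  f_hat <- twoComponentFraction(iso$isotopes$d2H, cfg$delta_old, cfg$delta_new)
  expect_equal(unname(f_hat), unname(iso$event_water_fraction),
               tolerance = 1e-12)
})

test_that("habitat profiles are simplex rows with class-dependent structure", {
  sim <- default_sim(seed = 3)
  prof <- sim$habitatProfiles
  expect_true(all(abs(rowSums(prof) - 1) < 1e-9))
  expect_true(all(prof >= 0))
  expect_identical(colnames(prof), SOURCE_ENVIRONMENTS)

  # degenerate concentration collapses to an indicator profile
  soil_only <- setNames(c(0, 0, 1, 0, 0, 0, 0, 0), SOURCE_ENVIRONMENTS)
  prof2 <- generateHabitatProfiles(sim$truth, sim$config,
                                   concentration = list(mobilized = soil_only))
  mob <- names(sim$truth$taxon_class)[sim$truth$taxon_class == "mobilized"]
  expect_true(all(prof2[mob, "soil"] == 1))
  expect_true(all(prof2[mob, setdiff(SOURCE_ENVIRONMENTS, "soil")] == 0))

  # mobilized vs diluted mean freshwater fraction differs in the designed
  # direction over many ASVs
  big <- default_sim(seed = 4, n_core_taxa = 400L,
                     class_probabilities = c(0.5, 0.5, 0))
  cls <- big$truth$taxon_class
  fw <- big$habitatProfiles[, "freshwater"]
  expect_gt(mean(fw[cls == "diluted"]), mean(fw[cls == "mobilized"]))
  soil <- big$habitatProfiles[, "soil"]
  expect_gt(mean(soil[cls == "mobilized"]), mean(soil[cls == "diluted"]))
})

test_that("simulation is reproducible and components are seed-isolated", {
  s1 <- default_sim(seed = 42)
  s2 <- default_sim(seed = 42)
  expect_identical(asvCounts(s1$experiment), asvCounts(s2$experiment))
  expect_identical(s1$habitatProfiles, s2$habitatProfiles)
  expect_identical(s1$truth, s2$truth)
  # isotope stream does not depend on the community draw
  cfg <- simulationConfig(rng_seed = 42)
  h <- generateHydrograph(cfg)
  expect_identical(generateIsotopes(h, cfg)$isotopes$d2H,
                   isotopeSeries(s1$experiment)$d2H)
})

test_that("written simulation files round-trip through the readers", {
  dir <- withr::local_tempdir()
  sim <- default_sim(seed = 9, n_core_taxa = 60L, n_event_taxa = 20L)
  paths <- writeSimulation(sim, dir)
  expect_true(all(file.exists(paths)))
  se <- suppressWarnings(readStormExperiment(paths["counts"], paths["taxonomy"],
                                             paths["hydro"], paths["isotopes"]))
  orig <- asvCounts(sim$experiment)
  orig <- orig[rowSums(orig) > 0, ]
  expect_identical(asvCounts(se), orig)
  expect_equal(unname(discharge(se)),
               unname(discharge(sim$experiment)))
  expect_equal(isotopeSeries(se)$d2H, isotopeSeries(sim$experiment)$d2H,
               tolerance = 1e-12)
})
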