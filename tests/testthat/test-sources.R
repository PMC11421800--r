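test_that("habitat aggregation normalizes and defaults to 'other'", {
  hits <- data.frame(asv_id = c("a", "a", "b", "b", "c"),
                     habitat = c("lake", "river", "soil", "lake", "summit"),
                     hits = c(3, 1, 3, 1, 0))
  map <- data.frame(habitat = c("lake", "river", "soil"),
                    environment = c("freshwater", "freshwater", "soil"))
  prof <- aggregateHabitats(hits, map, asv_ids = c("a", "b", "c", "d"))
  expect_equal(prof["a", "freshwater"], 1)
  expect_equal(prof["b", "soil"], 0.75)
  expect_equal(prof["b", "freshwater"], 0.25)
  # zero hits and unmapped habitats fall to 'other'
  expect_equal(prof["c", "other"], 1)
  expect_equal(prof["d", "other"], 1)
  expect_equal(unname(rowSums(prof)), rep(1, 4))
  expect_error(aggregateHabitats(data.frame(asv_id = "a", habitat = "lake",
                                            hits = -1)),
               "nonnegative")
})

test_that("community environment fractions are abundance-weighted means", {
  prof <- matrix(0, 2, 8, dimnames = list(c("A", "B"), SOURCE_ENVIRONMENTS))
  prof["A", "freshwater"] <- 1
  prof["B", "soil"] <- 1
  m <- matrix(c(300L, 100L), 2, 1, dimnames = list(c("A", "B"), "2020-10-06"))
  ef <- communityEnvironmentFractions(m, prof)
  expect_equal(ef$freshwater, 0.75)
  expect_equal(ef$soil, 0.25)

  # single-ASV community equals that ASV's profile
  one <- matrix(50L, 1, 1, dimnames = list("A", "2020-10-06"))
  ef1 <- communityEnvironmentFractions(one, prof)
  expect_equal(unlist(ef1[1, SOURCE_ENVIRONMENTS]),
               setNames(prof["A", ], SOURCE_ENVIRONMENTS))

  # equally abundant ASVs: arithmetic mean; rows sum to 1; order-invariant
  eq <- matrix(c(10L, 10L), 2, 1, dimnames = list(c("A", "B"), "2020-10-06"))
  ef2 <- communityEnvironmentFractions(eq, prof)
  expect_equal(ef2$freshwater, 0.5)
  sim <- default_sim(seed = 13, n_core_taxa = 40L, n_event_taxa = 10L)
  rar <- rarefyCounts(sim$experiment, seed = 13)
  ef3 <- communityEnvironmentFractions(rar, sim$habitatProfiles)
  expect_equal(unname(rowSums(ef3[, SOURCE_ENVIRONMENTS])),
               rep(1, nrow(ef3)), tolerance = 1e-9)
  shuf <- sample(nrow(rar))
  ef4 <- communityEnvironmentFractions(asvCounts(rar)[shuf, ],
                                       sim$habitatProfiles)
  expect_equal(ef3, ef4, tolerance = 1e-12)
})

test_that("Mann-Whitney U matches brute-force enumeration for small n", {
  res <- mannWhitneyU(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p_one_sided, 1 / 6)
  expect_equal(res$method, "exact")

  # 4 values all below 4 others: one-sided p = 1/70
  res2 <- mannWhitneyU(1:4, 5:8)
  expect_equal(res2$p_one_sided, 1 / 70)

  # random instances against exhaustive enumeration
  set.seed(23)
  for (i in 1:30) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    v <- sample(1000, nx + ny)                  # distinct -> no ties
    x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
    got <- mannWhitneyU(x, y)
    want <- enumerate_mw_p(x, y)
    expect_equal(got$U, want$U)
    expect_equal(got$p_one_sided, want$p_one_sided, tolerance = 1e-12)
    expect_equal(got$p_two_sided, want$p_two_sided, tolerance = 1e-12)
  }
})

test_that("tied or large samples use the corrected normal approximation", {
  # full tie: U = nx ny / 2, two-sided p = 1
  res <- mannWhitneyU(c(2, 2, 2), c(2, 2, 2))
  expect_equal(res$U, 4.5)
  expect_equal(res$p_two_sided, 1)
  expect_equal(res$method, "normal_approximation")
  # exact and approximate p agree within 0.02 for moderate n
  set.seed(31)
  for (i in 1:20) {
    v <- sample(10000, 12)
    x <- v[1:6]; y <- v[7:12]
    exact <- mannWhitneyU(x, y)           # n = 12 -> exact path
    if (exact$U == 18) next               # distribution center: approx is 0.5
    # compare against the tie-free normal approximation computed directly
    mu <- 18; sg <- sqrt(6 * 6 * 13 / 12)
    z <- (exact$U - mu - sign(exact$U - mu) * 0.5) / sg
    p1_norm <- stats::pnorm(-abs(z))
    expect_lt(abs(exact$p_one_sided - p1_norm), 0.02)
  }
  expect_error(mannWhitneyU(numeric(0), 1:3), "nonempty")
})

test_that("period contrast centers on the pre-event mean and tests shifts", {
  dates <- as.Date("2020-10-06") + 0:7
  ef <- data.frame(date = dates,
                   matrix(1 / 8, 8, 8, dimnames = list(NULL, SOURCE_ENVIRONMENTS)),
                   check.names = FALSE)
  ef$soil <- c(0.10, 0.12, 0.11, 0.13, 0.20, 0.22, 0.21, 0.23)
  ef$freshwater <- 1 / 8 + (0.1150 - ef$soil)  # keep rows comparable
  periods <- list(pre = dates[1:4], early_event = dates[5:8])
  pc <- periodContrast(ef, periods)

  # pre-event differences average zero
  pre_soil <- subset(pc$differences, environment == "soil" & period == "pre")
  expect_equal(mean(pre_soil$diff_pp), 0, tolerance = 1e-12)

  # all pre below all event: exact one-sided p = 1/70, flagged as increase
  soil_test <- subset(pc$tests, environment == "soil")
  expect_equal(soil_test$p_one_sided, 1 / 70)
  expect_equal(soil_test$direction, "increase")
  expect_equal(soil_test$method, "exact")

  # identical distributions: two-sided p = 1
  ef2 <- ef; ef2$soil <- rep(c(0.1, 0.2, 0.3, 0.4), 2)
  ef2$freshwater <- 1 / 8
  pc2 <- periodContrast(ef2, periods)
  expect_equal(subset(pc2$tests, environment == "soil")$p_two_sided, 1)

  # short periods are skipped with a warning
  expect_warning(
    pc3 <- periodContrast(ef, list(pre = dates[1:4], post_event = dates[5])),
    "fewer than 2")
  expect_null(pc3$tests)
  expect_error(periodContrast(ef, list(pre = as.Date(character()))), "pre")
  expect_error(periodContrast(ef, list(pre = dates[1:4],
                                       early_event = dates[4:6])),
               "disjoint")
})

test_that("simulated storms shift biofilm/soil sources in the designed direction", {
  ups <- vapply(1:8, function(s) {
    sim <- default_sim(seed = 1100 + s)
    rar <- rarefyCounts(sim$experiment, seed = s)
    ef <- communityEnvironmentFractions(rar, sim$habitatProfiles)
    per <- defaultPeriods(ef$date, discharge(rar))
    pc <- periodContrast(ef, per)
    ev <- subset(pc$differences, period == "early_event" &
                                 environment %in% c("soil", "biofilm"))
    mean(ev$diff_pp) > 0
  }, logical(1))
  expect_gte(mean(ups), 0.9)
})
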