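test_that("recovery profile has the closed exponential form", {
  flat <- simulate_recovery_profile(50, 50, 3)
  expect_equal(flat(c(0, 1, 10)), rep(50, 3))

  prof <- simulate_recovery_profile(50, 250, 2)
  expect_equal(prof(0), 250)
  expect_equal(prof(2), 50 + 200 * exp(-1))  # ~123.6
  expect_equal(prof(-1), 50)  # pre-chase rest
  y <- prof(seq(0, 12, by = 0.1))
  expect_true(all(diff(y) <= 0))
  expect_true(all(y >= 50))

  expect_error(simulate_recovery_profile(50, 250, 0), "positive")
  expect_error(simulate_recovery_profile(250, 50, 2), "smr")
})

test_that("impairment dip lies below the exponential envelope", {
  env <- simulate_recovery_profile(50, 250, 2)
  dip <- simulate_recovery_profile(50, 250, 2,
                                   impairment = list(onset_h = 2 / 60,
                                                     plateau_h = 28 / 60,
                                                     recover_h = 0.5,
                                                     depth = 0.4))
  expect_lt(dip(10 / 60), env(10 / 60))
  expect_equal(dip(10 / 60), env(10 / 60) * 0.6)
  expect_equal(dip(0), 250)        # dip starts after the chase
  expect_equal(dip(5), env(5))     # fully recovered envelope
  expect_true(all(dip(seq(0, 15, 0.01)) >= 0))
})

test_that("a zero metabolic profile leaves the trace flat at 100%", {
  sch <- cycle_schedule(240, 360)
  zero <- simulate_recovery_profile(0, 0, 1)
  tr <- simulate_airsat_trace(zero, sch, 0.5, 10, 11.29,
                              pre_chase_s = 0, chase_s = 0,
                              post_chase_s = 3600)
  expect_equal(tr$airsat, rep(100, nrow(tr)))
})

test_that("air-saturation traces are reproducible under a fixed seed", {
  sch <- cycle_schedule(240, 360)
  prof <- simulate_recovery_profile(50, 250, 2)
  gen <- function() {
    set.seed(99)
    simulate_airsat_trace(prof, sch, 0.5, 10, 11.29, background_alpha = 2e-4,
                          pre_chase_s = 3600, chase_s = 300,
                          post_chase_s = 3600, noise_sd = 0.2)
  }
  expect_identical(gen(), gen())
})

test_that("an extreme profile fails loudly, naming the cycle", {
  sch <- cycle_schedule(240, 600)
  huge <- simulate_recovery_profile(4000, 4000, 1)
  expect_error(
    suppressWarnings(simulate_airsat_trace(huge, sch, 0.9, 10, 11.29,
                                           pre_chase_s = 0, chase_s = 0,
                                           post_chase_s = 3600)),
    "cycle 1")
  expect_error(simulate_airsat_trace(simulate_recovery_profile(50, 50, 1),
                                     sch, 11, 10, 11.29), "volume")
})

test_that("round trip: respirometry recovers the profile per cycle", {
  # zero noise: every accepted cycle within 2% of the true window mean
  sch <- cycle_schedule(240, 600)
  beta <- oxygen_solubility(10, 0)
  prof <- simulate_recovery_profile(52, 240, 2)
  tr <- simulate_airsat_trace(prof, sch, 0.62, 10, beta,
                              background_alpha = 2e-4,
                              pre_chase_s = 2 * 840, chase_s = 300,
                              post_chase_s = 6 * 3600, noise_sd = 0,
                              post_schedule = cycle_schedule(240, 300),
                              post_short_s = 2 * 3600)
  ser <- mo2_series(tr, sch, 0.62, 10, background = 2e-4, beta = beta,
                    chase = attr(tr, "chase"),
                    post_schedule = cycle_schedule(240, 300),
                    post_short_s = 2 * 3600)
  cyc <- segment_cycles(tr, sch, chase = attr(tr, "chase"),
                        post_schedule = cycle_schedule(240, 300),
                        post_short_s = 2 * 3600)
  acc <- ser[ser$accepted, ]
  expect_gt(nrow(acc), 10)
  for (i in seq_len(nrow(acc))) {
    w <- cyc[cyc$cycle == acc$cycle[i], ]
    tt <- seq(w$start_s + 45, w$end_s - 1, by = 1)
    truth <- mean(prof((tt - attr(tr, "chase")[2]) / 3600))
    expect_equal(acc$mo2[i], truth, tolerance = 0.02)
  }
})

test_that("flow trace mean equals fH x SV x mass over beat windows", {
  fl <- simulate_flow_trace(function(t) rep(60, length(t)),
                            function(t) rep(0.4, length(t)), 1,
                            pre_chase_s = 0, chase_s = 0, post_chase_s = 60,
                            sampling_rate_hz = 10)
  expect_equal(mean(fl$flow_ml_min), 24, tolerance = 0.01)
  # arbitrary full-beat windows too (beats are 1 s here)
  w <- fl$flow_ml_min[fl$time_s >= 10 & fl$time_s < 40]
  expect_equal(mean(w), 24, tolerance = 0.01)
  # mass scaling
  fl2 <- simulate_flow_trace(function(t) rep(60, length(t)),
                             function(t) rep(0.4, length(t)), 2,
                             pre_chase_s = 0, chase_s = 0, post_chase_s = 60,
                             sampling_rate_hz = 10)
  expect_equal(mean(fl2$flow_ml_min), 48, tolerance = 0.01)
})

test_that("flow traces are deterministic and guard their preconditions", {
  gen <- function() {
    set.seed(7)
    simulate_flow_trace(function(t) rep(55, length(t)),
                        function(t) rep(0.3, length(t)), 0.6,
                        pre_chase_s = 0, chase_s = 0, post_chase_s = 30,
                        noise_sd = 0.3, sampling_rate_hz = 10)
  }
  expect_identical(gen(), gen())
  expect_error(
    simulate_flow_trace(function(t) rep(200, length(t)),
                        function(t) rep(0.3, length(t)), 0.6,
                        pre_chase_s = 0, chase_s = 0, post_chase_s = 30,
                        sampling_rate_hz = 10),
    "4x")
  expect_error(
    simulate_flow_trace(function(t) rep(60, length(t)),
                        function(t) rep(0.3, length(t)), 0.6,
                        av_block = list(onset_h = 2, duration_h = 1),
                        pre_chase_s = 0, chase_s = 0, post_chase_s = 30),
    "outside")
})

test_that("study generator honours counts, determinism and group effects", {
  # tiny recordings: the contract under test is the truth table
  base_design <- function(eff) {
    study_design(n_per_group = 2, pre_chase_h = 840 / 3600,
                 post_chase_h = 1, post_short_h = 1,
                 flow_hz = 5, cv = 0, tau_cv = 0,
                 noise_sd_sat = 0, noise_sd_flow = 0,
                 group_effects = eff)
  }
  eff <- null_effects()
  eff$fh_rest["sea"] <- 1.3
  st <- simulate_study(base_design(eff), seed = 5)
  expect_equal(nrow(st$fish), 8)
  expect_equal(length(st$traces), 8)
  tf <- st$truth
  expect_equal(mean(tf$fh_rest[tf$salinity_group == "sea"]) /
                 mean(tf$fh_rest[tf$salinity_group == "fresh"]), 1.3,
               tolerance = 1e-9)
  # null effects: identical cell means for every variable
  st0 <- simulate_study(base_design(null_effects()), seed = 5)
  expect_equal(length(unique(round(st0$truth$smr, 9))), 1)

  st_a <- simulate_study(base_design(eff), seed = 11)
  st_b <- simulate_study(base_design(eff), seed = 11)
  expect_identical(st_a$truth, st_b$truth)
  expect_identical(st_a$traces[[3]]$airsat, st_b$traces[[3]]$airsat)
})

test_that("truth records satisfy their invariants", {
  st <- simulate_study(study_design(n_per_group = 2, pre_chase_h = 840 / 3600,
                                    post_chase_h = 1, post_short_h = 1),
                       seed = 13)
  tf <- st$truth
  expect_true(all(tf$mmr > tf$smr))
  expect_true(all(tf$co_max >= 0 & tf$co_rest >= 0))
  expect_true(all(is.na(tf$epoc) | tf$epoc >= 0))
  expect_true(all(tf$av_block == (tf$surgery_group == "ligated")))
})
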