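sch46 <- cycle_schedule(240, 360)

test_that("cycle segmentation counts and phase labels are correct", {
  tr <- linear_trace(3600, 0)  # 60 min at 4 min flush + 6 min measure
  cyc <- segment_cycles(tr, sch46)
  expect_equal(nrow(cyc), 6)
  expect_true(all(cyc$phase == "pre_chase"))
  expect_equal(cyc$start_s, 240 + (0:5) * 600)
  # all measure-phase samples land in exactly one cycle, flush discarded
  n_assigned <- sum(vapply(cyc$samples, nrow, integer(1)))
  expect_equal(n_assigned, 6 * 360)

  expect_equal(nrow(segment_cycles(tr[0, ], sch46)), 0)
})

test_that("cycles straddling the chase are excluded and logged", {
  tr <- linear_trace(7200, 0)
  # chase begins mid-measure of cycle 2 (at 900 s) and ends at 1200 s
  cyc <- segment_cycles(tr, sch46, chase = c(900, 1200))
  excl <- attr(cyc, "excluded")
  expect_equal(excl$cycle, 2L)
  expect_equal(excl$reason, "straddles_chase")
  expect_false(2L %in% cyc$cycle)
  expect_setequal(unique(cyc$phase), c("pre_chase", "post_chase"))
  # post-chase grid restarts at chase end
  post <- cyc[cyc$phase == "post_chase", ]
  expect_equal(post$start_s[1], 1200 + 240)
})

test_that("post-chase cycles can follow a shorter schedule, then revert", {
  tr <- linear_trace(3600 * 3, 0)
  short <- cycle_schedule(120, 180)
  cyc <- segment_cycles(tr, sch46, chase = c(3600, 3660),
                        post_schedule = short, post_short_s = 1500)
  post <- cyc[cyc$phase == "post_chase", ]
  # 1500 s of short cycles = 5 whole cycles of 300 s, then long cycles
  expect_equal(sum(post$end_s - post$start_s == 180), 5)
  expect_true(all((post$end_s - post$start_s)[-(1:5)] == 360))
  expect_equal(post$start_s[6], 3660 + 5 * 300 + 240)
})

test_that("slope fitting recovers a perfectly linear decline", {
  tr <- linear_trace(600, -0.01)
  cyc <- make_cycle(tr, start_s = 0, end_s = 600)
  fit <- fit_slope(cyc, head_exclusion_s = 45)
  expect_equal(fit$alpha, -0.01, tolerance = 1e-12)
  expect_equal(fit$r2, 1)
  expect_equal(fit$time_s, (45 + 599) / 2)
  expect_error(fit_slope(cyc, head_exclusion_s = 20), "30")
})

test_that("degenerate and undersampled cycles are rejected with reasons", {
  flat <- make_cycle(linear_trace(600, 0), start_s = 0, end_s = 600)
  fit <- suppressWarnings(filter_slopes(fit_slope(flat)))
  expect_false(fit$accepted)
  expect_equal(fit$reason, "r2_undefined")

  tiny <- make_cycle(linear_trace(50, -0.01), start_s = 0, end_s = 50)
  fit2 <- fit_slope(tiny)
  expect_false(fit2$accepted)
  expect_equal(fit2$reason, "too_few_samples")
})

test_that("slope estimate agrees with lm on noisy data", {
  set.seed(1)
  tr <- linear_trace(600, -0.02)
  tr$airsat <- tr$airsat + rnorm(nrow(tr), 0, 0.3)
  fit <- fit_slope(make_cycle(tr, start_s = 0, end_s = 600))
  sub <- tr[tr$time_s >= 45, ]
  ref <- lm(airsat ~ time_s, data = sub)
  expect_equal(fit$alpha, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(fit$r2, summary(ref)$r.squared, tolerance = 1e-10)
  # truth inside the lm confidence interval
  ci <- confint(ref)["time_s", ]
  expect_gt(-0.02, ci[1]); expect_lt(-0.02, ci[2])
})

test_that("slope estimates are invariant to sampling density", {
  f1 <- fit_slope(make_cycle(linear_trace(600, -0.015, dt = 1),
                             start_s = 0, end_s = 600))
  f2 <- fit_slope(make_cycle(linear_trace(600, -0.015, dt = 0.2),
                             start_s = 0, end_s = 600))
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-9)
})

test_that("R^2 filter uses a strict inequality", {
  fits <- tibble::tibble(cycle = 1:3, phase = "pre_chase", time_s = 1:3,
                         alpha = -0.01, r2 = c(0.90, 0.95, 0.89),
                         n_points = 100, excluded_head_s = 45,
                         accepted = NA, reason = NA_character_)
  out <- filter_slopes(fits)
  expect_equal(out$accepted, c(FALSE, TRUE, FALSE))
  expect_equal(out$reason, c("low_r2", NA, "low_r2"))
  expect_warning(filter_slopes(fits[c(1, 3), ]), "no slope passed")
})

test_that("oxygen consumption follows the background-corrected equation", {
  fit0 <- tibble::tibble(cycle = 1L, phase = "pre_chase", time_s = 300,
                         alpha = 0, r2 = 1)
  expect_equal(compute_mo2(fit0, 0, 10, 10, 1)$mo2, 0)

  # hand calculation: 0.01 %/s * 9 l * 10 mg/l / 100 * 3600 / 1 kg
  fit1 <- fit0; fit1$alpha <- -0.01
  expect_equal(compute_mo2(fit1, 0, 10, 10, 1)$mo2, 32.4)

  # algebra: same slopes, doubled mass -> factor (Vn'/Vn) * (m/m')
  m1 <- compute_mo2(fit1, 0, 10, 10, 1)$mo2
  m2 <- compute_mo2(fit1, 0, 10, 10, 2)$mo2
  expect_equal(m2 / m1, (8 / 9) * (1 / 2), tolerance = 1e-12)

  # over-correction is flagged, not clipped
  neg <- compute_mo2(fit1, 0.02, 10, 10, 1)
  expect_lt(neg$mo2, 0)
  expect_equal(neg$flag, "mo2_negative")
  expect_error(compute_mo2(fit1, 0, 10, 1, 2), "volume")
})

test_that("background schedule supports constant and ramp modes", {
  cst <- background_schedule(-0.001)
  expect_equal(cst(c(0, 1e5)), c(0.001, 0.001))
  expect_equal(background_schedule(0)(123), 0)
  ramp <- background_schedule(-0.002, mode = "ramp", alpha_b_start = 0,
                              t_start = 0, t_end = 1000)
  expect_equal(ramp(500), 0.001)
  expect_equal(ramp(c(0, 1000, 2000)), c(0, 0.002, 0.002))
})

test_that("audit identity holds: cycles = accepted + rejected, one reason each", {
  set.seed(42)
  beta <- oxygen_solubility(10, 0)
  prof <- simulate_recovery_profile(50, 50, 1)
  tr <- simulate_airsat_trace(prof, sch46, 0.45, 10, beta,
                              pre_chase_s = 0, chase_s = 0,
                              post_chase_s = 3 * 3600, noise_sd = 0.6)
  ser <- suppressWarnings(mo2_series(tr, sch46, 0.45, 10, beta = beta))
  cyc <- segment_cycles(tr, sch46)
  expect_equal(nrow(ser), nrow(cyc))
  expect_false(any(is.na(ser$accepted)))
  rejected <- ser[!ser$accepted, ]
  expect_true(all(!is.na(rejected$reason)))
  expect_true(all(is.na(ser$reason[ser$accepted])))
})
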