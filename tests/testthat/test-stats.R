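test_that("two-way ANOVA matches the brute-force SS decomposition", {
  set.seed(21)
  for (rep in 1:5) {
    d <- cell_data(means = rnorm(4, 100, 10), resid = rnorm(32, 0, 5),
                   n_per_cell = 8)
    et <- two_way_anova(d, "y", "salinity_group", "surgery_group")
    bf <- brute_force_anova(d)
    expect_equal(et$F[et$term == "salinity_group"], bf$F_a,
                 tolerance = 1e-9)
    expect_equal(et$F[et$term == "surgery_group"], bf$F_b,
                 tolerance = 1e-9)
    expect_equal(et$F[grepl(":", et$term)], bf$F_ab, tolerance = 1e-9)
    expect_equal(unique(et$df_resid), bf$df_e)
  }
})

test_that("null and additive designs give the expected F statistics", {
  # equal cell means, symmetric residuals: every effect F is exactly 0
  d0 <- cell_data(rep(50, 4), rep(c(-1, 1), 8), n_per_cell = 4)
  et0 <- two_way_anova(d0, "y", "salinity_group", "surgery_group")
  expect_equal(et0$F, rep(0, 3), tolerance = 1e-12)

  # additive cell means: interaction SS (hence F) is exactly 0
  da <- cell_data(c(50, 60, 55, 65), rep(c(-1, 1), 8), n_per_cell = 4)
  eta <- two_way_anova(da, "y", "salinity_group", "surgery_group")
  expect_equal(eta$F[grepl(":", eta$term)], 0, tolerance = 1e-12)
  expect_gt(eta$F[eta$term == "salinity_group"], 0)
})

test_that("ANOVA validates cells and applies transformations", {
  d <- cell_data(rep(50, 4), rnorm(8), n_per_cell = 2)
  expect_error(two_way_anova(d[d$salinity_group == "fresh" |
                                 d$surgery_group == "sham", ],
                             "y", "salinity_group", "surgery_group"),
               "empty design cell")
  et_log <- two_way_anova(d, "y", "salinity_group", "surgery_group",
                          transform = "log")
  expect_identical(attr(et_log, "transform"), "log")
  ref <- two_way_anova(within(d, y <- log(y)), "y", "salinity_group",
                       "surgery_group")
  expect_equal(et_log$F, ref$F, tolerance = 1e-12)
})

test_that("simple main effects agree with emmeans under Bonferroni", {
  set.seed(31)
  d <- cell_data(c(100, 90, 104, 70), rnorm(36, 0, 8), n_per_cell = 9)
  et <- two_way_anova(d, "y", "surgery_group", "salinity_group")
  sme <- simple_main_effects(et, "surgery_group")
  fit <- attr(et, "model")
  em <- emmeans::emmeans(fit, ~ surgery_group | salinity_group)
  ep <- summary(emmeans::contrast(em, "revpairwise"), adjust = "bonferroni")
  # emmeans adjusts within each `by` level; replicate family-wide Bonferroni
  raw_p <- summary(emmeans::contrast(em, "revpairwise"), adjust = "none")
  expect_equal(sme$estimate, ep$estimate, tolerance = 1e-9)
  expect_equal(sme$se, ep$SE, tolerance = 1e-9)
  expect_equal(sme$p_adj, pmin(1, raw_p$p.value * 2), tolerance = 1e-9)
  expect_equal(attr(sme, "conf_level"), 1 - 0.05 / 2)
})

test_that("simple main effects detect an effect present in one level only", {
  set.seed(32)
  hits_sea <- 0; hits_fresh <- 0; n_rep <- 200
  for (i in seq_len(n_rep)) {
    # ligation lowers the response in sea water only (design-sized effect)
    d <- cell_data(c(274, 260, 274, 175), rnorm(36, 0, 27), n_per_cell = 9)
    et <- two_way_anova(d, "y", "surgery_group", "salinity_group")
    sme <- simple_main_effects(et, "surgery_group")
    hits_sea <- hits_sea + sme$significant[sme$at_level == "sea"]
    hits_fresh <- hits_fresh + sme$significant[sme$at_level == "fresh"]
  }
  expect_gte(hits_sea / n_rep, 0.8)
  expect_lte(hits_fresh / n_rep, 0.15)
})

test_that("identical groups yield no significant contrasts", {
  set.seed(33)
  d <- cell_data(rep(80, 4), rep(c(-2, -1, 1, 2), 8), n_per_cell = 8)
  et <- two_way_anova(d, "y", "salinity_group", "surgery_group")
  sme <- simple_main_effects(et, "salinity_group")
  expect_false(any(sme$significant))
})

test_that("percent effects reproduce report arithmetic exactly", {
  expect_equal(percent_effect(200, 200), 0)
  # percent_effect(x, x*(1-p)) == 100 p exactly
  for (p in c(0.05, 0.17, 0.33, 0.41)) {
    expect_equal(percent_effect(137.5, 137.5 * (1 - p), round_digits = NULL),
                 100 * p, tolerance = 1e-12)
  }
  expect_error(percent_effect(0, 10), "non-zero")

  expect_equal(relative_difference_ratio(c(10, 4), c(10, 4)), 0)
  expect_equal(relative_difference_ratio(c(30, 10), c(15, 5), NULL),
               100 * (20 / 10 - 1), tolerance = 1e-12)
  expect_error(relative_difference_ratio(c(1, 0), c(5, 5)), "non-zero")
})

test_that("group summaries report n, mean and s.e.m. per cell", {
  d <- cell_data(c(10, 20, 30, 40), rep(c(-1, 1), 8), n_per_cell = 4)
  gs <- group_summary(d, "y")
  expect_equal(nrow(gs), 4)
  expect_setequal(gs$mean, c(10, 20, 30, 40))
  expect_equal(unique(gs$n), 4)
  expect_equal(unique(gs$sem), sd(c(-1, 1, -1, 1)) / 2)
})
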