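#' Analyse one fish of a synthetic (or real) study
#'
#' Full pipeline for a single animal: air-saturation trace to quality-
#' filtered MO2 series; SMR, MMR, aerobic scope and EPOC; probe calibration;
#' cardiac output, heart rate and stroke volume over the respirometry
#' windows co-timed with the SMR-defining cycles, the MMR cycle and the
#' post-exercise time grid; and resting/maximum/scope cardiac summaries.
#'
#' @param airsat Air-saturation trace tibble (`time_s`, `airsat`).
#' @param flow Flow trace tibble (`time_s`, `flow_ml_min`), or `NULL` to
#'   skip cardiac analysis.
#' @param calibration Probe-calibration points tibble (`true`, `recorded`),
#'   or `NULL` for an uncalibrated probe.
#' @param body_mass Body mass, kg.
#' @param schedule Pre-chase [cycle_schedule()].
#' @param chase Chase window `c(start_s, end_s)` or `NULL`.
#' @param post_schedule Post-chase schedule; defaults to `schedule`.
#' @param post_short_s Span of the short post-chase cycles, s; see
#'   [segment_cycles()]. Default `Inf`.
#' @param beta Oxygen solubility, mg l-1.
#' @param background_alpha Background slope magnitude, % s-1.
#' @param vt Respirometer volume, l.
#' @param ligated Logical; enables the unsmoothed head in EPOC smoothing.
#' @param cardiac_cycles `"needed"` (SMR cycles, MMR cycle and time grid;
#'   default) or `"all"`.
#' @param head_exclusion_s,r2_min,smooth_threshold,recovery_margin,expected_max_fh
#'   Analysis settings.
#' @return List: `mo2` (mo2_series), `phenotype`, `calibration`,
#'   `cardiac_samples`, `cardiac_summary`, `timecourse` (MO2 and cardiac
#'   values on the post-exercise grid).
#' @export
analyze_fish <- function(airsat, flow, calibration, body_mass, schedule,
                         chase, beta, background_alpha, vt,
                         ligated = FALSE, post_schedule = schedule,
                         post_short_s = Inf,
                         cardiac_cycles = c("needed", "all"),
                         head_exclusion_s = 45, r2_min = 0.90,
                         smooth_threshold = 0.05, recovery_margin = 0.10,
                         expected_max_fh = 100) {
  cardiac_cycles <- match.arg(cardiac_cycles)
  mo2 <- mo2_series(airsat, schedule, body_mass, vt,
                    background = background_alpha, beta = beta,
                    chase = chase, post_schedule = post_schedule,
                    post_short_s = post_short_s,
                    head_exclusion_s = head_exclusion_s,
                    r2_min = r2_min)
  chase_end <- if (is.null(chase)) NA_real_ else chase[2]
  phen <- metabolic_phenotype(mo2, chase_end, ligated = ligated,
                              smooth_threshold = smooth_threshold,
                              recovery_margin = recovery_margin)
  smr_cycles <- attr(phen, "smr_cycles")

  grid_min <- c(0, 10, 20, 30, 60, 120, 300, 600, 900)
  post <- mo2[mo2$phase == "post_chase" & mo2$accepted %in% TRUE, ]
  tc_mo2 <- timecourse_extract((post$time_s - chase_end) / 60, post$mo2)

  cal <- if (is.null(calibration)) NULL else
    calibrate_probe(calibration$true, calibration$recorded)

  cardiac_samples <- NULL; cardiac_summary <- NULL; tc_card <- NULL
  if (!is.null(flow)) {
    windows <- segment_cycles(airsat, schedule, chase = chase,
                              post_schedule = post_schedule,
                              post_short_s = post_short_s)
    if (cardiac_cycles == "needed") {
      grid_cycles <- vapply(grid_min, function(g) {
        i <- which.min(abs((post$time_s - chase_end) / 60 - g))
        as.integer(post$cycle[i])
      }, integer(1))
      want <- unique(c(smr_cycles, phen$mmr_cycle, grid_cycles))
      windows <- windows[windows$cycle %in% want, ]
    }
    cardiac_samples <- do.call(rbind, lapply(seq_len(nrow(windows)), function(i) {
      s <- cardiac_during_cycle(flow,
                                c(windows$start_s[i], windows$end_s[i]),
                                calibration = cal, body_mass = body_mass,
                                expected_max_fh = expected_max_fh)
      s$cycle <- windows$cycle[i]
      s$phase <- windows$phase[i]
      s
    }))
    cardiac_summary <- summarize_cardiac(cardiac_samples, smr_cycles,
                                         phen$mmr_cycle)
    cpost <- cardiac_samples[cardiac_samples$phase == "post_chase", ]
    mid_min <- ((cpost$start_s + cpost$end_s) / 2 - chase_end) / 60
    tc_card <- list(co = timecourse_extract(mid_min, cpost$co),
                    fh = timecourse_extract(mid_min, cpost$fh),
                    sv = timecourse_extract(mid_min, cpost$sv))
  }
  list(mo2 = mo2, phenotype = phen, calibration = cal,
       cardiac_samples = cardiac_samples, cardiac_summary = cardiac_summary,
       timecourse = c(list(mo2 = tc_mo2), tc_card))
}

#' Analyse every fish of a synthetic study
#'
#' Maps [analyze_fish()] over a [simulate_study()] result and collects
#' per-fish metabolic phenotypes and cardiac summaries, joined with the
#' group factors, ready for the factorial analysis.
#'
#' @param study A `respicard_study`.
#' @param cardiac Run the cardiac branch (default `TRUE`).
#' @param ... Passed to [analyze_fish()].
#' @return List: `phenotypes` (tibble, one row per fish), `cardiac`
#'   (tibble), `details` (per-fish [analyze_fish()] results).
#' @export
analyze_study <- function(study, cardiac = TRUE, ...) {
  stopifnot(inherits(study, "respicard_study"))
  d <- study$design
  res <- lapply(seq_len(nrow(study$fish)), function(i) {
    f <- study$fish[i, ]
    tr <- study$traces[[i]]
    beta <- unname(study$beta[[if (f$salinity_group == "sea") "sea" else "fresh"]])
    analyze_fish(tr$airsat, if (cardiac) tr$flow else NULL,
                 tr$calibration, f$body_mass_kg, d$schedule, study$chase,
                 beta, d$background_alpha, d$respirometer_volume_l,
                 ligated = f$surgery_group == "ligated",
                 post_schedule = d$post_schedule,
                 post_short_s = d$post_short_h * 3600,
                 head_exclusion_s = d$head_exclusion_s, r2_min = d$r2_min,
                 ...)
  })
  phen <- do.call(rbind, lapply(res, `[[`, "phenotype"))
  phenotypes <- dplyr::bind_cols(
    study$fish[, c("fish_id", "salinity_group", "surgery_group",
                   "body_mass_kg")], phen)
  cardiac_tbl <- NULL
  if (cardiac) {
    card <- do.call(rbind, lapply(res, `[[`, "cardiac_summary"))
    cardiac_tbl <- dplyr::bind_cols(
      study$fish[, c("fish_id", "salinity_group", "surgery_group")], card)
  }
  list(phenotypes = phenotypes, cardiac = cardiac_tbl, details = res)
}

#' Empirical type-I error of the simulate-and-test loop
#'
#' Repeatedly simulates a reduced study under null group effects (pre-chase
#' respirometry only, coarser optode sampling), re-estimates SMR for every
#' fish through the full slope-fitting pipeline, runs the two-way ANOVA, and
#' counts how often either main effect is declared significant. Under the
#' null the rejection rate of each test should match `alpha`.
#'
#' @param n_reps Replicate studies. Default 500.
#' @param n_per_group Fish per cell. Default 6.
#' @param alpha Nominal level. Default 0.05.
#' @param seed Integer seed.
#' @param pre_chase_h Recording length, h. Default 4 (17 cycles, enough that
#'   occasional R^2 rejections never starve the SMR estimator).
#' @param dt_s Optode sampling interval, s. Default 20.
#' @param cv Between-fish CV of true SMR. Default 0.10.
#' @param noise_sd_sat Optode noise, %. Default 0.2.
#' @return List: `rate` (pooled over both main effects), `n_tests`,
#'   `p_values` (matrix reps x 2).
#' @export
type_i_error_sim <- function(n_reps = 500, n_per_group = 6, alpha = 0.05,
                             seed = 1, pre_chase_h = 4, dt_s = 20,
                             cv = 0.10, noise_sd_sat = 0.2) {
  set.seed(seed)
  sch <- cycle_schedule(240, 600)
  beta <- oxygen_solubility(10, 0)
  vt <- 10
  groups <- expand.grid(salinity_group = c("fresh", "sea"),
                        surgery_group = c("sham", "ligated"),
                        stringsAsFactors = FALSE)
  n_fish <- 4 * n_per_group
  pvals <- matrix(NA_real_, n_reps, 2,
                  dimnames = list(NULL, c("salinity", "surgery")))
  for (r in seq_len(n_reps)) {
    smr_hat <- numeric(n_fish)
    gidx <- rep(seq_len(4), each = n_per_group)
    for (i in seq_len(n_fish)) {
      smr_true <- .rlnorm_cv(1, 51.9, cv)
      mass <- stats::runif(1, 0.5, 0.7)
      profile <- simulate_recovery_profile(smr_true, smr_true, 1)
      tr <- simulate_airsat_trace(profile, sch, mass, vt, beta,
                                  background_alpha = 2e-4,
                                  pre_chase_s = 0, chase_s = 0,
                                  post_chase_s = pre_chase_h * 3600,
                                  noise_sd = noise_sd_sat, dt_s = dt_s)
      ser <- mo2_series(tr, sch, mass, vt, background = 2e-4, beta = beta)
      smr_hat[i] <- estimate_smr(ser$mo2[ser$accepted %in% TRUE])$smr
    }
    d <- data.frame(smr = smr_hat,
                    salinity_group = groups$salinity_group[gidx],
                    surgery_group = groups$surgery_group[gidx])
    et <- two_way_anova(d, "smr", "salinity_group", "surgery_group")
    pvals[r, ] <- et$p[1:2]
  }
  list(rate = mean(pvals < alpha), n_tests = length(pvals), p_values = pvals)
}
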