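#' Null group effects
#'
#' Group-effect table with every multiplier at 1 (no salinity, surgery or
#' interaction effect on any variable) for type-I-error experiments.
#'
#' @return Named list of `c(sea, ligated, interaction)` multipliers.
#' @export
null_effects <- function() {
  vars <- c("smr", "mmr", "fh_rest", "fh_max", "sv_max", "co_rest",
            "hb", "hct")
  stats::setNames(lapply(vars, function(v)
    c(sea = 1, ligated = 1, interaction = 1)), vars)
}

# default multiplicative group effects; cell mean = baseline *
# sea^[sea] * ligated^[ligated] * interaction^[sea & ligated]
.default_effects <- function() {
  list(
    smr     = c(sea = 1.143, ligated = 0.832, interaction = 1.155),
    mmr     = c(sea = 0.948, ligated = 0.828, interaction = 0.814),
    fh_rest = c(sea = 1.295, ligated = 1.136, interaction = 0.895),
    fh_max  = c(sea = 0.867, ligated = 1.000, interaction = 1.000),
    sv_max  = c(sea = 1.133, ligated = 0.727, interaction = 0.917),
    co_rest = c(sea = 1.000, ligated = 1.000, interaction = 1.000),
    hb      = c(sea = 1.000, ligated = 1.000, interaction = 0.840),
    hct     = c(sea = 1.000, ligated = 1.000, interaction = 0.830))
}

#' Design of a synthetic 2x2 cardiorespirometry study
#'
#' Defines the study conditions of a salinity (fresh/sea) x surgery
#' (sham/ligated) factorial experiment: respirometry protocol, recording
#' spans, fresh-sham baseline physiology, multiplicative group effects,
#' between-fish variability and noise levels. Baselines and effects default
#' to values typical of ~0.5 kg rainbow trout at 10-11 degrees C in this
#' experimental design.
#'
#' @param n_per_group Fish per salinity x surgery cell (>= 1). Default 9.
#' @param temperature_c Water temperature. Default 10.
#' @param salinity_fresh,salinity_sea Salinities of the two groups, ppt.
#' @param respirometer_volume_l Chamber volume, litres; must exceed the
#'   largest body mass (as litres). Default 10.
#' @param body_mass_range_kg Uniform body-mass range. Default 0.45-0.70 kg.
#' @param schedule Pre-chase flush/measure [cycle_schedule()]. Default 4 min
#'   flush / 10 min measure: long sealed phases give resting saturation
#'   slopes enough signal relative to optode noise to pass the R^2 filter.
#' @param post_schedule Post-chase schedule. Default 4 min / 5 min: shorter
#'   sealed phases keep end-of-cycle saturation above the floor while
#'   oxygen consumption is near maximal.
#' @param post_short_h Hours after the chase during which `post_schedule`
#'   applies; later cycles revert to the long pre-chase schedule so that
#'   shallow late-recovery slopes retain enough signal to pass the R^2
#'   filter. Default 3.
#' @param pre_chase_h,chase_min,post_chase_h Recording spans: pre-chase rest,
#'   chase duration, post-chase recovery. Defaults 6 h, 5 min, 15 h.
#' @param airsat_dt_s Optode sampling interval, s. Default 1.
#' @param flow_hz Flow-probe sampling rate, Hz. Default 10.
#' @param noise_sd_sat Optode noise s.d., % air saturation. Default 0.2.
#' @param noise_sd_flow Flow noise s.d., ml min-1. Default 0.5.
#' @param baseline Named list of fresh-sham means: `smr`, `mmr`
#'   (mg O2 h-1 kg-1), `tau_h` (EPOC decay constant, h), `fh_rest`, `fh_max`
#'   (beats min-1), `sv_max` (ml kg-1), `co_rest` (ml min-1 kg-1), `hb`
#'   (g l-1), `hct` (%).
#' @param group_effects Named list of `c(sea, ligated, interaction)`
#'   multipliers per baseline variable; see [null_effects()] for the null
#'   table. Maximum cardiac output is not set directly: it follows from the
#'   identity CO = fH x SV.
#' @param cv Between-fish coefficient of variation on each variable.
#' @param tau_cv,tau_ligated_factor,tau_sea_factor Between-fish CV and group
#'   multipliers of the recovery time constant; the ligated factor > 1
#'   prolongs recovery so that a realistic fraction of ligated fish fails to
#'   reach SMR + 10% within the recording.
#' @param background_alpha Microbial background slope, % s-1. Default 2e-4.
#' @param av_block AV-block schedule for ligated fish: list `onset_h`,
#'   `duration_h`, `ratio`. Default 2:1 block from 2 to 30 min post-chase.
#' @param mo2_impairment Impairment dip passed to
#'   [simulate_recovery_profile()] for ligated fish.
#' @param activity_spikes Inject spontaneous-activity spikes into the
#'   recovery profile (off by default; their magnitude is not a measured
#'   quantity in this design).
#' @param head_exclusion_s,r2_min Analysis settings carried with the design.
#' @return A `study_design` list.
#' @export
study_design <- function(n_per_group = 9,
                         temperature_c = 10,
                         salinity_fresh = 0, salinity_sea = 33,
                         respirometer_volume_l = 10,
                         body_mass_range_kg = c(0.45, 0.70),
                         schedule = cycle_schedule(240, 600),
                         post_schedule = cycle_schedule(240, 300),
                         post_short_h = 3,
                         pre_chase_h = 6, chase_min = 5, post_chase_h = 15,
                         airsat_dt_s = 1, flow_hz = 10,
                         noise_sd_sat = 0.2, noise_sd_flow = 0.5,
                         baseline = list(smr = 51.9, mmr = 274.3,
                                         tau_h = 2.5, fh_rest = 44,
                                         fh_max = 60, sv_max = 0.45,
                                         co_rest = 12.7, hb = 85, hct = 28),
                         group_effects = .default_effects(),
                         cv = 0.10,
                         tau_cv = 0.25, tau_ligated_factor = 1.6,
                         tau_sea_factor = 0.8,
                         background_alpha = 2e-4,
                         av_block = list(onset_h = 2 / 60,
                                         duration_h = 28 / 60, ratio = 2),
                         mo2_impairment = list(onset_h = 2 / 60,
                                               plateau_h = 28 / 60,
                                               recover_h = 0.5, depth = 0.4),
                         activity_spikes = FALSE,
                         head_exclusion_s = 45, r2_min = 0.90) {
  if (n_per_group < 1) stop("n_per_group must be >= 1", call. = FALSE)
  if (respirometer_volume_l <= max(body_mass_range_kg)) {
    stop("respirometer volume must exceed the largest body mass", call. = FALSE)
  }
  if (any(unlist(baseline) <= 0)) {
    stop("all baseline physiological parameters must be strictly positive",
         call. = FALSE)
  }
  if (is.null(group_effects)) group_effects <- null_effects()
  structure(as.list(environment()), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Synthetic 2x2 cardiorespirometry study design\n")
  cat(sprintf("  %d fish per cell (%d total), %g l chamber, %g degC\n",
              x$n_per_group, 4 * x$n_per_group, x$respirometer_volume_l,
              x$temperature_c))
  cat(sprintf("  pre %g h | chase %g min | post %g h; cycles %g+%g s pre, %g+%g s post\n",
              x$pre_chase_h, x$chase_min, x$post_chase_h,
              x$schedule$flush_s, x$schedule$measure_s,
              x$post_schedule$flush_s, x$post_schedule$measure_s))
  invisible(x)
}

.cell_mult <- function(eff, sea, ligated) {
  eff[["sea"]]^sea * eff[["ligated"]]^ligated *
    eff[["interaction"]]^(sea && ligated)
}

# lognormal draw with mean m and coefficient of variation cv
.rlnorm_cv <- function(n, m, cv) {
  if (cv <= 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, log(m) - sdlog^2 / 2, sdlog)
}

# EPOC of a recovery profile by dense quadrature: area above (1+margin)*smr
# until the first crossing, NA if never reached within horizon_h
.profile_epoc <- function(profile, smr, horizon_h, margin = 0.10,
                          dt_h = 0.002) {
  thr <- (1 + margin) * smr
  t <- seq(0, horizon_h, by = dt_h)
  y <- profile(t)
  below <- y <= thr
  if (!below[1] && !any(below)) {
    return(list(epoc = NA_real_, duration = NA_real_, recovered = FALSE))
  }
  j <- which(below)[1]
  if (j == 1) return(list(epoc = 0, duration = 0, recovered = TRUE))
  frac <- (y[j - 1] - thr) / (y[j - 1] - y[j])
  t_rec <- t[j - 1] + frac * dt_h
  tt <- c(t[seq_len(j - 1)], t_rec)
  yy <- pmax(c(y[seq_len(j - 1)], thr) - thr, 0)
  list(epoc = pracma::trapz(tt, yy), duration = t_rec, recovered = TRUE)
}

# noiseless cycle-mean MO2 over each post-chase fitted window; the maximum is
# the observable MMR for cycle-resolution respirometry
.observable_mmr <- function(profile, design) {
  post_s <- design$post_chase_h * 3600
  short <- design$post_schedule
  long <- design$schedule
  n_short <- floor(min(design$post_short_h * 3600, post_s) / short$period_s)
  starts_a <- (seq_len(n_short) - 1) * short$period_s + short$flush_s
  ends_a <- (seq_len(n_short) - 1) * short$period_s + short$period_s
  boundary <- n_short * short$period_s
  n_long <- floor((post_s - boundary) / long$period_s)
  starts_b <- boundary + (seq_len(n_long) - 1) * long$period_s + long$flush_s
  ends_b <- boundary + seq_len(n_long) * long$period_s
  starts <- c(starts_a, starts_b) + design$head_exclusion_s
  ends <- c(ends_a, ends_b)
  means <- vapply(seq_along(starts), function(k) {
    tt <- seq(starts[k], ends[k], by = 1) / 3600
    mean(profile(tt))
  }, numeric(1))
  list(mmr_obs = max(means), cycle = which.max(means))
}

#' Simulate a complete synthetic cardiorespirometry study
#'
#' Draws per-fish ground-truth physiology from the design's baselines, group
#' effects and between-fish variability, then generates one air-saturation
#' trace and one pulsatile flow trace per fish (pre-chase rest, chase gap,
#' post-chase recovery), a bench calibration table per flow probe, and the
#' biometric/haematological metadata table. Coronary-ligated fish receive a
#' 2:1 AV block and a matching metabolic impairment dip early in recovery.
#'
#' All randomness derives from `seed`: identical seeds give identical
#' datasets.
#'
#' @param design A [study_design()].
#' @param seed Integer seed.
#' @return A `respicard_study` list: `design`, `fish` (metadata tibble),
#'   `truth` (one TruthRecord row per fish, including the observable
#'   cycle-mean MMR `mmr_obs`), `traces` (per-fish list with `airsat`,
#'   `flow`, `calibration`), `chase` (window, s), `beta`.
#' @export
simulate_study <- function(design, seed = 1) {
  stopifnot(inherits(design, "study_design"))
  set.seed(seed)
  d <- design
  groups <- expand.grid(salinity_group = c("fresh", "sea"),
                        surgery_group = c("sham", "ligated"),
                        stringsAsFactors = FALSE)
  pre_s <- d$pre_chase_h * 3600
  chase_s <- d$chase_min * 60
  post_s <- d$post_chase_h * 3600
  chase <- c(pre_s, pre_s + chase_s)

  fish <- list(); truth <- list(); traces <- list()
  fid <- 0L
  for (g in seq_len(nrow(groups))) {
    sea <- groups$salinity_group[g] == "sea"
    lig <- groups$surgery_group[g] == "ligated"
    for (k in seq_len(d$n_per_group)) {
      fid <- fid + 1L
      mass <- stats::runif(1, d$body_mass_range_kg[1], d$body_mass_range_kg[2])
      draw <- function(v) .rlnorm_cv(1, d$baseline[[v]] *
                                       .cell_mult(d$group_effects[[v]], sea, lig),
                                     d$cv)
      smr <- draw("smr")
      mmr <- max(draw("mmr"), 1.2 * smr)  # keep scope positive for every fish
      fh_rest <- draw("fh_rest"); fh_max <- draw("fh_max")
      sv_max <- draw("sv_max"); co_rest <- draw("co_rest")
      hb <- draw("hb"); hct <- min(draw("hct"), 55)
      sv_rest <- co_rest / fh_rest
      tau <- .rlnorm_cv(1, d$baseline$tau_h *
                          (if (lig) d$tau_ligated_factor else 1) *
                          (if (sea) d$tau_sea_factor else 1), d$tau_cv)
      imp <- if (lig) d$mo2_impairment else NULL
      profile <- simulate_recovery_profile(smr, mmr, tau, impairment = imp)
      tau_card <- 1  # cardiac recovery time constant, h
      fh_fn <- function(t_h) ifelse(t_h < 0, fh_rest,
                                    fh_rest + (fh_max - fh_rest) *
                                      exp(-t_h / tau_card))
      sv_fn <- function(t_h) ifelse(t_h < 0, sv_rest,
                                    sv_rest + (sv_max - sv_rest) *
                                      exp(-t_h / tau_card))
      beta <- oxygen_solubility(d$temperature_c,
                                if (sea) d$salinity_sea else d$salinity_fresh)
      airsat <- simulate_airsat_trace(
        profile, d$schedule, mass, d$respirometer_volume_l, beta,
        background_alpha = d$background_alpha,
        pre_chase_s = pre_s, chase_s = chase_s, post_chase_s = post_s,
        noise_sd = d$noise_sd_sat, dt_s = d$airsat_dt_s,
        post_schedule = d$post_schedule,
        post_short_s = d$post_short_h * 3600)
      block <- if (lig) d$av_block else NULL
      flow_true <- simulate_flow_trace(
        fh_fn, sv_fn, mass, av_block = block,
        pre_chase_s = pre_s, chase_s = chase_s, post_chase_s = post_s,
        noise_sd = 0, sampling_rate_hz = d$flow_hz)
      # probe distortion: recorded = gain_r * true + offset_r (+ noise)
      gain_r <- stats::rnorm(1, 0.92, 0.02)
      offset_r <- stats::rnorm(1, 0.5, 0.2)
      flow <- flow_true
      flow$flow_ml_min <- gain_r * flow_true$flow_ml_min + offset_r +
        (if (d$noise_sd_flow > 0)
          stats::rnorm(nrow(flow_true), 0, d$noise_sd_flow) else 0)
      cal_true <- c(1, 2, 5, 10, 20, 30, 40, 50, 60, 70)
      calibration <- tibble::tibble(
        true = cal_true,
        recorded = gain_r * cal_true + offset_r + stats::rnorm(10, 0, 0.05))
      ep <- .profile_epoc(profile, smr, d$post_chase_h)
      obs <- .observable_mmr(profile, d)

      cf <- stats::rnorm(1, 1.2, 0.08)
      mass_g <- mass * 1000
      fork <- (100 * mass_g / cf)^(1 / 3)
      vent_wet <- mass_g * stats::rnorm(1, 0.08, 0.008) / 100
      rcm <- stats::rnorm(1, c(28, 33, 28, 29)[g], 2)  # relative compact mass %
      vent_dry <- vent_wet * 0.2
      fish[[fid]] <- tibble::tibble(
        fish_id = fid,
        salinity_group = groups$salinity_group[g],
        surgery_group = groups$surgery_group[g],
        body_mass_kg = mass, body_mass_g = mass_g, fork_length_cm = fork,
        spleen_mass_g = mass_g * stats::rnorm(1, 0.15, 0.03) / 100,
        ventricle_wet_mass_g = vent_wet,
        compact_dry_mass_g = vent_dry * rcm / 100,
        spongy_dry_mass_g = vent_dry * (1 - rcm / 100),
        hb_g_l = hb, hct_pct = hct,
        osmolality_mosm = stats::rnorm(1, if (sea) 305 else 292, 5),
        na_mmol_l = stats::rnorm(1, if (sea) 162 else 152, 4),
        cl_mmol_l = stats::rnorm(1, if (sea) 138 else 128, 4),
        k_mmol_l = stats::rnorm(1, if (lig && !sea) 2.7 else 3.2, 0.25),
        ca_mmol_l = stats::rnorm(1, 1.25, 0.08),
        respirometer = fid)
      truth[[fid]] <- tibble::tibble(
        fish_id = fid,
        salinity_group = groups$salinity_group[g],
        surgery_group = groups$surgery_group[g],
        smr = smr, mmr = mmr, mmr_obs = obs$mmr_obs, tau_h = tau,
        epoc = ep$epoc, epoc_duration = ep$duration,
        recovered = ep$recovered,
        fh_rest = fh_rest, fh_max = fh_max,
        sv_rest = sv_rest, sv_max = sv_max,
        co_rest = co_rest, co_max = fh_max * sv_max,
        background_alpha = d$background_alpha,
        probe_gain = gain_r, probe_offset = offset_r,
        av_block = lig)
      traces[[fid]] <- list(airsat = airsat, flow = flow,
                            calibration = calibration)
    }
  }
  structure(list(design = d, fish = do.call(rbind, fish),
                 truth = do.call(rbind, truth), traces = traces,
                 chase = chase,
                 beta = c(fresh = oxygen_solubility(d$temperature_c,
                                                    d$salinity_fresh),
                          sea = oxygen_solubility(d$temperature_c,
                                                  d$salinity_sea))),
            class = "respicard_study")
}

#' @export
print.respicard_study <- function(x, ...) {
  cat(sprintf("Synthetic cardiorespirometry study: %d fish (%d per cell), %d traces\n",
              nrow(x$fish), x$design$n_per_group, 2 * nrow(x$fish)))
  invisible(x)
}
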