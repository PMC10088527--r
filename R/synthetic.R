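#' Post-exercise metabolic recovery profile
#'
#' Continuous oxygen-consumption profile: constant at SMR before the chase
#' (negative times) and a single-exponential decay from MMR back towards SMR
#' afterwards, optionally multiplied by an impairment dip that depresses the
#' profile below its exponential envelope for a window early in recovery
#' (the respiratory signature of post-chase atrioventricular block in
#' coronary-ligated fish).
#'
#' @param smr Standard metabolic rate, mg O2 h-1 kg-1.
#' @param mmr Maximum metabolic rate at the moment the chase ends; must be
#'   >= smr (equality gives a flat profile).
#' @param tau_h Exponential time constant of recovery, hours, > 0.
#' @param impairment Optional dip: list with `onset_h`, `plateau_h`,
#'   `recover_h`, `depth` (fraction in \[0, 1)). The profile is multiplied by
#'   `1 - depth` from onset for `plateau_h`, then returns linearly to the
#'   envelope over `recover_h`.
#' @return Function `f(t_h)` of time in hours since the chase ended
#'   (vectorised; t < 0 returns smr).
#' @export
simulate_recovery_profile <- function(smr, mmr, tau_h, impairment = NULL) {
  if (tau_h <= 0) stop("decay time constant must be positive", call. = FALSE)
  if (smr < 0 || mmr < smr) stop("need 0 <= smr <= mmr", call. = FALSE)
  if (!is.null(impairment)) {
    stopifnot(impairment$depth >= 0, impairment$depth < 1,
              impairment$onset_h >= 0)
  }
  function(t_h) {
    base <- ifelse(t_h < 0, smr, smr + (mmr - smr) * exp(-t_h / tau_h))
    if (is.null(impairment)) return(base)
    o <- impairment$onset_h
    p <- o + impairment$plateau_h
    r <- p + impairment$recover_h
    frac <- ifelse(t_h >= o & t_h < p, 1,
                   ifelse(t_h >= p & t_h < r,
                          1 - (t_h - p) / impairment$recover_h, 0))
    base * (1 - impairment$depth * frac)
  }
}

#' Simulate an intermittent-flow air-saturation trace
#'
#' Forward model of the respirometry chamber: during sealed measure phases
#' the % air saturation declines at the rate implied by inverting the
#' oxygen-consumption equation for the given metabolic profile plus
#' background respiration; during flush phases the saturation relaxes
#' exponentially back towards 100%. The fish is out of the chamber during
#' the chase window (saturation held at 100%).
#'
#' @param profile Metabolic profile function `f(t_h)` of hours since chase
#'   end (negative = pre-chase), mg O2 h-1 kg-1; see
#'   [simulate_recovery_profile()].
#' @param schedule A [cycle_schedule()].
#' @param fish_mass Body mass, kg (taken as litres of displaced water).
#' @param volume_l Total respirometer volume, litres; must exceed the mass.
#' @param beta Oxygen solubility, mg l-1 at 100% air saturation.
#' @param background_alpha Background (microbial) saturation slope magnitude
#'   in the empty chamber, % s-1.
#' @param pre_chase_s,chase_s,post_chase_s Segment durations, seconds.
#'   `pre_chase_s = chase_s = 0` gives a post-only recording.
#' @param noise_sd Gaussian optode noise, % air saturation.
#' @param dt_s Optode sampling interval, seconds.
#' @param sat_floor Warn if any measure phase ends below this saturation
#'   (the protocol adjusts cycle lengths to stay above it). Default 80.
#' @param post_schedule Schedule after the chase; shorter measure phases are
#'   typically used there because oxygen consumption is highest. Defaults to
#'   `schedule`.
#' @param post_short_s Seconds after the chase during which `post_schedule`
#'   applies before the grid reverts to `schedule` (whole cycles only).
#'   Default `Inf`.
#' @param flush_tau_s Flush re-oxygenation time constant, seconds.
#' @return Tibble `time_s`, `airsat`, with attributes `chase`
#'   (`c(start_s, end_s)` or `NULL`) and `schedule`.
#' @export
simulate_airsat_trace <- function(profile, schedule, fish_mass, volume_l,
                                  beta, background_alpha = 0,
                                  pre_chase_s = 0, chase_s = 0,
                                  post_chase_s = 3600 * 15,
                                  noise_sd = 0, dt_s = 1, sat_floor = 80,
                                  post_schedule = schedule, post_short_s = Inf,
                                  flush_tau_s = 40) {
  stopifnot(inherits(schedule, "cycle_schedule"),
            inherits(post_schedule, "cycle_schedule"))
  if (volume_l <= fish_mass) {
    stop("respirometer volume must exceed fish volume", call. = FALSE)
  }
  vn <- volume_l - fish_mass
  chase_start <- pre_chase_s
  chase_end <- pre_chase_s + chase_s
  total <- pre_chase_s + chase_s + post_chase_s
  time_s <- seq(0, total - dt_s, by = dt_s)
  sat <- numeric(length(time_s))
  # saturation slope magnitude (%/s) implied by the profile at trace time t
  slope_at <- function(t) {
    mo2 <- profile((t - chase_end) / 3600)
    (mo2 * fish_mass / 3600 / (beta / 100) + background_alpha * volume_l) / vn
  }
  run_segment <- function(origin, stop_at, cycle0, sch) {
    n_cyc <- floor((stop_at - origin) / sch$period_s)
    sat_now <- 100
    for (k in seq_len(n_cyc)) {
      c_start <- origin + (k - 1) * sch$period_s
      m_start <- c_start + sch$flush_s
      m_end <- c_start + sch$period_s
      fi <- which(time_s >= c_start & time_s < m_start)
      sat[fi] <<- 100 + (sat_now - 100) * exp(-(time_s[fi] - c_start) / flush_tau_s)
      sat_now <- 100 + (sat_now - 100) * exp(-sch$flush_s / flush_tau_s)
      mi <- which(time_s >= m_start & time_s < m_end)
      drops <- cumsum(slope_at(time_s[mi]) * dt_s)
      sat[mi] <<- sat_now - c(0, drops[-length(drops)])
      sat_now <- sat_now - drops[length(drops)]
      if (sat_now < 0) {
        stop(sprintf("profile drives saturation below 0%% in cycle %d",
                     cycle0 + k), call. = FALSE)
      }
      if (sat_now < sat_floor) {
        warning(sprintf("end-of-cycle saturation %.1f%% below floor %g%% in cycle %d",
                        sat_now, sat_floor, cycle0 + k), call. = FALSE)
      }
    }
    n_cyc
  }
  n_pre <- 0
  if (pre_chase_s > 0) n_pre <- run_segment(0, chase_start, 0L, schedule)
  if (chase_s > 0) {
    gi <- which(time_s >= chase_start & time_s < chase_end)
    sat[gi] <- 100
  }
  span_short <- min(post_short_s, total - chase_end)
  n_short <- floor(span_short / post_schedule$period_s)
  boundary <- chase_end + n_short * post_schedule$period_s
  run_segment(chase_end, boundary, n_pre, post_schedule)
  run_segment(boundary, total, n_pre + n_short, schedule)
  if (noise_sd > 0) sat <- sat + stats::rnorm(length(sat), 0, noise_sd)
  out <- tibble::tibble(time_s = time_s, airsat = sat)
  attr(out, "chase") <- if (chase_s > 0) c(chase_start, chase_end) else NULL
  attr(out, "schedule") <- schedule
  attr(out, "post_schedule") <- post_schedule
  out
}

#' Simulate a pulsatile ventral-aortic blood-flow trace
#'
#' Beat times are laid down sequentially from the instantaneous heart-rate
#' profile; each retained beat ejects its stroke volume as a half-sine pulse
#' with zero diastolic flow, and the recorded sample value is the exact
#' average flow over the sample interval (so mean flow over any window
#' equals ejected volume per unit time). During an optional AV-block window
#' every `ratio`-th conducted beat pattern degrades to dropped ventricular
#' beats: with the default 2:1 ratio every second beat is omitted, halving
#' pulse frequency while leaving per-beat stroke volume unchanged.
#'
#' @param fh_profile Heart-rate function `f(t_h)` (beats min-1) of hours
#'   since chase end (negative = pre-chase).
#' @param sv_profile Stroke-volume function `f(t_h)` (ml kg-1).
#' @param fish_mass Body mass, kg.
#' @param av_block Optional list `onset_h`, `duration_h`, `ratio` (default 2)
#'   in recovery time; must lie within the post-chase span.
#' @param pre_chase_s,chase_s,post_chase_s Segment durations, seconds.
#' @param noise_sd Gaussian sensor noise, ml min-1.
#' @param sampling_rate_hz Sampling rate; must be at least 4x the maximum
#'   heart rate expressed in Hz.
#' @param systole_frac Fraction of the beat period occupied by ejection.
#' @return Tibble `time_s`, `flow_ml_min` with attributes `beat_times_s`
#'   (retained beats), `dropped_beats_s`, `chase`.
#' @export
simulate_flow_trace <- function(fh_profile, sv_profile, fish_mass,
                                av_block = NULL,
                                pre_chase_s = 0, chase_s = 0,
                                post_chase_s = 3600, noise_sd = 0,
                                sampling_rate_hz = 10, systole_frac = 0.5) {
  chase_end <- pre_chase_s + chase_s
  total <- pre_chase_s + chase_s + post_chase_s
  rec_h <- function(t) (t - chase_end) / 3600
  # lay down beats sequentially from the instantaneous rate
  beats <- numeric(ceiling(total / (60 / 200)) + 2)
  nb <- 0L
  t <- 0
  max_fh <- 0
  while (t < total) {
    fh <- fh_profile(rec_h(t))
    if (!is.finite(fh) || fh <= 0) stop("heart-rate profile must be positive",
                                        call. = FALSE)
    max_fh <- max(max_fh, fh)
    nb <- nb + 1L
    if (nb > length(beats)) beats <- c(beats, numeric(length(beats)))
    beats[nb] <- t
    t <- t + 60 / fh
  }
  beats <- beats[seq_len(nb)]
  if (sampling_rate_hz < 4 * max_fh / 60) {
    stop("sampling rate must be at least 4x the maximum heart rate",
         call. = FALSE)
  }
  dropped <- rep(FALSE, nb)
  if (!is.null(av_block)) {
    ratio <- if (is.null(av_block$ratio)) 2L else av_block$ratio
    w0 <- chase_end + av_block$onset_h * 3600
    w1 <- w0 + av_block$duration_h * 3600
    if (w0 < 0 || w1 > total) stop("AV-block window outside trace span",
                                   call. = FALSE)
    inw <- which(beats >= w0 & beats < w1)
    dropped[inw[seq_along(inw) %% ratio == 0]] <- TRUE
  }
  kept <- beats[!dropped]
  fh_at_beat <- vapply(kept, function(b) fh_profile(rec_h(b)), numeric(1))
  vs <- vapply(kept, function(b) sv_profile(rec_h(b)), numeric(1)) * fish_mass
  if (any(vs <= 0)) stop("stroke-volume profile must be positive", call. = FALSE)
  eject <- systole_frac * 60 / fh_at_beat
  # cumulative ejected volume at the sample-grid edges; sample value is the
  # exact mean flow over each sample interval
  dt <- 1 / sampling_rate_hz
  edges <- seq(0, total, by = dt)
  idx <- findInterval(edges, kept)
  cum_vs <- c(0, cumsum(vs))
  phase <- edges - c(0, kept)[idx + 1L]
  partial <- ifelse(idx == 0, 0,
                    vs[pmax(idx, 1L)] / 2 *
                      (1 - cos(pi * pmin(phase, eject[pmax(idx, 1L)]) /
                                 eject[pmax(idx, 1L)])))
  vcum <- cum_vs[idx + 1L] - ifelse(idx == 0, 0, vs[pmax(idx, 1L)]) + partial
  flow <- diff(vcum) / dt * 60  # ml min-1
  time_s <- edges[-length(edges)]
  if (noise_sd > 0) flow <- flow + stats::rnorm(length(flow), 0, noise_sd)
  out <- tibble::tibble(time_s = time_s, flow_ml_min = flow)
  attr(out, "beat_times_s") <- kept
  attr(out, "dropped_beats_s") <- beats[dropped]
  attr(out, "chase") <- if (chase_s > 0) c(pre_chase_s, chase_end) else NULL
  out
}
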