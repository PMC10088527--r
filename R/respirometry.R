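#' @importFrom stats sd setNames quantile
#' @importFrom tibble tibble as_tibble
NULL

#' Flush/measure cycle schedule
#'
#' @param flush_s Flush-phase duration in seconds (re-oxygenation, inflow on).
#' @param measure_s Measure-phase duration in seconds (chamber sealed).
#' @return A `cycle_schedule` list.
#' @export
cycle_schedule <- function(flush_s = 240, measure_s = 360) {
  if (!is.numeric(flush_s) || !is.numeric(measure_s) ||
      flush_s <= 0 || measure_s <= 0) {
    stop("schedule phases must be positive", call. = FALSE)
  }
  structure(list(flush_s = flush_s, measure_s = measure_s,
                 period_s = flush_s + measure_s),
            class = "cycle_schedule")
}

#' Segment an air-saturation trace into measure cycles
#'
#' Assigns every sample of an intermittent-flow recording to a flush or
#' measure phase of the repeating cycle grid, labels cycles as pre- or
#' post-chase, and drops (with a logged reason) any cycle that straddles the
#' chase window, during which the fish is out of the respirometer.
#'
#' Each cycle starts with its flush phase. The cycle grid restarts at the end
#' of the chase window, so the first post-chase cycle begins with a flush as
#' the chamber is re-closed.
#'
#' @param trace Data frame with columns `time_s` and `airsat` (% air
#'   saturation), times strictly increasing, seconds from recording start.
#' @param schedule A [cycle_schedule()].
#' @param chase Optional numeric length-2 vector `c(start_s, end_s)` marking
#'   the chase (fish removed). Cycles overlapping it are excluded.
#' @param post_schedule Schedule used after the chase; the protocol typically
#'   runs shorter cycles just after exercise, when oxygen consumption is
#'   highest, to keep end-of-cycle saturation high. Defaults to `schedule`.
#' @param post_short_s Seconds after the chase during which `post_schedule`
#'   applies; beyond it the grid reverts to `schedule` (shallow late-recovery
#'   slopes need the longer sealed phase to pass the R^2 filter). The
#'   boundary snaps to a whole number of post cycles. Default `Inf`.
#' @return Tibble with one row per retained cycle: `cycle`, `phase`
#'   (`"pre_chase"`/`"post_chase"`), `start_s`, `end_s` (measure-phase
#'   window) and a list-column `samples` of (time_s, airsat) within the
#'   measure phase. The attribute `"excluded"` records dropped cycles with a
#'   reason.
#' @export
segment_cycles <- function(trace, schedule, chase = NULL,
                           post_schedule = schedule, post_short_s = Inf) {
  stopifnot(inherits(schedule, "cycle_schedule"),
            inherits(post_schedule, "cycle_schedule"))
  if (!all(c("time_s", "airsat") %in% names(trace))) {
    stop("trace must have columns time_s and airsat", call. = FALSE)
  }
  if (nrow(trace) == 0) {
    out <- tibble(cycle = integer(), phase = character(),
                  start_s = numeric(), end_s = numeric(), samples = list())
    attr(out, "excluded") <- tibble(cycle = integer(), reason = character())
    return(out)
  }
  if (is.unsorted(trace$time_s, strictly = TRUE)) {
    stop("trace times must be strictly increasing", call. = FALSE)
  }
  t0 <- trace$time_s[1]
  # the span covered by the recording extends one sample interval past the
  # final timestamp; without it the last cycle of a trace is lost
  dt_med <- if (nrow(trace) > 1) stats::median(diff(trace$time_s)) else 0
  t_end <- trace$time_s[nrow(trace)] + dt_med

  grid_windows <- function(origin, stop_at, phase, cycle_offset, sch) {
    n <- max(0L, floor((stop_at - origin) / sch$period_s))
    if (n == 0L) return(NULL)
    starts <- origin + (seq_len(n) - 1L) * sch$period_s + sch$flush_s
    tibble(cycle = cycle_offset + seq_len(n), phase = phase,
           start_s = starts, end_s = starts + sch$measure_s)
  }

  if (is.null(chase)) {
    win <- grid_windows(t0, t_end, "pre_chase", 0L, schedule)
    excl <- tibble(cycle = integer(), reason = character())
  } else {
    stopifnot(length(chase) == 2, chase[2] > chase[1])
    pre <- grid_windows(t0, chase[1], "pre_chase", 0L, schedule)
    # a pre-grid cycle whose measure window would cross into the chase is
    # excluded rather than truncated: no measurement during transfer
    n_pre_full <- floor((chase[1] - t0) / schedule$period_s)
    straddle_start <- t0 + n_pre_full * schedule$period_s
    excl <- if (straddle_start + schedule$flush_s < chase[1]) {
      tibble(cycle = n_pre_full + 1L, reason = "straddles_chase")
    } else {
      tibble(cycle = integer(), reason = character())
    }
    off <- (if (is.null(pre)) 0L else max(pre$cycle)) + nrow(excl)
    span_short <- min(post_short_s, t_end - chase[2])
    n_short <- floor(span_short / post_schedule$period_s)
    boundary <- chase[2] + n_short * post_schedule$period_s
    post_a <- grid_windows(chase[2], boundary, "post_chase", off,
                           post_schedule)
    post_b <- grid_windows(boundary, t_end, "post_chase", off + n_short,
                           schedule)
    win <- rbind(pre, post_a, post_b)
  }
  if (is.null(win) || nrow(win) == 0) {
    out <- tibble(cycle = integer(), phase = character(),
                  start_s = numeric(), end_s = numeric(), samples = list())
    attr(out, "excluded") <- excl
    return(out)
  }
  win$samples <- lapply(seq_len(nrow(win)), function(i) {
    sel <- trace$time_s >= win$start_s[i] & trace$time_s < win$end_s[i]
    trace[sel, c("time_s", "airsat")]
  })
  keep <- vapply(win$samples, nrow, integer(1)) > 0
  if (any(!keep)) {
    gap <- tibble(cycle = win$cycle[!keep], reason = "no_samples")
    excl <- rbind(excl, gap)
    if (sum(!keep) > 1) {
      warning("trace has gaps spanning more than one cycle", call. = FALSE)
    }
  }
  out <- win[keep, ]
  attr(out, "excluded") <- excl
  out
}

# closed-form OLS slope and R^2; much faster than lm() in tight loops
.slope_r2 <- function(t, y) {
  n <- length(t)
  tc <- t - mean(t)
  yc <- y - mean(y)
  sxx <- sum(tc^2)
  sxy <- sum(tc * yc)
  syy <- sum(yc^2)
  slope <- sxy / sxx
  r2 <- if (syy <= 0) NA_real_ else (sxy^2) / (sxx * syy)
  list(slope = slope, r2 = r2, n = n)
}

#' Fit the air-saturation decline slope of one measure cycle
#'
#' Ordinary least-squares slope of % air saturation against time (in % per
#' second) after discarding the head of the measure phase, where mixing makes
#' the decline non-linear.
#'
#' @param cycle One row of the output of [segment_cycles()] (or a list with
#'   `samples`, `cycle`, `start_s`, `end_s`, `phase`).
#' @param head_exclusion_s Seconds trimmed from the start of the measure
#'   phase; must lie in \[30, 60\]. Default 45.
#' @return A `slope_fit` tibble row: `cycle`, `phase`, `time_s` (midpoint of
#'   the fitted window), `alpha` (slope, % s-1, typically negative), `r2`,
#'   `n_points`, `excluded_head_s`, `accepted` (NA until filtered), `reason`.
#' @export
fit_slope <- function(cycle, head_exclusion_s = 45) {
  if (head_exclusion_s < 30 || head_exclusion_s > 60) {
    stop("head_exclusion_s must be within [30, 60] seconds", call. = FALSE)
  }
  cyc_id <- cycle$cycle
  cyc_phase <- cycle$phase
  s <- if (is.data.frame(cycle$samples[[1]])) cycle$samples[[1]] else cycle$samples
  keep <- s$time_s >= cycle$start_s + head_exclusion_s
  s <- s[keep, ]
  row <- function(time_s, alpha, r2, accepted, reason) {
    tibble::new_tibble(list(
      cycle = cyc_id, phase = cyc_phase, time_s = time_s, alpha = alpha,
      r2 = r2, n_points = nrow(s), excluded_head_s = head_exclusion_s,
      accepted = accepted, reason = reason), nrow = 1L)
  }
  if (nrow(s) < 10) {
    return(row(NA_real_, NA_real_, NA_real_, FALSE, "too_few_samples"))
  }
  f <- .slope_r2(s$time_s, s$airsat)
  row((min(s$time_s) + max(s$time_s)) / 2, f$slope, f$r2, NA, NA_character_)
}

#' Accept or reject slope fits on goodness of fit
#'
#' A slope is accepted only when its coefficient of determination strictly
#' exceeds `r2_min`; a fit at exactly the threshold is rejected. Rejected
#' fits are retained, flagged with a reason, so that the audit identity
#' (cycles = accepted + rejected) always holds.
#'
#' @param fits Tibble of [fit_slope()] rows.
#' @param r2_min Acceptance threshold on R^2 (strict `>`). Default 0.90.
#' @return The same tibble with `accepted` and `reason` filled in.
#' @export
filter_slopes <- function(fits, r2_min = 0.90) {
  undecided <- is.na(fits$accepted)
  ok <- undecided & !is.na(fits$r2) & fits$r2 > r2_min
  fits$accepted[undecided] <- ok[undecided]
  bad <- undecided & !ok
  fits$reason[bad] <- ifelse(is.na(fits$r2[bad]), "r2_undefined", "low_r2")
  if (!any(fits$accepted)) {
    warning("no slope passed the R^2 filter", call. = FALSE)
  }
  fits
}

#' Background respiration schedule
#'
#' Builds the background slope alpha_b(t) applied when correcting fish
#' slopes for microbial respiration. The measurement protocol records the
#' background at the end of each experimental series, so the default mode
#' applies that end-point value as a constant; a linear ramp from an assumed
#' zero (or measured) start value is available but off by default.
#'
#' @param alpha_b_end Background slope magnitude (% s-1, >= 0) measured in
#'   the empty respirometer at the end of the series.
#' @param mode `"constant"` (default) or `"ramp"`.
#' @param alpha_b_start Start-of-series background used by the ramp mode.
#' @param t_start,t_end Recording span (s) over which the ramp runs.
#' @return A function alpha_b(t) returning the background magnitude (% s-1).
#' @export
background_schedule <- function(alpha_b_end, mode = c("constant", "ramp"),
                                alpha_b_start = 0, t_start = 0, t_end = 1) {
  mode <- match.arg(mode)
  alpha_b_end <- abs(alpha_b_end)
  if (mode == "constant") {
    function(t) rep(alpha_b_end, length(t))
  } else {
    alpha_b_start <- abs(alpha_b_start)
    function(t) {
      frac <- pmin(1, pmax(0, (t - t_start) / (t_end - t_start)))
      alpha_b_start + frac * (alpha_b_end - alpha_b_start)
    }
  }
}

#' Oxygen consumption rate from a fitted slope
#'
#' Background-corrected mass-specific oxygen consumption:
#' \deqn{\dot{M}_{O_2} = (|\alpha_a| V_n - |\alpha_b| V_t)\,
#'   \frac{\beta}{100} \cdot \frac{3600}{m}}
#' where alpha_a is the fish-run saturation slope (% s-1), alpha_b the
#' background slope from the empty respirometer, beta the oxygen solubility
#' at 100% air saturation (mg l-1), V_t the total respirometer volume (l),
#' V_n = V_t - body mass the net volume (body mass in kg taken as litres of
#' displaced water) and m the body mass (kg). Result in mg O2 h-1 kg-1.
#'
#' A correction larger than the fish signal yields a negative value, which is
#' flagged (`mo2_negative`) rather than clipped.
#'
#' @param fit A [fit_slope()] row (uses `alpha`, `time_s`, `phase`).
#' @param background_alpha Background slope magnitude (% s-1) at this cycle.
#' @param beta Oxygen solubility, mg O2 l-1 at 100% air saturation.
#' @param vt Total respirometer volume, litres.
#' @param body_mass Fish body mass, kg. Must be less than `vt`.
#' @return Tibble row: `time_s`, `mo2`, `phase`, `flag`.
#' @export
compute_mo2 <- function(fit, background_alpha, beta, vt, body_mass) {
  if (vt <= body_mass) stop("respirometer volume must exceed body mass",
                            call. = FALSE)
  vn <- vt - body_mass
  mo2 <- (abs(fit$alpha) * vn - abs(background_alpha) * vt) *
    beta / 100 * 3600 / body_mass
  tibble::new_tibble(list(
    time_s = fit$time_s, mo2 = mo2, phase = fit$phase,
    flag = if (mo2 < 0) "mo2_negative" else NA_character_), nrow = 1L)
}

#' Air-saturation trace to quality-filtered oxygen-consumption series
#'
#' Full respirometry path: segment the trace into measure cycles, fit and
#' filter saturation slopes, and convert accepted slopes to mass-specific
#' oxygen consumption with background correction.
#'
#' @inheritParams segment_cycles
#' @inheritParams fit_slope
#' @inheritParams filter_slopes
#' @param background A [background_schedule()] function, or a single numeric
#'   background slope magnitude (% s-1).
#' @param beta Oxygen solubility (mg l-1); computed from `temperature_c` and
#'   `salinity_ppt` when `NULL`.
#' @param temperature_c,salinity_ppt Used to compute `beta` when not given.
#' @param vt Respirometer volume (l).
#' @param body_mass Body mass (kg).
#' @return An `mo2_series` tibble: `cycle`, `time_s`, `mo2`, `phase`,
#'   `accepted`, `reason`, `flag`, with the excluded-cycle audit attached as
#'   attribute `"excluded"`.
#' @export
mo2_series <- function(trace, schedule, body_mass, vt,
                       background = 0, beta = NULL,
                       temperature_c = 10, salinity_ppt = 0,
                       chase = NULL, post_schedule = schedule,
                       post_short_s = Inf,
                       head_exclusion_s = 45, r2_min = 0.90) {
  if (is.null(beta)) beta <- oxygen_solubility(temperature_c, salinity_ppt)
  if (is.numeric(background)) background <- background_schedule(background)
  cyc <- segment_cycles(trace, schedule, chase = chase,
                        post_schedule = post_schedule,
                        post_short_s = post_short_s)
  fits <- do.call(rbind, lapply(seq_len(nrow(cyc)), function(i) {
    fit_slope(cyc[i, ], head_exclusion_s = head_exclusion_s)
  }))
  if (is.null(fits)) {
    out <- tibble(cycle = integer(), time_s = numeric(), mo2 = numeric(),
                  phase = character(), accepted = logical(),
                  reason = character(), flag = character())
    attr(out, "excluded") <- attr(cyc, "excluded")
    class(out) <- c("mo2_series", class(out))
    return(out)
  }
  fits <- filter_slopes(fits, r2_min = r2_min)
  mo2 <- rep(NA_real_, nrow(fits))
  flag <- rep(NA_character_, nrow(fits))
  acc <- which(fits$accepted)
  for (i in acc) {
    m <- compute_mo2(fits[i, ], background(fits$time_s[i]), beta, vt, body_mass)
    mo2[i] <- m$mo2
    flag[i] <- m$flag
  }
  out <- tibble(cycle = fits$cycle, time_s = fits$time_s, mo2 = mo2,
                phase = fits$phase, accepted = fits$accepted,
                reason = fits$reason, flag = flag)
  attr(out, "excluded") <- attr(cyc, "excluded")
  class(out) <- c("mo2_series", class(out))
  out
}
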