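#' Gravimetric flow-probe calibration
#'
#' Least-squares linear map from recorded to true flow, fitted from bench
#' calibration points in which known (gravimetrically determined) flow rates
#' are pumped through the probe. The returned correction is applied to in
#' vivo traces before cardiac output is computed.
#'
#' @param true_flow True flow rates, ml min-1 (typically spanning 1-70).
#' @param recorded_flow Flow recorded by the probe at each true rate.
#' @return A `probe_calibration` list: `gain`, `offset` (true = gain x
#'   recorded + offset), `r2`, `points`, and `correct`, a vectorised function
#'   applying the map.
#' @export
calibrate_probe <- function(true_flow, recorded_flow) {
  stopifnot(length(true_flow) == length(recorded_flow))
  if (length(true_flow) < 2 || length(unique(recorded_flow)) < 2) {
    stop("need at least 2 distinct calibration points", call. = FALSE)
  }
  f <- .slope_r2(recorded_flow, true_flow)
  gain <- f$slope
  if (!is.finite(gain) || gain <= 0) {
    stop("degenerate calibration: non-positive gain", call. = FALSE)
  }
  offset <- mean(true_flow) - gain * mean(recorded_flow)
  structure(list(
    gain = gain, offset = offset,
    r2 = if (is.na(f$r2)) 1 else f$r2,
    points = tibble::tibble(true = true_flow, recorded = recorded_flow),
    correct = function(x) gain * x + offset
  ), class = "probe_calibration")
}

#' Detect heart beats in a pulsatile flow trace window
#'
#' Peaks are systolic ejection maxima found with a minimum inter-peak
#' distance of half the expected shortest beat period and a prominence floor
#' of 25% of the window amplitude, which rejects dicrotic and noise peaks
#' while preserving the long diastolic gaps of dropped (AV-blocked) beats.
#' Heart rate is the pulse frequency over the window:
#' `(n_beats - 1) / (t_last - t_first) * 60`.
#'
#' @param time_s Sample times (s).
#' @param flow Instantaneous flow (ml min-1), same length.
#' @param expected_max_fh Upper bound on heart rate (beats min-1) used to set
#'   the minimum inter-peak distance. Default 120.
#' @param prominence_frac Peak height floor as a fraction of the window
#'   amplitude. Default 0.25.
#' @return List: `beat_times_s`, `n_beats`, `fh` (beats min-1, `NA` and
#'   `flag = "too_few_beats"` when fewer than 2 beats are found).
#' @export
detect_beats <- function(time_s, flow, expected_max_fh = 120,
                         prominence_frac = 0.25) {
  stopifnot(length(time_s) == length(flow))
  n <- length(flow)
  flagged <- list(beat_times_s = numeric(), n_beats = 0L, fh = NA_real_,
                  flag = "too_few_beats")
  if (n < 3) return(flagged)
  amp <- max(flow) - min(flow)
  if (amp <= 0) return(flagged)
  dt <- stats::median(diff(time_s))
  min_dist_s <- 0.5 * 60 / expected_max_fh
  # zero = "+" keeps flat-topped peaks, which bin-averaged pulses produce
  # whenever the beat period is commensurate with the sampling grid
  pk <- pracma::findpeaks(flow, zero = "+",
                          minpeakheight = min(flow) + prominence_frac * amp,
                          minpeakdistance = max(1L, round(min_dist_s / dt)))
  if (is.null(pk) || nrow(pk) < 2) return(flagged)
  bt <- sort(time_s[pk[, 2]])
  list(beat_times_s = bt, n_beats = length(bt),
       fh = (length(bt) - 1) / (bt[length(bt)] - bt[1]) * 60,
       flag = NA_character_)
}

#' Cardiac variables over one respirometry measure window
#'
#' Cardiac output is the calibrated mean flow over the window divided by
#' body mass; heart rate comes from beat detection; stroke volume is CO/fH.
#' When heart rate cannot be determined the sample keeps its CO with
#' `sv = NA` and a flag.
#'
#' @param flow_trace Data frame with `time_s`, `flow_ml_min`.
#' @param window Numeric `c(start_s, end_s)`.
#' @param calibration A [calibrate_probe()] object, or `NULL` for identity.
#' @param body_mass Body mass, kg.
#' @param ... Passed to [detect_beats()].
#' @return One-row tibble: `start_s`, `end_s`, `co` (ml min-1 kg-1), `fh`
#'   (beats min-1), `sv` (ml kg-1), `n_beats`, `flag`.
#' @export
cardiac_during_cycle <- function(flow_trace, window, calibration = NULL,
                                 body_mass = 1, ...) {
  sel <- flow_trace$time_s >= window[1] & flow_trace$time_s < window[2]
  if (!any(sel)) stop(sprintf("window [%g, %g] does not overlap flow trace",
                              window[1], window[2]), call. = FALSE)
  t <- flow_trace$time_s[sel]
  f <- flow_trace$flow_ml_min[sel]
  if (!is.null(calibration)) f <- calibration$correct(f)
  co <- mean(f) / body_mass
  b <- detect_beats(t, f, ...)
  sv <- if (is.na(b$fh)) NA_real_ else co / b$fh
  tibble::tibble(start_s = window[1], end_s = window[2], co = co, fh = b$fh,
                 sv = sv, n_beats = b$n_beats, flag = b$flag)
}

#' Resting, maximum and scope of cardiac variables
#'
#' Resting values are the means of cardiac samples co-timed with the
#' SMR-defining respirometry cycles; maximum values are taken from the single
#' cardiac sample co-timed with the MMR cycle; scope is maximum minus resting
#' and may legitimately be negative (post-chase heart rate can fall below the
#' resting rate, e.g. in seawater-acclimated fish).
#'
#' @param samples Tibble of [cardiac_during_cycle()] rows with a `cycle`
#'   column.
#' @param smr_cycles Integer cycle ids that defined SMR.
#' @param mmr_cycle Integer cycle id of the MMR measurement.
#' @return One-row tibble with `co_rest`, `co_max`, `co_scope`, `fh_rest`,
#'   `fh_max`, `fh_scope`, `sv_rest`, `sv_max`, `sv_scope`.
#' @export
summarize_cardiac <- function(samples, smr_cycles, mmr_cycle) {
  missing_cycles <- setdiff(c(smr_cycles, mmr_cycle), samples$cycle)
  if (length(missing_cycles) > 0) {
    stop("no cardiac sample co-timed with cycle(s) ",
         paste(missing_cycles, collapse = ", "), call. = FALSE)
  }
  rest <- samples[samples$cycle %in% smr_cycles, ]
  mx <- samples[samples$cycle == mmr_cycle, ]
  tibble::tibble(
    co_rest = mean(rest$co, na.rm = TRUE), co_max = mx$co[1],
    co_scope = mx$co[1] - mean(rest$co, na.rm = TRUE),
    fh_rest = mean(rest$fh, na.rm = TRUE), fh_max = mx$fh[1],
    fh_scope = mx$fh[1] - mean(rest$fh, na.rm = TRUE),
    sv_rest = mean(rest$sv, na.rm = TRUE), sv_max = mx$sv[1],
    sv_scope = mx$sv[1] - mean(rest$sv, na.rm = TRUE))
}

#' Extract values on the post-exercise time grid
#'
#' For each target time after the chase, returns the temporally closest
#' available sample, recording the offset actually used; targets with no
#' sample within `max_distance_min` yield `NA` with a warning.
#'
#' @param time_min Sample times, minutes since the chase.
#' @param value Sample values.
#' @param grid_min Target grid, minutes. Default
#'   `c(0, 10, 20, 30, 60, 120, 300, 600, 900)`.
#' @param max_distance_min Maximum tolerated distance, default 30 min.
#' @return Tibble: `target_min`, `value`, `actual_min`, `offset_min`.
#' @export
timecourse_extract <- function(time_min, value,
                               grid_min = c(0, 10, 20, 30, 60, 120,
                                            300, 600, 900),
                               max_distance_min = 30) {
  stopifnot(length(time_min) == length(value))
  out <- lapply(grid_min, function(g) {
    if (length(time_min) == 0) {
      return(tibble::tibble(target_min = g, value = NA_real_,
                            actual_min = NA_real_, offset_min = NA_real_))
    }
    d <- abs(time_min - g)
    i <- which.min(d)
    if (d[i] > max_distance_min) {
      warning(sprintf("no sample within %g min of target %g min",
                      max_distance_min, g), call. = FALSE)
      return(tibble::tibble(target_min = g, value = NA_real_,
                            actual_min = NA_real_, offset_min = NA_real_))
    }
    tibble::tibble(target_min = g, value = value[i], actual_min = time_min[i],
                   offset_min = time_min[i] - g)
  })
  do.call(rbind, out)
}
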