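#' Standard metabolic rate from the lowest quantile of pre-chase samples
#'
#' SMR is the mean of the lowest 20% of accepted pre-chase oxygen-consumption
#' samples after a one-pass outlier screen: within that lowest-20% subset,
#' values outside the subset mean +/- 2 s.d. are removed before averaging.
#' The subset size is `ceiling(q * n)` so at least one sample always remains.
#'
#' @param mo2 Numeric vector of accepted pre-chase MO2 samples
#'   (mg O2 h-1 kg-1), or an `mo2_series` tibble (accepted pre-chase rows are
#'   used).
#' @param q Lowest-quantile fraction, default 0.2.
#' @param outlier_sd Outlier screen half-width in subset standard deviations,
#'   default 2. `Inf` disables the screen.
#' @param outlier_scope Whether the mean/s.d. of the screen come from the
#'   lowest-quantile `"subset"` (default) or the `"full"` pre-chase series.
#' @return List with `smr` and `n_smr_samples` (samples retained in the
#'   mean), plus `idx` giving their positions in the input vector.
#' @export
estimate_smr <- function(mo2, q = 0.2, outlier_sd = 2,
                         outlier_scope = c("subset", "full")) {
  outlier_scope <- match.arg(outlier_scope)
  if (is.data.frame(mo2)) {
    mo2 <- mo2$mo2[mo2$phase == "pre_chase" & mo2$accepted %in% TRUE]
  }
  mo2 <- mo2[!is.na(mo2)]
  n <- length(mo2)
  if (n < 10) stop("need at least 10 accepted pre-chase samples", call. = FALSE)
  k <- ceiling(q * n)
  ord <- order(mo2)
  idx <- ord[seq_len(k)]
  subset <- mo2[idx]
  ref <- if (outlier_scope == "subset") subset else mo2
  ctr <- mean(ref)
  s <- stats::sd(ref)
  keep <- if (!is.finite(s) || s == 0) rep(TRUE, k) else
    abs(subset - ctr) <= outlier_sd * s
  if (!any(keep)) stop("all lowest-quantile samples excluded as outliers",
                       call. = FALSE)
  list(smr = mean(subset[keep]), n_smr_samples = sum(keep), idx = idx[keep])
}

#' Maximum metabolic rate: highest post-chase sample
#'
#' MMR is the single highest accepted oxygen-consumption measurement after
#' exhaustive exercise. Ties are broken to the earliest timestamp so that
#' maximum cardiac variables align with the first physiological peak.
#'
#' @param series An `mo2_series` tibble (or any data frame with `time_s`,
#'   `mo2`, `phase`, `accepted`).
#' @return List with `mmr`, its `time_s`, and `cycle` (if present).
#' @export
estimate_mmr <- function(series) {
  post <- series[series$phase == "post_chase" & series$accepted %in% TRUE &
                   !is.na(series$mo2), , drop = FALSE]
  if (nrow(post) == 0) stop("no accepted post-chase samples", call. = FALSE)
  post <- post[order(post$time_s), ]
  i <- which.max(post$mo2)  # which.max returns the first maximum: earliest tie
  list(mmr = post$mo2[i], time_s = post$time_s[i],
       cycle = if ("cycle" %in% names(post)) post$cycle[i] else NA_integer_)
}

#' Suppress spontaneous-activity spikes in a recovery series
#'
#' Forward scan: when a sample exceeds the running held value by at least
#' `threshold` (5% by default), it is replaced by the held value, and
#' replacement continues until a raw sample returns to within `threshold`
#' above the held value. Only upward excursions are touched; the rule never
#' increases a sample, and applying it twice equals applying it once.
#'
#' Fish whose early recovery is genuinely depressed (for example by
#' post-chase bradycardia in coronary-ligated animals) would have real
#' rebounds clipped, so an initial window after the chase can be passed
#' through unsmoothed via `unsmoothed_head_h`.
#'
#' @param mo2 Numeric vector of post-chase MO2 samples in time order.
#' @param time_h Optional sample times in hours since the chase; required
#'   when `unsmoothed_head_h > 0`.
#' @param threshold Fractional increase that defines a spike, default 0.05.
#' @param unsmoothed_head_h Hours after the chase left untouched, default 0.
#' @return Numeric vector of smoothed samples.
#' @export
smooth_activity <- function(mo2, time_h = NULL, threshold = 0.05,
                            unsmoothed_head_h = 0) {
  n <- length(mo2)
  if (n <= 1) return(mo2)
  start <- 2L
  if (unsmoothed_head_h > 0) {
    if (is.null(time_h)) stop("time_h required when unsmoothed_head_h > 0",
                              call. = FALSE)
    inside <- which(time_h >= unsmoothed_head_h)
    if (length(inside) == 0) return(mo2)
    start <- max(2L, inside[1])
  }
  out <- mo2
  held <- NA_real_
  in_spike <- FALSE
  for (i in start:n) {
    if (!in_spike) {
      if (out[i] >= (1 + threshold) * out[i - 1]) {
        held <- out[i - 1]
        out[i] <- held
        in_spike <- TRUE
      }
    } else {
      if (mo2[i] > (1 + threshold) * held) {
        out[i] <- held
      } else {
        in_spike <- FALSE  # back within threshold of the held value
      }
    }
  }
  out
}

#' Excess post-exercise oxygen consumption
#'
#' EPOC is the trapezoidal integral of the (smoothed) post-chase
#' oxygen-consumption series above the recovery threshold SMR x (1 + margin),
#' from the chase until recovery. Recovery time is the first moment a sample
#' reaches the threshold, linearly interpolated between the straddling
#' samples; a fish that never reaches it is flagged `recovered = FALSE` and
#' its EPOC fields are `NA` (it is excluded from EPOC summaries, not imputed).
#'
#' The short gap between the chase and the first accepted cycle is filled by
#' carrying the first sample value back to time zero.
#'
#' @param mo2 Numeric vector of post-chase (smoothed) MO2 samples.
#' @param time_h Sample times, hours since the chase, increasing.
#' @param smr Standard metabolic rate (mg O2 h-1 kg-1), > 0.
#' @param recovery_margin Fractional margin above SMR defining recovery,
#'   default 0.10.
#' @return List: `epoc` (mg O2 kg-1), `epoc_duration` (h), `epoc_rate`
#'   (mg O2 kg-1 h-1), `recovered`, `threshold`.
#' @export
compute_epoc <- function(mo2, time_h, smr, recovery_margin = 0.10) {
  stopifnot(length(mo2) == length(time_h), smr > 0)
  ok <- !is.na(mo2) & !is.na(time_h)
  mo2 <- mo2[ok]; time_h <- time_h[ok]
  if (length(mo2) == 0) stop("post-chase series is empty", call. = FALSE)
  thr <- (1 + recovery_margin) * smr
  # carry the first sample back to the chase itself
  if (time_h[1] > 0) {
    mo2 <- c(mo2[1], mo2)
    time_h <- c(0, time_h)
  }
  below <- mo2 <= thr
  if (below[1]) {
    return(list(epoc = 0, epoc_duration = 0, epoc_rate = NA_real_,
                recovered = TRUE, threshold = thr))
  }
  if (!any(below)) {
    return(list(epoc = NA_real_, epoc_duration = NA_real_,
                epoc_rate = NA_real_, recovered = FALSE, threshold = thr))
  }
  j <- which(below)[1]                      # first sample at/below threshold
  frac <- (mo2[j - 1] - thr) / (mo2[j - 1] - mo2[j])
  t_rec <- time_h[j - 1] + frac * (time_h[j] - time_h[j - 1])
  tt <- c(time_h[seq_len(j - 1)], t_rec)
  yy <- c(mo2[seq_len(j - 1)], thr) - thr
  epoc <- pracma::trapz(tt, pmax(yy, 0))
  list(epoc = epoc, epoc_duration = t_rec,
       epoc_rate = if (t_rec > 0) epoc / t_rec else NA_real_,
       recovered = TRUE, threshold = thr)
}

#' Derive the full metabolic phenotype of one fish
#'
#' Combines [estimate_smr()], [estimate_mmr()], [smooth_activity()] and
#' [compute_epoc()] on an `mo2_series`, returning SMR, MMR, aerobic scope
#' (MMR - SMR) and the EPOC triplet.
#'
#' @param series An `mo2_series` tibble.
#' @param chase_end_s Recording time (s) at which post-chase recovery starts.
#' @param ligated Logical; when `TRUE` the first `unsmoothed_head_h` hours
#'   after the chase are not smoothed (impaired early recovery is real signal
#'   in coronary-ligated fish, not spontaneous activity).
#' @param smooth_threshold Spike threshold for [smooth_activity()].
#' @param recovery_margin Margin for [compute_epoc()].
#' @param unsmoothed_head_h Unsmoothed head applied to ligated fish, hours.
#' @return A one-row `metabolic_phenotype` tibble.
#' @export
metabolic_phenotype <- function(series, chase_end_s, ligated = FALSE,
                                smooth_threshold = 0.05,
                                recovery_margin = 0.10,
                                unsmoothed_head_h = 2) {
  pre <- series[series$phase == "pre_chase" & series$accepted %in% TRUE &
                  !is.na(series$mo2), ]
  smr_fit <- estimate_smr(pre$mo2)
  mmr_fit <- estimate_mmr(series)
  post <- series[series$phase == "post_chase" & series$accepted %in% TRUE &
                   !is.na(series$mo2), ]
  post <- post[order(post$time_s), ]
  t_h <- (post$time_s - chase_end_s) / 3600
  sm <- smooth_activity(post$mo2, time_h = t_h, threshold = smooth_threshold,
                        unsmoothed_head_h = if (ligated) unsmoothed_head_h else 0)
  ep <- compute_epoc(sm, t_h, smr_fit$smr, recovery_margin = recovery_margin)
  out <- tibble::tibble(
    smr = smr_fit$smr, mmr = mmr_fit$mmr,
    aerobic_scope = mmr_fit$mmr - smr_fit$smr,
    epoc = ep$epoc, epoc_duration = ep$epoc_duration,
    epoc_rate = ep$epoc_rate, recovered = ep$recovered,
    n_smr_samples = smr_fit$n_smr_samples,
    mmr_time_s = mmr_fit$time_s, mmr_cycle = mmr_fit$cycle)
  attr(out, "smr_cycles") <- pre$cycle[smr_fit$idx]
  class(out) <- c("metabolic_phenotype", class(out))
  out
}
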