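# shared builders for trace- and cycle-level fixtures, all generated in code

# air-saturation trace declining linearly at `slope` %/s from `start`
linear_trace <- function(duration_s, slope, start = 100, dt = 1) {
  t <- seq(0, duration_s - dt, by = dt)
  tibble::tibble(time_s = t, airsat = start + slope * t)
}

# a single measure-cycle row shaped like segment_cycles() output
make_cycle <- function(samples, cycle = 1L, phase = "pre_chase",
                       start_s = min(samples$time_s),
                       end_s = max(samples$time_s) + 1) {
  tibble::tibble(cycle = cycle, phase = phase, start_s = start_s,
                 end_s = end_s, samples = list(samples))
}

# minimal mo2_series tibble from vectors
make_series <- function(time_s, mo2, phase, accepted = TRUE) {
  tibble::tibble(cycle = seq_along(time_s), time_s = time_s, mo2 = mo2,
                 phase = phase, accepted = rep(accepted, length.out = length(time_s)),
                 reason = NA_character_, flag = NA_character_)
}

# balanced 2x2 data frame with given cell means and residuals
cell_data <- function(means, resid, n_per_cell) {
  g <- expand.grid(salinity_group = c("fresh", "sea"),
                   surgery_group = c("sham", "ligated"),
                   stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(4), function(i) {
    data.frame(salinity_group = g$salinity_group[i],
               surgery_group = g$surgery_group[i],
               y = means[i] + resid[((i - 1) * n_per_cell + 1):(i * n_per_cell)])
  }))
  out
}

# classical balanced two-way ANOVA by explicit sums of squares (oracle)
brute_force_anova <- function(d) {
  a <- factor(d$salinity_group); b <- factor(d$surgery_group)
  y <- d$y
  gm <- mean(y)
  ma <- tapply(y, a, mean); mb <- tapply(y, b, mean)
  mab <- tapply(y, list(a, b), mean)
  nn <- table(a, b)
  n <- nn[1, 1]
  ss_a <- sum(table(a) * (ma - gm)^2)
  ss_b <- sum(table(b) * (mb - gm)^2)
  ss_ab <- sum(nn * (sweep(sweep(mab, 1, ma), 2, mb) + gm)^2)
  ss_e <- sum((y - mab[cbind(a, b)])^2)
  df_e <- length(y) - 4
  list(F_a = (ss_a / 1) / (ss_e / df_e),
       F_b = (ss_b / 1) / (ss_e / df_e),
       F_ab = (ss_ab / 1) / (ss_e / df_e),
       df_e = df_e)
}
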