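#' Two-way factorial ANOVA with Type II sums of squares
#'
#' Fits `response ~ A * B` and returns F statistics, degrees of freedom and
#' p-values for both main effects and the interaction, using Type II sums of
#' squares so that near-balanced designs with variable-specific exclusions
#' are handled consistently (on a balanced design Type II equals the
#' textbook decomposition exactly). An optional variance-stabilising
#' transformation is applied to the response before fitting.
#'
#' @param data Data frame.
#' @param response Name of the response column (string).
#' @param factor_a,factor_b Names of the two factor columns (strings), e.g.
#'   salinity and surgery group.
#' @param transform One of `"none"`, `"log"`, `"sqrt"`, `"square"`.
#' @return An `effect_table` tibble: `term`, `df`, `df_resid`, `F`, `p`,
#'   with the fitted model and transformation as attributes.
#' @export
two_way_anova <- function(data, response, factor_a, factor_b,
                          transform = c("none", "log", "sqrt", "square")) {
  transform <- match.arg(transform)
  d <- data[stats::complete.cases(data[, c(response, factor_a, factor_b)]), ]
  d[[factor_a]] <- factor(d[[factor_a]])
  d[[factor_b]] <- factor(d[[factor_b]])
  cells <- table(d[[factor_a]], d[[factor_b]])
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop("empty design cell: ",
         paste(rownames(cells)[empty[, 1]], colnames(cells)[empty[, 2]],
               sep = ":", collapse = ", "), call. = FALSE)
  }
  if (sum(cells >= 2) < 2) {
    stop("need at least 2 cells with at least 2 observations", call. = FALSE)
  }
  y <- switch(transform,
              none = d[[response]],
              log = log(d[[response]]),
              sqrt = sqrt(d[[response]]),
              square = d[[response]]^2)
  d$.y <- y
  fml <- stats::as.formula(paste(".y ~", factor_a, "*", factor_b))
  fit <- stats::lm(fml, data = d)
  a2 <- car::Anova(fit, type = 2)
  terms <- rownames(a2)
  keep <- terms != "Residuals"
  out <- tibble::tibble(
    term = terms[keep],
    df = a2$Df[keep],
    df_resid = a2$Df[!keep],
    F = a2$`F value`[keep],
    p = a2$`Pr(>F)`[keep])
  attr(out, "model") <- fit
  attr(out, "transform") <- transform
  attr(out, "factors") <- c(factor_a, factor_b)
  class(out) <- c("effect_table", class(out))
  out
}

#' Simple main effects with Bonferroni correction
#'
#' When a factor shows a significant overall effect, its simple main effect
#' is evaluated at each level of the other factor: the difference of cell
#' means at that level, tested with the pooled residual variance of the full
#' factorial model, with Bonferroni adjustment of the p-values and
#' confidence level across the number of levels tested.
#'
#' @param effect_table An [two_way_anova()] result.
#' @param factor Name of the factor whose simple effects are wanted.
#' @param alpha Family-wise significance level, default 0.05.
#' @return Tibble with one row per level of the other factor: `at_level`,
#'   `estimate` (difference on the transformed scale), `se`, `df`, `t`,
#'   `p_adj` (Bonferroni), `lower`, `upper` (Bonferroni-adjusted CI),
#'   `significant`.
#' @export
simple_main_effects <- function(effect_table, factor, alpha = 0.05) {
  fit <- attr(effect_table, "model")
  facs <- attr(effect_table, "factors")
  if (!factor %in% facs) stop("unknown factor: ", factor, call. = FALSE)
  other <- setdiff(facs, factor)
  d <- fit$model
  lv_f <- levels(d[[factor]])
  lv_o <- levels(d[[other]])
  if (length(lv_f) != 2) {
    stop("simple contrasts implemented for 2-level factors", call. = FALSE)
  }
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  m <- length(lv_o)  # Bonferroni divisor: number of levels tested
  conf <- 1 - alpha / m
  rows <- lapply(lv_o, function(lo) {
    sel1 <- d[[factor]] == lv_f[1] & d[[other]] == lo
    sel2 <- d[[factor]] == lv_f[2] & d[[other]] == lo
    n1 <- sum(sel1); n2 <- sum(sel2)
    est <- mean(d$.y[sel2]) - mean(d$.y[sel1])
    se <- sqrt(mse * (1 / n1 + 1 / n2))
    tval <- est / se
    p <- 2 * stats::pt(-abs(tval), fit$df.residual)
    crit <- stats::qt(1 - (alpha / m) / 2, fit$df.residual)
    tibble::tibble(at_level = lo,
                   contrast = paste(lv_f[2], "-", lv_f[1]),
                   estimate = est, se = se, df = fit$df.residual, t = tval,
                   p_adj = min(1, p * m),
                   lower = est - crit * se, upper = est + crit * se,
                   significant = min(1, p * m) < alpha)
  })
  out <- do.call(rbind, rows)
  attr(out, "conf_level") <- conf
  out
}

#' Percent effect of a treatment relative to a reference
#'
#' `100 * (reference - treatment) / reference`; e.g. a maximum metabolic
#' rate falling from 259.9 to 175.3 mg O2 h-1 kg-1 under coronary ligation
#' is a 33% reduction once rounded to report precision.
#'
#' @param mean_reference Reference-group mean (non-zero).
#' @param mean_treatment Treatment-group mean.
#' @param round_digits Digits for report parity; `NULL` returns the raw
#'   value. Default 0 (nearest integer, as effects are printed).
#' @return Percent change (positive = reduction).
#' @export
percent_effect <- function(mean_reference, mean_treatment, round_digits = 0) {
  if (any(mean_reference == 0)) stop("reference mean must be non-zero",
                                     call. = FALSE)
  p <- 100 * (mean_reference - mean_treatment) / mean_reference
  if (is.null(round_digits)) p else round(p, round_digits)
}

#' How much larger one group difference is than another
#'
#' `100 * ((a1 - a2) / (b1 - b2) - 1)`: the percent by which the difference
#' `a1 - a2` (e.g. the sham-ligated gap in sea water) exceeds the difference
#' `b1 - b2` (the same gap in fresh water).
#'
#' @param diff_numerator Numeric length-2 `c(a1, a2)`.
#' @param diff_denominator Numeric length-2 `c(b1, b2)`; difference non-zero.
#' @param round_digits Digits for report parity; `NULL` for raw. Default 0.
#' @return Percent larger.
#' @export
relative_difference_ratio <- function(diff_numerator, diff_denominator,
                                      round_digits = 0) {
  stopifnot(length(diff_numerator) == 2, length(diff_denominator) == 2)
  den <- diff_denominator[1] - diff_denominator[2]
  if (den == 0) stop("denominator difference must be non-zero", call. = FALSE)
  p <- 100 * ((diff_numerator[1] - diff_numerator[2]) / den - 1)
  if (is.null(round_digits)) p else round(p, round_digits)
}

#' Per-cell group summary (mean +/- s.e.m.)
#'
#' @param data Data frame.
#' @param variables Character vector of numeric columns to summarise.
#' @param factor_a,factor_b Grouping factor column names.
#' @return Tibble: one row per cell x variable with `n`, `mean`, `sem`.
#' @export
group_summary <- function(data, variables, factor_a = "salinity_group",
                          factor_b = "surgery_group") {
  rows <- list()
  for (v in variables) {
    agg <- split(data[[v]], list(data[[factor_a]], data[[factor_b]]),
                 sep = "\r")
    for (nm in names(agg)) {
      x <- agg[[nm]][!is.na(agg[[nm]])]
      key <- strsplit(nm, "\r", fixed = TRUE)[[1]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        variable = v, !!factor_a := key[1], !!factor_b := key[2],
        n = length(x),
        mean = if (length(x)) mean(x) else NA_real_,
        sem = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_)
    }
  }
  do.call(rbind, rows)
}
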