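#' One-way ANOVA power and sample size for the heart-rate assay
#'
#' Works through the assay's sample-size chain: the effect size
#' `d = expected effect / SD` (e.g. a 15 bpm expected change over a 12 bpm
#' control standard deviation gives d = 1.25), Cohen's effect size index
#' `f = d / 2` for a one-way ANOVA, and the continuous per-group `n` at
#' which the noncentral-F power reaches the target. Power is evaluated as
#' `P(F' > F_crit)` with `F_crit` the upper-`alpha` quantile of the central
#' F distribution on `(k - 1, k (n - 1))` degrees of freedom and
#' noncentrality `lambda = f^2 k n`. The design's final well count adds one
#' sample to the rounded-up `n` and then a loss-rate allowance:
#' `n_final = ceiling((ceiling(n_exact) + 1) * (1 + loss_rate))`.
#'
#' @param effect Expected effect range in bpm (ignored when `f` is given).
#' @param sd Control standard deviation in bpm (ignored when `f` is given).
#' @param k Number of groups (>= 2).
#' @param alpha Significance level (default 0.05).
#' @param power Target power (default 0.8).
#' @param loss_rate Anticipated attrition fraction added to the final well
#'   count (default 0.25).
#' @param f Optional effect size index, overriding `effect / sd / 2`.
#' @return An object of class `power_design` with `d`, `f`, `k`, `alpha`,
#'   `power`, `n_exact` (continuous), `n_rounded` (`ceiling(n_exact)`) and
#'   `n_final` (wells/group after the extra sample and loss allowance).
#' @examples
#' anova_sample_size(effect = 15, sd = 12, k = 5)
#' @export
anova_sample_size <- function(effect = NULL, sd = NULL, k, alpha = 0.05,
                              power = 0.8, loss_rate = 0.25, f = NULL) {
  stopifnot(k >= 2, alpha > 0, alpha < 1, power > 0, power < 1,
            loss_rate >= 0)
  if (is.null(f)) {
    stopifnot(effect > 0, sd > 0)
    d <- effect / sd
    f <- 0.5 * d
  } else {
    stopifnot(f > 0)
    d <- 2 * f
  }
  pow_at <- function(n) {
    df2 <- k * (n - 1)
    1 - stats::pf(stats::qf(1 - alpha, k - 1, df2), k - 1, df2,
                  ncp = f^2 * k * n)
  }
  upper <- 1e6
  if (pow_at(upper) < power) {
    stop("no solution: requested power is unattainable at n <= 1e6",
         call. = FALSE)
  }
  n_exact <- stats::uniroot(function(n) pow_at(n) - power,
                            lower = 1 + 1e-9, upper = upper,
                            tol = 1e-9)$root
  n_rounded <- ceiling(n_exact)
  n_final <- ceiling((n_rounded + 1) * (1 + loss_rate))
  structure(list(expected_effect = effect, sd = sd, d = d, f = f, k = k,
                 alpha = alpha, power = power, loss_rate = loss_rate,
                 n_exact = n_exact, n_rounded = n_rounded,
                 n_final = n_final),
            class = "power_design")
}

#' @export
print.power_design <- function(x, ...) {
  cat("<power_design> one-way ANOVA sample size\n")
  half_up2 <- function(v) sprintf("%.2f", floor(v * 100 + 0.5) / 100)
  if (!is.null(x$expected_effect)) {
    cat(sprintf("  d = %g / %g = %s; f = %s\n",
                x$expected_effect, x$sd, half_up2(x$d), half_up2(x$f)))
  } else {
    cat(sprintf("  f = %s (d = %s)\n", half_up2(x$f), half_up2(x$d)))
  }
  cat(sprintf("  k = %d, alpha = %g, power = %g -> n_exact = %.2f\n",
              x$k, x$alpha, x$power, x$n_exact))
  cat(sprintf("  rounded %d, +1 sample, +%g%% loss -> %d wells/group\n",
              x$n_rounded, 100 * x$loss_rate, x$n_final))
  invisible(x)
}

#' @rdname tidy-fishbeat
#' @method tidy power_design
#' @export
tidy.power_design <- function(x, ...) {
  tibble::tibble(term = c("d", "f", "n_exact", "n_rounded", "n_final"),
                 estimate = c(x$d, x$f, x$n_exact, x$n_rounded, x$n_final))
}

#' @rdname glance-fishbeat
#' @method glance power_design
#' @export
glance.power_design <- function(x, ...) {
  tibble::tibble(d = x$d, f = x$f, k = x$k, alpha = x$alpha,
                 power = x$power, n_exact = x$n_exact,
                 n_rounded = x$n_rounded, n_final = x$n_final)
}

#' Bland-Altman method comparison
#'
#' Quantifies disagreement between two methods measuring the same quantity
#' on the same subjects (e.g. automated vs manual ROI placement): the bias
#' is the mean of the paired differences `a - b`, and the 95% limits of
#' agreement, `bias +/- 1.96 * SD(differences)`, delimit the interval in
#' which 95% of differences between the methods are expected. The fraction
#' of exactly-zero differences is also reported, a natural summary when
#' both methods quantize to the same spectral grid.
#'
#' @param a,b Paired measurements (equal length >= 2), e.g. bpm.
#' @return An object of class `bland_altman`: `bias`, `sd_diff` (sample
#'   SD, n - 1 denominator), `loa_low`, `loa_high`, `n`, `zero_fraction`,
#'   and the differences.
#' @export
bland_altman <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop("pairing error: `a` and `b` differ in length", call. = FALSE)
  }
  if (length(a) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = length(d), zero_fraction = mean(d == 0),
                 differences = d, means = (a + b) / 2),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n = %d: bias %.4f, 95%% limits of agreement [%.4f, %.4f]\n",
    x$n, x$bias, x$loa_low, x$loa_high))
  cat(sprintf("  exactly-zero differences: %.1f%%\n", 100 * x$zero_fraction))
  invisible(x)
}

#' @rdname glance-fishbeat
#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, sd_diff = x$sd_diff, loa_low = x$loa_low,
                 loa_high = x$loa_high, n = x$n,
                 zero_fraction = x$zero_fraction)
}

#' @rdname tidy-fishbeat
#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(mean = x$means, difference = x$differences)
}

#' Pre-defined control-group outlier exclusion
#'
#' Applies the assay's pre-registered exclusion rule to a control group:
#' animals whose well-averaged heart rate falls outside two pilot standard
#' deviations of the pilot control mean (closed interval) are excluded.
#' The rule is defined for control groups only — treated groups must not be
#' filtered this way, since a true treatment effect would be removed.
#'
#' @param controls Control-group heart rates (bpm).
#' @param pilot_mean,pilot_sd Mean and SD of the pilot control data (bpm;
#'   `pilot_sd >= 0`).
#' @return A list with numeric vectors `kept` and `excluded`.
#' @export
exclude_control_outliers <- function(controls, pilot_mean, pilot_sd) {
  stopifnot(pilot_sd >= 0)
  controls <- as.numeric(controls)
  lo <- pilot_mean - 2 * pilot_sd
  hi <- pilot_mean + 2 * pilot_sd
  keep <- controls >= lo & controls <= hi
  list(kept = controls[keep], excluded = controls[!keep])
}

#' Potency slope of a concentration-response series
#'
#' Ordinary least-squares slope of well-averaged heart rate against
#' exposure concentration, in bpm per ug/ml — the potency summary used to
#' compare extracts. The slope, its standard error and the residual
#' degrees of freedom are the inputs a downstream group comparison of
#' slopes needs (entered as mean, SEM and `n = df + 1`); that comparison
#' itself is a standard ANOVA and is not performed here.
#'
#' @param concentrations Exposure concentrations (ug/ml), >= 3 points with
#'   >= 2 distinct values.
#' @param well_bpm Well-averaged heart rates (bpm), same length.
#' @return A tibble with `slope`, `slope_se`, `df`, `intercept`,
#'   `r_squared`.
#' @export
potency_slope <- function(concentrations, well_bpm) {
  x <- as.numeric(concentrations)
  y <- as.numeric(well_bpm)
  if (length(x) != length(y)) {
    stop("pairing error: lengths differ", call. = FALSE)
  }
  if (length(x) < 3L) {
    stop("insufficient data: need at least 3 points", call. = FALSE)
  }
  if (length(unique(x)) < 2L) {
    stop("rank deficiency: all concentrations identical", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 slope_se = sm$coefficients[2, 2],
                 df = fit$df.residual,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared)
}
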