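#' Two-tailed Student t-test between two groups
#'
#' Pooled-variance Student t by default (`df = n_a + n_b - 2`), or Welch.
#' Identical groups with zero variance return `t = 0, p = 1` (with a
#' warning) so batch pipelines keep running; zero variance with unequal
#' means is an error.
#'
#' @param group_a,group_b Numeric vectors, each with n >= 2 finite values.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return An object of class `t_test_result`: `t`, `df`, `p_raw`,
#'   `p_adjusted` (NA until [adjust_multiple()] is applied), `variant`.
#' @export
student_t_two_tailed <- function(group_a, group_b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(group_a) < 2 || length(group_b) < 2) stop("each group needs n >= 2")
  if (!all(is.finite(group_a)) || !all(is.finite(group_b)))
    stop("groups must be finite")
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    if (isTRUE(all.equal(mean(group_a), mean(group_b)))) {
      warning("zero variance in both groups with equal means; returning t = 0, p = 1")
      return(new_t_result(0, length(group_a) + length(group_b) - 2, 1, variant))
    }
    stop("degenerate variance: zero variance with unequal means")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = (variant == "pooled"),
                      alternative = "two.sided")
  new_t_result(unname(ht$statistic), unname(ht$parameter), ht$p.value, variant)
}

new_t_result <- function(t, df, p, variant) {
  structure(list(t = t, df = df, p_raw = p, p_adjusted = NA_real_,
                 variant = variant),
            class = "t_test_result")
}

#' One-way ANOVA
#'
#' Standard between/within sums-of-squares decomposition via
#' [stats::oneway.test()] with equal variances. All-constant identical
#' groups return `F = 0, p = 1` by the zero-variance rule (warning).
#'
#' @param groups List of >= 2 numeric vectors, each with n >= 2.
#' @return An object of class `anova_result`: `F`, `df_between`,
#'   `df_within`, `p`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2)) stop("each group needs n >= 2")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  dfb <- length(groups) - 1L
  dfw <- length(y) - length(groups)
  if (stats::var(y) == 0) {
    warning("all groups identical constants; returning F = 0, p = 1")
    return(structure(list(F = 0, df_between = dfb, df_within = dfw, p = 1),
                     class = "anova_result"))
  }
  ht <- stats::oneway.test(y ~ g, var.equal = TRUE)
  structure(list(F = unname(ht$statistic), df_between = dfb, df_within = dfw,
                 p = ht$p.value),
            class = "anova_result")
}

#' Multiple-comparison adjustment of p-values
#'
#' Bonferroni by default. With `cap = FALSE` the adjusted values `p * m` are
#' reported uncapped (values above 1 possible, matching the reporting style
#' of corrected tables); with `cap = TRUE` they are clamped at 1 as in
#' [stats::p.adjust()].
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @param method Adjustment method (only `"bonferroni"` supports uncapped
#'   mode; other methods are delegated to [stats::p.adjust()]).
#' @param cap Clamp adjusted values at 1 (default TRUE).
#' @param m Number of comparisons (defaults to `length(p_values)`).
#' @return Numeric vector of adjusted p-values.
#' @export
adjust_multiple <- function(p_values, method = "bonferroni", cap = TRUE,
                            m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values outside [0, 1]")
  if (method == "bonferroni") {
    adj <- p_values * m
    if (cap) adj <- pmin(adj, 1)
    return(adj)
  }
  stats::p.adjust(p_values, method = method, n = m)
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("<t_test_result> t = %.4f, df = %.4g, p = %.4g (%s)\n",
              x$t, x$df, x$p_raw, x$variant))
  invisible(x)
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.4f, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Simulated group study of theta-power deficits
#'
#' Monte-Carlo power analysis for the two-group comparison of 1/f-normalized
#' theta (4-10 Hz) band power: each replicate simulates `n_per_group`
#' control and deficit "animals" (single-channel theta-state field
#' recordings from the forward model), reduces the deficit group's theta
#' amplitude by `deficit_db` (power dB), measures normalized theta area per
#' animal, and applies the two-tailed pooled t-test at `alpha`.
#'
#' @param n_per_group Animals per group (default 8).
#' @param n_replicates Monte-Carlo replicates (default 200).
#' @param deficit_db Theta power deficit of the treated group in dB.
#' @param seed Master seed; all animal-level seeds and amplitude jitter
#'   derive from it.
#' @param duration_s,fs Per-animal recording length and rate (defaults 10 s
#'   at 2500 Hz; the rate must reach the 1 kHz normalization band).
#' @param animal_sd_db Between-animal SD of theta power (dB), default 1.
#' @param alpha Significance level (default 0.05).
#' @return List with `power` (fraction of replicates with p < alpha),
#'   `p_values`, and `mean_effect_db` (mean measured group difference).
#' @export
simulate_theta_power_study <- function(n_per_group = 8, n_replicates = 200,
                                       deficit_db = 3, seed = 1,
                                       duration_s = 10, fs = 2500,
                                       animal_sd_db = 1, alpha = 0.05) {
  set.seed(seed)
  jit <- matrix(stats::rnorm(2 * n_per_group * n_replicates, sd = animal_sd_db),
                nrow = n_replicates)
  measure_animal <- function(sub_seed, amp_db_offset) {
    amp <- 200 * 10^(amp_db_offset / 20)
    cfg <- sim_config(seed = sub_seed, duration_s = duration_s, fs = fs,
                      n_channels = 1, theta = list(amp_uv = amp),
                      ripples = list(rate_hz = 0), mua = list(amp_uv = 0),
                      lia = list(delta_amp_uv = 0),
                      epochs = epoch_table("theta", 0, duration_s))
    x <- generate_laminar_lfp(cfg)$recording$samples[1, ]
    sp <- normalize_1f(average_spectrum(x, fs, segment_s = 1, resolution_hz = 1))
    band_power(sp, 4, 10)$area_db
  }
  p_values <- numeric(n_replicates)
  eff <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    base <- (seed %% 1000L) * 1000000L + r * 100L
    ctrl <- vapply(seq_len(n_per_group), function(i)
      measure_animal(base + i, jit[r, i]), numeric(1))
    defi <- vapply(seq_len(n_per_group), function(i)
      measure_animal(base + 50L + i, jit[r, n_per_group + i] - deficit_db),
      numeric(1))
    p_values[r] <- student_t_two_tailed(ctrl, defi)$p_raw
    eff[r] <- mean(ctrl) - mean(defi)
  }
  list(power = mean(p_values < alpha), p_values = p_values,
       mean_effect_db = mean(eff))
}
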