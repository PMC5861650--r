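# Assay-validation statistics: haplome-equivalent input accounting, exact
# binomial expectation/power curves, titration linearity regression with
# slope comparison, replicate reproducibility, and limit-of-detection
# estimation.

#' Haploid genome equivalents in a DNA mass
#'
#' @param mass_ng Input DNA mass in nanograms.
#' @param pg_per_haplome Mass of one haploid genome in picograms
#'   (default 3.5 pg for human; a 3.2-3.4 Gb genome assumption gives
#'   roughly 14,200-14,700 haplomes per 50 ng).
#' @return Haplome count, rounded to the nearest integer.
#' @export
haplome_equivalents <- function(mass_ng, pg_per_haplome = 3.5) {
  if (pg_per_haplome <= 0) stop("pg_per_haplome must be positive")
  stopifnot(all(mass_ng >= 0))
  round(mass_ng * 1000 / pg_per_haplome)
}

#' Expected number of observed molecules
#'
#' Expected count of edited molecules among the unique molecules recovered
#' from a library: `n_haplomes * process_yield * frequency`.
#'
#' @param n_haplomes Input haplome count.
#' @param process_yield Fraction of input molecules surviving library
#'   preparation to countable unique UMIs (0-1).
#' @param frequency Event frequency (0-1).
#' @return Expected count (not rounded).
#' @export
expected_observations <- function(n_haplomes, process_yield, frequency) {
  stopifnot(process_yield >= 0, process_yield <= 1,
            frequency >= 0, frequency <= 1)
  n_haplomes * process_yield * frequency
}

#' Minimum number of trials for k successes at a given confidence
#'
#' Smallest `n` with `P(X >= k | X ~ Binomial(n, p)) >= confidence`,
#' evaluated with exact binomial tails (no normal approximation).
#'
#' @param k Required number of observations (>= 1).
#' @param p Event frequency (0 < p <= 1).
#' @param confidence Required probability (default 0.95).
#' @param n_cap Upper bound on the search (default 1e8); exceeding it is an
#'   error, signalling an infeasibly small `p`.
#' @return Minimal integer `n`.
#' @export
min_trials <- function(k, p, confidence = 0.95, n_cap = 1e8) {
  stopifnot(k >= 1, p > 0, p <= 1, confidence > 0, confidence < 1)
  tail_ok <- function(n) pbinom(k - 1, n, p, lower.tail = FALSE) >= confidence
  hi <- max(k, ceiling(k / p))
  while (!tail_ok(hi)) {
    hi <- hi * 2
    if (hi > n_cap) stop("min_trials: required n exceeds cap ", n_cap)
  }
  lo <- k  # smallest conceivable n
  while (lo < hi) {
    mid <- (lo + hi) %/% 2
    if (tail_ok(mid)) hi <- mid else lo <- mid + 1
  }
  as.integer(lo)
}

#' Power-curve table over a grid
#'
#' Tabulates [min_trials()] over frequencies and expected-observation
#' requirements, for plotting trials-vs-frequency curves.
#'
#' @param frequencies Event frequencies.
#' @param k_values Required observation counts (default 1:3).
#' @param confidence Confidence levels (default c(0.95, 0.99)).
#' @return data.frame `frequency`, `k`, `confidence`, `n_trials`.
#' @export
power_curve <- function(frequencies, k_values = 1:3,
                        confidence = c(0.95, 0.99)) {
  grid <- expand.grid(frequency = frequencies, k = k_values,
                      confidence = confidence)
  grid$n_trials <- mapply(min_trials, grid$k, grid$frequency, grid$confidence)
  grid
}

#' Fit titration linearity
#'
#' Ordinary least squares of measured on expected signal, by default on the
#' log10-log10 scale where a slope (beta) of 1 indicates a proportional
#' response.
#'
#' @param points data.frame with columns `expected` and `measured` (and
#'   optionally `replicate_id`); values must be positive for log fitting
#'   (zeros belong in detection analysis, not regression).
#' @param log_scale Fit on log10-log10 scale (default TRUE).
#' @return A list of class `ue_linfit`: `beta`, `intercept`, `r_squared`,
#'   `beta_ci` (95%), `n_points`, `fit` (the `lm` object).
#' @export
fit_linearity <- function(points, log_scale = TRUE) {
  stopifnot(all(c("expected", "measured") %in% names(points)))
  pts <- points[!is.na(points$expected) & !is.na(points$measured), ]
  if (log_scale) {
    if (any(pts$expected <= 0 | pts$measured <= 0))
      stop("log-scale fit requires positive values; route zeros to detection analysis")
    x <- log10(pts$expected); y <- log10(pts$measured)
  } else {
    x <- pts$expected; y <- pts$measured
  }
  if (length(x) < 3) stop("need at least 3 points")
  if (diff(range(x)) == 0) stop("degenerate design: all expected values equal")
  fit <- lm(y ~ x)
  ci <- confint(fit, "x", level = 0.95)
  structure(list(beta = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 beta_ci = c(ci[1], ci[2]),
                 n_points = length(x), fit = fit),
            class = "ue_linfit")
}

#' @export
print.ue_linfit <- function(x, ...) {
  cat(sprintf("<ue_linfit> beta = %.4f [%.4f, %.4f], R^2 = %.4f, n = %d\n",
              x$beta, x$beta_ci[1], x$beta_ci[2], x$r_squared, x$n_points))
  invisible(x)
}

#' Compare titration slopes between two methods
#'
#' F-test p-value for the group-by-log10(expected) interaction in the pooled
#' two-group linear model (ANOVA on nested models).
#'
#' @param points_a,points_b data.frames as in [fit_linearity()].
#' @param log_scale Compare on log10-log10 scale (default TRUE).
#' @return A list: `p_value`, `beta_a`, `beta_b`, `fit` (full model).
#' @export
compare_slopes <- function(points_a, points_b, log_scale = TRUE) {
  fa <- fit_linearity(points_a, log_scale)
  fb <- fit_linearity(points_b, log_scale)
  tr <- function(p, g) {
    x <- if (log_scale) log10(p$expected) else p$expected
    y <- if (log_scale) log10(p$measured) else p$measured
    data.frame(x = x, y = y, group = g)
  }
  d <- rbind(tr(points_a, "A"), tr(points_b, "B"))
  d$group <- factor(d$group)
  full <- lm(y ~ x * group, data = d)
  reduced <- lm(y ~ x + group, data = d)
  p <- anova(reduced, full)[["Pr(>F)"]][2]
  list(p_value = p, beta_a = fa$beta, beta_b = fb$beta, fit = full)
}

#' Estimate the lower limit of detection from a replicated titration
#'
#' The LLoD is the lowest titration frequency at which (a) at least
#' `detection_rate` of replicates detect one or more molecules and (b) the
#' median measured frequency is within `max_fold_error` of truth. Returns
#' `Inf` if no level qualifies. The 90%-detection / 2-fold-accuracy rule is
#' this package's formalization of a detection limit; report it alongside
#' the raw titration when comparing assays.
#'
#' @param titration data.frame with columns `expected_frequency`,
#'   `measured_frequency` (0 when nothing was detected), `replicate_id`.
#' @param detection_rate Required fraction of detecting replicates
#'   (default 0.9).
#' @param max_fold_error Maximum fold deviation of the median measurement
#'   (default 2).
#' @return The estimated LLoD frequency (or `Inf`).
#' @export
estimate_llod <- function(titration, detection_rate = 0.9, max_fold_error = 2) {
  need <- c("expected_frequency", "measured_frequency", "replicate_id")
  stopifnot(all(need %in% names(titration)))
  levels_ <- sort(unique(titration$expected_frequency))
  qualifies <- vapply(levels_, function(f) {
    sub <- titration[titration$expected_frequency == f, ]
    if (length(unique(sub$replicate_id)) < 2) return(FALSE)
    det <- mean(sub$measured_frequency > 0)
    if (det < detection_rate) return(FALSE)
    med <- median(sub$measured_frequency)
    med > 0 && med / f <= max_fold_error && f / med <= max_fold_error
  }, logical(1))
  if (!any(qualifies)) return(Inf)
  min(levels_[qualifies])
}

#' Replicate reproducibility
#'
#' R-squared between two replicate measurement vectors, by default on the
#' log10 scale with non-positive pairs removed.
#'
#' @param a,b Paired measurement vectors (e.g. per-titration-level
#'   frequencies from two independent libraries).
#' @param log_scale Correlate log10 values (default TRUE).
#' @return Squared Pearson correlation.
#' @export
replicate_r_squared <- function(a, b, log_scale = TRUE) {
  stopifnot(length(a) == length(b))
  keep <- !is.na(a) & !is.na(b)
  if (log_scale) keep <- keep & a > 0 & b > 0
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3) stop("need at least 3 positive paired values")
  if (log_scale) { a <- log10(a); b <- log10(b) }
  unname(cor(a, b)^2)
}
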