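test_that("haplome-equivalent accounting reproduces the standard input math", {
  expect_equal(haplome_equivalents(50), 14286)
  expect_equal(round(haplome_equivalents(50), -2), 14300)  # ~14,300
  expect_equal(haplome_equivalents(0), 0)
  expect_equal(haplome_equivalents(0.0035), 1)             # one haplome mass
  expect_error(haplome_equivalents(50, pg_per_haplome = 0), "positive")

  # linear in mass (on masses whose count is exact, so rounding is neutral)
  expect_equal(haplome_equivalents(14), 2 * haplome_equivalents(7))
})

test_that("expected observed molecules is the bilinear thinning product", {
  expect_equal(expected_observations(14300, 0.20, 0.001), 2.86)
  expect_equal(expected_observations(14300, 0.20, 0), 0)
  expect_equal(expected_observations(1000, 1, 1), 1000)
  # bilinear
  expect_equal(expected_observations(14300, 0.4, 0.001),
               2 * expected_observations(14300, 0.2, 0.001))
})

test_that("min_trials matches the exact binomial tail scan", {
  # closed form for k = 1: 1 - (1-p)^n
  expect_equal(min_trials(1, 0.5, 0.95), 5L)
  expect_equal(min_trials(1, 1.0, 0.95), 1L)
  expect_equal(min_trials(1, 1.0, 0.5), 1L)

  # brute-force scan oracle over a (k, p, confidence) grid
  for (k in c(1L, 2L, 3L)) for (p in c(0.5, 0.1, 0.02))
    for (conf in c(0.9, 0.95, 0.99)) {
      expect_equal(min_trials(k, p, conf), oracle_min_trials(k, p, conf),
                   info = sprintf("k=%d p=%g conf=%g", k, p, conf))
    }
  # the k=3, p=0.001 power point
  expect_equal(min_trials(3, 0.001, 0.95), oracle_min_trials(3, 0.001, 0.95))

  # monotone: nonincreasing in p and confidence-complement, nondecreasing in k
  grid_p <- c(0.01, 0.05, 0.2, 0.5)
  n_by_p <- vapply(grid_p, function(p) min_trials(2, p, 0.95), integer(1))
  expect_true(all(diff(n_by_p) <= 0))
  n_by_k <- vapply(1:4, function(k) min_trials(k, 0.05, 0.95), integer(1))
  expect_true(all(diff(n_by_k) >= 0))
  n_by_c <- vapply(c(0.8, 0.9, 0.95, 0.99), function(cf)
    min_trials(2, 0.05, cf), integer(1))
  expect_true(all(diff(n_by_c) >= 0))

  expect_error(min_trials(1, 1e-9, 0.95, n_cap = 1e4), "cap")

  pc <- power_curve(c(0.01, 0.001))
  expect_equal(nrow(pc), 2L * 3L * 2L)
})

test_that("titration linearity regression recovers known slopes", {
  expected <- 10^seq(-3, 0, length.out = 8)

  # noise-free fits trip lm's perfect-fit warning; that is the point here
  fit <- suppressWarnings(
    fit_linearity(data.frame(expected = expected, measured = expected)))
  expect_equal(fit$beta, 1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  fit2 <- suppressWarnings(
    fit_linearity(data.frame(expected = expected, measured = 2 * expected)))
  expect_equal(fit2$beta, 1, tolerance = 1e-10)
  expect_equal(fit2$intercept, log10(2), tolerance = 1e-10)

  # generate with beta 0.9 plus small noise and refit
  set.seed(123)
  meas <- 10^(0.9 * log10(expected) + rnorm(8, 0, 0.02))
  fit3 <- fit_linearity(data.frame(expected = expected, measured = meas))
  expect_true(fit3$beta_ci[1] <= 0.9 && 0.9 <= fit3$beta_ci[2])
  expect_true(fit3$beta_ci[1] <= fit3$beta && fit3$beta <= fit3$beta_ci[2])

  # permutation invariance
  perm <- sample(8)
  fit4 <- fit_linearity(data.frame(expected = expected[perm],
                                   measured = meas[perm]))
  expect_equal(fit4$beta, fit3$beta)
  expect_equal(fit4$r_squared, fit3$r_squared)

  expect_error(fit_linearity(data.frame(expected = rep(1, 5),
                                        measured = 1:5)), "degenerate")
  expect_error(fit_linearity(data.frame(expected = c(0, 1, 2),
                                        measured = c(1, 1, 1))), "positive")
})

test_that("slope comparison detects different betas and is label symmetric", {
  set.seed(42)
  expected <- 10^seq(-2, 0, length.out = 11)
  noisy <- function(beta) data.frame(
    expected = expected,
    measured = 10^(beta * log10(expected) + rnorm(11, 0, 0.01)))
  a <- noisy(1.0); b <- noisy(0.7)

  # identical data in both groups: interaction is null
  same <- compare_slopes(a, a)
  expect_gt(same$p_value, 0.99)

  diff <- compare_slopes(a, b)
  expect_lt(diff$p_value, 0.01)
  expect_equal(diff$beta_a, 1.0, tolerance = 0.05)
  expect_equal(diff$beta_b, 0.7, tolerance = 0.05)

  # swapping group labels leaves the p-value unchanged
  swapped <- compare_slopes(b, a)
  expect_equal(swapped$p_value, diff$p_value)
})

test_that("LLoD rule: detection rate plus fold accuracy over replicates", {
  levels_ <- c(0.5, 0.05, 0.005, 0.001)
  perfect <- expand.grid(expected_frequency = levels_, replicate_id = 1:3)
  perfect$measured_frequency <- perfect$expected_frequency
  expect_equal(estimate_llod(perfect), 0.001)

  # deepest level never detected: LLoD moves one level up
  miss <- perfect
  miss$measured_frequency[miss$expected_frequency == 0.001] <- 0
  expect_equal(estimate_llod(miss), 0.005)

  # gross quantitative error disqualifies a level even when detected
  off <- perfect
  off$measured_frequency[off$expected_frequency == 0.001] <- 0.01
  expect_equal(estimate_llod(off), 0.005)

  # nothing qualifies
  none <- perfect; none$measured_frequency <- 0
  expect_equal(estimate_llod(none), Inf)
})

test_that("binomial-thinned titration yields an LLoD at or below 0.1%", {
  # molecule counting at library scale: 2,860 unique molecules per library
  # (50 ng at ~20% process yield), titrated 50% ... 0.01%
  set.seed(314)
  n_mol <- 2860L
  levels_ <- c(0.5, 0.1, 0.02, 0.005, 0.001, 2e-4, 1e-4)
  tit <- do.call(rbind, lapply(1:100, function(rep_id) {
    counts <- rbinom(length(levels_), n_mol, levels_)
    data.frame(expected_frequency = levels_,
               measured_frequency = counts / n_mol,
               replicate_id = rep_id)
  }))
  expect_lte(estimate_llod(tit), 0.001)
})

test_that("replicate R^2 is computed on positive log-scale pairs", {
  a <- c(0.5, 0.05, 0.005, 0.0005, 0)
  b <- c(0.48, 0.052, 0.0048, 0.00055, 0.0001)
  r2 <- replicate_r_squared(a, b)
  expect_gt(r2, 0.99)
  expect_error(replicate_r_squared(c(1, 2), c(1, 2, 3)), "length")
  expect_error(replicate_r_squared(c(0, 0, 0, 1), c(0, 0, 0, 1)), "positive")
})
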