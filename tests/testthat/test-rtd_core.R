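# Exit-age normalization, cumulative distribution, moments, dimensionless
# curves and the Peclet inversion.

test_that("tracer_series validates its invariants", {
  expect_s3_class(tracer_series(c(0, 10), c(0, 1)), "tracer_series")
  expect_error(tracer_series(c(10, 0), c(0, 1)), class = "extrurtd_domain_error")
  expect_error(tracer_series(c(0, 10), c(-1, 1)), class = "extrurtd_domain_error")
  expect_error(tracer_series(c(0, 10), c(0, 0)), class = "extrurtd_unnormalizable")
  expect_error(tracer_series(0, 1), class = "extrurtd_domain_error")
})

test_that("normalize_to_E reproduces the hand-summed examples", {
  e1 <- normalize_to_E(tracer_series(c(0, 10, 20), c(0, 1, 0)))
  expect_equal(e1$E, c(0, 0.1, 0))
  e2 <- normalize_to_E(tracer_series(c(0, 10, 20, 30), c(0, 2, 2, 0)))
  expect_equal(e2$E, c(0, 0.05, 0.05, 0))
})

test_that("sum E dt = 1 for every normalizable input (property)", {
  set.seed(42)
  for (i in 1:25) {
    s <- random_series(sample(3:40, 1))
    cur <- normalize_to_E(s)
    expect_equal(sum(cur$E * cur$weights), 1, tolerance = 1e-9)
  }
})

test_that("baseline is subtracted then clipped; all-zero signal errors", {
  s <- tracer_series(c(0, 10, 20), c(0.01, 0.5, 0.02))
  cur <- normalize_to_E(s, baseline = 0.05)
  expect_equal(cur$E[c(1, 3)], c(0, 0))
  expect_equal(sum(cur$E * cur$weights), 1)
  expect_error(normalize_to_E(s, baseline = 0.6),
               class = "extrurtd_domain_error")
})

test_that("cumulative_F is a running segment sum, monotone, ending at 1", {
  cur <- cumulative_F(normalize_to_E(tracer_series(c(0, 10, 20), c(0, 1, 0))))
  expect_equal(cur$F, c(0, 1, 1))
  # all mass in the last segment
  cur2 <- cumulative_F(normalize_to_E(
    tracer_series(c(0, 10, 20, 30), c(0, 0, 0, 3))))
  expect_equal(cur2$F, c(0, 0, 0, 1))
  set.seed(7)
  for (i in 1:10) {
    cur <- cumulative_F(normalize_to_E(random_series()))
    expect_true(all(diff(cur$F) >= 0))
    expect_gte(cur$F[1], 0)
    expect_equal(cur$F[length(cur$F)], 1, tolerance = 1e-9)
  }
})

test_that("F is invariant to a consistent rescaling of time units", {
  s_sec <- tracer_series(c(10, 20, 40, 70), c(0, 1, 2, 0.5))
  s_min <- tracer_series(c(10, 20, 40, 70) / 60, c(0, 1, 2, 0.5))
  expect_equal(cumulative_F(normalize_to_E(s_sec))$F,
               cumulative_F(normalize_to_E(s_min))$F)
})

test_that("mean_residence_time matches hand sums and shifts with time", {
  expect_equal(mean_residence_time(tracer_series(c(10, 20, 30), c(0, 1, 0))), 20)
  expect_equal(mean_residence_time(tracer_series(c(10, 20), c(1, 1))), 15)
  s <- tracer_series(c(5, 12, 30, 41), c(0.1, 1, 0.7, 0))
  shifted <- tracer_series(s$times + 5, s$concentrations)
  expect_equal(mean_residence_time(shifted),
               mean_residence_time(s) + 5, tolerance = 1e-12)
})

test_that("rtd_variance matches hand moments and is shift invariant", {
  s1 <- tracer_series(c(10, 20, 30), c(0, 1, 0))
  expect_equal(rtd_variance(s1, mean_residence_time(s1)), 0)
  s2 <- tracer_series(c(10, 20), c(1, 1))
  expect_equal(rtd_variance(s2, 15), 25)
  s <- tracer_series(c(5, 12, 30, 41), c(0.1, 1, 0.7, 0))
  v0 <- rtd_variance(s, mean_residence_time(s))
  shifted <- tracer_series(s$times + 100, s$concentrations)
  v1 <- rtd_variance(shifted, mean_residence_time(shifted))
  expect_equal(v1, v0, tolerance = 1e-9)
  expect_error(rtd_variance(s2, 100),
               class = "extrurtd_numerical_inconsistency")
})

test_that("segment-sum moments agree with the brute-force oracle", {
  set.seed(11)
  for (i in 1:20) {
    s <- random_series(sample(4:30, 1))
    oracle <- brute_moments(s$times, s$concentrations)
    expect_equal(mean_residence_time(s), oracle$mrt, tolerance = 1e-12)
    expect_equal(rtd_variance(s, oracle$mrt), oracle$variance,
                 tolerance = 1e-12)
  }
})

test_that("dimensionless curves follow theta = t/MRT", {
  s <- tracer_series(c(10, 20, 30), c(0, 1, 0))
  cur <- dimensionless(cumulative_F(normalize_to_E(s)), mrt = 20)
  expect_equal(cur$theta, c(0.5, 1.0, 1.5))
  expect_equal(cur$E_theta, 20 * cur$E)
  expect_identical(cur$F_theta, cur$F)
  # mean of theta under E(theta) is 1 by construction
  expect_equal(sum(cur$theta * cur$E_theta * (cur$weights / 20)), 1,
               tolerance = 1e-9)
})

test_that("peclet_forward evaluates, decreases, and obeys both limits", {
  expect_equal(peclet_forward(20), 2 / 20 - (2 / 400) * (1 - exp(-20)),
               tolerance = 1e-12)
  expect_equal(peclet_forward(20), 0.095, tolerance = 1e-6)
  expect_equal(peclet_forward(10.805), 0.16797, tolerance = 1e-4)
  pe <- 10^seq(-3, 5, length.out = 200)
  expect_true(all(diff(peclet_forward(pe)) < 0))
  # small-Pe series: |f(Pe) - (1 - Pe/3)| <= Pe^2/8
  small <- c(1e-6, 1e-4, 1e-3, 0.01, 0.05, 0.09)
  expect_true(all(abs(peclet_forward(small) - (1 - small / 3)) <=
                    small^2 / 8))
  # large-Pe: f(Pe) * Pe -> 2
  expect_equal(peclet_forward(1e6) * 1e6, 2, tolerance = 1e-5)
  expect_error(peclet_forward(0), class = "extrurtd_domain_error")
  expect_error(peclet_forward(-3), class = "extrurtd_domain_error")
})

test_that("solve_peclet inverts peclet_forward and handles its domain", {
  for (pe in c(0.1, 0.5, 5, 50, 150, 500)) {
    expect_equal(solve_peclet(peclet_forward(pe)), pe,
                 tolerance = 1e-8)
  }
  expect_equal(solve_peclet(0.16797), 10.80, tolerance = 0.01)
  expect_error(solve_peclet(1), class = "extrurtd_no_solution")
  expect_error(solve_peclet(1.3), class = "extrurtd_no_solution")
  expect_error(solve_peclet(0), class = "extrurtd_domain_error")
  expect_error(solve_peclet(-0.2), class = "extrurtd_domain_error")
})

test_that("analyze_run composes the individual operations", {
  s <- tracer_series(seq(0, 120, by = 10),
                     c(0, 0.02, 0.15, 0.35, 0.30, 0.18, 0.10, 0.05,
                       0.02, 0.01, 0.005, 0, 0))
  fit <- analyze_run(s, trim = FALSE)
  mrt <- mean_residence_time(s)
  expect_equal(fit$mrt, mrt)
  expect_equal(fit$variance, rtd_variance(s, mrt))
  expect_equal(fit$sigma_theta2, fit$variance / fit$mrt^2, tolerance = 1e-12)
  expect_equal(fit$peclet, solve_peclet(fit$sigma_theta2))
  expect_true(fit$peclet_solvable)
  expect_equal(sum(fit$curves$E * fit$curves$weights), 1, tolerance = 1e-9)
})

test_that("trailing baseline samples are trimmed before analysis", {
  s <- tracer_series(seq(0, 80, by = 10),
                     c(0, 0.1, 0.4, 0.2, 0.05, 0, 0, 0, 0))
  trimmed <- trim_trailing_baseline(s)
  expect_equal(length(trimmed$times), 5L)
  fit <- analyze_run(s)
  expect_equal(length(fit$curves$times), 5L)
})

test_that("a flat exponential-like series flags Pe unsolvable", {
  # sigma_theta2 >= 1: single-mixer-like decay sampled coarsely
  t <- seq(0, 3000, by = 10)
  conc <- exp(-t / 170) / 170
  fit <- analyze_run(tracer_series(t, conc), trim = FALSE)
  expect_gte(fit$sigma_theta2, 0.97)
  if (!fit$peclet_solvable) expect_true(is.na(fit$peclet))
})

test_that("trapezoid discretization agrees with segment sums on fine grids", {
  t <- seq(0, 900, by = 2)
  conc <- dgamma(t / 180, shape = 8, rate = 8)
  s <- tracer_series(t, conc)
  expect_equal(mean_residence_time(s, method = "trapezoid"),
               mean_residence_time(s, method = "segment"),
               tolerance = 1e-2)
  cur <- normalize_to_E(s, method = "trapezoid")
  expect_equal(sum(cur$E * cur$weights), 1, tolerance = 1e-9)
})

test_that("relative_change reports signed percentage reductions", {
  expect_equal(relative_change(186.19, 169.72), 8.8458, tolerance = 1e-4)
  expect_equal(round(relative_change(204.09, 173.52), 2), 14.98)
  expect_equal(relative_change(5, 5), 0)
  expect_error(relative_change(0, 1), class = "extrurtd_domain_error")
})
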