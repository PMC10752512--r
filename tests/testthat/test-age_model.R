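test_that("group-estimate sampling honours margins, truncation and seeds", {
  bands <- age_band_table(c(18, 30), c(29, 49), c(0.5, 0.3), 0)
  # zero margin: degenerate at the point estimate
  expect_equal(sample_group_estimates(bands, seed = 1), c(0.5, 0.3))

  # SD of draws ~ margin95 / 1.96
  b <- age_band_table(18, 29, 0.5, 0.073)
  draws <- vapply(1:10000, function(s) {
    sample_group_estimates(b, seed = s)
  }, numeric(1))
  expect_equal(sd(draws), 0.073 / 1.96, tolerance = 0.05)

  # truncation keeps proportions legal even near the boundary
  b0 <- age_band_table(8, 12, 0.01, 0.05)
  draws <- vapply(1:2000, function(s) {
    sample_group_estimates(b0, seed = s)
  }, numeric(1))
  expect_true(all(draws >= 0 & draws <= 1))
  expect_gt(min(draws), -1e-15)

  # seeded draws are reproducible and leave the caller's RNG untouched
  set.seed(123); before <- .Random.seed
  d1 <- sample_group_estimates(b, seed = 42)
  expect_identical(.Random.seed, before)
  expect_identical(d1, sample_group_estimates(b, seed = 42))
})

test_that("natural spline is exact at knots, linear with 2 knots, flat-ended", {
  expect_equal(spline_interpolate(c(10, 20), c(0.2, 0.6), 15), 0.4)

  x <- c(8, 15, 24, 40); y <- c(0.1, 0.5, 0.7, 0.3)
  expect_equal(spline_interpolate(x, y, x), y, tolerance = 1e-10)

  # zero second derivative at the boundary knots (finite differences)
  h <- 1e-3
  for (b in c(8, 40)) {
    d2 <- (spline_interpolate(x, y, b + 2 * h) -
      2 * spline_interpolate(x, y, b + h) +
      spline_interpolate(x, y, b)) / h^2
    expect_lt(abs(d2), 1e-3)
  }

  # linear extrapolation beyond the boundary knots
  lo <- spline_interpolate(x, y, c(4, 5, 6))
  expect_equal(diff(lo), rep(diff(lo)[1], 2), tolerance = 1e-10)

  expect_error(spline_interpolate(8, 0.1, 5), "at least 2 knots")
  expect_error(spline_interpolate(c(8, 8, 10), c(1, 2, 3), 5),
    "strictly increasing")
})

test_that("spline matches an independently solved tridiagonal system", {
  set.seed(2024)
  for (rep in 1:25) {
    n <- sample(3:9, 1)
    x <- sort(sample(0:84, n))
    while (any(diff(x) == 0)) x <- sort(sample(0:84, n))
    y <- runif(n)
    xo <- seq(min(x), max(x), length.out = 40)
    expect_equal(spline_interpolate(x, y, xo),
      natural_spline_oracle(x, y, xo), tolerance = 1e-8)
    # and the linear tails agree too
    xt <- c(min(x) - c(5, 2), max(x) + c(2, 5))
    expect_equal(spline_interpolate(x, y, xt),
      natural_spline_oracle(x, y, xt), tolerance = 1e-8)
  }
})

test_that("age profiles interpolate band draws with clamping", {
  inputs <- tiny_inputs()
  cfg <- run_config(seed = 1, n_candidates = 1, n_keep = 1)

  ps <- draw_parameter_set(inputs, seed = 7)
  expect_true(all(ps$prevalence_draws >= 0 & ps$prevalence_draws <= 1))
  expect_true(all(ps$minutes_draws >= 0))
  # zero margins: draws equal the table estimates
  expect_equal(ps$prevalence_draws, inputs$use_prevalence$estimate)

  prof <- build_age_profile(ps, inputs, age_max = 84)
  expect_length(prof$p, 85)
  expect_true(all(prof$p >= 0 & prof$p <= 1))
  expect_true(all(prof$m >= 0))
  # knots reproduced at band midpoints
  mids <- band_midpoints(inputs$use_prevalence, 84)
  expect_equal(prof$p[prof$ages %in% mids],
    ps$prevalence_draws[mids %% 1 == 0], tolerance = 1e-10)

  # all-zero draws give an identically zero profile
  ps0 <- ps; ps0$prevalence_draws[] <- 0
  expect_equal(build_age_profile(ps0, inputs, 84)$p, rep(0, 85))

  # constant draws give a constant profile at every age (incl. 0-7 tail)
  psc <- ps; psc$prevalence_draws[] <- 0.3
  expect_equal(build_age_profile(psc, inputs, 84)$p, rep(0.3, 85),
    tolerance = 1e-10)
})

test_that("a steep overshooting spline is clamped to [0, 1]", {
  inputs <- platform_inputs("steep",
    use_prevalence = age_band_table(
      group_lo = c(8, 13, 18, 30), group_hi = c(12, 17, 29, 49),
      estimate = c(0.02, 0.98, 0.05, 0.9), margin95 = 0),
    minutes = age_band_table(0, 49, 30, 0, proportion = FALSE),
    user_totals = data.frame(group_lo = 0, group_hi = 49, users = 100),
    total_revenue = 1, age_max = 84)
  ps <- draw_parameter_set(inputs, seed = 1)
  prof <- build_age_profile(ps, inputs, 84)
  raw <- spline_interpolate(band_midpoints(inputs$use_prevalence, 84),
    ps$prevalence_draws, prof$ages)
  expect_true(any(raw > 1) || any(raw < 0)) # the case really overshoots
  expect_equal(prof$p, pmin(pmax(raw, 0), 1), tolerance = 1e-12)
  expect_true(all(prof$p <= 1 & prof$p >= 0))
})

test_that("users by age multiply population by use probability", {
  pop <- flat_population(84, count = 1000)
  inputs <- tiny_inputs()
  ps <- draw_parameter_set(inputs, seed = 3)
  prof <- build_age_profile(ps, inputs, 84)

  prof0 <- prof; prof0$p[] <- 0
  expect_equal(users_by_age(prof0, pop), rep(0, 85))
  prof5 <- prof; prof5$p[] <- 0.5
  expect_equal(users_by_age(prof5, pop), rep(500, 85))

  # band sums agree with brute-force per-age summation
  u <- users_by_age(prof, pop)
  for (b in list(c(0, 12), c(13, 17), c(18, 49))) {
    expect_equal(sum(u[pop$age >= b[1] & pop$age <= b[2]]),
      sum(vapply(b[1]:b[2], function(a) u[pop$age == a], numeric(1))))
  }

  short <- flat_population(50)
  expect_error(users_by_age(prof, short), "different age ranges")
})
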