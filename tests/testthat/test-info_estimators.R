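test_that("MI is ~0 for independent input/output and ~1 bit for a
          noiseless binary channel", {
  s0 <- make_identical_sample(2, 2000, seed = 70)
  mi0 <- estimate_mi(s0)
  expect_gt(mi0$mi_bits, -0.02)
  expect_lt(mi0$mi_bits, 0.05)
  expect_equal(mi0$mi_bits,
               sum(mi0$prior_used * mi0$per_class_terms), tolerance = 1e-12)

  s1 <- make_gaussian_sample(c(0, 100), n = 1000, seed = 71)
  expect_equal(estimate_mi(s1)$mi_bits, 1, tolerance = 0.02)
})

test_that("MI rejects a prior with zero mass on an observed level", {
  s <- make_gaussian_sample(c(0, 1), n = 100, seed = 72)
  expect_error(estimate_mi(s, prior = c(1, 0)), "positive mass")
})

test_that("classifier MI matches the quadrature oracle on the log-normal
          benchmark channel", {
  spec <- scenario1_spec()
  s <- transform_response(simulate_channel(spec, 1000, seed = 73), log)
  expect_equal(estimate_mi(s)$mi_bits, oracle_mi(spec), tolerance = 0.05)
})

test_that("monte_carlo_D equals its defining sum and respects bounds", {
  s <- make_gaussian_sample(c(0, 1.2), n = 200, seed = 80)
  fit <- fit_posterior(s, prior = "uniform")
  D <- monte_carlo_D(fit, s)
  expect_true(all(D <= 0))

  # brute-force recomputation, cell by cell, straight from the definition
  lev <- input_levels(s)
  brute <- vapply(seq_along(lev), function(i) {
    rows <- which(as.character(s$input) == lev[i])
    mean(vapply(rows, function(r) {
      p <- posterior_probs(fit, s$response[r, ])[i]
      log2(min(max(p, 1e-12), 1 - 1e-12))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(unname(D), brute, tolerance = 1e-12)

  # uniform posteriors everywhere -> D_i = -1 for both levels
  flat <- fit
  flat$alphas[] <- 0
  flat$betas[] <- 0
  expect_equal(unname(monte_carlo_D(flat, s)), c(-1, -1))

  # near-perfect classifier on separated data -> D_i ~ 0
  ssep <- make_gaussian_sample(c(0, 100), n = 200, seed = 81)
  expect_equal(unname(monte_carlo_D(fit_posterior(ssep), ssep)), c(0, 0),
               tolerance = 0.01)

  smis <- make_gaussian_sample(c(0, 1), n = 200, seed = 82)
  expect_error(monte_carlo_D(fit, smis), "level structure")
})

test_that("input-distribution update is a shift-invariant softmax", {
  expect_equal(unname(capacity_input_update(c(-1, -1, -1))), rep(1 / 3, 3))
  expect_equal(unname(capacity_input_update(c(0, -1e9))), c(1, 0),
               tolerance = 1e-12)
  set.seed(90)
  for (r in 1:10) {
    D <- rnorm(5, sd = 3)
    p <- capacity_input_update(D)
    expect_lt(abs(sum(p) - 1), 1e-12)
    expect_equal(capacity_input_update(D + 17.3), p, tolerance = 1e-12)
  }
  expect_error(capacity_input_update(c(0, NA)), "NA")
})

test_that("capacity recovers noiseless and partially degenerate channels", {
  s4 <- simulate_channel(disjoint_uniform_spec(4), 500, seed = 100)
  c4 <- estimate_capacity(s4)
  expect_equal(c4$capacity_bits, 2, tolerance = 0.03)
  expect_equal(unname(c4$optimal_input), rep(0.25, 4), tolerance = 0.02)
  expect_true(c4$converged)

  # two of three inputs share a distribution: one bit, and the optimal
  # input splits half the mass across the indistinguishable pair
  set.seed(101)
  s3 <- channel_sample(rep(c("a", "b", "c"), each = 1000),
                       c(rnorm(1000), rnorm(1000), rnorm(1000, 100)))
  c3 <- estimate_capacity(s3)
  expect_equal(c3$capacity_bits, 1, tolerance = 0.05)
  expect_equal(unname(c3$optimal_input["a"] + c3$optimal_input["b"]), 0.5,
               tolerance = 0.05)
  expect_equal(unname(c3$optimal_input["c"]), 0.5, tolerance = 0.05)
})

test_that("capacity matches the discretized Blahut-Arimoto oracle on the
          log-normal benchmark channel", {
  spec <- scenario1_spec()
  s <- transform_response(simulate_channel(spec, 1000, seed = 102), log)
  est <- estimate_capacity(s)
  expect_true(est$converged)
  expect_equal(est$capacity_bits, oracle_capacity(spec)$capacity_bits,
               tolerance = 0.05)
})

test_that("the capacity trace is non-decreasing and dominates the
          uniform-prior MI", {
  fixtures <- list(
    make_identical_sample(3, 400, seed = 110),
    make_gaussian_sample(c(0, 1, 2, 5), n = 300, seed = 111),
    transform_response(simulate_channel(scenario1_spec(), 200, seed = 112),
                       log))
  for (s in fixtures) {
    cap <- estimate_capacity(s)
    if (length(cap$trace) > 1) {
      expect_true(all(diff(cap$trace) >= -1e-6))
    }
    expect_gte(cap$capacity_bits, 0 - 0.02)
    expect_lte(cap$capacity_bits, log2(length(input_levels(s))) + 0.02)
    mi <- estimate_mi(s, prior = "uniform")$mi_bits
    expect_gte(cap$capacity_bits, mi - 0.02)
  }
})

test_that("MI and capacity are invariant to relabeling the inputs", {
  s <- make_gaussian_sample(c(0, 1, 3), n = 400, seed = 120,
                            labels = c("a", "b", "c"))
  relab <- c(a = "q", b = "f", c = "k")  # permutes the sort order
  s2 <- channel_sample(unname(relab[as.character(s$input)]), s$response)
  expect_equal(estimate_mi(s2, regularization = 0)$mi_bits,
               estimate_mi(s, regularization = 0)$mi_bits,
               tolerance = 1e-6)
  expect_equal(estimate_capacity(s2, regularization = 0)$capacity_bits,
               estimate_capacity(s, regularization = 0)$capacity_bits,
               tolerance = 1e-6)
})

test_that("non-convergence at the iteration cap is flagged, not thrown", {
  s <- make_gaussian_sample(c(0, 1, 2), n = 200, seed = 130)
  cap <- estimate_capacity(s, max_iterations = 1L)
  expect_false(cap$converged)
  expect_equal(cap$iterations, 1L)
})

test_that("bootstrap replicates are reproducible and collapse at
          fraction 1", {
  s <- make_gaussian_sample(c(0, 2), n = 120, seed = 140)
  full <- estimate_mi(s)$mi_bits
  b1 <- bootstrap_statistic(s, "mi", fraction = 1, repeats = 3, seed = 7)
  expect_true(all(abs(b1$replicates - full) < 1e-12))

  b2 <- bootstrap_statistic(s, "mi", fraction = 0.8, repeats = 5, seed = 7)
  b3 <- bootstrap_statistic(s, "mi", fraction = 0.8, repeats = 5, seed = 7)
  expect_identical(b2$replicates, b3$replicates)
  expect_gt(stats::sd(b2$replicates), 0)

  expect_error(bootstrap_statistic(s, "mi", fraction = 0.01, repeats = 3),
               "fraction too small")
  expect_error(bootstrap_statistic(s, "mi", repeats = 1), "repeats")
})

test_that("bootstrap spread tracks the spread across fresh simulations", {
  spec <- gaussian_shift_spec(c(0, 1, 2))
  s <- simulate_channel(spec, 250, seed = 150)
  boot <- bootstrap_statistic(s, "capacity", fraction = 0.8, repeats = 30,
                              seed = 8)
  fresh <- vapply(1:30, function(r) {
    estimate_capacity(simulate_channel(spec, 200, seed = 1000 + r))$capacity_bits
  }, numeric(1))
  # subsampling a fraction f without replacement understates the sampling
  # sd at the subsample size by about sqrt(1 - f); compare on that scale
  ratio <- boot$sd / (sqrt(1 - 0.8) * stats::sd(fresh))
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})
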