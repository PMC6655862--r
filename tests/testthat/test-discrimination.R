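two_class_model <- function(alpha = 0, beta = 1) {
  structure(
    list(alphas = c(a = alpha),
         betas = matrix(beta, 1, 1, dimnames = list("a", "y")),
         prior = stats::setNames(c(0.5, 0.5), c("a", "b")),
         levels = c("a", "b")),
    class = "posterior_model")
}

test_that("pointwise PCD is the larger posterior and never below 1/2", {
  m <- two_class_model()
  expect_equal(pcd_pointwise(m, 0), 0.5)              # posteriors (1/2, 1/2)
  y9 <- log(9)                                        # posteriors (0.9, 0.1)
  expect_equal(pcd_pointwise(m, y9), 0.9, tolerance = 1e-12)

  set.seed(200)
  ys <- matrix(rnorm(100, sd = 4), ncol = 1)
  expect_true(all(pcd_pointwise(m, ys) >= 0.5))

  three <- fit_posterior(make_gaussian_sample(c(0, 1, 2), 50, seed = 1))
  expect_error(pcd_pointwise(three, 0), "exactly 2")
  skew <- reweight_prior(m, c(0.7, 0.3))
  expect_error(pcd_pointwise(skew, 0), "equal prior")
})

test_that("pair PCD hits the degenerate limits", {
  # fully overlapping conditional distributions: discrimination is random
  s0 <- make_gaussian_sample(c(0, 0), n = 2000, seed = 210,
                             labels = c("a", "b"))
  p0 <- estimate_pcd_pair(s0, "a", "b", repeats = 20, seed = 1)
  expect_equal(p0$mean, 0.5, tolerance = 0.03)

  # disjoint supports: every cell is assigned correctly
  s1 <- make_gaussian_sample(c(0, 100), n = 1000, seed = 211)
  p1 <- estimate_pcd_pair(s1, "0", "100", repeats = 20, seed = 1)
  expect_gte(p1$mean, 0.99)
  expect_lte(p1$mean, 1)
})

test_that("pair PCD matches the analytic Gaussian oracle across
          separations", {
  for (d in c(1, 2)) {
    s <- make_gaussian_sample(c(0, d), n = 4000, seed = 220 + d)
    est <- estimate_pcd_pair(s, "0", as.character(d), repeats = 20, seed = 3)
    expect_equal(est$mean, oracle_pcd_gaussian(0, d, 1), tolerance = 0.02)
  }
})

test_that("pair PCD validates its inputs", {
  s <- make_gaussian_sample(c(0, 1), n = 5, seed = 230)
  expect_error(estimate_pcd_pair(s, "0", "1"), "at least 10")
  s2 <- make_gaussian_sample(c(0, 1), n = 50, seed = 231)
  expect_error(estimate_pcd_pair(s2, "0", "9"), "not present")
  expect_error(estimate_pcd_pair(s2, "0", "1", train_fraction = 1),
               "train_fraction")
})

test_that("pair PCD is reproducible under a seed and symmetric in its
          arguments", {
  s <- make_gaussian_sample(c(0, 1.5), n = 200, seed = 240)
  a <- estimate_pcd_pair(s, "0", "1.5", repeats = 10, seed = 5)
  b <- estimate_pcd_pair(s, "0", "1.5", repeats = 10, seed = 5)
  expect_identical(a$replicates, b$replicates)
  swapped <- estimate_pcd_pair(s, "1.5", "0", repeats = 10, seed = 5)
  expect_equal(swapped$mean, a$mean, tolerance = 1e-12)
})

test_that("an irrelevant noise dimension barely changes PCD", {
  s <- make_gaussian_sample(c(0, 2), n = 2000, seed = 250)
  set.seed(251)
  noisy <- channel_sample(as.character(s$input),
                          cbind(s$response, rnorm(nrow(s$response))))
  p_clean <- estimate_pcd_pair(s, "0", "2", repeats = 20, seed = 6)$mean
  p_noisy <- estimate_pcd_pair(noisy, "0", "2", repeats = 20, seed = 6)$mean
  expect_lt(abs(p_clean - p_noisy), 0.02)
})

test_that("a time window discriminates at least as well as any single
          time point", {
  s <- make_trajectory_sample(n = 600, seed = 252)
  p_window <- estimate_pcd_pair(time_window_view(s, 9), "low", "high",
                                repeats = 10, seed = 2)$mean
  for (t in c(3, 6, 9)) {
    p_point <- estimate_pcd_pair(time_point_view(s, t), "low", "high",
                                 repeats = 10, seed = 2)$mean
    expect_gte(p_window, p_point - 0.03)
  }
})

test_that("the PCD matrix is symmetric with the expected degenerate
          values", {
  s_iid <- make_identical_sample(3, 300, seed = 260)
  m_iid <- estimate_pcd_matrix(s_iid, repeats = 10, seed = 4)
  off <- m_iid$values[upper.tri(m_iid$values)]
  expect_true(all(abs(off - 0.5) < 0.03))
  expect_equal(m_iid$values, t(m_iid$values))
  expect_true(all(is.na(diag(m_iid$values))))

  s_sep <- simulate_channel(disjoint_uniform_spec(3), 100, seed = 261)
  m_sep <- estimate_pcd_matrix(s_sep, repeats = 10, seed = 4)
  expect_true(all(m_sep$values[upper.tri(m_sep$values)] > 0.97))
})

test_that("PCD grows with mean separation on the benchmark channel", {
  spec <- scenario1_spec()
  s <- transform_response(simulate_channel(spec, 300, seed = 270), log)
  x <- as.numeric(input_levels(s))
  mu <- 10 * x / (1 + x)
  pick <- c(1, 5, 8, 11)  # a spread of levels keeps the runtime modest
  sub <- subset_levels(s, as.character(x[pick]))
  m <- estimate_pcd_matrix(sub, repeats = 10, seed = 9)
  lev <- input_levels(sub)
  sep <- abs(outer(mu[pick], mu[pick], "-"))[order(x[pick]), order(x[pick])]
  ut <- upper.tri(sep)
  ord <- order(sep[ut])
  vals <- m$values[ut][ord]
  expect_true(all(diff(vals) >= -0.02))
})

test_that("matrix differences subtract elementwise and antisymmetrically", {
  s <- make_gaussian_sample(c(0, 1, 3), n = 150, seed = 280)
  m1 <- estimate_pcd_matrix(s, repeats = 5, seed = 11)
  zero <- pcd_difference(m1, m1)
  expect_true(all(zero$values[upper.tri(zero$values)] == 0))

  s2 <- make_gaussian_sample(c(0, 1, 3), n = 150, seed = 281)
  m2 <- estimate_pcd_matrix(s2, repeats = 5, seed = 11)
  d12 <- pcd_difference(m1, m2)
  d21 <- pcd_difference(m2, m1)
  expect_equal(d12$values, -d21$values)

  s3 <- make_gaussian_sample(c(0, 1), n = 150, seed = 282)
  expect_error(pcd_difference(m1, estimate_pcd_matrix(s3, repeats = 5)),
               "different level sets")
})

test_that("extra columns that separate only one pair shift only that
          pair's PCD", {
  # base column: level c separated, a and b identical; the extra column
  # separates a from b only
  set.seed(290)
  n <- 800
  lab <- rep(c("a", "b", "c"), each = n)
  col1 <- c(rnorm(n), rnorm(n), rnorm(n, 10))
  col2 <- c(rnorm(n), rnorm(n, 3), rnorm(n))
  base <- channel_sample(lab, matrix(col1, ncol = 1))
  both <- channel_sample(lab, cbind(col1, col2))
  m_base <- estimate_pcd_matrix(base, repeats = 10, seed = 13)
  m_both <- estimate_pcd_matrix(both, repeats = 10, seed = 13)
  d <- pcd_difference(m_base, m_both)
  expect_gt(d$values["a", "b"], 0.3)       # the pair that gained a feature
  expect_lt(abs(d$values["a", "c"]), 0.02) # already perfectly separated
  expect_lt(abs(d$values["b", "c"]), 0.02)
})
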