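#' Synthetic test channels with evaluable densities
#'
#' A `channel_spec` describes a stochastic channel from a discrete input to a
#' continuous output, with conditional densities that can be evaluated
#' exactly. These channels serve two purposes: generating benchmark data
#' ([simulate_channel()]) and providing independent, density-based numeric
#' oracles ([oracle_mi()], [oracle_capacity()]) against which the
#' classifier-based estimators are validated.
#'
#' Families:
#' * `lognormal_sigmoid`: one-dimensional output
#'   `Y | x ~ exp(N(mu(x), sigma2))` with the saturating dose-response mean
#'   `mu(x) = V x / (1 + x)` -- a minimal model of a signaling readout whose
#'   log-intensity noise is constant across doses.
#' * `gaussian_shift`: per-level Gaussian mean vectors with common standard
#'   deviation `sigma`; `means` may be a matrix (levels x dimensions) for a
#'   multivariate output.
#' * `disjoint_uniform`: level i uniform on \[3(i-1), 3(i-1)+1\] -- a
#'   noiseless m-symbol channel (supports mutually disjoint).
#' * `identical`: every level shares one N(0, 1) output -- a channel that
#'   transmits nothing.
#'
#' The oracle operations work on an internal one-dimensional analysis scale
#' on which densities are smooth (the log scale for the log-normal family;
#' mutual information is invariant under monotone output transformations).
#'
#' @param family one of `"lognormal_sigmoid"`, `"gaussian_shift"`,
#'   `"disjoint_uniform"`, `"identical"`.
#' @param parameters named list of family parameters (see the convenience
#'   constructors).
#' @param input_levels vector of input labels / values.
#' @return An object of class `channel_spec`.
#' @export
channel_spec <- function(family, parameters, input_levels) {
  family <- match.arg(family, c("lognormal_sigmoid", "gaussian_shift",
                                "disjoint_uniform", "identical"))
  spec <- structure(list(family = family, parameters = parameters,
                         input_levels = input_levels),
                    class = "channel_spec")
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  p <- spec$parameters
  m <- length(spec$input_levels)
  if (m < 2L) stop("at least 2 input levels required", call. = FALSE)
  switch(spec$family,
    lognormal_sigmoid = {
      if (is.null(p$V) || is.null(p$sigma2) || p$sigma2 <= 0) {
        stop("lognormal_sigmoid needs parameters V and sigma2 > 0",
             call. = FALSE)
      }
      x <- as.numeric(spec$input_levels)
      if (anyNA(x) || any(x < 0)) {
        stop("lognormal_sigmoid input levels must be non-negative numbers",
             call. = FALSE)
      }
    },
    gaussian_shift = {
      if (is.null(p$means) || is.null(p$sigma) || p$sigma <= 0) {
        stop("gaussian_shift needs parameters means and sigma > 0",
             call. = FALSE)
      }
      if (nrow(as.matrix(p$means)) != m) {
        stop("gaussian_shift: one mean (row) per input level required",
             call. = FALSE)
      }
    },
    disjoint_uniform = NULL,
    identical = NULL)
  invisible(spec)
}

#' @export
print.channel_spec <- function(x, ...) {
  cat("<channel_spec>", x$family, "with", length(x$input_levels),
      "input levels\n")
  invisible(x)
}

#' @rdname channel_spec
#' @param V saturation level of the sigmoid log-mean `mu(x) = V x / (1 + x)`.
#' @param sigma2 variance of the log-output.
#' @export
lognormal_sigmoid_spec <- function(input_levels, V = 10, sigma2 = 1) {
  channel_spec("lognormal_sigmoid", list(V = V, sigma2 = sigma2),
               input_levels)
}

#' @rdname channel_spec
#' @param means numeric vector (one mean per level, d = 1) or matrix
#'   (levels x dimensions).
#' @param sigma common standard deviation of every output dimension.
#' @export
gaussian_shift_spec <- function(means, sigma = 1, input_levels = NULL) {
  means <- as.matrix(means)
  if (is.null(input_levels)) {
    input_levels <- if (ncol(means) == 1L) as.numeric(means) else
      seq_len(nrow(means))
  }
  channel_spec("gaussian_shift", list(means = means, sigma = sigma),
               input_levels)
}

#' @rdname channel_spec
#' @param m number of input levels.
#' @export
disjoint_uniform_spec <- function(m) {
  channel_spec("disjoint_uniform", list(), seq_len(m))
}

#' @rdname channel_spec
#' @export
identical_spec <- function(m) {
  channel_spec("identical", list(), seq_len(m))
}

#' Benchmark log-normal dose-response channel
#'
#' The standard one-dimensional benchmark: a log-normally distributed output
#' whose log-mean follows the saturating dose response
#' `mu(x) = V x / (1 + x)` with `V = 10` and constant log-variance
#' `sigma2 = 1`, observed at eleven input values spanning 0 to 100. The
#' eleven levels default to 0 together with ten log-spaced doses from 0.01 to
#' 100 (the usual dose-ladder design; pass `input_levels` to override).
#'
#' @param input_levels optional override of the eleven input values.
#' @return A `channel_spec` of family `lognormal_sigmoid`.
#' @export
scenario1_spec <- function(input_levels = NULL) {
  if (is.null(input_levels)) {
    input_levels <- c(0, 10^seq(-2, 2, length.out = 10))
  }
  lognormal_sigmoid_spec(input_levels, V = 10, sigma2 = 1)
}

# per-level conditional law on the analysis scale: density, quantile, and a
# sampler for the raw output
channel_laws <- function(spec) {
  m <- length(spec$input_levels)
  switch(spec$family,
    lognormal_sigmoid = {
      x <- as.numeric(spec$input_levels)
      mu <- spec$parameters$V * x / (1 + x)
      s <- sqrt(spec$parameters$sigma2)
      list(d = function(z, i) stats::dnorm(z, mu[i], s),
           q = function(p, i) stats::qnorm(p, mu[i], s),
           r = function(n, i) exp(stats::rnorm(n, mu[i], s)),
           dim = 1L)
    },
    gaussian_shift = {
      means <- as.matrix(spec$parameters$means)
      s <- spec$parameters$sigma
      list(d = if (ncol(means) == 1L)
             function(z, i) stats::dnorm(z, means[i, 1L], s) else NULL,
           q = if (ncol(means) == 1L)
             function(p, i) stats::qnorm(p, means[i, 1L], s) else NULL,
           r = function(n, i) {
             matrix(stats::rnorm(n * ncol(means), mean = rep(means[i, ],
                                                             each = n),
                                 sd = s), nrow = n)
           },
           dim = ncol(means))
    },
    disjoint_uniform = {
      lo <- 3 * (seq_len(m) - 1)
      list(d = function(z, i) stats::dunif(z, lo[i], lo[i] + 1),
           q = function(p, i) stats::qunif(p, lo[i], lo[i] + 1),
           r = function(n, i) stats::runif(n, lo[i], lo[i] + 1),
           dim = 1L)
    },
    identical = {
      list(d = function(z, i) stats::dnorm(z),
           q = function(p, i) stats::qnorm(p),
           r = function(n, i) stats::rnorm(n),
           dim = 1L)
    })
}

#' Simulate cells from a synthetic channel
#'
#' Draws `n_per_level` output vectors for each input level and assembles a
#' [channel_sample()]; reproducible under `seed`.
#'
#' @param spec a [channel_spec()].
#' @param n_per_level number of cells per input level (>= 1).
#' @param seed integer seed.
#' @return A [channel_sample()] with `m * n_per_level` rows.
#' @examples
#' s <- simulate_channel(scenario1_spec(), 100, seed = 1)
#' n_per_level(s)
#' @export
simulate_channel <- function(spec, n_per_level, seed = 1L) {
  stopifnot(inherits(spec, "channel_spec"))
  if (n_per_level < 1L) stop("n_per_level must be >= 1", call. = FALSE)
  laws <- channel_laws(spec)
  m <- length(spec$input_levels)
  set.seed(seed)
  resp <- do.call(rbind, lapply(seq_len(m), function(i) {
    y <- laws$r(n_per_level, i)
    if (is.null(dim(y))) matrix(y, ncol = 1L) else y
  }))
  colnames(resp) <- paste0("output", seq_len(ncol(resp)))
  channel_sample(rep(as.character(spec$input_levels), each = n_per_level),
                 resp)
}

# shared discretization: midpoint bin masses of each conditional on a common
# grid spanning the 1e-8 .. 1 - 1e-8 quantile range of all levels; rows are
# normalized so each conditional is an exact probability vector
transition_matrix <- function(spec, n_grid = 4096L) {
  laws <- channel_laws(spec)
  if (laws$dim != 1L || is.null(laws$d)) {
    stop("oracles support one-dimensional channels only", call. = FALSE)
  }
  m <- length(spec$input_levels)
  lo <- min(vapply(seq_len(m), function(i) laws$q(1e-8, i), numeric(1)))
  hi <- max(vapply(seq_len(m), function(i) laws$q(1 - 1e-8, i), numeric(1)))
  edges <- seq(lo, hi, length.out = n_grid + 1L)
  mid <- (edges[-1L] + edges[-length(edges)]) / 2
  dz <- diff(edges)
  W <- t(vapply(seq_len(m), function(i) {
    w <- laws$d(mid, i) * dz
    w / sum(w)
  }, numeric(n_grid)))
  rownames(W) <- as.character(spec$input_levels)
  W
}

# MI in bits of a discrete channel given transition matrix W and prior p
discrete_mi <- function(W, p) {
  py <- as.numeric(p %*% W)
  mi <- 0
  for (i in seq_along(p)) {
    pos <- W[i, ] > 0
    mi <- mi + p[i] * sum(W[i, pos] * log2(W[i, pos] / py[pos]))
  }
  mi
}

#' Quadrature oracle for mutual information
#'
#' Computes MI(X, Y) directly from the known conditional densities of a
#' one-dimensional synthetic channel by discretizing the output on a fine
#' grid (default 4096 bins spanning the 1e-8 quantile range of every level;
#' the log scale for log-normal families). This is the density-based ground
#' truth that the classifier-based [estimate_mi()] is validated against; it
#' never touches sampled data.
#'
#' @param spec a one-dimensional [channel_spec()].
#' @param prior probability vector over the levels, or `"uniform"` (default).
#' @param n_grid number of grid bins (default 4096).
#' @return MI in bits.
#' @export
oracle_mi <- function(spec, prior = "uniform", n_grid = 4096L) {
  stopifnot(inherits(spec, "channel_spec"))
  m <- length(spec$input_levels)
  if (identical(prior, "uniform")) prior <- rep(1 / m, m)
  prior <- validate_prior(prior, m)
  discrete_mi(transition_matrix(spec, n_grid), prior)
}

#' Discretized Blahut-Arimoto oracle for channel capacity
#'
#' Discretizes a one-dimensional synthetic channel into a finite transition
#' matrix (same grid as [oracle_mi()]) and runs the classical discrete
#' Blahut-Arimoto iteration, using the standard lower/upper capacity bounds
#' as the stopping rule. Serves as the density-based ground truth for
#' [estimate_capacity()].
#'
#' @param spec a one-dimensional [channel_spec()].
#' @param n_grid number of grid bins (default 4096).
#' @param tolerance gap between the capacity bounds at termination, in bits
#'   (default 1e-9).
#' @param prior if supplied, the maximization is skipped and the mutual
#'   information at this fixed input distribution is returned instead (with
#'   `optimal_prior` set to it) -- a self-consistency hook for testing.
#' @param max_iterations iteration cap (default 1e5).
#' @return List with `capacity_bits` and `optimal_prior`.
#' @export
oracle_capacity <- function(spec, n_grid = 4096L, tolerance = 1e-9,
                            prior = NULL, max_iterations = 100000L) {
  stopifnot(inherits(spec, "channel_spec"))
  W <- transition_matrix(spec, n_grid)
  m <- nrow(W)
  if (!is.null(prior)) {
    prior <- validate_prior(prior, m)
    return(list(capacity_bits = discrete_mi(W, prior),
                optimal_prior = stats::setNames(prior, rownames(W))))
  }
  p <- rep(1 / m, m)
  lw <- log(W)          # natural log; -Inf where mass is exactly zero
  for (k in seq_len(max_iterations)) {
    py <- as.numeric(p %*% W)
    # log c_i = sum_j W_ij * log( posterior_i(j) / p_i ); the p_i factors
    # cancel, leaving the KL divergence of row i from the output mix (nats)
    logc <- vapply(seq_len(m), function(i) {
      pos <- W[i, ] > 0
      sum(W[i, pos] * (lw[i, pos] - log(py[pos])))
    }, numeric(1))
    il <- log(sum(p * exp(logc)))
    iu <- max(logc)
    if (iu - il < tolerance * log(2)) break
    p <- p * exp(logc)
    p <- p / sum(p)
  }
  list(capacity_bits = il / log(2),
       optimal_prior = stats::setNames(p, rownames(W)))
}

#' Analytic discrimination oracle for equal-variance Gaussians
#'
#' For two univariate normals with common standard deviation `sigma` and
#' equal priors, the Bayes rule thresholds at the midpoint of the means, and
#' the probability of a correct assignment is
#' `pnorm(|mean_a - mean_b| / (2 sigma))` -- the closed-form ground truth for
#' [estimate_pcd_pair()] on Gaussian channels.
#'
#' @param mean_a,mean_b the two class means.
#' @param sigma common standard deviation (> 0).
#' @return Probability in \[0.5, 1\].
#' @export
oracle_pcd_gaussian <- function(mean_a, mean_b, sigma) {
  if (!is.numeric(sigma) || sigma <= 0) {
    stop("sigma must be > 0", call. = FALSE)
  }
  stats::pnorm(abs(mean_a - mean_b) / (2 * sigma))
}
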