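# posteriors are clipped before any logarithm so that log2() is bounded
# below by log2(.post_clip); keeps Monte-Carlo averages finite when the
# classifier saturates on well-separated data
.post_clip <- 1e-12

clip_probs <- function(p) pmin(pmax(p, .post_clip), 1 - .post_clip)

# resolve a prior specification against a sample's levels
resolve_prior <- function(sample, prior) {
  n <- n_per_level(sample)
  m <- length(n)
  if (is.character(prior) && length(prior) == 1L) {
    prior <- switch(prior,
                    uniform = rep(1 / m, m),
                    empirical = as.numeric(n) / sum(n),
                    stop("unknown prior choice '", prior, "'", call. = FALSE))
  }
  prior <- validate_prior(prior, m)
  if (any(prior == 0)) {
    stop("prior must put positive mass on every observed input level",
         call. = FALSE)
  }
  stats::setNames(prior, names(n))
}

#' Estimate mutual information from classifier posteriors
#'
#' Mutual information between the discrete input X and the (possibly
#' high-dimensional) output Y is estimated without any density estimation:
#' the expectation over P(Y | X = x_i) is replaced by the sample average over
#' that level's cells, and the unknown posterior P(x_i | Y = y) by the fitted
#' logistic posterior, giving
#'
#'   MI(X, Y) ~ sum_i P(x_i) (1/n_i) sum_l log2( Phat(x_i | y_l^i) / P(x_i) ).
#'
#' The model is fitted once at the empirical class frequencies and then
#' re-calibrated to `prior` by the exact intercept adjustment
#' ([reweight_prior()]). The estimate is computed in-sample; use
#' [bootstrap_statistic()] to quantify sampling variability.
#'
#' @param sample a [channel_sample()].
#' @param prior `"uniform"` (default), `"empirical"`, or a strictly positive
#'   probability vector over [input_levels()].
#' @param regularization ridge penalty passed to [fit_posterior()].
#' @param model optionally, a pre-fitted [fit_posterior()] model for this
#'   sample (it is reweighted to `prior`); avoids refitting in sweeps.
#' @return An object of class `mi_result`: list with `mi_bits`,
#'   `prior_used`, `per_class_terms` (the inner averages, in bits, so that
#'   `mi_bits == sum(prior_used * per_class_terms)`), and `model`.
#' @examples
#' s <- simulate_channel(gaussian_shift_spec(c(0, 3)), 200, seed = 1)
#' estimate_mi(s)$mi_bits
#' @export
estimate_mi <- function(sample, prior = "uniform", regularization = 1e-4,
                        model = NULL) {
  stopifnot(inherits(sample, "channel_sample"))
  prior <- resolve_prior(sample, prior)
  if (is.null(model)) {
    model <- fit_posterior(sample, regularization = regularization)
  }
  model <- reweight_prior(model, prior)
  post <- clip_probs(posterior_probs(model, sample$response))
  lev <- input_levels(sample)
  idx <- as.integer(sample$input)
  own <- post[cbind(seq_along(idx), idx)]  # Phat(x_i | y_l^i) for each cell
  terms <- vapply(seq_along(lev), function(i) {
    mean(log2(own[idx == i] / prior[i]))
  }, numeric(1))
  names(terms) <- lev
  structure(list(mi_bits = sum(prior * terms),
                 prior_used = prior,
                 per_class_terms = terms,
                 model = model),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat("<mi_result> MI =", format(x$mi_bits, digits = 4), "bits over",
      length(x$prior_used), "input levels\n")
  invisible(x)
}

#' Per-level expected log-posterior by Monte Carlo averaging
#'
#' Computes, for each input level i, the sample-average log posterior of the
#' correct level under the model Q:
#'
#'   D_i = (1/n_i) sum_l log2 Q(x_i | y_l^i),
#'
#' the Monte-Carlo approximation of the expectation of log2 Q(x_i | Y) under
#' P(Y | X = x_i). These drive the closed-form input-distribution update of
#' the capacity iteration. Posteriors are clipped (1e-12) before the log, so
#' each D_i lies in \[log2(1e-12), 0\].
#'
#' @param model a [fit_posterior()] model.
#' @param sample a [channel_sample()] with the same input levels.
#' @return Named numeric vector D_i (bits), one entry per level; all `<= 0`.
#' @export
monte_carlo_D <- function(model, sample) {
  stopifnot(inherits(model, "posterior_model"),
            inherits(sample, "channel_sample"))
  if (!identical(model$levels, input_levels(sample))) {
    stop("model and sample have different input-level structure",
         call. = FALSE)
  }
  n <- n_per_level(sample)
  if (any(n < 1L)) stop("empty input level", call. = FALSE)
  post <- clip_probs(posterior_probs(model, sample$response))
  idx <- as.integer(sample$input)
  own <- log2(post[cbind(seq_along(idx), idx)])
  D <- vapply(seq_along(model$levels), function(i) mean(own[idx == i]),
              numeric(1))
  stats::setNames(D, model$levels)
}

#' Closed-form input-distribution update of the capacity iteration
#'
#' For a fixed surrogate posterior Q, the input distribution maximizing the
#' capacity lower bound has the closed form P*(x_i) proportional to
#' base^(D_i), a softmax of the per-level expected log-posteriors in the same
#' logarithmic base in which D was accumulated (base 2 for the bit-valued
#' output of [monte_carlo_D()]). Computed with a max-shift, so it is
#' overflow-safe and invariant to adding a constant to all D_i.
#'
#' @param D numeric vector of per-level expected log-posteriors.
#' @param base logarithm base in which `D` is expressed (default 2).
#' @return Probability vector summing to 1, names preserved.
#' @export
capacity_input_update <- function(D, base = 2) {
  if (any(is.na(D))) stop("D must be free of NA", call. = FALSE)
  e <- base^(D - max(D))
  e / sum(e)
}

#' Channel capacity by alternate maximization
#'
#' Estimates the information capacity C* = max over P(X) of MI(X, Y) by the
#' classifier-based alternate-maximization scheme. Capacity is first recast
#' as a double maximization of the auxiliary functional
#' J(P, Q) = sum_i P(x_i) E\[ log2( Q(x_i | Y) / P(x_i) ) | X = x_i \]
#' over the input distribution P and a surrogate posterior Q. Both partial
#' maximizations have closed forms: in P, the softmax of the D_i
#' ([capacity_input_update()]); in Q, the Bayes posterior at the current P,
#' realized here by the logistic model re-calibrated via the intercept
#' adjustment ([reweight_prior()]) -- so the regression is fitted exactly
#' once.
#'
#' The iteration starts from the empirical input frequencies
#' P0(x_i) = n_i / N and the model fitted at them, then alternates: compute
#' D_i under the current model, update P, re-calibrate the model, and record
#'
#'   C_k = sum_i P_k(x_i) ( D_i(Q_k) - log2 P_k(x_i) ).
#'
#' It stops when the lagged trace difference `|C(k-1) - C(k-2)|` drops to
#' `tolerance_bits` or at `max_iterations` (then `converged = FALSE`,
#' without error).
#'
#' @param sample a [channel_sample()].
#' @param max_iterations maximum number of iterations (default 5000).
#' @param tolerance_bits stopping tolerance on the capacity trace, in bits
#'   (default 1e-6).
#' @param regularization ridge penalty passed to [fit_posterior()].
#' @param refit_check if `TRUE`, each iteration additionally refits the
#'   regression from scratch with class weights matching the current input
#'   distribution and records the worst posterior disagreement with the
#'   intercept-updated model (`refit_max_abs_diff`); a diagnostic of the
#'   closed-form prior update, at the cost of one fit per iteration.
#' @return An object of class `capacity_result`: `capacity_bits`,
#'   `optimal_input` (P*), `trace` (C_k per iteration), `iterations`,
#'   `converged`, `D_values` (final D_i, bits), `model` (final re-calibrated
#'   model), and `refit_max_abs_diff` when `refit_check = TRUE`.
#' @examples
#' s <- simulate_channel(disjoint_uniform_spec(4), 100, seed = 1)
#' estimate_capacity(s)$capacity_bits   # ~2 bits: four separable inputs
#' @export
estimate_capacity <- function(sample, max_iterations = 5000L,
                              tolerance_bits = 1e-6,
                              regularization = 1e-4,
                              refit_check = FALSE) {
  stopifnot(inherits(sample, "channel_sample"))
  if (max_iterations < 1L) stop("max_iterations must be >= 1", call. = FALSE)
  if (tolerance_bits <= 0) stop("tolerance_bits must be > 0", call. = FALSE)

  model <- fit_posterior(sample, regularization = regularization)
  lev <- model$levels
  m <- length(lev)
  idx <- as.integer(sample$input)
  # the slope part of the linear scores never changes across iterations;
  # only the intercepts move with the prior
  B <- sample$response %*% t(model$betas)

  D_of <- function(alphas) {
    post <- clip_probs(softmax_posteriors(sweep(B, 2L, alphas, "+")))
    own <- log2(post[cbind(seq_along(idx), idx)])
    vapply(seq_len(m), function(i) mean(own[idx == i]), numeric(1))
  }
  shift_alphas <- function(alphas, p_old, p_new) {
    i <- seq_len(m - 1L)
    alphas + log(p_old[m] / p_old[i]) - log(p_new[m] / p_new[i])
  }

  P <- as.numeric(n_per_level(sample)) / nrow(sample$response)
  alphas <- model$alphas
  C_prev2 <- -Inf   # C(-1)
  C_prev1 <- 0      # C(0)
  trace <- numeric(0)
  refit_diff <- if (refit_check) numeric(0) else NULL
  k <- 0L
  converged <- FALSE

  while (k < max_iterations) {
    if (abs(C_prev1 - C_prev2) <= tolerance_bits) { converged <- TRUE; break }
    k <- k + 1L
    D_prev <- D_of(alphas)
    P_new <- capacity_input_update(D_prev, base = 2)
    alphas <- shift_alphas(alphas, P, P_new)
    P <- P_new
    D_cur <- D_of(alphas)
    C_k <- sum(P * (D_cur - log2(P)))
    trace <- c(trace, C_k)
    if (refit_check) {
      refit <- fit_weighted(sample, P, regularization)
      p_upd <- softmax_posteriors(sweep(B, 2L, alphas, "+"))
      p_ref <- posterior_probs(refit, sample$response)
      refit_diff <- c(refit_diff, max(abs(p_upd - p_ref)))
    }
    C_prev2 <- C_prev1
    C_prev1 <- C_k
  }
  if (!converged && abs(C_prev1 - C_prev2) <= tolerance_bits) {
    converged <- TRUE
  }

  model$alphas <- stats::setNames(alphas, lev[-m])
  model$prior <- stats::setNames(P, lev)
  out <- list(capacity_bits = if (length(trace)) trace[length(trace)] else 0,
              optimal_input = stats::setNames(P, lev),
              trace = trace,
              iterations = length(trace),
              converged = converged,
              D_values = stats::setNames(D_of(alphas), lev),
              model = model)
  if (refit_check) out$refit_max_abs_diff <- max(refit_diff)
  structure(out, class = "capacity_result")
}

# from-scratch fit with class weights matching a target input distribution;
# diagnostic oracle for the intercept-only prior update
fit_weighted <- function(sample, target_prior, regularization) {
  n <- n_per_level(sample)
  w_level <- target_prior / (as.numeric(n) / sum(n))
  w <- w_level[as.integer(sample$input)]
  mu <- colMeans(sample$response)
  sd_ <- apply(sample$response, 2L, stats::sd)
  sd_[sd_ == 0 | !is.finite(sd_)] <- 1
  z <- sweep(sweep(sample$response, 2L, mu, "-"), 2L, sd_, "/")
  lev <- input_levels(sample)
  m <- length(lev)
  df <- data.frame(z)
  names(df) <- paste0("V", seq_len(ncol(z)))
  df$.cls <- factor(sample$input, levels = c(lev[m], lev[-m]))
  df$.w <- w
  fit <- nnet::multinom(.cls ~ . - .w, data = df, weights = df$.w,
                        decay = regularization, maxit = 10000L,
                        reltol = 1e-10, trace = FALSE)
  co <- stats::coef(fit)
  if (m == 2L) co <- matrix(co, nrow = 1L)
  b_std <- co[, -1L, drop = FALSE]
  betas <- sweep(b_std, 2L, sd_, "/")
  alphas <- as.numeric(co[, 1L]) - as.numeric(b_std %*% (mu / sd_))
  dimnames(betas) <- list(lev[-m], colnames(sample$response))
  structure(list(alphas = stats::setNames(alphas, lev[-m]), betas = betas,
                 prior = stats::setNames(as.numeric(target_prior), lev),
                 levels = lev),
            class = "posterior_model")
}

#' @export
print.capacity_result <- function(x, ...) {
  cat("<capacity_result> C* =", format(x$capacity_bits, digits = 4),
      "bits after", x$iterations, "iteration(s)",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  P*:", paste0(names(x$optimal_input), ":",
                      signif(x$optimal_input, 3), collapse = "  "), "\n")
  invisible(x)
}

#' Bootstrap spread of an information estimate
#'
#' Draws stratified subsamples (a fixed fraction of each level's cells,
#' without replacement), recomputes the statistic on each, and summarizes the
#' replicate values. This is the uncertainty protocol used for the temporal
#' information profiles: the point estimate is computed on the full data, and
#' the bootstrap quantifies its sampling variability.
#'
#' @param sample a [channel_sample()].
#' @param statistic `"mi"` or `"capacity"`.
#' @param fraction fraction of each level's cells per replicate, in (0, 1\]
#'   (default 0.8).
#' @param repeats number of replicates (default 100).
#' @param seed integer seed; the replicate vector is reproducible given it.
#' @param ... further arguments passed to [estimate_mi()] or
#'   [estimate_capacity()] (e.g. `prior`, `regularization`).
#' @return List with `mean`, `sd`, `replicates` (numeric vector of length
#'   `repeats`), `statistic`, `fraction`, `seed`.
#' @export
bootstrap_statistic <- function(sample, statistic = c("mi", "capacity"),
                                fraction = 0.8, repeats = 100L, seed = 1L,
                                ...) {
  stopifnot(inherits(sample, "channel_sample"))
  statistic <- match.arg(statistic)
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  if (repeats < 2L) stop("repeats must be >= 2", call. = FALSE)
  n <- n_per_level(sample)
  take <- floor(fraction * as.numeric(n))
  if (any(take < 2L)) {
    stop("fraction too small: fewer than 2 cells would remain for level(s) ",
         paste(names(n)[take < 2L], collapse = ", "), call. = FALSE)
  }
  fun <- switch(statistic,
                mi = function(s) estimate_mi(s, ...)$mi_bits,
                capacity = function(s) estimate_capacity(s, ...)$capacity_bits)
  labels <- as.character(sample$input)
  idx_by_level <- split(seq_along(labels), sample$input)
  set.seed(seed)
  reps <- vapply(seq_len(repeats), function(r) {
    keep <- unlist(lapply(seq_along(idx_by_level), function(i) {
      ix <- idx_by_level[[i]]
      if (take[i] == length(ix)) ix
      else ix[sample.int(length(ix), take[i])]
    }), use.names = FALSE)
    fun(channel_sample(labels[keep], sample$response[keep, , drop = FALSE]))
  }, numeric(1))
  list(mean = mean(reps), sd = stats::sd(reps), replicates = reps,
       statistic = statistic, fraction = fraction, seed = seed)
}
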