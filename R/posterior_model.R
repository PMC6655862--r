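#' Multinomial logistic posterior over input levels
#'
#' The conditional input distribution P(x_i | Y = y) is modeled by assuming
#' the log-ratio against the baseline (last) level x_m is linear in the
#' response:
#'
#'   log( P(x_i | Y = y) / P(x_m | Y = y) ) = alpha_i + beta_i' y,
#'   i = 1, ..., m - 1,
#'
#' so that the posterior is the softmax of the m - 1 linear scores together
#' with an implicit zero score for x_m. A fitted model carries the intercepts
#' `alphas`, the coefficient matrix `betas` ((m-1) x d), the input prior
#' `prior` it is calibrated to, and the level order (baseline last).
#'
#' Fitting maximizes the (optionally ridge-penalized) multinomial likelihood
#' via [nnet::multinom()] on internally standardized responses; coefficients
#' are mapped back to the original response scale, so the linear form above
#' holds in user coordinates. The model is calibrated at the empirical class
#' frequencies of the training data; any other requested prior is imposed
#' afterwards by the exact intercept adjustment of [reweight_prior()], not by
#' resampling.
#'
#' @param sample a [channel_sample()]; every level needs at least 2 cells.
#' @param prior `"empirical"` (default), `"uniform"`, or a probability vector
#'   over [input_levels()] to calibrate the returned model to.
#' @param regularization non-negative ridge penalty (weight decay) applied on
#'   the standardized scale. The default `1e-4` keeps estimates finite when
#'   classes are linearly separable, which is common for well-discriminating
#'   channels; set to 0 for the unpenalized maximum-likelihood fit.
#'
#' @return An object of class `posterior_model` with elements `alphas`
#'   (length m-1), `betas` ((m-1) x d matrix), `prior`, `levels`.
#' @seealso [posterior_probs()], [reweight_prior()]
#' @export
fit_posterior <- function(sample, prior = "empirical", regularization = 1e-4) {
  stopifnot(inherits(sample, "channel_sample"))
  if (!is.numeric(regularization) || length(regularization) != 1L ||
      regularization < 0) {
    stop("`regularization` must be a single non-negative number",
         call. = FALSE)
  }
  n <- n_per_level(sample)
  if (any(n < 2L)) {
    stop("every input level needs at least 2 cells; got ",
         paste0(names(n)[n < 2L], ":", n[n < 2L], collapse = ", "),
         call. = FALSE)
  }
  lev <- input_levels(sample)
  m <- length(lev)
  d <- ncol(sample$response)

  # standardize for optimizer conditioning; constant columns are left as-is
  mu <- colMeans(sample$response)
  sd_ <- apply(sample$response, 2L, stats::sd)
  sd_[sd_ == 0 | !is.finite(sd_)] <- 1
  z <- sweep(sweep(sample$response, 2L, mu, "-"), 2L, sd_, "/")

  df <- data.frame(z)
  names(df) <- paste0("V", seq_len(d))
  # nnet::multinom takes the FIRST factor level as reference; putting the
  # baseline x_m first makes coefficient rows line up with x_1 ... x_{m-1}
  df$.cls <- factor(sample$input, levels = c(lev[m], lev[-m]))

  fit <- nnet::multinom(.cls ~ ., data = df, decay = regularization,
                        maxit = 10000L, reltol = 1e-10, trace = FALSE)
  if (!is.null(fit$convergence) && fit$convergence != 0) {
    stop("logistic-regression optimizer did not converge (value ",
         format(fit$value), "); classes may be linearly separable -- ",
         "use regularization > 0", call. = FALSE)
  }
  co <- stats::coef(fit)
  if (m == 2L) co <- matrix(co, nrow = 1L, dimnames = list(NULL, names(co)))

  b_std <- co[, -1L, drop = FALSE]
  betas <- sweep(b_std, 2L, sd_, "/")
  alphas <- as.numeric(co[, 1L]) - as.numeric(b_std %*% (mu / sd_))
  dimnames(betas) <- list(lev[-m], colnames(sample$response))
  names(alphas) <- lev[-m]

  model <- structure(
    list(alphas = alphas, betas = betas,
         prior = stats::setNames(as.numeric(n) / sum(n), lev),
         levels = lev),
    class = "posterior_model")

  if (is.character(prior) && length(prior) == 1L) {
    if (prior == "empirical") return(model)
    if (prior == "uniform") return(reweight_prior(model, rep(1 / m, m)))
    stop("unknown prior choice '", prior, "'", call. = FALSE)
  }
  reweight_prior(model, validate_prior(prior, m))
}

#' @export
print.posterior_model <- function(x, ...) {
  cat("<posterior_model>", length(x$levels), "input levels (baseline:",
      x$levels[length(x$levels)], "), d =", ncol(x$betas), "\n")
  cat("  prior:", paste0(x$levels, ":", signif(x$prior, 3), collapse = "  "),
      "\n")
  invisible(x)
}

# linear scores alpha_i + beta_i' y for a response matrix (n x d);
# returns n x (m-1)
linear_scores <- function(model, Y) {
  sweep(Y %*% t(model$betas), 2L, model$alphas, "+")
}

# overflow-safe softmax of scores with an implicit 0 score for the baseline;
# returns n x m posterior matrix, columns in level order
softmax_posteriors <- function(scores) {
  eta <- cbind(scores, 0)
  mx <- apply(eta, 1L, max)
  e <- exp(eta - mx)
  e / rowSums(e)
}

#' Posterior input probabilities for responses
#'
#' Evaluates the fitted model's conditional input distribution
#' P(x_i | Y = y) at one response vector or a matrix of responses, using
#' overflow-safe (log-sum-exp) normalization.
#'
#' @param model a [fit_posterior()] model.
#' @param y numeric vector of length d, or an n x d matrix of responses.
#' @return For a vector `y`, a named probability vector over the m levels
#'   (sums to 1 within 1e-12); for a matrix, an n x m matrix of posteriors.
#' @export
posterior_probs <- function(model, y) {
  stopifnot(inherits(model, "posterior_model"))
  d <- ncol(model$betas)
  single <- is.null(dim(y))
  if (single) {
    if (length(y) != d) {
      stop("response has dimension ", length(y), ", model expects ", d,
           call. = FALSE)
    }
    y <- matrix(as.numeric(y), nrow = 1L)
  } else if (ncol(y) != d) {
    stop("response has dimension ", ncol(y), ", model expects ", d,
         call. = FALSE)
  }
  p <- softmax_posteriors(linear_scores(model, y))
  colnames(p) <- model$levels
  if (single) p[1L, ] else p
}

#' Re-calibrate a posterior model to a new input prior
#'
#' Changing the input distribution from P to P' changes only the intercepts
#' of the logistic posterior:
#'
#'   alpha_i' = alpha_i + log( P(x_m) / P(x_i) ) - log( P'(x_m) / P'(x_i) ),
#'
#' while the slope vectors beta_i are unchanged. This closed form makes the
#' prior update exact and free of refitting, which is what allows the
#' capacity iteration ([estimate_capacity()]) to use a single regression fit.
#'
#' @param model a [fit_posterior()] model with strictly positive prior.
#' @param new_prior strictly positive probability vector over the model's
#'   levels.
#' @return A `posterior_model` calibrated to `new_prior`.
#' @export
reweight_prior <- function(model, new_prior) {
  stopifnot(inherits(model, "posterior_model"))
  m <- length(model$levels)
  new_prior <- validate_prior(new_prior, m, "new_prior")
  if (any(new_prior == 0)) {
    stop("new_prior must be strictly positive (intercept undefined at 0)",
         call. = FALSE)
  }
  if (any(model$prior == 0)) {
    stop("model prior has a zero entry; cannot reweight", call. = FALSE)
  }
  old <- model$prior
  i <- seq_len(m - 1L)
  model$alphas <- model$alphas +
    log(old[m] / old[i]) - log(new_prior[m] / new_prior[i])
  model$prior <- stats::setNames(new_prior, model$levels)
  model
}

#' Export / import a posterior model as JSON
#'
#' Serializes intercepts, slopes, prior and level order so fitted models can
#' be stored alongside reports and reloaded exactly.
#'
#' @param model a [fit_posterior()] model.
#' @param path JSON file path.
#' @return `write_posterior_json` returns `path` invisibly;
#'   `read_posterior_json` returns the reconstructed `posterior_model`.
#' @export
write_posterior_json <- function(model, path) {
  stopifnot(inherits(model, "posterior_model"))
  obj <- list(levels = model$levels,
              alphas = as.numeric(model$alphas),
              betas = unname(model$betas),
              prior = as.numeric(model$prior),
              columns = colnames(model$betas))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_posterior_json
#' @export
read_posterior_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lev <- as.character(obj$levels)
  betas <- matrix(as.numeric(obj$betas), nrow = length(lev) - 1L,
                  dimnames = list(lev[-length(lev)],
                                  as.character(obj$columns)))
  structure(
    list(alphas = stats::setNames(as.numeric(obj$alphas),
                                  lev[-length(lev)]),
         betas = betas,
         prior = stats::setNames(as.numeric(obj$prior), lev),
         levels = lev),
    class = "posterior_model")
}
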