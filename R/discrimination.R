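#' Pointwise probability of correct discrimination
#'
#' For two equiprobable inputs, a response `y` is best assigned to the input
#' with the larger posterior, so the probability that this assignment is
#' correct is
#'
#'   PCD(y) = max( P(x_i | Y = y), P(x_j | Y = y) ),
#'
#' which lies in \[0.5, 1\]: 0.5 when the two conditional output
#' distributions overlap completely at `y`, 1 when `y` identifies its input
#' unambiguously. Ties (posterior exactly 1/2) yield 0.5 by the max.
#'
#' @param model a two-level [fit_posterior()] model calibrated to the
#'   equal prior (1/2, 1/2).
#' @param y numeric response vector (length d) or an n x d matrix.
#' @return Probability (or vector of probabilities) in \[0.5, 1\].
#' @export
pcd_pointwise <- function(model, y) {
  stopifnot(inherits(model, "posterior_model"))
  if (length(model$levels) != 2L) {
    stop("PCD is defined for exactly 2 input levels; model has ",
         length(model$levels), call. = FALSE)
  }
  if (max(abs(model$prior - 0.5)) > 1e-9) {
    stop("PCD requires the equal prior (1/2, 1/2); reweight the model first",
         call. = FALSE)
  }
  p <- posterior_probs(model, y)
  if (is.null(dim(p))) max(p) else pmax(p[, 1L], p[, 2L])
}

# deterministic per-pair seed so the matrix is reproducible pair by pair;
# kept below 2^31 - 1
pair_seed <- function(seed, level_a, level_b) {
  h <- sum(utf8ToInt(paste(level_a, level_b, sep = "\r"))) %% 99991L
  (as.integer(seed) %% 20000L) * 100003L + h
}

#' Probability of correct discrimination for one input pair
#'
#' Estimates the overall PCD between two input levels: the model is given the
#' equal prior (1/2, 1/2) so both inputs count equally, and the pointwise
#' maxima are averaged over responses of both levels,
#'
#'   PCD = 1/2 (1/n_i) sum_l max(...) + 1/2 (1/n_j) sum_l max(...).
#'
#' Because a classifier evaluated on its own training data overstates
#' separability, the estimate uses repeated train/test splits: each repeat
#' fits the two-class posterior on a stratified `train_fraction` of cells
#' (re-calibrated to the equal prior by the exact intercept adjustment,
#' regardless of unequal n_i) and averages the pointwise maxima over the
#' held-out cells only. The mean over repeats is the final estimate.
#'
#' @param sample a [channel_sample()] containing both levels (>= 10 cells
#'   each).
#' @param level_a,level_b the two input labels.
#' @param train_fraction fraction of each level's cells used for fitting, in
#'   (0, 1) (default 0.8).
#' @param repeats number of train/test repeats (default 50).
#' @param seed integer seed.
#' @param regularization ridge penalty passed to [fit_posterior()].
#' @return List with `mean`, `sd`, `replicates`, `levels`.
#' @examples
#' s <- simulate_channel(gaussian_shift_spec(c(0, 2)), 500, seed = 1)
#' estimate_pcd_pair(s, "0", "2", repeats = 10, seed = 1)$mean  # ~ pnorm(1)
#' @export
estimate_pcd_pair <- function(sample, level_a, level_b, train_fraction = 0.8,
                              repeats = 50L, seed = 1L,
                              regularization = 1e-4) {
  stopifnot(inherits(sample, "channel_sample"))
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  level_a <- as.character(level_a)
  level_b <- as.character(level_b)
  pairdat <- subset_levels(sample, c(level_a, level_b))
  n <- n_per_level(pairdat)
  if (any(n < 10L)) {
    stop("both levels need at least 10 cells; got ",
         paste0(names(n), ":", n, collapse = ", "), call. = FALSE)
  }
  labels <- as.character(pairdat$input)
  idx_by_level <- split(seq_along(labels), pairdat$input)
  n_train <- pmax(2L, floor(train_fraction * as.numeric(n)))
  if (any(as.numeric(n) - n_train < 1L)) {
    stop("train_fraction leaves no test cells for some level", call. = FALSE)
  }

  set.seed(seed)
  reps <- vapply(seq_len(repeats), function(r) {
    train <- unlist(lapply(seq_along(idx_by_level), function(i) {
      ix <- idx_by_level[[i]]
      ix[sample.int(length(ix), n_train[i])]
    }), use.names = FALSE)
    test <- setdiff(seq_along(labels), train)
    fit <- fit_posterior(
      channel_sample(labels[train], pairdat$response[train, , drop = FALSE]),
      prior = c(0.5, 0.5), regularization = regularization)
    pcd_y <- pcd_pointwise(fit, pairdat$response[test, , drop = FALSE])
    grp <- labels[test]
    mean(vapply(input_levels(pairdat), function(l) mean(pcd_y[grp == l]),
                numeric(1)))
  }, numeric(1))
  list(mean = mean(reps), sd = stats::sd(reps), replicates = reps,
       levels = c(level_a, level_b))
}

#' Pairwise discrimination matrix
#'
#' Applies [estimate_pcd_pair()] to every unordered pair of input levels and
#' assembles the symmetric m x m matrix of mean PCDs together with the
#' bootstrap standard deviations. Each pair uses a seed derived
#' deterministically from `seed` and the pair's labels, so any single pair
#' can be recomputed independently with an identical result.
#'
#' @param sample a [channel_sample()] with m >= 2 levels.
#' @inheritParams estimate_pcd_pair
#' @return An object of class `pcd_matrix`: list with `levels`, `values`
#'   (m x m, diagonal `NA`), `spread` (bootstrap sd, diagonal `NA`).
#' @export
estimate_pcd_matrix <- function(sample, train_fraction = 0.8, repeats = 50L,
                                seed = 1L, regularization = 1e-4) {
  stopifnot(inherits(sample, "channel_sample"))
  lev <- input_levels(sample)
  m <- length(lev)
  values <- matrix(NA_real_, m, m, dimnames = list(lev, lev))
  spread <- values
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      est <- tryCatch(
        estimate_pcd_pair(sample, lev[i], lev[j],
                          train_fraction = train_fraction, repeats = repeats,
                          seed = pair_seed(seed, lev[i], lev[j]),
                          regularization = regularization),
        error = function(e) {
          stop("PCD estimation failed for pair (", lev[i], ", ", lev[j],
               "): ", conditionMessage(e), call. = FALSE)
        })
      values[i, j] <- values[j, i] <- est$mean
      spread[i, j] <- spread[j, i] <- est$sd
    }
  }
  structure(list(levels = lev, values = values, spread = spread),
            class = "pcd_matrix")
}

#' @export
print.pcd_matrix <- function(x, digits = 3, ...) {
  cat("<pcd_matrix>", length(x$levels), "input levels\n")
  print(round(x$values, digits))
  invisible(x)
}

#' Difference between two discrimination matrices
#'
#' Elementwise `matrix_b - matrix_a` over a shared level set; used to compare
#' representations of the same cells, e.g. how much discriminability
#' full trajectories add over a single time point.
#'
#' @param matrix_a,matrix_b [estimate_pcd_matrix()] results with identical
#'   levels.
#' @return A `pcd_matrix`-shaped object whose `values` are the differences
#'   and whose `spread` is the root-sum-square of the two spreads.
#' @export
pcd_difference <- function(matrix_a, matrix_b) {
  stopifnot(inherits(matrix_a, "pcd_matrix"), inherits(matrix_b, "pcd_matrix"))
  if (!identical(matrix_a$levels, matrix_b$levels)) {
    stop("PCD matrices have different level sets", call. = FALSE)
  }
  structure(list(levels = matrix_a$levels,
                 values = matrix_b$values - matrix_a$values,
                 spread = sqrt(matrix_a$spread^2 + matrix_b$spread^2)),
            class = "pcd_matrix")
}

#' Write a discrimination matrix as CSV
#'
#' Levels appear as both header and row names; the diagonal is empty.
#'
#' @param pcd a `pcd_matrix`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_pcd_csv <- function(pcd, path) {
  stopifnot(inherits(pcd, "pcd_matrix"))
  utils::write.csv(as.data.frame(pcd$values), path, row.names = TRUE)
  invisible(path)
}
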