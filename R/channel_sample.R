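#' Empirical channel: labeled single-cell responses
#'
#' A `channel_sample` holds the empirical input-output channel of a signaling
#' experiment: for each of `m` discrete input levels (e.g. ligand
#' concentrations), a set of real-valued output vectors of common dimension
#' `d` (e.g. a single readout, or successive time points of a trajectory).
#' One row of the response matrix is one cell.
#'
#' Input levels are ordered deterministically: if every label parses as a
#' number, ascending numeric order; otherwise lexicographic (C locale). The
#' last level in this ordering is the baseline class of the logistic
#' posterior model (see [fit_posterior()]).
#'
#' @param input vector of input labels, one per cell (numeric or character).
#' @param response numeric matrix (cells x output dimensions) or a vector for
#'   one-dimensional outputs. Column names, when numeric, are interpreted as
#'   measurement stamps (e.g. minutes); otherwise stamps default to the
#'   1-based column index.
#'
#' @return An object of class `channel_sample`: a list with elements
#'   `input` (factor, levels in canonical order), `response` (numeric
#'   matrix) and `stamps` (numeric vector of column stamps).
#' @examples
#' s <- channel_sample(c(0, 0, 1, 1), matrix(rnorm(8), 4, 2))
#' input_levels(s)
#' n_per_level(s)
#' @export
channel_sample <- function(input, response) {
  if (is.null(dim(response))) {
    response <- matrix(as.numeric(response), ncol = 1)
  }
  response <- as.matrix(response)
  storage.mode(response) <- "double"
  if (length(input) != nrow(response)) {
    stop("`input` must have one entry per response row (", length(input),
         " labels vs ", nrow(response), " rows)", call. = FALSE)
  }
  if (nrow(response) < 1L || ncol(response) < 1L) {
    stop("response matrix must have at least one row and one column",
         call. = FALSE)
  }
  bad <- which(!is.finite(response), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-finite response values in rows: ",
         paste(utils::head(sort(unique(bad[, 1L])), 10L), collapse = ", "),
         call. = FALSE)
  }
  labels <- as.character(input)
  if (anyNA(labels)) stop("missing input labels", call. = FALSE)
  levels <- order_levels(unique(labels))
  if (length(levels) < 2L) {
    stop("m >= 2 required: need at least two distinct input levels",
         call. = FALSE)
  }
  if (is.null(colnames(response))) {
    colnames(response) <- paste0("output", seq_len(ncol(response)))
  }
  out <- structure(
    list(input = factor(labels, levels = levels),
         response = response,
         stamps = column_stamps(colnames(response))),
    class = "channel_sample")
  out
}

# canonical level order: numeric ascending when all labels parse, else
# lexicographic in the C locale (radix sort) for reproducibility
order_levels <- function(labels) {
  num <- suppressWarnings(as.numeric(labels))
  if (!anyNA(num)) labels[order(num)] else sort(labels, method = "radix")
}

# numeric headers become stamps; anything else falls back to column index
column_stamps <- function(nms) {
  num <- suppressWarnings(as.numeric(nms))
  if (!anyNA(num)) num else seq_along(nms)
}

#' @export
print.channel_sample <- function(x, ...) {
  n <- n_per_level(x)
  cat("<channel_sample> m =", length(n), "input levels, d =",
      ncol(x$response), "output dimension(s)\n")
  cat("  cells per level:",
      paste0(names(n), ":", n, collapse = "  "), "\n")
  invisible(x)
}

#' Input levels of a channel sample
#' @param sample a [channel_sample()].
#' @return Character vector of the m input labels in canonical order.
#' @export
input_levels <- function(sample) {
  stopifnot(inherits(sample, "channel_sample"))
  levels(sample$input)
}

#' Number of cells per input level
#' @param sample a [channel_sample()].
#' @return Named integer vector n_i, aligned to [input_levels()].
#' @export
n_per_level <- function(sample) {
  stopifnot(inherits(sample, "channel_sample"))
  table(sample$input)[input_levels(sample)]
}

#' Read a delimited single-cell response table
#'
#' Reads a table with one row per cell: one column holding the input
#' (stimulus) label and the remaining columns holding numeric output
#' dimensions, and validates it into a [channel_sample()].
#'
#' @param path path to a delimited text file with a header row.
#' @param delimiter field delimiter (default comma).
#' @param input_column name of the input-label column (default `"input"`).
#' @return A validated [channel_sample()].
#' @export
read_channel_table <- function(path, delimiter = ",", input_column = "input") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!input_column %in% names(df)) {
    stop("input column '", input_column, "' not found; columns are: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
  out_cols <- setdiff(names(df), input_column)
  if (length(out_cols) < 1L) stop("no output columns found", call. = FALSE)
  resp <- df[out_cols]
  non_num <- !vapply(resp, is.numeric, logical(1))
  if (any(non_num)) {
    # point at the offending cells rather than just failing the coercion
    for (cn in out_cols[non_num]) {
      v <- suppressWarnings(as.numeric(resp[[cn]]))
      bad <- which(is.na(v) & !is.na(resp[[cn]]))
      if (length(bad) > 0L) {
        stop("non-numeric output values in column '", cn, "', rows: ",
             paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
      }
      resp[[cn]] <- v
    }
  }
  resp <- as.matrix(resp)
  if (anyNA(resp)) {
    bad <- sort(unique(which(is.na(resp), arr.ind = TRUE)[, 1L]))
    stop("missing output values in rows: ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  channel_sample(df[[input_column]], resp)
}

#' Write a channel sample as a delimited table
#'
#' Inverse of [read_channel_table()]: one row per cell, input labels in the
#' first column. Values round-trip up to text precision (15 significant
#' digits).
#'
#' @param sample a [channel_sample()].
#' @param path output file path.
#' @param delimiter field delimiter (default comma).
#' @param input_column header for the input column (default `"input"`).
#' @return Invisibly, `path`.
#' @export
write_channel_table <- function(sample, path, delimiter = ",",
                                input_column = "input") {
  stopifnot(inherits(sample, "channel_sample"))
  df <- data.frame(as.character(sample$input),
                   format(sample$response, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(input_column, colnames(sample$response))
  ok <- tryCatch({
    utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                       quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write '", path, "': ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Single time-point view of a trajectory sample
#'
#' Restricts the response to the single output column with stamp `t`, so each
#' cell is represented by one number -- the readout at that time.
#'
#' @param sample a [channel_sample()] whose columns are ordered measurement
#'   stamps.
#' @param t a column stamp (numeric header value, or 1-based index when
#'   headers are not numeric).
#' @return A d = 1 [channel_sample()]; input structure unchanged.
#' @export
time_point_view <- function(sample, t) {
  stopifnot(inherits(sample, "channel_sample"))
  j <- match(t, sample$stamps)
  if (is.na(j)) {
    stop("unknown column stamp ", t, "; available: ",
         paste(sample$stamps, collapse = ", "), call. = FALSE)
  }
  out <- sample
  out$response <- sample$response[, j, drop = FALSE]
  out$stamps <- sample$stamps[j]
  attr(out, "view") <- list(mode = "time_point", stamp = t)
  out
}

#' Cumulative time-window view of a trajectory sample
#'
#' Restricts the response to all output columns with stamp `<= t`, so each
#' cell is represented by the vector of measurements from the start of the
#' experiment up to time `t`.
#'
#' @inheritParams time_point_view
#' @return A [channel_sample()] whose columns are the prefix of the parent's
#'   columns with stamps `<= t`.
#' @export
time_window_view <- function(sample, t) {
  stopifnot(inherits(sample, "channel_sample"))
  if (!t %in% sample$stamps) {
    stop("unknown column stamp ", t, "; available: ",
         paste(sample$stamps, collapse = ", "), call. = FALSE)
  }
  keep <- which(sample$stamps <= t)
  out <- sample
  out$response <- sample$response[, keep, drop = FALSE]
  out$stamps <- sample$stamps[keep]
  attr(out, "view") <- list(mode = "time_window", stamp = t)
  out
}

#' Transform the response columns of a channel sample
#'
#' Applies an elementwise transformation (e.g. `log` for intensity data whose
#' conditional distributions are log-normal, making the Bayes posterior
#' log-ratio linear in the transformed response). The result is validated, so
#' transformations producing non-finite values fail loudly.
#'
#' @param sample a [channel_sample()].
#' @param fun vectorized numeric function applied to the response matrix.
#' @return A [channel_sample()] with transformed responses.
#' @export
transform_response <- function(sample, fun) {
  stopifnot(inherits(sample, "channel_sample"))
  resp <- fun(sample$response)
  resp <- matrix(as.numeric(resp), nrow = nrow(sample$response),
                 dimnames = dimnames(sample$response))
  channel_sample(as.character(sample$input), resp)
}

#' Restrict a channel sample to a subset of input levels
#'
#' @param sample a [channel_sample()].
#' @param levels input labels to keep (at least two).
#' @return A [channel_sample()] containing only cells of the given levels.
#' @export
subset_levels <- function(sample, levels) {
  stopifnot(inherits(sample, "channel_sample"))
  levels <- as.character(levels)
  missing <- setdiff(levels, input_levels(sample))
  if (length(missing) > 0L) {
    stop("input level(s) not present: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  keep <- sample$input %in% levels
  channel_sample(as.character(sample$input)[keep],
                 sample$response[keep, , drop = FALSE])
}

# validate a probability vector over the m input levels
validate_prior <- function(prior, m, what = "prior") {
  if (!is.numeric(prior) || length(prior) != m) {
    stop(what, " must be a numeric vector of length ", m, call. = FALSE)
  }
  if (any(!is.finite(prior)) || any(prior < 0)) {
    stop(what, " must be finite and non-negative", call. = FALSE)
  }
  if (abs(sum(prior) - 1) > 1e-12) {
    stop(what, " must sum to 1 (got ", format(sum(prior)), ")", call. = FALSE)
  }
  as.numeric(prior)
}
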