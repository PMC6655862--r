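# fixtures built in code: small labeled channels with known structure

make_gaussian_sample <- function(means, n, sigma = 1, seed = 1,
                                 labels = NULL) {
  set.seed(seed)
  if (is.null(labels)) labels <- as.character(means)
  y <- unlist(lapply(means, function(m) rnorm(n, m, sigma)))
  channel_sample(rep(labels, each = n), y)
}

make_identical_sample <- function(m, n, seed = 1) {
  set.seed(seed)
  channel_sample(rep(letters[seq_len(m)], each = n), rnorm(m * n))
}

make_trajectory_sample <- function(n = 200, seed = 1) {
  # three time stamps; level separation grows with time, so later windows
  # carry strictly more information
  set.seed(seed)
  lab <- rep(c("low", "high"), each = n)
  shift <- ifelse(lab == "high", 1, 0)
  resp <- cbind(rnorm(2 * n, 0.2 * shift),
                rnorm(2 * n, 1.0 * shift),
                rnorm(2 * n, 2.0 * shift))
  colnames(resp) <- c(3, 6, 9)
  channel_sample(lab, resp)
}
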