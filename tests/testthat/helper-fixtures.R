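# shared fixtures, built once per test run

patterns17 <- build_pattern_pairs(generate_group_table(17))

# independent oracle: modular exponentiation by square-and-multiply,
# a different route than the repeated-multiplication cycle in the package
powmod <- function(a, e, p) {
  r <- 1
  b <- a %% p
  while (e > 0) {
    if (e %% 2 == 1) r <- (r * b) %% p
    b <- (b * b) %% p
    e <- e %/% 2
  }
  r
}

# independent oracle: literal per-window, per-bit reference extractor
naive_cgp_extract <- function(signal, patterns) {
  p <- patterns$p
  wlen <- p - 1L
  nbin <- 2L^patterns$bit_width
  H <- nrow(patterns$left)
  out <- integer(H * nbin)
  for (i in seq_len(length(signal) - wlen + 1L)) {
    win <- signal[i:(i + wlen - 1L)]
    for (h in seq_len(H)) {
      code <- 0L
      for (k in seq_len(patterns$bit_width)) {
        bit <- (win[patterns$left[h, k]] - win[patterns$right[h, k]]) >= 0
        code <- code + as.integer(bit) * 2L^(k - 1L)
      }
      j <- (h - 1L) * nbin + code + 1L
      out[j] <- out[j] + 1L
    }
  }
  out
}

# small deterministic two-class feature matrix: class clusters shifted by
# `gap` noise standard deviations in every dimension
make_separable_X <- function(n_per_class = 20, d = 5, gap = 10, seed = 42) {
  set.seed(seed)
  y <- rep(0:1, each = n_per_class)
  X <- matrix(rnorm(2 * n_per_class * d), ncol = d) + y * gap
  list(X = X, y = y)
}
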