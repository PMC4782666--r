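# Independent oracles and fixture builders. Everything here is written
# deliberately naively (triple loops, closed-form formulas) so the tests
# cross-check the package implementation rather than restate it.

# Naive valid-position 3x3 correlation: one output pixel at a time.
naive_conv_valid <- function(img, kernel) {
  m <- nrow(img)
  n <- ncol(img)
  out <- matrix(0, m - 2, n - 2)
  for (i in seq_len(m - 2)) {
    for (j in seq_len(n - 2)) {
      acc <- 0
      for (u in 1:3) {
        for (v in 1:3) {
          acc <- acc + kernel[u, v] * img[i + u - 1, j + v - 1]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

naive_compass_responses <- function(img) {
  vapply(robinson_kernels(), function(k) max(abs(naive_conv_valid(img, k))),
         numeric(1))
}

# A tile with a vertical intensity step of the given height between two
# adjacent interior columns.
step_tile <- function(h = 16, w = 16, step = 10, at = w %/% 2) {
  m <- matrix(0, h, w)
  m[, (at + 1):w] <- step
  m
}

random_tile <- function(h = 16, w = 16) {
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}

rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])

# Closed-form paired t (textbook formula, independent of stats::t.test).
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

# Closed-form Welch t with Welch-Satterthwaite df.
oracle_welch_t <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# A small deterministic textured stack with integer intensities <= limit,
# suitable for exact gain-invariance checks.
textured_stack <- function(n_slices = 2, size = 64, limit = 100, seed = 404) {
  withr::with_seed(seed, {
    slices <- lapply(seq_len(n_slices), function(i) {
      matrix(sample(0:limit, size * size, replace = TRUE), size, size)
    })
    slice_stack(slices, sprintf("textured_%d", seed))
  })
}
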