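# shared test fixtures, all generated in code

# seeded random 8-bit image
rand_image <- function(n, m = n, seed = 1) {
  set.seed(seed)
  matrix(sample(0:255, n * m, replace = TRUE), n, m)
}

# deterministic analytic image pair used for the SSIM cross-implementation
# check; the frozen reference value was computed on exactly these matrices
ssim_fixture_pair <- function() {
  S <- 32
  X <- matrix(seq_len(S), S, S); Y <- t(X)
  a <- round(pmin(pmax(127.5 + 80 * sin(X / 3) * cos(Y / 5) +
                         30 * exp(-((X - 16)^2 + (Y - 16)^2) / 50), 0), 255))
  b <- round(pmin(pmax(a + 12 * cos(X * 0.7) * sin(Y * 0.45) + 5, 0), 255))
  list(a = a, b = b)
}

# centroid (intensity-weighted mean position) of an absolute difference image
diff_centroid <- function(d) {
  w <- abs(d)
  tot <- sum(w)
  c(row = sum(row(d) * w) / tot, col = sum(col(d) * w) / tot)
}
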