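#' Structural similarity index (SSIM) for grayscale images
#'
#' Mean local SSIM with an 11 x 11 Gaussian window (sigma = 1.5), data range
#' 255, and the standard stabilization constants C1 = (0.01 * 255)^2,
#' C2 = (0.03 * 255)^2. Local means, variances and covariance use the
#' Gaussian window as weights (population form, no sample-covariance
#' correction); the map of local SSIM values is cropped by the window radius
#' before averaging so only fully supported windows contribute.
#'
#' @param a,b numeric matrices of equal dimensions, intensities on the 0..255
#'   scale.
#' @param data_range dynamic range of the data (default 255 for 8-bit).
#' @return a single number in \[-1, 1\] (in practice \[0, 1\] for images);
#'   1 means identical images.
#' @export
ssim_index <- function(a, b, data_range = 255) {
  check_image(a, "a"); check_image(b, "b")
  if (!all(dim(a) == dim(b)))
    stop("images differ in dimensions", call. = FALSE)
  r <- 5L # radius: 11 x 11 window
  if (any(dim(a) < 2L * r + 1L))
    stop("images smaller than the 11x11 SSIM window", call. = FALSE)
  k <- exp(-((-r):r)^2 / (2 * 1.5^2))
  k <- k / sum(k)
  f <- function(m) gauss_filter2(m, k)
  mu_a <- f(a); mu_b <- f(b)
  va <- f(a * a) - mu_a^2
  vb <- f(b * b) - mu_b^2
  cab <- f(a * b) - mu_a * mu_b
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  S <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
       ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  S <- S[(r + 1L):(nrow(S) - r), (r + 1L):(ncol(S) - r), drop = FALSE]
  mean(S)
}

# separable Gaussian filter with replicate (nearest) edge padding
gauss_filter2 <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(m); p <- ncol(m)
  mp <- m[c(rep(1L, r), 1:n, rep(n, r)), , drop = FALSE]
  out <- matrix(0, n, p)
  for (j in seq_along(k)) out <- out + k[j] * mp[j:(j + n - 1L), , drop = FALSE]
  mp <- out[, c(rep(1L, r), 1:p, rep(p, r)), drop = FALSE]
  out <- matrix(0, n, p)
  for (j in seq_along(k)) out <- out + k[j] * mp[, j:(j + p - 1L), drop = FALSE]
  out
}
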