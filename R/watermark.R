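#' Watermarking keys
#'
#' Bundles the secret material of the scheme: the locality pair
#' \code{(p1, p2)} (key set K1, fixing where in the image the payload lands),
#' the quantization step \code{delta} (key K2, the embedding strength), and
#' the integer \code{seed} that generates the dither vectors.
#'
#' @param p1,p2 locality parameters in (0, 1); p1 positions the embedding
#'   region vertically (rows), p2 horizontally (columns).
#' @param delta quantization step, > 0. Larger values give a wider decoding
#'   margin (delta/4) and a more visible watermark.
#' @param seed integer seed for the dither generator; part of the key.
#' @return object of class \code{"wm_keys"}.
#' @export
wm_keys <- function(p1, p2, delta, seed = 0L) {
  check_p(p1, "p1"); check_p(p2, "p2")
  check_scalar(delta, "delta")
  if (delta <= 0) stop("'delta' must be positive", call. = FALSE)
  check_scalar(seed, "seed")
  structure(list(p1 = p1, p2 = p2, delta = delta, seed = as.integer(seed)),
            class = "wm_keys")
}

#' @export
print.wm_keys <- function(x, ...) {
  cat(sprintf("Watermark keys: p1=%g, p2=%g, delta=%g, seed=%d\n",
              x$p1, x$p2, x$delta, x$seed))
  invisible(x)
}

#' Carrier-moment schedule
#'
#' Deterministically assigns message bits to moment orders: enumerate
#' \code{(n, m)} in zigzag order of ascending total order \code{n + m} (ties
#' by ascending \code{n}), skip the DC moment \code{(0, 0)} -- modifying it
#' would shift global brightness -- and take the first \code{L} pairs. Low
#' orders carry the bits because that is where the locality of the basis is
#' strongest.
#'
#' @param L message length in bits; at most \code{N*M - 1}.
#' @param N,M image dimensions (rows, columns).
#' @return integer matrix \code{L x 2} with 0-based columns \code{(n, m)}.
#' @examples
#' wm_schedule(3, 8, 8) # (0,1), (1,0), (0,2)
#' @export
wm_schedule <- function(L, N, M) {
  check_scalar(L, "L")
  if (L != round(L) || L < 1) stop("'L' must be a positive integer", call. = FALSE)
  if (L > N * M - 1)
    stop(sprintf("message length %d exceeds capacity %d for a %dx%d image",
                 L, N * M - 1, N, M), call. = FALSE)
  out <- matrix(0L, L, 2L, dimnames = list(NULL, c("n", "m")))
  got <- 0L
  for (s in 0:((N - 1L) + (M - 1L))) {
    for (n in max(0L, s - (M - 1L)):min(s, N - 1L)) {
      m <- s - n
      if (n == 0L && m == 0L) next
      got <- got + 1L
      out[got, ] <- c(n, m)
      if (got == L) return(out)
    }
  }
  out # unreachable given the capacity check
}

#' Dither vectors for quantization index modulation
#'
#' Draws \code{d_i(0)} i.i.d. uniform on \code{[0, delta)} from a seeded
#' generator and sets \code{d_i(1) = (d_i(0) + delta/2) mod delta}, so the
#' two codebooks are lattices offset by exactly half a step. The seed is key
#' material: embedder and decoder must share it.
#'
#' @param L number of dither pairs (message length).
#' @param delta quantization step, > 0.
#' @param seed integer seed; identical inputs give identical vectors.
#' @return list with numeric vectors \code{d0} and \code{d1}, both in
#'   \code{[0, delta)}.
#' @export
wm_dither <- function(L, delta, seed = 0L) {
  check_scalar(L, "L")
  if (L != round(L) || L < 1) stop("'L' must be a positive integer", call. = FALSE)
  check_scalar(delta, "delta")
  if (delta <= 0) stop("'delta' must be positive", call. = FALSE)
  d0 <- with_seed(seed, stats::runif(L, 0, delta))
  list(d0 = d0, d1 = (d0 + delta / 2) %% delta)
}

#' Dither-modulation quantizer
#'
#' \code{Ktilde = round((K - d(b)) / delta) * delta + d(b)}: snaps the host
#' moment onto the lattice of the bit being embedded. The perturbation never
#' exceeds \code{delta/2}. Vectorized over all arguments.
#'
#' @param K host moment value(s).
#' @param bit bit(s) in \{0, 1\}.
#' @param delta quantization step.
#' @param d0,d1 dither value(s) for bit 0 / bit 1.
#' @return modified moment value(s).
#' @examples
#' wm_quantize(10.3, 1, 4, d0 = 1, d1 = 3) # 11
#' @export
wm_quantize <- function(K, bit, delta, d0, d1) {
  if (any(bit != 0 & bit != 1)) stop("'bit' must be 0 or 1", call. = FALSE)
  n <- max(length(K), length(bit), length(d0), length(d1))
  bit <- rep_len(bit, n)
  d <- ifelse(bit == 1, rep_len(d1, n), rep_len(d0, n))
  round((rep_len(K, n) - d) / delta) * delta + d
}

#' Embed a binary message by dither modulation of Krawtchouk moments
#'
#' The pipeline: build the per-axis orthonormal bases for \code{(p1, N)} and
#' \code{(p2, M)}; compute the carrier moments on the zigzag schedule; snap
#' each onto the lattice of its bit with \code{\link{wm_quantize}}; expand the
#' moment changes back to the pixel domain,
#' \code{w(x,y) = sum_i (Ktilde_i - K_i) Kbar_{n_i}(x) Kbar_{m_i}(y)}; and add
#' \code{w} to the image. By orthonormality the carrier moments of
#' \code{image + w} equal \code{Ktilde} exactly and all other moments are
#' untouched.
#'
#' The real-valued watermarked image is kept alongside its 8-bit export
#' (clip to \[0, 255\], round half-to-even); SSIM is computed between the
#' original and the export.
#'
#' @param image numeric \code{N x M} matrix on the 0..255 scale.
#' @param bits integer vector of 0/1 message bits (length L).
#' @param keys \code{\link{wm_keys}} object.
#' @return object of class \code{"wm_embedding"}: list with
#'   \code{watermarked} (real-valued), \code{exported} (8-bit), \code{bits},
#'   \code{keys}, \code{schedule}, \code{moments} (carrier values before),
#'   \code{moments_modified} (after), \code{ssim}, and
#'   \code{clipped_pixel_count}.
#' @export
wm_embed <- function(image, bits, keys) {
  check_image(image)
  stopifnot(inherits(keys, "wm_keys"))
  bits <- check_bits(bits)
  L <- length(bits)
  N <- nrow(image); M <- ncol(image)
  sched <- wm_schedule(L, N, M)
  bx <- basis_cached(keys$p1, N)
  by <- basis_cached(keys$p2, M)
  K <- kraw_moments(image, bx, by, orders = sched)
  dith <- wm_dither(L, keys$delta, keys$seed)
  Kt <- wm_quantize(K$values, bits, keys$delta, dith$d0, dith$d1)
  dK <- Kt - K$values
  A <- bx$values[sched[, 1L] + 1L, , drop = FALSE] # L x N
  B <- by$values[sched[, 2L] + 1L, , drop = FALSE] # L x M
  w <- crossprod(A, dK * B)                        # N x M watermark signal
  marked <- image + w
  exp8 <- export_uint8(marked)
  structure(list(watermarked = marked, exported = exp8$pixels,
                 signal = w, bits = bits, keys = keys, schedule = sched,
                 moments = K$values, moments_modified = Kt,
                 ssim = ssim_index(image, exp8$pixels),
                 clipped_pixel_count = exp8$clipped),
            class = "wm_embedding")
}

#' @export
print.wm_embedding <- function(x, ...) {
  cat(sprintf("Watermark embedding: %d bits into a %d x %d image\n",
              length(x$bits), nrow(x$watermarked), ncol(x$watermarked)))
  print(x$keys)
  cat(sprintf("  SSIM vs original: %.4f; pixels clipped at export: %d\n",
              x$ssim, x$clipped_pixel_count))
  invisible(x)
}

#' Visualize an embedding
#'
#' Three panels: the original image (watermarked minus signal), the 8-bit
#' watermarked export, and the absolute watermark signal (contrast-stretched),
#' which makes the embedding locality controlled by (p1, p2) visible.
#'
#' @param x \code{"wm_embedding"} object.
#' @param ... ignored.
#' @export
plot.wm_embedding <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  show_gray(x$watermarked - x$signal, "original")
  show_gray(x$exported, "watermarked (8-bit)")
  a <- abs(x$signal)
  show_gray(a / max(a, 1e-12) * 255, "|watermark signal|")
  invisible(x)
}

show_gray <- function(img, main) {
  graphics::image(t(img)[, nrow(img):1], col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, main = main, useRaster = TRUE)
}

#' Extract a message by minimum-distance dither-modulation decoding
#'
#' For each scheduled carrier moment \code{K'}, the decoder quantizes onto
#' both codebooks and picks the nearer one:
#' \code{bhat_i = argmin_b |K' - Q_b(K')|}, ties resolved to bit 0. With the
#' correct keys and an unperturbed real-valued watermarked image this inverts
#' \code{\link{wm_embed}} exactly; perturbations below \code{delta/4} per
#' moment are tolerated.
#'
#' @param image numeric \code{N x M} matrix (watermarked, possibly perturbed).
#' @param keys \code{\link{wm_keys}} used at embedding.
#' @param L message length used at embedding.
#' @return integer vector of L decoded bits.
#' @export
wm_extract <- function(image, keys, L) {
  check_image(image)
  stopifnot(inherits(keys, "wm_keys"))
  sched <- wm_schedule(L, nrow(image), ncol(image))
  bx <- basis_cached(keys$p1, nrow(image))
  by <- basis_cached(keys$p2, ncol(image))
  Kp <- kraw_moments(image, bx, by, orders = sched)$values
  dith <- wm_dither(L, keys$delta, keys$seed)
  e0 <- abs(Kp - wm_quantize(Kp, 0, keys$delta, dith$d0, dith$d1))
  e1 <- abs(Kp - wm_quantize(Kp, 1, keys$delta, dith$d0, dith$d1))
  as.integer(e1 < e0) # tie -> bit 0
}

#' Bit error rate between two equal-length messages
#'
#' @param sent,received integer 0/1 vectors of equal length.
#' @return fraction of differing positions, in \[0, 1\].
#' @export
bit_error_rate <- function(sent, received) {
  sent <- check_bits(sent); received <- check_bits(received)
  if (length(sent) != length(received))
    stop("messages differ in length", call. = FALSE)
  mean(sent != received)
}

#' Seeded random message
#'
#' @param L message length.
#' @param seed integer seed.
#' @return integer vector of L bits.
#' @export
random_message <- function(L, seed = 0L) {
  check_scalar(L, "L")
  if (L != round(L) || L < 1) stop("'L' must be a positive integer", call. = FALSE)
  with_seed(seed, sample(0:1, L, replace = TRUE))
}

check_bits <- function(bits) {
  if (!is.numeric(bits) && !is.logical(bits))
    stop("message bits must be numeric or logical 0/1", call. = FALSE)
  bits <- as.integer(bits)
  if (length(bits) < 1L || any(is.na(bits)) || any(bits != 0L & bits != 1L))
    stop("message bits must be 0 or 1", call. = FALSE)
  bits
}
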