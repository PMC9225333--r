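#' Watermarking attack on a single image
#'
#' Embeds a seeded random L-bit message with keys \code{(p1, p2, delta,
#' seed)} and returns the 8-bit export -- the adversarial image. Only the
#' embedding half of the watermarking scheme is exercised: the attack's
#' effect is the local distortion itself, not a recoverable payload.
#'
#' @param image numeric matrix on the 0..255 scale.
#' @param p1,p2 locality parameters in (0, 1).
#' @param delta quantization step (embedding strength), > 0.
#' @param L message length in bits.
#' @param seed integer seed for both the random message and the dither.
#' @return 8-bit integer-valued matrix of the same dimensions.
#' @export
attack_image <- function(image, p1, p2, delta, L, seed = 0L) {
  wm_embed(image, random_message(L, seed), wm_keys(p1, p2, delta, seed))$exported
}

#' Attack parameter grid
#'
#' Default values are the study grid: locality values 0.1 to 0.9 in steps of
#' 0.1 (all 81 (p1, p2) pairs examined per cell), message lengths 100 to
#' 1000 in steps of 100, and embedding strengths 50, 100, 200, 300.
#'
#' @param p_values locality values, each in (0, 1).
#' @param l_values message lengths (positive integers).
#' @param delta_values embedding strengths (positive).
#' @param seed integer seed; per-image message seeds derive from it.
#' @return object of class \code{"sweep_grid"}.
#' @export
sweep_grid <- function(p_values = seq(0.1, 0.9, by = 0.1),
                       l_values = seq(100L, 1000L, by = 100L),
                       delta_values = c(50, 100, 200, 300),
                       seed = 1L) {
  for (p in p_values) check_p(p, "p_values")
  if (any(l_values < 1) || any(l_values != round(l_values)))
    stop("'l_values' must be positive integers", call. = FALSE)
  if (any(delta_values <= 0))
    stop("'delta_values' must be positive", call. = FALSE)
  check_scalar(seed, "seed")
  structure(list(p_values = as.numeric(p_values),
                 l_values = as.integer(l_values),
                 delta_values = as.numeric(delta_values),
                 seed = as.integer(seed)),
            class = "sweep_grid")
}

#' @export
print.sweep_grid <- function(x, ...) {
  cat(sprintf("Attack sweep grid: %d p-values x %d -> %d (p1,p2) pairs; L in {%s}; delta in {%s}; seed %d\n",
              length(x$p_values), length(x$p_values), length(x$p_values)^2,
              paste(x$l_values, collapse = ","),
              paste(x$delta_values, collapse = ","), x$seed))
  invisible(x)
}

#' Sweep the watermarking attack over a parameter grid
#'
#' For every (L, delta) cell, attacks every image with every (p1, p2) pair
#' of the grid, evaluates the classifier on the attacked images, and selects
#' the most effective pair: minimum attacked accuracy, ties broken by higher
#' mean SSIM (stealthier attack), then by lexicographic (p1, p2). Each image
#' carries its own random message, seeded by \code{grid$seed + image index},
#' so results are fully reproducible. Images are processed in dataset order.
#'
#' @param images non-empty list of image matrices (0..255 scale).
#' @param labels true labels, one per image.
#' @param classifier fitted object with a \code{predict} method or a
#'   function mapping an image to a label (see
#'   \code{\link{evaluate_accuracy}}).
#' @param grid \code{\link{sweep_grid}} object.
#' @param details if \code{TRUE}, attach a long-format data frame of all
#'   examined (cell, pair) results as attribute \code{"details"}.
#' @return data frame of class \code{"sweep_result"} with one row per
#'   (L, delta) cell and columns \code{L}, \code{delta}, \code{p1_best},
#'   \code{p2_best}, \code{mean_ssim}, \code{accuracy},
#'   \code{clean_accuracy}.
#' @export
attack_sweep <- function(images, labels, classifier, grid = sweep_grid(),
                         details = FALSE) {
  stopifnot(inherits(grid, "sweep_grid"))
  if (!is.list(images) || length(images) == 0L)
    stop("'images' must be a non-empty list", call. = FALSE)
  if (length(labels) != length(images))
    stop("one label per image required", call. = FALSE)
  clean_acc <- evaluate_accuracy(classifier, images, labels)
  pv <- grid$p_values
  # lexicographic (p1, p2) enumeration order: p1 outer, p2 inner
  pairs <- cbind(p1 = rep(pv, each = length(pv)), p2 = rep(pv, length(pv)))
  n_img <- length(images)
  rows <- vector("list", length(grid$delta_values) * length(grid$l_values))
  det <- if (details) vector("list", length(rows)) else NULL
  ri <- 0L
  for (delta in grid$delta_values) for (L in grid$l_values) {
    ri <- ri + 1L
    acc <- mss <- numeric(nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      preds <- numeric(n_img); ssims <- numeric(n_img)
      keys0 <- list(p1 = pairs[k, 1L], p2 = pairs[k, 2L])
      for (i in seq_len(n_img)) {
        seed_i <- grid$seed + i
        emb <- wm_embed(images[[i]], random_message(L, seed_i),
                        wm_keys(keys0$p1, keys0$p2, delta, seed_i))
        ssims[i] <- emb$ssim
        preds[i] <- classify_batch(classifier, list(emb$exported))
      }
      acc[k] <- mean(preds == labels)
      mss[k] <- mean(ssims)
    }
    best <- which(acc == min(acc))
    if (length(best) > 1L) best <- best[mss[best] == max(mss[best])]
    best <- best[1L] # lexicographic (p1, p2) order of enumeration
    rows[[ri]] <- data.frame(L = L, delta = delta,
                             p1_best = pairs[best, 1L], p2_best = pairs[best, 2L],
                             mean_ssim = mss[best], accuracy = acc[best],
                             clean_accuracy = clean_acc)
    if (details)
      det[[ri]] <- data.frame(L = L, delta = delta, p1 = pairs[, 1L],
                              p2 = pairs[, 2L], mean_ssim = mss, accuracy = acc)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  if (details) attr(out, "details") <- do.call(rbind, det)
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Attack sweep: %d (L, delta) cells; clean accuracy %.4f\n",
              nrow(x), x$clean_accuracy[1L]))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
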