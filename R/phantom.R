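#' Synthetic grayscale medical-like phantom
#'
#' Generates a deterministic 8-bit phantom: a smooth elliptical "anatomy"
#' whose shape is jittered by the seed, a class-dependent set of bright
#' elliptical lesions, a border vignette, and additive Gaussian noise
#' (sigma = 5 intensity units). Phantoms stand in for clinical images in all
#' tests and demos: they give the toy classifier learnable class structure
#' (lesion count and placement depend only on \code{class_label}) and a
#' spatial layout on which the locality of the watermark is visible.
#'
#' The seeded random draws are consumed in a fixed order independent of the
#' class label, so two phantoms with the same seed but different classes are
#' identical outside the union of their lesion regions.
#'
#' @param size pixels per axis, between 32 and 512.
#' @param class_label non-negative integer; class \code{c} gets \code{c + 1}
#'   lesions at class-specific positions.
#' @param seed integer seed controlling anatomy jitter and noise.
#' @param style background style: \code{"mri"} (dark inner ventricle),
#'   \code{"xray"} (gradient-lit body), or \code{"ct"} (bright outer ring).
#' @return integer-valued numeric matrix \code{size x size} in \[0, 255\].
#' @export
phantom_image <- function(size = 128, class_label = 0, seed = 1,
                          style = c("mri", "xray", "ct")) {
  style <- match.arg(style)
  check_scalar(size, "size")
  if (size != round(size) || size < 32 || size > 512)
    stop("'size' must be an integer in [32, 512]", call. = FALSE)
  check_scalar(class_label, "class_label")
  if (class_label != round(class_label) || class_label < 0)
    stop("'class_label' must be a non-negative integer", call. = FALSE)
  S <- as.integer(size)
  # fixed draw order: 7 jitters then S^2 noise values, independent of class
  rng <- with_seed(seed, list(jit = stats::runif(7, -1, 1),
                              noise = stats::rnorm(S * S, 0, 5)))
  jit <- rng$jit
  X <- matrix(seq_len(S), S, S)        # row coordinate (vertical, x)
  Y <- matrix(seq_len(S), S, S, byrow = TRUE)
  cx <- S * (0.5 + 0.01 * jit[1]); cy <- S * (0.5 + 0.01 * jit[2])
  ax <- S * (0.38 + 0.02 * jit[3]); ay <- S * (0.32 + 0.02 * jit[4])
  base <- 115 + 2 * jit[5]   # small common-mode jitter: keeps classes separable
  ell <- function(scale) ((X - cx) / (ax * scale))^2 + ((Y - cy) / (ay * scale))^2 <= 1
  body <- ell(1)
  # backgrounds sit on a raised pedestal: the moment-domain embedder needs
  # 8-bit headroom at the strongest study setting (delta = 300), or clipping
  # at export would corrupt the dither-modulated carrier moments
  img <- matrix(switch(style, xray = 60, mri = 50, ct = 45), S, S)
  if (style == "xray") {
    img[body] <- base + 25 * (X[body] / S)
  } else if (style == "mri") {
    img[body] <- base + 20
    inner <- ell(0.45)
    img[inner] <- base - 40
  } else { # ct: bright shell around a softer interior
    img[body] <- 175 + 5 * jit[6]
    inner <- ell(0.85)
    img[inner] <- base - 15
  }
  # class-dependent lesions: geometry is a pure function of the class label
  n_les <- class_label + 1
  phi <- 0.9 * class_label
  rl <- S / 12
  for (j in seq_len(n_les)) {
    th <- phi + 2 * pi * (j - 1) / n_les
    lx <- cx + 0.55 * ax * cos(th)
    ly <- cy + 0.55 * ay * sin(th)
    d2 <- ((X - lx)^2 + (Y - ly)^2) / rl^2
    bump <- 50 * pmax(0, 1 - d2)     # compactly supported: exact zero outside
    img <- img + bump
  }
  dn <- (((X - (S + 1) / 2)^2 + (Y - (S + 1) / 2)^2) / (2 * ((S - 1) / 2)^2))
  img <- img * (1 - 0.15 * dn)       # border vignette
  img <- img + matrix(rng$noise, S, S)
  export_uint8(img)$pixels
}

#' Balanced labeled phantom dataset
#'
#' Generates \code{n_per_class * n_classes} phantoms with 0-based integer
#' class labels, each from its own derived seed, shuffled into a stable
#' seed-determined order.
#'
#' @param n_per_class images per class, >= 1.
#' @param n_classes number of classes, >= 2.
#' @param size pixels per axis.
#' @param seed integer master seed; per-image seeds are
#'   \code{seed + 7919 * k} for image index \code{k}.
#' @param style passed to \code{\link{phantom_image}}.
#' @return object of class \code{"phantom_set"}: list with \code{images}
#'   (list of matrices), \code{labels} (integer vector), and the generating
#'   parameters.
#' @export
phantom_dataset <- function(n_per_class, n_classes, size = 128, seed = 1,
                            style = "mri") {
  check_scalar(n_per_class, "n_per_class"); check_scalar(n_classes, "n_classes")
  if (n_per_class < 1 || n_per_class != round(n_per_class))
    stop("'n_per_class' must be a positive integer", call. = FALSE)
  if (n_classes < 2 || n_classes != round(n_classes))
    stop("'n_classes' must be an integer >= 2", call. = FALSE)
  labels <- rep(0:(n_classes - 1L), each = n_per_class)
  k <- seq_along(labels) - 1L
  imgs <- mapply(function(lab, kk) {
    phantom_image(size, lab, seed + 7919L * kk, style)
  }, labels, k, SIMPLIFY = FALSE)
  ord <- with_seed(seed, sample(length(labels)))
  structure(list(images = imgs[ord], labels = labels[ord],
                 n_per_class = n_per_class, n_classes = n_classes,
                 size = size, seed = seed, style = style),
            class = "phantom_set")
}

#' @export
print.phantom_set <- function(x, ...) {
  cat(sprintf("Phantom dataset: %d images (%d classes x %d), %dx%d, style '%s', seed %d\n",
              length(x$images), x$n_classes, x$n_per_class, x$size, x$size,
              x$style, x$seed))
  invisible(x)
}
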