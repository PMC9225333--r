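# internal helpers shared across modules

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

check_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop(sprintf("'%s' must be a numeric matrix", arg), call. = FALSE)
  if (nrow(image) < 2L || ncol(image) < 2L)
    stop(sprintf("'%s' must be at least 2x2", arg), call. = FALSE)
  if (!all(is.finite(image)))
    stop(sprintf("'%s' contains non-finite intensities", arg), call. = FALSE)
  invisible(image)
}

check_scalar <- function(x, arg) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", arg), call. = FALSE)
  invisible(x)
}

#' Clip and round a real-valued image to 8-bit
#'
#' Clamps intensities to \[0, 255\] and rounds half-to-even, the export step
#' applied whenever an image leaves the real-valued internal representation.
#'
#' @param image numeric matrix of intensities.
#' @return list with \code{pixels} (integer-valued matrix in \[0, 255\]) and
#'   \code{clipped} (count of pixels that were clamped).
#' @export
export_uint8 <- function(image) {
  check_image(image)
  clipped <- sum(image < 0 | image > 255)
  list(pixels = round(pmin(pmax(image, 0), 255)), clipped = clipped)
}
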