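#' Forward Krawtchouk moment transform
#'
#' Computes the discrete orthogonal Krawtchouk moments
#' \code{K_nm = sum_x sum_y Kbar_n(x; p1, N-1) Kbar_m(y; p2, M-1) f(x, y)}
#' of an \code{N x M} image. Rows of the image index the vertical axis
#' \code{x} (controlled by \code{basis_x}, locality \code{p1}); columns index
#' the horizontal axis \code{y} (\code{basis_y}, locality \code{p2}).
#'
#' @param image numeric \code{N x M} matrix \code{f(x, y)}.
#' @param basis_x \code{\link{kraw_basis}} of size \code{N} (rows).
#' @param basis_y \code{\link{kraw_basis}} of size \code{M} (columns).
#' @param orders \code{NULL} for the complete \code{N*M} moment set, or an
#'   integer matrix with columns \code{(n, m)} (0-based) selecting moments.
#' @return an object of class \code{"kraw_moments"}: list with \code{orders}
#'   (L x 2 integer matrix), \code{values} (numeric vector, one per order
#'   pair), \code{dim} (source image dimensions) and \code{full} (logical).
#' @export
kraw_moments <- function(image, basis_x, basis_y, orders = NULL) {
  check_image(image)
  stopifnot(inherits(basis_x, "kraw_basis"), inherits(basis_y, "kraw_basis"))
  if (basis_x$size != nrow(image) || basis_y$size != ncol(image))
    stop(sprintf("basis sizes (%d, %d) do not match image dimensions (%d, %d)",
                 basis_x$size, basis_y$size, nrow(image), ncol(image)),
         call. = FALSE)
  K <- basis_x$values %*% image %*% t(basis_y$values)
  if (is.null(orders)) {
    ord <- as.matrix(expand.grid(n = 0:(nrow(image) - 1L),
                                 m = 0:(ncol(image) - 1L)))
    vals <- as.vector(K) # column-major: n fastest, matching expand.grid
    full <- TRUE
  } else {
    ord <- check_orders(orders, nrow(image), ncol(image))
    vals <- K[cbind(ord[, 1L] + 1L, ord[, 2L] + 1L)]
    full <- FALSE
  }
  structure(list(orders = ord, values = vals,
                 dim = c(nrow(image), ncol(image)), full = full,
                 p = c(basis_x$p, basis_y$p)),
            class = "kraw_moments")
}

#' Inverse Krawtchouk moment transform
#'
#' Reconstructs the real-valued image
#' \code{fhat(x, y) = sum_n sum_m K_nm Kbar_n(x) Kbar_m(y)} from a complete
#' moment set. Because the bases are orthonormal the round trip
#' \code{kraw_reconstruct(kraw_moments(f, ...), ...)} reproduces \code{f} to
#' machine precision.
#'
#' @param moments complete \code{\link{kraw_moments}} object (all \code{N*M}
#'   order pairs).
#' @inheritParams kraw_moments
#' @return numeric \code{N x M} matrix (real-valued; not clipped or rounded).
#' @export
kraw_reconstruct <- function(moments, basis_x, basis_y) {
  stopifnot(inherits(moments, "kraw_moments"),
            inherits(basis_x, "kraw_basis"), inherits(basis_y, "kraw_basis"))
  N <- moments$dim[1L]; M <- moments$dim[2L]
  if (basis_x$size != N || basis_y$size != M)
    stop("basis sizes do not match the moments' source dimensions", call. = FALSE)
  if (!isTRUE(moments$full) || length(moments$values) != N * M)
    stop(sprintf("reconstruction needs the complete moment set (%d orders); got %d",
                 N * M, length(moments$values)), call. = FALSE)
  K <- matrix(moments$values, N, M)
  t(basis_x$values) %*% K %*% basis_y$values
}

#' @export
print.kraw_moments <- function(x, ...) {
  cat(sprintf("Krawtchouk moment set: %d moment(s) of a %d x %d image (p1=%g, p2=%g)%s\n",
              length(x$values), x$dim[1L], x$dim[2L], x$p[1L], x$p[2L],
              if (isTRUE(x$full)) " [complete]" else ""))
  invisible(x)
}

check_orders <- function(orders, N, M) {
  orders <- as.matrix(orders)
  if (ncol(orders) != 2L || !is.numeric(orders) || any(orders != round(orders)))
    stop("'orders' must be an integer matrix with columns (n, m)", call. = FALSE)
  storage.mode(orders) <- "integer"
  if (any(orders[, 1L] < 0L) || any(orders[, 1L] >= N) ||
      any(orders[, 2L] < 0L) || any(orders[, 2L] >= M))
    stop("moment orders out of range for the image dimensions", call. = FALSE)
  if (anyDuplicated(paste(orders[, 1L], orders[, 2L])))
    stop("duplicate (n, m) order pairs", call. = FALSE)
  dimnames(orders) <- list(NULL, c("n", "m"))
  orders
}
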