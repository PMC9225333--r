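#' Binomial weight function of the Krawtchouk polynomials
#'
#' \code{w(x; p, N) = choose(N, x) p^x (1-p)^(N-x)} for \code{x = 0..N}: the
#' binomial(N, p) probability mass function. Its mass centre \code{p*N} is what
#' makes low-order Krawtchouk moments local descriptors: the weight (and hence
#' the energy of the low-order orthonormal basis functions) concentrates
#' around \code{x = p*N}.
#'
#' @param p locality parameter, in (0, 1).
#' @param N support degree; the weight is defined on \code{x = 0..N}.
#' @return numeric vector of length \code{N + 1}, strictly positive, summing
#'   to 1.
#' @examples
#' kraw_weight(0.5, 2) # 0.25 0.50 0.25
#' @export
kraw_weight <- function(p, N) {
  check_p(p)
  check_support(N)
  x <- 0:N
  # log-space: stable for N up to hundreds even at extreme p
  exp(lchoose(N, x) + x * log(p) + (N - x) * log1p(-p))
}

#' Norm of the (unweighted) Krawtchouk polynomials
#'
#' \code{rho(n; p, N) = ((1-p)/p)^n * n! * (N-n)! / N!} for \code{n = 0..N},
#' the squared norm of \code{K_n} under the binomial weight, written with the
#' standard rising-factorial Pochhammer symbol resolved:
#' \code{(-N)_n = (-1)^n N!/(N-n)!}. \code{rho(0) = 1} always.
#'
#' @inheritParams kraw_weight
#' @param log if \code{TRUE}, return \code{log(rho)} (useful for large
#'   \code{N} where \code{rho} itself over/underflows).
#' @return numeric vector of length \code{N + 1}, all entries strictly
#'   positive (or their logs).
#' @examples
#' kraw_norm(0.5, 4)[2] # rho(1; 0.5, 4) = 0.25
#' @export
kraw_norm <- function(p, N, log = FALSE) {
  check_p(p)
  check_support(N)
  n <- 0:N
  lr <- n * (log1p(-p) - base::log(p)) + lfactorial(n) + lfactorial(N - n) - lfactorial(N)
  if (log) lr else exp(lr)
}

#' Orthonormal weighted Krawtchouk basis
#'
#' Builds the matrix \code{V} with \code{V[n+1, x+1] = Kbar_n(x; p, size-1)},
#' the weighted Krawtchouk polynomial \code{Kbar_n = K_n * sqrt(w/rho)}, for
#' \code{n, x = 0..size-1}. Rows are orthonormal, so \code{V} is an orthogonal
#' matrix and the forward/inverse moment transforms are exact inverses.
#'
#' Rather than iterating the three-term recurrence in \code{n} (which loses
#' orthogonality catastrophically beyond size ~32 for p far from 0.5), the
#' recurrence is solved globally: its symmetric tridiagonal Jacobi matrix has
#' eigenvalues exactly \code{0..size-1} and eigenvectors equal to the basis
#' columns, so a LAPACK symmetric eigendecomposition yields the basis with
#' machine-precision orthonormality at any size up to the 512 cap. Column
#' signs are fixed by \code{Kbar_0(x) = sqrt(w(x)) > 0}.
#'
#' @param p locality parameter in (0, 1); low-order rows peak near
#'   \code{x = p * (size - 1)}.
#' @param size number of support points (image axis length), >= 2; the
#'   polynomial degree parameter is \code{size - 1}.
#' @return an object of class \code{"kraw_basis"}: list with \code{values}
#'   (the \code{size x size} matrix \code{V}), \code{p}, and \code{size}.
#' @examples
#' b <- kraw_basis(0.5, 16)
#' max(abs(tcrossprod(b$values) - diag(16))) # ~1e-15
#' @export
kraw_basis <- function(p, size) {
  check_p(p)
  if (!is.numeric(size) || length(size) != 1L || size != round(size) || size < 2)
    stop("'size' must be an integer >= 2", call. = FALSE)
  if (size > 512)
    stop("'size' exceeds the 512-pixel-per-axis cap; resize explicitly first",
         call. = FALSE)
  size <- as.integer(size)
  N <- size - 1L
  n <- 0:N
  # Jacobi matrix of x * Kbar_n(x) = a_n Kbar_n - c_n Kbar_{n+1} - c_{n-1} Kbar_{n-1}
  J <- diag(N * p + n * (1 - 2 * p), size)
  if (N >= 1L) {
    off <- -sqrt(p * (1 - p) * (1:N) * (N:1))
    J[cbind(1:N, 2:size)] <- off
    J[cbind(2:size, 1:N)] <- off
  }
  e <- eigen(J, symmetric = TRUE)
  V <- e$vectors[, order(e$values), drop = FALSE] # column x+1 <-> eigenvalue x
  V <- fix_column_signs(V)
  dev <- max(abs(tcrossprod(V) - diag(size)))
  if (dev >= 1e-6)
    stop(sprintf("basis construction failed orthonormality (deviation %.2e) at p=%g, size=%d",
                 dev, p, size), call. = FALSE)
  structure(list(values = V, p = p, size = size), class = "kraw_basis")
}

#' @export
print.kraw_basis <- function(x, ...) {
  cat(sprintf("Weighted Krawtchouk basis: size %d, p = %g\n", x$size, x$p))
  cat(sprintf("  low-order energy centred near x = %.1f (0-based)\n",
              x$p * (x$size - 1)))
  invisible(x)
}

# Resolve the sign ambiguity of each eigenvector column. Column 0 is the
# all-positive square-root weight. For x > 0 the duality K_n(x) = K_x(n)
# forces V[n, x] = V[x, n]; the sign of column x is read off against the
# already-signed columns at the best-resolved entry. The first-entry rule
# (Kbar_0(x) = sqrt(w(x)) > 0) alone fails for extreme p at large sizes,
# where sqrt(w(x)) underflows below the eigensolver's noise floor.
fix_column_signs <- function(V) {
  size <- ncol(V)
  tol <- 1e-6
  signed <- logical(size)
  # anchor columns whose square-root-weight entry is well resolved
  anchor <- abs(V[1L, ]) > tol
  V[, anchor & V[1L, ] < 0] <- -V[, anchor & V[1L, ] < 0, drop = FALSE]
  signed[anchor] <- TRUE
  # propagate outward wherever the mutual entry pair is well resolved
  while (!all(signed)) {
    progressed <- FALSE
    for (x in which(!signed)) {
      js <- which(signed)
      ov <- pmin(abs(V[x, js]), abs(V[js, x]))
      best <- which.max(ov)
      if (ov[best] > tol) {
        j <- js[best]
        if (sign(V[x, j]) != sign(V[j, x])) V[, x] <- -V[, x]
        signed[x] <- TRUE
        progressed <- TRUE
      }
    }
    if (!progressed) { # remaining columns are noise-level: best effort
      for (x in which(!signed)) {
        js <- which(signed)
        ov <- pmin(abs(V[x, js]), abs(V[js, x]))
        j <- js[which.max(ov)]
        if (sign(V[x, j]) != sign(V[j, x])) V[, x] <- -V[, x]
      }
      break
    }
  }
  V
}

check_p <- function(p, arg = "p") {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
    stop(sprintf("'%s' must lie strictly inside (0, 1)", arg), call. = FALSE)
  invisible(p)
}

check_support <- function(N) {
  if (!is.numeric(N) || length(N) != 1L || N != round(N) || N < 1)
    stop("'N' must be an integer >= 1", call. = FALSE)
  invisible(N)
}

# small per-session cache so sweeps do not rebuild identical bases
.basis_cache <- new.env(parent = emptyenv())

basis_cached <- function(p, size) {
  key <- paste(format(p, digits = 17), size, sep = "|")
  b <- .basis_cache[[key]]
  if (is.null(b)) {
    b <- kraw_basis(p, size)
    .basis_cache[[key]] <- b
  }
  b
}
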