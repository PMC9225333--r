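#' Nearest-centroid toy classifier on block-averaged features
#'
#' A deliberately simple, deterministic stand-in for a trained vision model:
#' each image is reduced to an 8 x 8 grid of block-mean intensities (64
#' features) and a query is assigned the class of the nearest per-class
#' feature centroid (Euclidean distance, ties to the lowest label). Training
#' is closed-form (per-class means), so permuting the training order leaves
#' the model unchanged.
#'
#' @param images list of numeric matrices (equal dimensions).
#' @param labels integer class labels, one per image; at least 2 classes
#'   with at least 2 images each.
#' @return object of class \code{"centroid_classifier"} with a
#'   \code{predict} method accepting a single image matrix or a list of them.
#' @export
toy_classifier <- function(images, labels) {
  if (!is.list(images) || length(images) == 0L)
    stop("'images' must be a non-empty list of matrices", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != length(images))
    stop("one label per image required", call. = FALSE)
  tab <- table(labels)
  if (length(tab) < 2L || any(tab < 2L))
    stop("need >= 2 classes with >= 2 images each", call. = FALSE)
  feats <- t(vapply(images, block_features, numeric(64)))
  classes <- sort(unique(labels))
  centroids <- t(vapply(classes, function(cl) colMeans(feats[labels == cl, , drop = FALSE]),
                        numeric(64)))
  structure(list(classes = classes, centroids = centroids), class = "centroid_classifier")
}

#' @export
print.centroid_classifier <- function(x, ...) {
  cat(sprintf("Nearest-centroid classifier: %d classes, 64 block-mean features\n",
              length(x$classes)))
  invisible(x)
}

#' @rdname toy_classifier
#' @param object fitted \code{"centroid_classifier"}.
#' @param newdata a single image matrix or a list of image matrices.
#' @param ... ignored.
#' @export
predict.centroid_classifier <- function(object, newdata, ...) {
  if (is.matrix(newdata)) newdata <- list(newdata)
  vapply(newdata, function(img) {
    f <- block_features(img)
    d2 <- rowSums(sweep(object$centroids, 2L, f)^2)
    object$classes[which.min(d2)] # which.min: first (lowest label) on ties
  }, integer(1))
}

# 8x8 block-mean features; handles sizes not divisible by 8
block_features <- function(img) {
  check_image(img)
  bi <- floor((seq_len(nrow(img)) - 1L) * 8L / nrow(img)) + 1L
  bj <- floor((seq_len(ncol(img)) - 1L) * 8L / ncol(img)) + 1L
  sums <- rowsum(t(rowsum(img, bi)), bj)        # 8 x 8 block sums (transposed)
  cnt <- outer(tabulate(bj, 8L), tabulate(bi, 8L))
  as.vector(sums / cnt)
}

#' Classification accuracy of an opaque classifier on a labeled set
#'
#' The classifier may be a fitted object with a \code{predict} method (e.g.
#' \code{\link{toy_classifier}}) or a plain function mapping one image matrix
#' to a label -- the contract a black-box attack needs.
#'
#' @param classifier fitted object or \code{function(image) -> label}.
#' @param images non-empty list of image matrices.
#' @param labels true labels, one per image.
#' @return fraction of correct predictions, in \[0, 1\].
#' @export
evaluate_accuracy <- function(classifier, images, labels) {
  if (!is.list(images) || length(images) == 0L)
    stop("'images' must be a non-empty list", call. = FALSE)
  if (length(labels) != length(images))
    stop("one label per image required", call. = FALSE)
  preds <- classify_batch(classifier, images)
  mean(preds == labels)
}

classify_batch <- function(classifier, images) {
  if (is.function(classifier))
    unlist(lapply(images, function(im) classifier(im)[[1L]]), use.names = FALSE)
  else
    predict(classifier, images)
}
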