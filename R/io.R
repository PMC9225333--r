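#' Load an 8-bit grayscale image
#'
#' Reads PNG, PGM (P2 ASCII or P5 binary), or TIFF. RGB inputs are converted
#' to grayscale with the ITU-R BT.601 luma weights (0.299, 0.587, 0.114);
#' an alpha channel, if present, is ignored. Bit depths other than 8 are
#' rejected. Intensities are returned on the 0..255 scale; matrix rows run
#' top to bottom (the vertical axis steered by p1).
#'
#' @param path file path; format is chosen by extension
#'   (\code{.png}, \code{.pgm}, \code{.tif}/\code{.tiff}).
#' @return numeric matrix with integer values in \[0, 255\].
#' @export
load_image <- function(path) {
  if (!file.exists(path))
    stop(sprintf("image file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = {
      depth <- png_bit_depth(path)
      if (depth != 8L)
        stop(sprintf("unsupported bit depth %d in %s (8-bit required)", depth, path),
             call. = FALSE)
      png::readPNG(path) * 255
    },
    pgm = read_pgm(path),
    tif = ,
    tiff = {
      im <- tiff::readTIFF(path, info = TRUE)
      bps <- attr(im, "bits.per.sample")
      if (!is.null(bps) && bps != 8L)
        stop(sprintf("unsupported bit depth %d in %s (8-bit required)", bps, path),
             call. = FALSE)
      im * 255
    },
    stop(sprintf("unsupported image format '%s' for %s (PNG/PGM/TIFF supported)",
                 ext, path), call. = FALSE)
  )
  if (length(dim(arr)) == 3L) {
    ch <- dim(arr)[3L]
    arr <- if (ch >= 3L)
      0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L]
    else arr[, , 1L]
  }
  matrix(round(arr), nrow(arr), ncol(arr)) # drop reader metadata attributes
}

#' Save an image as 8-bit PNG, PGM, or TIFF
#'
#' Values are clipped to \[0, 255\] and rounded before writing.
#'
#' @param image numeric matrix on the 0..255 scale.
#' @param path output path; format chosen by extension.
#' @param ascii for PGM only: write ASCII P2 instead of binary P5.
#' @return the path, invisibly.
#' @export
save_image <- function(image, path, ascii = FALSE) {
  px <- export_uint8(image)$pixels
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(px / 255, path),
    pgm = write_pgm(px, path, ascii = ascii),
    tif = ,
    tiff = tiff::writeTIFF(px / 255, path, bits.per.sample = 8L),
    stop(sprintf("unsupported image format '%s' (PNG/PGM/TIFF supported)", ext),
         call. = FALSE)
  )
  invisible(path)
}

# bit depth byte of the PNG IHDR chunk (offset 24, 0-based)
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  if (length(hdr) < 26L || !identical(hdr[1:4], as.raw(c(0x89, 0x50, 0x4e, 0x47))))
    stop(sprintf("not a PNG file: %s", path), call. = FALSE)
  as.integer(hdr[25L])
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_pnm_token(con)
  if (!magic %in% c("P2", "P5"))
    stop(sprintf("not a PGM file (magic '%s'): %s", magic, path), call. = FALSE)
  w <- as.integer(read_pnm_token(con))
  h <- as.integer(read_pnm_token(con))
  maxval <- as.integer(read_pnm_token(con))
  if (is.na(w) || is.na(h) || is.na(maxval) || w < 1L || h < 1L)
    stop(sprintf("malformed PGM header in %s", path), call. = FALSE)
  if (maxval > 255L)
    stop(sprintf("unsupported bit depth (maxval %d) in %s (8-bit required)",
                 maxval, path), call. = FALSE)
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", n = w * h))
  } else {
    as.integer(scan(con, what = integer(), n = w * h, quiet = TRUE,
                    comment.char = "#"))
  }
  if (length(vals) != w * h)
    stop(sprintf("truncated PGM data in %s", path), call. = FALSE)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) * (255 / maxval)
}

# one whitespace-delimited header token, skipping '#' comments
read_pnm_token <- function(con) {
  tok <- character(0)
  repeat {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) break
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
      next
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(tok) > 0L) break else next
    }
    tok <- c(tok, ch)
  }
  paste(tok, collapse = "")
}

write_pgm <- function(px, path, ascii = FALSE) {
  h <- nrow(px); w <- ncol(px)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(w, h), "255"), con)
    write(t(px), con, ncolumns = w)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", w, h), con, eos = NULL)
    writeBin(as.raw(as.integer(t(px))), con)
  }
  invisible(path)
}

#' Read a binary message from an ASCII bit file
#'
#' Accepts any whitespace-separated arrangement of '0'/'1' characters.
#'
#' @param path file of ASCII 0/1 characters.
#' @return integer vector of bits.
#' @export
read_bits <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  txt <- gsub("[[:space:]]", "", txt)
  if (nchar(txt) == 0L || grepl("[^01]", txt))
    stop(sprintf("bit file %s must contain only '0'/'1' characters", path),
         call. = FALSE)
  as.integer(strsplit(txt, "")[[1L]])
}

#' Write a sweep report as CSV
#'
#' Columns (in order): \code{L,delta,p1_best,p2_best,mean_ssim,accuracy,}
#' \code{clean_accuracy}; floats carry 4 decimal places; rows are sorted by
#' (delta, L). Refuses to write an empty report.
#'
#' @param records \code{\link{attack_sweep}} result (or compatible data
#'   frame).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_sweep_report <- function(records, path) {
  cols <- c("L", "delta", "p1_best", "p2_best", "mean_ssim", "accuracy",
            "clean_accuracy")
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("empty sweep report: nothing to write", call. = FALSE)
  if (!all(cols %in% names(records)))
    stop(sprintf("sweep records missing columns: %s",
                 paste(setdiff(cols, names(records)), collapse = ", ")),
         call. = FALSE)
  records <- records[order(records$delta, records$L), cols]
  lines <- c(paste(cols, collapse = ","),
             sprintf("%d,%g,%.4f,%.4f,%.4f,%.4f,%.4f",
                     as.integer(records$L), records$delta, records$p1_best,
                     records$p2_best, records$mean_ssim, records$accuracy,
                     records$clean_accuracy))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sweep configuration file
#'
#' YAML with the blocks:
#' \itemize{
#'   \item \code{dataset}: either \code{glob} + \code{labels} (a CSV with
#'     columns \code{path,label}) for images on disk, or \code{phantoms}
#'     with \code{classes}, \code{per_class}, \code{size}, optional
#'     \code{style}, for generated data;
#'   \item \code{grid}: optional \code{p_values}, \code{l_values},
#'     \code{delta_values} (defaults: the full study grid);
#'   \item \code{seed}: integer;
#'   \item \code{classifier}: \code{"centroid"} (train the bundled
#'     nearest-centroid model on the dataset) or \code{script: path} to an R
#'     file defining \code{make_classifier(images, labels)}.
#' }
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
read_sweep_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$dataset))
    stop("sweep config needs a 'dataset' block", call. = FALSE)
  if (is.null(cfg$dataset$glob) && is.null(cfg$dataset$phantoms))
    stop("dataset block needs either 'glob' + 'labels' or a 'phantoms' block",
         call. = FALSE)
  if (!is.null(cfg$dataset$glob) && is.null(cfg$dataset$labels))
    stop("file datasets need a 'labels' CSV (columns: path,label)", call. = FALSE)
  cfg$seed <- as.integer(if (is.null(cfg$seed)) 1L else cfg$seed)
  g <- cfg$grid
  cfg$grid <- sweep_grid(
    p_values = if (is.null(g$p_values)) seq(0.1, 0.9, by = 0.1) else as.numeric(g$p_values),
    l_values = if (is.null(g$l_values)) seq(100L, 1000L, by = 100L) else as.integer(g$l_values),
    delta_values = if (is.null(g$delta_values)) c(50, 100, 200, 300) else as.numeric(g$delta_values),
    seed = cfg$seed)
  if (is.null(cfg$classifier)) cfg$classifier <- "centroid"
  cfg
}

# materialize the labeled image set a sweep config describes
load_sweep_dataset <- function(cfg) {
  ds <- cfg$dataset
  if (!is.null(ds$phantoms)) {
    ph <- ds$phantoms
    set <- phantom_dataset(n_per_class = as.integer(ph$per_class),
                           n_classes = as.integer(ph$classes),
                           size = as.integer(if (is.null(ph$size)) 128L else ph$size),
                           seed = cfg$seed,
                           style = if (is.null(ph$style)) "mri" else ph$style)
    return(list(images = set$images, labels = set$labels))
  }
  lab <- utils::read.csv(ds$labels, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(lab)))
    stop("labels CSV must have columns 'path' and 'label'", call. = FALSE)
  base <- dirname(ds$labels)
  paths <- ifelse(file.exists(lab$path), lab$path, file.path(base, lab$path))
  files <- Sys.glob(ds$glob)
  keep <- normalizePath(paths, mustWork = FALSE) %in%
          normalizePath(files, mustWork = FALSE)
  if (!any(keep))
    stop("no labeled images match the dataset glob", call. = FALSE)
  list(images = lapply(paths[keep], load_image),
       labels = as.integer(lab$label[keep]))
}
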