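#' Grayscale image container
#'
#' A `gray_image` is the unit of indexing and querying: a 2-D matrix of
#' intensities in `[0, 255]` (stored as doubles, rows = image rows) plus an
#' opaque `id` and an optional category `label` used for evaluation.
#'
#' @param pixels Numeric matrix of intensities in `[0, 255]`.
#' @param id Character scalar identifying the image.
#' @param label Optional category label (character) for evaluation.
#' @return An object of class `gray_image` with elements `pixels`, `id`,
#'   `label`, `w` (width = ncol) and `h` (height = nrow).
#' @export
gray_image <- function(pixels, id = "img", label = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("intensities must be finite")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("intensities must lie in [0, 255]")
  storage.mode(pixels) <- "double"
  structure(
    list(pixels = pixels, id = as.character(id),
         label = if (is.null(label)) NULL else as.character(label),
         w = ncol(pixels), h = nrow(pixels)),
    class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> id=%s  %d x %d (w x h)  range [%.1f, %.1f]%s\n",
              x$id, x$w, x$h, min(x$pixels), max(x$pixels),
              if (is.null(x$label)) "" else paste0("  label=", x$label)))
  invisible(x)
}

#' Read a grayscale image from disk
#'
#' Reads PNG and TIFF through EBImage and plain/binary PGM (P2/P5) with a
#' built-in parser. Colour inputs are converted to luminance
#' (0.2126 R + 0.7152 G + 0.0722 B). Intensities are promoted to doubles in
#' `[0, 255]`.
#'
#' @param path File path (`.png`, `.tif`/`.tiff`, `.pgm`).
#' @param id Image id; defaults to the file name without extension.
#' @param label Optional category label.
#' @return A [gray_image].
#' @export
read_gray_image <- function(path, id = NULL, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(id)) id <- sub("\\.[^.]+$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "pgm") {
    px <- read_pgm(path)
  } else {
    img <- EBImage::readImage(path)
    dat <- EBImage::imageData(img)
    if (length(dim(dat)) == 3L) {
      nch <- dim(dat)[3L]
      dat <- if (nch >= 3L)
        0.2126 * dat[, , 1L] + 0.7152 * dat[, , 2L] + 0.0722 * dat[, , 3L]
      else dat[, , 1L]
    }
    # EBImage stores dim1 = x (columns of the displayed image)
    px <- t(dat) * 255
  }
  px[px < 0] <- 0
  px[px > 255] <- 255
  gray_image(px, id = id, label = label)
}

#' Write a grayscale image
#'
#' PNG/TIFF go through EBImage; `.pgm` writes binary P5. Values are clamped
#' to `[0, 255]`.
#'
#' @param img A [gray_image] or numeric matrix in `[0, 255]`.
#' @param path Destination path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  px <- if (inherits(img, "gray_image")) img$pixels else img
  px[px < 0] <- 0
  px[px > 255] <- 255
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "pgm") {
    write_pgm(px, path)
  } else {
    EBImage::writeImage(EBImage::Image(t(px) / 255), path)
  }
  invisible(path)
}

# P2 (ASCII) / P5 (binary) PGM reader; maxval <= 255 supported.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # header tokens: magic, width, height, maxval (comments skipped)
  buf <- ""
  while (length(tokens) < 4L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("truncated PGM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[ \t\r\n]", ch)) {
      if (nzchar(buf)) { tokens <- c(tokens, buf); buf <- "" }
    } else buf <- paste0(buf, ch)
  }
  magic <- tokens[1L]
  w <- as.integer(tokens[2L]); h <- as.integer(tokens[3L])
  maxval <- as.integer(tokens[4L])
  if (!magic %in% c("P2", "P5")) stop("unsupported PGM magic: ", magic)
  if (is.na(w) || is.na(h) || w < 1L || h < 1L) stop("bad PGM dimensions")
  if (maxval > 255L) stop("only 8-bit PGM supported")
  n <- w * h
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", n))
  } else {
    scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(vals) < n) stop("truncated PGM data")
  matrix(vals * (255 / maxval), nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(px, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(px), nrow(px)), con,
            eos = NULL, useBytes = TRUE)
  writeBin(as.raw(round(t(px))), con)
  invisible(path)
}
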