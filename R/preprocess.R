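#' Adaptive rescale factor for the fixed-size network input
#'
#' The longer image side is mapped to the target side `T`: the scale factor
#' is `T/h` when `h > w` and `T/w` otherwise, so the aspect ratio is
#' preserved and the shorter side is later zero-padded. Rescaled sides are
#' rounded half-away-from-zero to the nearest integer.
#'
#' @param w,h Image width and height in pixels (positive).
#' @param T_side Target square side (default 224).
#' @return List with `s_f` (scale factor), `w_r`, `h_r` (rescaled sides).
#' @export
compute_scale <- function(w, h, T_side = 224L) {
  if (w < 1 || h < 1 || T_side < 1) stop("dimensions must be positive")
  s_f <- if (h > w) T_side / h else T_side / w
  list(s_f = s_f,
       w_r = round_half_up(w * s_f),
       h_r = round_half_up(h * s_f))
}

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x) trunc(x + sign(x) * 0.5)

#' Rescale an image and zero-pad it to a square
#'
#' Content is resampled to the adaptive size from [compute_scale] with
#' bilinear interpolation and centred on the padded axis; all non-content
#' pixels are exactly zero. Odd padding remainders go to the trailing
#' (bottom/right) side.
#'
#' @param img A [gray_image] or numeric matrix.
#' @param T_side Target square side (default 224).
#' @return List with `square` (`T_side` x `T_side` matrix), `s_f`, `w_r`,
#'   `h_r`, and `pad_offsets = c(row, col)` of the top-left content pixel
#'   (1-based).
#' @export
rescale_and_pad <- function(img, T_side = 224L) {
  px <- if (inherits(img, "gray_image")) img$pixels else img
  sc <- compute_scale(ncol(px), nrow(px), T_side)
  content <- if (nrow(px) == sc$h_r && ncol(px) == sc$w_r) px
             else bilinear_resize(px, sc$h_r, sc$w_r)
  square <- matrix(0, T_side, T_side)
  row0 <- (T_side - sc$h_r) %/% 2L + 1L
  col0 <- (T_side - sc$w_r) %/% 2L + 1L
  square[row0:(row0 + sc$h_r - 1L), col0:(col0 + sc$w_r - 1L)] <- content
  list(square = square, s_f = sc$s_f, w_r = sc$w_r, h_r = sc$h_r,
       pad_offsets = c(row = row0, col = col0))
}

# bilinear resampling of a plain matrix (rows x cols)
bilinear_resize <- function(px, nr, nc) {
  out <- EBImage::resize(px, w = nr, h = nc, filter = "bilinear")
  matrix(as.numeric(out), nr, nc)
}

#' Per-pixel mean image over a set of squares
#'
#' The mean image is computed over the index (training) squares only and
#' persisted with the index; queries reuse it.
#'
#' @param squares Non-empty list of `T x T` matrices.
#' @return A `T x T` matrix of per-pixel means.
#' @export
compute_mean_image <- function(squares) {
  if (length(squares) == 0L) stop("empty collection")
  d <- dim(squares[[1L]])
  acc <- matrix(0, d[1L], d[2L])
  for (s in squares) {
    if (!all(dim(s) == d)) stop("all squares must share the same side")
    acc <- acc + s
  }
  acc / length(squares)
}

#' Assemble the zero-centred network input
#'
#' Subtracts the mean image and replicates the result into three identical
#' planes, the fixed `T x T x 3` input shape expected by a feature
#' extractor.
#'
#' @param sq Output of [rescale_and_pad] (or a bare `T x T` matrix).
#' @param mean_image `T x T` matrix of per-pixel means (0 for none).
#' @return Object of class `net_input`: `planes` (`T x T x 3` array),
#'   `T_side`, plus `s_f`, `w_r`, `h_r`, `pad_offsets` carried over.
#' @export
to_net_input <- function(sq, mean_image = 0) {
  if (is.matrix(sq)) sq <- list(square = sq, s_f = 1, w_r = ncol(sq),
                                h_r = nrow(sq), pad_offsets = c(1L, 1L))
  if (is.matrix(mean_image) && !all(dim(mean_image) == dim(sq$square)))
    stop("mean image side does not match input side")
  centred <- sq$square - mean_image
  structure(
    list(planes = array(centred, c(nrow(centred), ncol(centred), 3L)),
         T_side = nrow(centred), s_f = sq$s_f, w_r = sq$w_r, h_r = sq$h_r,
         pad_offsets = sq$pad_offsets),
    class = "net_input")
}

#' Full preprocessing: rescale, pad, centre
#'
#' @param img A [gray_image].
#' @param mean_image Mean image matrix (or 0).
#' @param T_side Target side.
#' @return A `net_input` object.
#' @export
preprocess_image <- function(img, mean_image = 0, T_side = 224L) {
  to_net_input(rescale_and_pad(img, T_side), mean_image)
}
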