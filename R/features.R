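#' Feature-extractor configuration
#'
#' The pipeline treats feature extraction as a pluggable contract: an
#' extractor is a pure function of the preprocessed network input and this
#' configuration, returning a fixed-length numeric code. The built-in
#' `"ohist"` backbone partitions the input plane into `g x g` cells and
#' concatenates per-cell gradient-orientation histograms
#' (length `n = g * g * o`). A learned network satisfying the same
#' contract can be registered with [register_extractor].
#'
#' @param backbone Registered backbone id (default `"ohist"`).
#' @param g Cells per side (>= 2).
#' @param o Orientation bins (>= 4).
#' @param deterministic Contract flag: identical inputs must give
#'   bit-identical codes.
#' @return Object of class `extractor_config` with derived length `n`.
#' @export
extractor_config <- function(backbone = "ohist", g = 4L, o = 8L,
                             deterministic = TRUE) {
  if (g < 2L) stop("g must be >= 2")
  if (o < 4L) stop("o must be >= 4")
  n <- as.integer(g * g * o)
  if (n < 8L) stop("code length must be >= 8")
  structure(list(backbone = backbone, g = as.integer(g), o = as.integer(o),
                 n = n, deterministic = isTRUE(deterministic)),
            class = "extractor_config")
}

# backbone registry
.extractors <- new.env(parent = emptyenv())

#' Register a feature-extractor backbone
#'
#' @param id Backbone id used in [extractor_config].
#' @param fun Function `(net_input, cfg) -> numeric vector of length
#'   cfg$n`.
#' @return `id`, invisibly.
#' @export
register_extractor <- function(id, fun) {
  stopifnot(is.character(id), is.function(fun))
  assign(id, fun, envir = .extractors)
  invisible(id)
}

#' Extract a feature code from a preprocessed input
#'
#' Dispatches to the backbone named in the configuration. Codes are
#' deterministic: the same input and configuration always give the same
#' vector.
#'
#' @param input A `net_input` (from [preprocess_image]).
#' @param cfg An [extractor_config].
#' @return Numeric vector of length `cfg$n`.
#' @export
extract_codes <- function(input, cfg = extractor_config()) {
  if (!inherits(input, "net_input")) stop("input must be a net_input")
  fun <- get0(cfg$backbone, envir = .extractors)
  if (is.null(fun)) stop("unknown backbone: ", cfg$backbone)
  v <- fun(input, cfg)
  if (length(v) != cfg$n) stop("backbone returned wrong code length")
  if (anyNA(v) || any(!is.finite(v))) stop("backbone returned non-finite code")
  as.numeric(v)
}

# built-in backbone: grid of L2-normalised gradient-orientation histograms
ohist_backbone <- function(input, cfg) {
  plane <- input$planes[, , 1L]
  T_side <- nrow(plane)
  if (T_side %% cfg$g != 0L)
    stop("input side ", T_side, " not divisible by g = ", cfg$g)
  gx <- central_diff(plane, "col")
  gy <- central_diff(plane, "row")
  mag <- sqrt(gx^2 + gy^2)
  # unsigned orientation in [0, pi): bin edges at pi/o
  ang <- atan2(gy, gx) %% pi
  bin <- pmin(floor(ang / (pi / cfg$o)), cfg$o - 1L)
  cell_side <- T_side %/% cfg$g
  rows <- (row(plane) - 1L) %/% cell_side
  cols <- (col(plane) - 1L) %/% cell_side
  # linear histogram index: (cell_row, cell_col, bin), cells row-major
  idx <- (rows * cfg$g + cols) * cfg$o + bin + 1L
  hist <- numeric(cfg$g * cfg$g * cfg$o)
  acc <- rowsum(as.numeric(mag), group = as.integer(idx))
  hist[as.integer(rownames(acc))] <- acc[, 1L]
  # L2-normalise per cell with epsilon guard
  hm <- matrix(hist, nrow = cfg$o)
  nrm <- sqrt(colSums(hm^2))
  hm <- sweep(hm, 2L, pmax(nrm, 1e-12), "/")
  hm[, nrm == 0] <- 0
  as.numeric(hm)
}

#' Whole-image and salient-region codes
#'
#' Computes the two codes that the fused descriptor is built from: the
#' code of the preprocessed whole image and the code of the preprocessed
#' bounding-box crop of the saliency-masked image.
#'
#' @param img A [gray_image].
#' @param S Its `saliency_map` (computed if `NULL`).
#' @param cfg An [extractor_config].
#' @param mean_image Mean image (or 0) reused from the index.
#' @param T_side Preprocessing side.
#' @param r,sigma_frac Saliency working parameters (used when `S` is
#'   `NULL`).
#' @return List with `nc_i` and `nc_s`, both length `cfg$n`.
#' @export
codes_for_image <- function(img, S = NULL, cfg = extractor_config(),
                            mean_image = 0, T_side = 224L, r = 32L,
                            sigma_frac = 0.1) {
  if (is.null(S)) S <- saliency_map(img, r = r, sigma_frac = sigma_frac)
  nc_i <- extract_codes(preprocess_image(img, mean_image, T_side), cfg)
  crop <- salient_crop(extract_salient(img, S))
  nc_s <- extract_codes(
    to_net_input(rescale_and_pad(crop, T_side), mean_image), cfg)
  list(nc_i = nc_i, nc_s = nc_s)
}
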