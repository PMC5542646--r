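#' @name saliency
#' @title Graph-based visual saliency
#'
#' @description
#' Saliency is computed channel-wise on small working-resolution feature
#' maps. For every map a fully connected directed graph over the r x r
#' locations is weighted by a logarithmic dissimilarity times a Gaussian
#' proximity kernel; the equilibrium distribution of the induced Markov
#' chain is the activation map, and a second mass-concentration chain
#' sharpens it. Channel maps are averaged, upsampled to image resolution
#' and affinely rescaled to `[0, 1]`. The salient region is the set of
#' pixels at or above the map mean.
NULL

SAL_EPS <- 1e-6

#' Build working-resolution feature maps
#'
#' One intensity channel (downsampled luminance) plus four
#' gradient-orientation energy channels at 0, 45, 90 and 135 degrees
#' (edge-orientation convention: the 90-degree channel responds to
#' vertical edges). Each map is normalised to max 1 and clamped to at
#' least `1e-6` so the logarithmic dissimilarity is defined.
#'
#' @param img A [gray_image] or numeric matrix.
#' @param r Working side (default 32, must give `r^2 <= 2304`).
#' @return Named list of `r x r` matrices:
#'   `intensity`, `orient_0`, `orient_45`, `orient_90`, `orient_135`.
#' @export
build_feature_maps <- function(img, r = 32L) {
  px <- if (inherits(img, "gray_image")) img$pixels else img
  small <- if (all(dim(px) == c(r, r))) px else bilinear_resize(px, r, r)
  gx <- central_diff(small, along = "col")  # d/dx
  gy <- central_diff(small, along = "row")  # d/dy
  theta <- c(0, 45, 90, 135) * pi / 180
  maps <- c(list(intensity = small),
            lapply(theta, function(th) abs(gx * sin(th) - gy * cos(th))))
  names(maps) <- c("intensity", "orient_0", "orient_45", "orient_90",
                   "orient_135")
  lapply(maps, function(m) {
    mx <- max(m)
    if (mx > 0) m <- m / mx
    m[m < SAL_EPS] <- SAL_EPS
    m
  })
}

# central differences, one-sided at the borders
central_diff <- function(m, along = c("row", "col")) {
  along <- match.arg(along)
  if (along == "col") return(t(central_diff(t(m), "row")))
  n <- nrow(m)
  if (n == 1L) return(m * 0)
  out <- m * 0
  out[1L, ] <- m[2L, ] - m[1L, ]
  out[n, ] <- m[n, ] - m[n - 1L, ]
  if (n > 2L) out[2:(n - 1L), ] <- (m[3:n, ] - m[1:(n - 2L), ]) / 2
  out
}

#' Logarithmic dissimilarity between two feature-map locations
#'
#' `d = |log(M(i,j) / M(p,q))|`; maps are clamped to at least `1e-6`
#' beforehand so the ratio is always defined.
#'
#' @param M Feature-map matrix (clamped positive).
#' @param a,b Length-2 positions `c(row, col)` (1-based).
#' @return Non-negative dissimilarity.
#' @export
log_dissimilarity <- function(M, a, b) {
  abs(log(M[a[1L], a[2L]] / M[b[1L], b[2L]]))
}

#' Gaussian proximity kernel
#'
#' `F(a, b) = exp(-(a^2 + b^2) / (2 sigma^2))`, the closeness term of the
#' activation-graph edge weights. `sigma` defaults to one tenth of the
#' working map width and is sensibly kept between a tenth and a fifth of
#' it.
#'
#' @param a,b Coordinate offsets in pixels.
#' @param sigma Bandwidth in pixels (> 0).
#' @return Kernel value in `(0, 1]`.
#' @export
proximity <- function(a, b, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  exp(-(a^2 + b^2) / (2 * sigma^2))
}

# pairwise proximity matrix over all r^2 grid nodes (row-major node order)
proximity_matrix <- function(nr, nc, sigma) {
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  dr <- outer(rows, rows, "-")
  dc <- outer(cols, cols, "-")
  exp(-(dr^2 + dc^2) / (2 * sigma^2))
}

#' Activation graph over a feature map
#'
#' Fully connected directed graph whose edge from node `(i,j)` to `(p,q)`
#' has weight `d((i,j)||(p,q)) * F(i-p, j-q)`.
#'
#' @param M Feature-map matrix with `length(M) <= 2304` nodes.
#' @param sigma Proximity bandwidth; defaults to `ncol(M)/10`.
#' @return List with `weights` (n x n matrix, n = number of cells; node
#'   order is column-major over `M`, i.e. `M[i,j]` is node
#'   `(j-1)*nrow + i`), `sigma`, and `dim`.
#' @export
build_activation_graph <- function(M, sigma = ncol(M) / 10) {
  n <- length(M)
  if (n > 2304L)
    stop("feature map too large (", n, " nodes > 2304); downsample first")
  if (sigma <= 0) stop("sigma must be positive")
  lm <- log(as.numeric(M))
  d <- abs(outer(lm, lm, "-"))
  # column-major node order: node index = (col-1)*nrow + row
  rows <- rep(seq_len(nrow(M)), times = ncol(M))
  cols <- rep(seq_len(ncol(M)), each = nrow(M))
  dr <- outer(rows, rows, "-")
  dc <- outer(cols, cols, "-")
  Fm <- exp(-(dr^2 + dc^2) / (2 * sigma^2))
  list(weights = d * Fm, sigma = sigma, dim = dim(M))
}

#' Stationary distribution of a weighted graph's Markov chain
#'
#' Outgoing weights are row-normalised into a stochastic transition matrix
#' and the equilibrium distribution is obtained by power iteration from a
#' uniform start vector (L1 change `< 1e-9`, at most 10,000 iterations).
#' A graph whose weights are all zero (e.g. a constant feature map) has no
#' preferred location and yields the uniform distribution.
#'
#' @param graph Output of [build_activation_graph], or a bare non-negative
#'   weight matrix.
#' @param tol L1 convergence tolerance.
#' @param max_iter Iteration cap; non-convergence is an error reporting
#'   the iteration count.
#' @return Numeric vector summing to 1.
#' @export
equilibrium <- function(graph, tol = 1e-9, max_iter = 10000L) {
  W <- if (is.list(graph)) graph$weights else graph
  n <- nrow(W)
  rs <- rowSums(W)
  if (all(rs == 0)) return(rep(1 / n, n))
  # isolated rows (can only happen off the standard construction): self-loop
  if (any(rs == 0)) {
    W[cbind(which(rs == 0), which(rs == 0))] <- 1
    rs <- rowSums(W)
  }
  P <- W / rs
  x <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    x_new <- as.numeric(x %*% P)
    x_new <- x_new / sum(x_new)
    if (sum(abs(x_new - x)) < tol) return(x_new)
    x <- x_new
  }
  stop("power iteration failed to converge within ", max_iter, " iterations")
}

#' Mass-concentration pass
#'
#' Second Markov chain whose edge weight into node `(p,q)` is
#' `A(p,q) * F(i-p, j-q)`: mass flows towards high-activation nodes,
#' sharpening the activation map. Solved with the same power-iteration
#' settings as [equilibrium].
#'
#' @param A Activation map (matrix, non-negative).
#' @param sigma Proximity bandwidth; defaults to `ncol(A)/10`.
#' @return Matrix of the same shape, entries summing to 1.
#' @export
concentrate_mass <- function(A, sigma = ncol(A) / 10) {
  a <- as.numeric(A)
  if (all(a == 0) || max(a) == min(a))
    return(matrix(1 / length(a), nrow(A), ncol(A)))
  Fm <- proximity_matrix(nrow(A), ncol(A), sigma)
  # weight from i into j proportional to A_j: scale columns by a
  W <- sweep(Fm, 2L, a, "*")
  matrix(equilibrium(W), nrow(A), ncol(A))
}

#' Combine channel maps into the final saliency map
#'
#' Arithmetic mean across channels, bilinear upsampling to image
#' resolution, and affine rescale to `[0, 1]` (min -> 0, max -> 1; a
#' constant map becomes all 0.5).
#'
#' @param maps Non-empty list of working-resolution matrices.
#' @param image_shape `c(rows, cols)` of the target image.
#' @return Object of class `saliency_map`: `values` (image-resolution
#'   matrix in `[0, 1]`) and `working` (the mean working-resolution map).
#' @export
combine_maps <- function(maps, image_shape) {
  if (length(maps) == 0L) stop("need at least one map")
  acc <- Reduce(`+`, maps) / length(maps)
  up <- if (all(dim(acc) == image_shape)) acc
        else bilinear_resize(acc, image_shape[1L], image_shape[2L])
  rng <- range(up)
  values <- if (rng[2L] > rng[1L]) (up - rng[1L]) / (rng[2L] - rng[1L])
            else matrix(0.5, image_shape[1L], image_shape[2L])
  structure(list(values = values, working = acc), class = "saliency_map")
}

#' Compute the saliency map of an image
#'
#' Runs the full channel pipeline: feature maps, activation-graph
#' equilibrium per channel, one mass-concentration pass per channel, then
#' [combine_maps].
#'
#' @param img A [gray_image].
#' @param r Working side (default 32).
#' @param sigma_frac Proximity bandwidth as a fraction of the working
#'   width (default 1/10; up to 1/5 is sensible).
#' @return A `saliency_map`.
#' @export
saliency_map <- function(img, r = 32L, sigma_frac = 0.1) {
  px <- if (inherits(img, "gray_image")) img$pixels else img
  fmaps <- build_feature_maps(px, r = r)
  sigma <- r * sigma_frac
  working <- lapply(fmaps, function(M) {
    act <- matrix(equilibrium(build_activation_graph(M, sigma)), r, r)
    concentrate_mass(act, sigma)
  })
  combine_maps(working, dim(px))
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("<saliency_map> %d x %d, working %d x %d, mean %.4f\n",
              nrow(x$values), ncol(x$values), nrow(x$working),
              ncol(x$working), mean(x$values)))
  invisible(x)
}

#' Dynamic saliency threshold
#'
#' The threshold is the arithmetic mean of the saliency map, so the
#' retained region adapts to each image.
#'
#' @param S A `saliency_map` or numeric matrix.
#' @return Scalar threshold in `[0, 1]`.
#' @export
threshold_tau <- function(S) {
  v <- if (inherits(S, "saliency_map")) S$values else S
  mean(v)
}

#' Extract the salient region of an image
#'
#' The mask keeps pixels whose saliency is at or above the map mean; the
#' masked image equals the input on the mask and is exactly zero
#' elsewhere. If fewer than 16 pixels survive, the whole image is used as
#' a fallback. The bounding box is the tight box of the mask, 1-based and
#' inclusive.
#'
#' @param img A [gray_image].
#' @param S A `saliency_map` at image resolution.
#' @return Object of class `salient_region`: `mask` (logical matrix),
#'   `tau`, `masked` (matrix), `bbox` (`c(row0, col0, row1, col1)`).
#' @export
extract_salient <- function(img, S) {
  px <- if (inherits(img, "gray_image")) img$pixels else img
  sv <- if (inherits(S, "saliency_map")) S$values else S
  if (!all(dim(sv) == dim(px)))
    stop("saliency map must be at image resolution")
  tau <- mean(sv)
  mask <- sv >= tau
  if (sum(mask) < 16L) mask[] <- TRUE
  masked <- px
  masked[!mask] <- 0
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  structure(
    list(mask = mask, tau = tau, masked = masked,
         bbox = c(row0 = rr[1L], col0 = cc[1L], row1 = rr[2L],
                  col1 = cc[2L])),
    class = "salient_region")
}

#' Crop the masked salient region to its bounding box
#'
#' This is the patch handed to feature extraction, which is then rescaled
#' and padded like any image.
#'
#' @param region A `salient_region`.
#' @return Numeric matrix (the bbox crop of the masked image).
#' @export
salient_crop <- function(region) {
  b <- region$bbox
  region$masked[b[1L]:b[3L], b[2L]:b[4L], drop = FALSE]
}

#' Write saliency debug images
#'
#' Saliency map as a PNG heat image (grayscale) and the mask as PGM.
#'
#' @param S A `saliency_map`.
#' @param region A `salient_region` (optional).
#' @param prefix Output path prefix.
#' @return Written paths, invisibly.
#' @export
write_saliency_debug <- function(S, region = NULL, prefix = "saliency") {
  paths <- paste0(prefix, "_map.png")
  write_gray_image(S$values * 255, paths)
  if (!is.null(region)) {
    mp <- paste0(prefix, "_mask.pgm")
    write_pgm(region$mask * 255, mp)
    paths <- c(paths, mp)
  }
  invisible(paths)
}
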