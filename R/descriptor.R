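#' Fuse whole-image and salient codes into one descriptor
#'
#' The fused descriptor is the elementwise weighted sum
#' `alpha * nc_i + beta * nc_s` with `alpha + beta = 1`. `alpha = 1`
#' ignores saliency entirely; `alpha = 0` keeps only the salient-region
#' code. The defaults `alpha = 0.4`, `beta = 0.6` weight the salient
#' region slightly higher than the whole-image context.
#'
#' @param nc_i Whole-image code.
#' @param nc_s Salient-region code (same length).
#' @param alpha,beta Non-negative fusion weights summing to 1 (within
#'   1e-12).
#' @return Numeric vector of the common length, with attributes `alpha`
#'   and `beta`.
#' @export
fuse <- function(nc_i, nc_s, alpha = 0.4, beta = 0.6) {
  if (length(nc_i) != length(nc_s)) stop("code lengths differ")
  if (alpha < 0 || beta < 0 || abs(alpha + beta - 1) > 1e-12)
    stop("weights must be non-negative and sum to 1")
  structure(alpha * nc_i + beta * nc_s, alpha = alpha, beta = beta)
}

#' Fit the min-max normalizer over a descriptor collection
#'
#' The normalizer records the global scalar minimum and maximum
#' activation over every entry of every descriptor in the fitted (index)
#' set; descriptors are then mapped entrywise to `[0, 1]`. A
#' per-dimension variant is available behind `mode = "per_dimension"`.
#'
#' @param descriptors List of numeric vectors, or a matrix with one
#'   descriptor per row.
#' @param mode `"global"` (scalar min/max, default) or `"per_dimension"`.
#' @return Object of class `sinc_normalizer` with `m_n`, `m_x`, `mode`.
#' @export
fit_normalizer <- function(descriptors, mode = c("global", "per_dimension")) {
  mode <- match.arg(mode)
  X <- if (is.matrix(descriptors)) descriptors
       else do.call(rbind, lapply(descriptors, as.numeric))
  if (mode == "global") {
    m_n <- min(X); m_x <- max(X)
    if (m_x <= m_n) stop("constant collection: cannot fit normalizer")
  } else {
    m_n <- apply(X, 2L, min); m_x <- apply(X, 2L, max)
    if (all(m_x <= m_n)) stop("constant collection: cannot fit normalizer")
    # flat dimensions map to 0 via a unit span
    flat <- m_x <= m_n
    m_x[flat] <- m_n[flat] + 1
  }
  structure(list(m_n = m_n, m_x = m_x, mode = mode),
            class = "sinc_normalizer")
}

#' Min-max normalize a descriptor
#'
#' `(v - m_n) / (m_x - m_n)`, clamped to `[0, 1]` so query descriptors
#' outside the fitted range remain valid.
#'
#' @param desc Numeric descriptor.
#' @param norm A fitted `sinc_normalizer`.
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_descriptor <- function(desc, norm) {
  if (!inherits(norm, "sinc_normalizer")) stop("norm must be a fitted normalizer")
  v <- (as.numeric(desc) - norm$m_n) / (norm$m_x - norm$m_n)
  pmin(pmax(v, 0), 1)
}
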