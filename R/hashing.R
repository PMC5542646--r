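#' RBF kernel between two vectors
#'
#' `kappa(x, y) = exp(-gamma * ||x - y||^2)`, the kernel through which
#' the hashing model accesses descriptors.
#'
#' @param x,y Numeric vectors of equal length.
#' @param gamma Positive bandwidth (inverse squared-length scale).
#' @return Kernel value in `(0, 1]`.
#' @export
rbf_kernel <- function(x, y, gamma) {
  if (length(x) != length(y)) stop("vector lengths differ")
  if (gamma <= 0) stop("gamma must be positive")
  exp(-gamma * sum((x - y)^2))
}

# squared Euclidean distances between rows of A and rows of B
sqdist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

#' Fit a kernelized locality-sensitive hashing model
#'
#' `rho` anchor descriptors are sampled without replacement and their RBF
#' kernel matrix `K` is double-centred (row means, column means and grand
#' mean removed). `K^{-1/2}` is obtained from the symmetric
#' eigendecomposition restricted to the eigenspace with eigenvalues at
#' least `eig_floor` (smaller components carry no usable signal and are
#' dropped). For each of the `b` bits, `t` distinct anchor indices are
#' drawn to form the indicator vector `e_s`, and the bit's weight row is
#' `w = K^{-1/2} e_s`. The whole fit is a deterministic function of
#' `(data, rho, t, b, gamma, seed)`.
#'
#' @param X Matrix of normalized descriptors (one per row), at least
#'   `rho` of them.
#' @param rho Number of anchors (default 300, capped by callers at the
#'   collection size).
#' @param t Indices drawn per bit (default 30, `t <= rho`).
#' @param b Bits per key (default 128).
#' @param seed Integer seed controlling anchor and index draws.
#' @param gamma RBF bandwidth; `NULL` (default) uses the median
#'   heuristic `1 / median(||x - y||^2)` over anchor pairs.
#' @param eig_floor Eigenvalue retention floor (default 1e-12).
#' @return Object of class `klsh_model`: `anchors`, `gamma`, `W`
#'   (`b x rho`), `rho`, `t`, `b`, `seed`, `eig_floor`.
#' @export
fit_klsh <- function(X, rho = 300L, t = 30L, b = 128L, seed = 1L,
                     gamma = NULL, eig_floor = 1e-12) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (rho > n) stop("rho (", rho, ") exceeds collection size (", n, ")")
  if (t > rho || t < 1L) stop("need 1 <= t <= rho")
  if (b < 1L) stop("b must be >= 1")
  draws <- with_seed(seed, {
    anchor_idx <- sample.int(n, rho)
    es_idx <- lapply(seq_len(b), function(j) sample.int(rho, t))
    list(anchor_idx = anchor_idx, es_idx = es_idx)
  })
  Z <- X[draws$anchor_idx, , drop = FALSE]
  # explicit pairwise differences: accurate even for near-duplicate anchors
  D2 <- as.matrix(stats::dist(Z))^2
  if (is.null(gamma)) {
    off <- D2[upper.tri(D2)]
    med <- stats::median(off)
    gamma <- if (is.finite(med) && med > 0) 1 / med else 1
  }
  K <- exp(-gamma * D2)
  # symmetric double-centring
  Kc <- sweep(sweep(K, 1L, rowMeans(K)), 2L, colMeans(K)) + mean(K)
  eig <- eigen(Kc, symmetric = TRUE)
  keep <- eig$values >= eig_floor
  if (!any(keep))
    stop("degenerate kernel: all anchors identical (no retained eigenvalues)")
  V <- eig$vectors[, keep, drop = FALSE]
  Kinv_sqrt <- V %*% (t(V) / sqrt(eig$values[keep]))
  W <- matrix(0, b, rho)
  for (j in seq_len(b)) {
    es <- numeric(rho)
    es[draws$es_idx[[j]]] <- 1
    W[j, ] <- Kinv_sqrt %*% es
  }
  structure(list(anchors = Z, gamma = gamma, W = W, rho = as.integer(rho),
                 t = as.integer(t), b = as.integer(b),
                 seed = as.integer(seed), eig_floor = eig_floor),
            class = "klsh_model")
}

#' @export
print.klsh_model <- function(x, ...) {
  cat(sprintf("<klsh_model> b=%d bits, rho=%d anchors, t=%d, gamma=%.4g\n",
              x$b, x$rho, x$t, x$gamma))
  invisible(x)
}

#' Hash a normalized descriptor to a b-bit key
#'
#' Bit `j` is 1 when `sum_i W[j, i] * kappa(x, anchor_i) >= 0` (the sign
#' of zero maps to 1 for determinism).
#'
#' @param model A fitted `klsh_model`.
#' @param x Normalized descriptor (length = anchor dimension), or a
#'   matrix of descriptors (one per row).
#' @return Integer vector of `b` bits in `{0, 1}`, or a matrix of keys
#'   (one per row) for matrix input.
#' @export
klsh_hash <- function(model, x) {
  if (!inherits(model, "klsh_model")) stop("model must be a klsh_model")
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(X) != ncol(model$anchors)) stop("descriptor length mismatch")
  Kq <- exp(-model$gamma * sqdist(X, model$anchors))  # n x rho
  bits <- (tcrossprod(Kq, model$W) >= 0) * 1L         # n x b
  if (is.matrix(x)) bits else as.integer(bits[1L, ])
}

#' Hamming distance between two keys
#'
#' @param k1,k2 Bit vectors of equal length.
#' @return Count of differing bits.
#' @export
hamming <- function(k1, k2) {
  if (length(k1) != length(k2)) stop("key lengths differ")
  sum(k1 != k2)
}

# compact string form of a key, used for hash buckets
key_string <- function(bits) paste(bits, collapse = "")

# run code with a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
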