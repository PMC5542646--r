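#' Specification for a synthetic radiograph dataset
#'
#' The generator renders category-structured grayscale images: each
#' category is a parametric motif (ellipse "skull", banded "chest",
#' rod "long bone", fanned rods "hand", paired rings "pelvis", jointed
#' rods "knee", horizontal "ribs", diagonal rod + ring "shoulder"),
#' cycled with jittered parameters. Images get an optional planted
#' anomaly (bright calcification-like Gaussian blob, or a dark
#' fracture-like transverse gap across a rod) recorded in a mask,
#' additive Gaussian noise, a linear illumination gradient, and a 50%
#' random horizontal flip. Everything is reproducible from `seed`; each
#' image uses its own RNG stream derived from `(seed, image index)`.
#'
#' @param n_categories Number of categories (motifs cycle if more than
#'   8).
#' @param images_per_category Images per category.
#' @param size_range `c(min_side, max_side)` in pixels (default
#'   `c(120, 512)`, `min_side >= 32`).
#' @param anomaly_prevalence Fraction of images with a planted anomaly
#'   (default 0.5).
#' @param anomaly_types Types to draw from (`"blob"`, `"fracture"`).
#' @param noise_sigma Additive Gaussian noise SD in intensity units
#'   (default 4).
#' @param illumination_gradient Maximum relative illumination slope
#'   (default 0.2).
#' @param seed Integer seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_categories = 8L, images_per_category = 25L,
                           size_range = c(120L, 512L),
                           anomaly_prevalence = 0.5,
                           anomaly_types = c("blob", "fracture"),
                           noise_sigma = 4, illumination_gradient = 0.2,
                           seed = 1L) {
  if (size_range[1L] < 32L) stop("min_side must be >= 32")
  if (size_range[2L] < size_range[1L]) stop("invalid size range")
  if (anomaly_prevalence < 0 || anomaly_prevalence > 1)
    stop("prevalence must be in [0, 1]")
  if (n_categories < 1L || images_per_category < 1L)
    stop("counts must be positive")
  structure(list(n_categories = as.integer(n_categories),
                 images_per_category = as.integer(images_per_category),
                 size_range = as.integer(size_range),
                 anomaly_prevalence = anomaly_prevalence,
                 anomaly_types = match.arg(anomaly_types, several.ok = TRUE),
                 noise_sigma = noise_sigma,
                 illumination_gradient = illumination_gradient,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# motif renderers operate on normalized coordinate grids X (col/side),
# Y (row/side) in [0, 1]; each returns list(intensity, rod_mask) where
# rod_mask marks fracture-eligible structure (or NULL)
motif_library <- function() {
  seg_dist <- function(X, Y, x1, y1, x2, y2) {
    vx <- x2 - x1; vy <- y2 - y1
    tt <- ((X - x1) * vx + (Y - y1) * vy) / (vx^2 + vy^2)
    tt <- pmin(pmax(tt, 0), 1)
    sqrt((X - (x1 + tt * vx))^2 + (Y - (y1 + tt * vy))^2)
  }
  rod <- function(X, Y, x1, y1, x2, y2, w, A) {
    d <- seg_dist(X, Y, x1, y1, x2, y2)
    list(I = A * exp(-(d / w)^2), mask = d < 1.5 * w)
  }
  ring <- function(X, Y, cx, cy, rx, ry, shell, A) {
    q <- sqrt(((X - cx) / rx)^2 + ((Y - cy) / ry)^2)
    A * exp(-((q - 1) / shell)^2)
  }
  j <- function(x, s) x + stats::runif(1L, -s, s)
  list(
    skull = function(X, Y) {
      cx <- j(0.5, 0.04); cy <- j(0.45, 0.04)
      rx <- j(0.28, 0.03); ry <- j(0.35, 0.03)
      q <- sqrt(((X - cx) / rx)^2 + ((Y - cy) / ry)^2)
      I <- 85 * exp(-((q - 1) / 0.07)^2) + 40 * (q < 1)
      list(I = I, rod = NULL)
    },
    chest = function(X, Y) {
      I <- 70 * exp(-((abs(X - 0.5) / j(0.36, 0.03))^6 +
                        (abs(Y - 0.5) / j(0.42, 0.03))^6))
      for (cx in c(j(0.34, 0.02), j(0.66, 0.02)))
        I <- I - 45 * (sqrt(((X - cx) / 0.13)^2 +
                              ((Y - j(0.45, 0.02)) / 0.22)^2) < 1)
      list(I = I, rod = NULL)
    },
    long_bone = function(X, Y) {
      x1 <- j(0.5, 0.06); x2 <- j(0.5, 0.06)
      r <- rod(X, Y, x1, j(0.12, 0.03), x2, j(0.88, 0.03),
               j(0.05, 0.008), 95)
      I <- r$I +
        60 * exp(-((X - x1)^2 + (Y - 0.12)^2) / 0.006) +
        60 * exp(-((X - x2)^2 + (Y - 0.88)^2) / 0.006)
      list(I = I, rod = r$mask)
    },
    hand = function(X, Y) {
      bx <- j(0.5, 0.03); by <- j(0.85, 0.03)
      tips <- c(0.30, 0.43, 0.57, 0.70)
      I <- 0; mask <- FALSE
      for (tx in tips) {
        r <- rod(X, Y, bx, by, j(tx, 0.02), j(0.15, 0.03),
                 j(0.018, 0.004), 85)
        I <- I + r$I; mask <- mask | r$mask
      }
      list(I = I, rod = mask)
    },
    pelvis = function(X, Y) {
      I <- ring(X, Y, j(0.35, 0.02), j(0.5, 0.02), j(0.17, 0.02),
                j(0.17, 0.02), 0.12, 80) +
        ring(X, Y, j(0.65, 0.02), j(0.5, 0.02), j(0.17, 0.02),
             j(0.17, 0.02), 0.12, 80)
      list(I = I, rod = NULL)
    },
    knee = function(X, Y) {
      x0 <- j(0.5, 0.04)
      r1 <- rod(X, Y, x0, j(0.06, 0.02), x0, j(0.42, 0.02),
                j(0.055, 0.008), 90)
      r2 <- rod(X, Y, x0, j(0.58, 0.02), x0, j(0.94, 0.02),
                j(0.055, 0.008), 90)
      I <- r1$I + r2$I +
        55 * exp(-(((X - x0) / 0.16)^2 + ((Y - 0.5) / 0.05)^2))
      list(I = I, rod = r1$mask | r2$mask)
    },
    ribs = function(X, Y) {
      f <- j(6, 1)
      I <- 60 * (0.5 + 0.5 * cos(2 * pi * f * Y)) *
        exp(-(abs(X - 0.5) / j(0.38, 0.03))^6)
      list(I = I, rod = NULL)
    },
    shoulder = function(X, Y) {
      r <- rod(X, Y, j(0.15, 0.03), j(0.75, 0.03), j(0.72, 0.03),
               j(0.28, 0.03), j(0.045, 0.008), 85)
      I <- r$I + ring(X, Y, j(0.72, 0.02), j(0.26, 0.02), 0.1, 0.1,
                      0.09, 70)
      list(I = I, rod = r$mask)
    })
}

# derived 32-bit seed for image `i` of stream `seed`
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(i) * 9973) %%
               2147483647)
}

#' Generate a labeled synthetic dataset
#'
#' @param spec A [synthetic_spec].
#' @return List of records, each with `image` ([gray_image] with label
#'   `"cat<j>"`), `category`, `anomaly_type` (`"none"`, `"blob"` or
#'   `"fracture"`), and `anomaly_mask` (logical matrix, or `NULL` when no
#'   anomaly is planted).
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  if (!inherits(spec, "synthetic_spec")) stop("spec must be a synthetic_spec")
  motifs <- motif_library()
  n_total <- spec$n_categories * spec$images_per_category
  out <- vector("list", n_total)
  idx <- 0L
  for (cat_i in seq_len(spec$n_categories)) {
    motif <- motifs[[(cat_i - 1L) %% length(motifs) + 1L]]
    for (img_i in seq_len(spec$images_per_category)) {
      idx <- idx + 1L
      out[[idx]] <- with_seed(derive_seed(spec$seed, idx), {
        render_synthetic(motif, spec,
                         id = sprintf("img%04d", idx),
                         label = paste0("cat", cat_i))
      })
    }
  }
  out
}

render_synthetic <- function(motif, spec, id, label) {
  side <- sample(spec$size_range[1L]:spec$size_range[2L], 1L)
  X <- matrix(rep((seq_len(side) - 0.5) / side, each = side), side, side)
  Y <- matrix(rep((seq_len(side) - 0.5) / side, times = side), side, side)
  base <- 25 +
    10 * sin(2 * pi * (stats::runif(1L, 0.5, 2) * X +
                         stats::runif(1L, 0.5, 2) * Y) +
               stats::runif(1L, 0, 2 * pi))
  m <- motif(X, Y)
  I <- base + m$I
  anomaly_type <- "none"
  mask <- NULL
  if (stats::runif(1L) < spec$anomaly_prevalence) {
    types <- spec$anomaly_types
    if (is.null(m$rod) || !any(m$rod)) types <- setdiff(types, "fracture")
    if (length(types) > 0L) {
      anomaly_type <- if (length(types) == 1L) types else
        sample(types, 1L)
      if (anomaly_type == "blob") {
        bx <- stats::runif(1L, 0.3, 0.7); by <- stats::runif(1L, 0.3, 0.7)
        s <- stats::runif(1L, 0.035, 0.06)
        A <- stats::runif(1L, 100, 135)
        bump <- A * exp(-((X - bx)^2 + (Y - by)^2) / s^2)
        I <- I + bump
        mask <- bump > A / 2
      } else {
        # dark transverse gap across the rod structure
        rows_with_rod <- which(rowSums(m$rod) > 0)
        yc <- stats::runif(1L, 0.35, 0.65)
        yc <- rows_with_rod[which.min(abs(rows_with_rod / side - yc))] /
          side
        gap <- abs(Y - yc) < stats::runif(1L, 0.012, 0.02)
        cut <- gap & m$rod
        I[cut] <- I[cut] - 75
        mask <- cut
      }
      if (!any(mask)) { anomaly_type <- "none"; mask <- NULL }
    }
  }
  slope <- stats::runif(1L, 0, spec$illumination_gradient)
  phi <- stats::runif(1L, 0, 2 * pi)
  I <- I * (1 + slope * ((X - 0.5) * cos(phi) + (Y - 0.5) * sin(phi)))
  if (spec$noise_sigma > 0)
    I <- I + stats::rnorm(length(I), sd = spec$noise_sigma)
  if (stats::runif(1L) < 0.5) {
    I <- I[, side:1L]
    if (!is.null(mask)) mask <- mask[, side:1L]
  }
  I[I < 0] <- 0; I[I > 255] <- 255
  list(image = gray_image(I, id = id, label = label), category = label,
       anomaly_type = anomaly_type, anomaly_mask = mask)
}

#' Corrupt an image with salt & pepper or Gaussian noise
#'
#' Salt & pepper flips each pixel independently to 0 or 255 (equal
#' split) with probability `level`; Gaussian adds zero-mean noise with
#' variance `level` (intensity units squared) and clamps to `[0, 255]`.
#' Level 0 returns the input unchanged.
#'
#' @param img A [gray_image].
#' @param model `"saltpepper"` or `"gaussian"`.
#' @param level Flip probability in `[0, 1]`, or variance `>= 0`.
#' @param seed Integer seed for the noise draw.
#' @return A corrupted [gray_image] (same id and label).
#' @export
corrupt <- function(img, model = c("saltpepper", "gaussian"), level,
                    seed = 1L) {
  model <- match.arg(model)
  px <- img$pixels
  if (model == "saltpepper") {
    if (level < 0 || level > 1) stop("flip probability must be in [0, 1]")
    if (level > 0) {
      px <- with_seed(seed, {
        u <- stats::runif(length(px))
        flip <- u < level
        salt <- u < level / 2
        px[flip] <- 255
        px[salt] <- 0
        px
      })
    }
  } else {
    if (level < 0) stop("variance must be >= 0")
    if (level > 0) {
      px <- with_seed(seed,
                      px + stats::rnorm(length(px), sd = sqrt(level)))
      px[px < 0] <- 0; px[px > 255] <- 255
    }
  }
  gray_image(px, id = img$id, label = img$label)
}

#' Write a synthetic dataset to disk
#'
#' PNG images plus a manifest CSV (`id`, `path`, `category`,
#' `anomaly_type`) and mask PNGs for anomalous images.
#'
#' @param dataset Output of [generate_dataset].
#' @param dir Output directory (created if needed).
#' @return Manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(dataset, function(rec) {
    path <- file.path(dir, paste0(rec$image$id, ".png"))
    write_gray_image(rec$image, path)
    if (!is.null(rec$anomaly_mask))
      write_gray_image(rec$anomaly_mask * 255,
                       file.path(dir, paste0(rec$image$id, "_mask.png")))
    data.frame(id = rec$image$id, path = path, category = rec$category,
               anomaly_type = rec$anomaly_type, stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset back from a manifest
#'
#' @param manifest Path to a manifest CSV written by [write_dataset].
#' @return List of labeled [gray_image] objects.
#' @export
read_dataset <- function(manifest) {
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  missing <- tab$path[!file.exists(tab$path)]
  if (length(missing) > 0L)
    stop("missing image files: ", paste(missing, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i)
    read_gray_image(tab$path[i], id = tab$id[i], label = tab$category[i]))
}
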