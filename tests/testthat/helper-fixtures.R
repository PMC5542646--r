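# Shared fixtures, built lazily once per test run and memoized.
# Heavy pipeline fixtures use a saliency working side of 16 to keep the
# suite desk-scale; the saliency-quality benchmark uses 24.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# 500-image clustered index with 128-bit keys (hashing/retrieval criteria)
fx_dataset500 <- function() fixture("ds500", function() {
  generate_dataset(synthetic_spec(n_categories = 10,
                                  images_per_category = 50, seed = 101))
})

fx_index500 <- function() fixture("idx500", function() {
  build_index(fx_dataset500(), pipeline_config(r = 16L, seed = 7L))
})

fx_queries500 <- function() fixture("q500", function() {
  ds <- fx_dataset500()
  ds[seq(1L, length(ds), by = 10L)][1:50]
})

# descriptors of the 50 query images through the fitted index (cached so
# linear/hashed comparisons do not recompute the pipeline)
fx_query_descs500 <- function() fixture("qd500", function() {
  idx <- fx_index500()
  lapply(fx_queries500(), function(rec)
    sincir:::query_descriptor(idx, rec$image))
})

# labeled benchmark (8 categories x 25 images) for fusion/noise sweeps
fx_benchmark <- function() fixture("bench", function() {
  generate_dataset(synthetic_spec(n_categories = 8L,
                                  images_per_category = 25L, seed = 11L))
})

fx_bench_split <- function() fixture("bench_split", function() {
  sincir:::split_dataset(fx_benchmark(), n_query_per_cat = 5L)
})

fx_bench_index <- function() fixture("bench_idx", function() {
  build_index(fx_bench_split()$index,
              pipeline_config(r = 16L, b = 64L, seed = 3L))
})

fx_fusion_table <- function() fixture("fusion_tab", function() {
  fusion_sweep(fx_benchmark(), alphas = c(0, 0.2, 0.4, 0.6, 0.8, 1),
               config = pipeline_config(r = 16L), n_query_per_cat = 5L,
               k = 10L)
})

# small labeled pipeline fixture for fast unit tests
fx_small_dataset <- function() fixture("small_ds", function() {
  generate_dataset(synthetic_spec(n_categories = 4L,
                                  images_per_category = 4L,
                                  size_range = c(96L, 160L), seed = 5L))
})

fx_small_index <- function() fixture("small_idx", function() {
  build_index(fx_small_dataset(),
              pipeline_config(r = 16L, rho = 16L, t = 4L, b = 32L,
                              seed = 2L))
})

# deterministic gradient test image: vertical step edge
step_image <- function(side = 64L, at = side %/% 2L) {
  px <- matrix(0, side, side)
  px[, (at + 1L):side] <- 200
  gray_image(px, id = "step")
}

# exact dilated-mask hit test: is point within `radius` of any mask pixel
near_mask <- function(point, mask, radius = 5) {
  mpix <- which(mask, arr.ind = TRUE)
  min(sqrt((mpix[, 1L] - point[1L])^2 + (mpix[, 2L] - point[2L])^2)) <=
    radius
}

# exact area fraction of the mask dilated by a disc of `radius`
dilated_fraction <- function(mask, radius = 5) {
  mpix <- which(mask, arr.ind = TRUE)
  nr <- nrow(mask); nc <- ncol(mask)
  hit <- matrix(FALSE, nr, nc)
  rr <- seq(-radius, radius)
  disc <- expand.grid(dr = rr, dc = rr)
  disc <- disc[disc$dr^2 + disc$dc^2 <= radius^2, ]
  for (i in seq_len(nrow(disc))) {
    r2 <- mpix[, 1L] + disc$dr[i]; c2 <- mpix[, 2L] + disc$dc[i]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    hit[cbind(r2[ok], c2[ok])] <- TRUE
  }
  mean(hit)
}
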