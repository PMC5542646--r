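test_that("the generator produces balanced, reproducible datasets", {
  spec <- synthetic_spec(n_categories = 8, images_per_category = 5,
                         size_range = c(64L, 96L), seed = 7)
  ds1 <- generate_dataset(spec)
  expect_length(ds1, 40)
  labels <- vapply(ds1, function(r) r$image$label, character(1))
  expect_equal(unname(table(labels)), rep(5L, 8), ignore_attr = TRUE)
  sides <- vapply(ds1, function(r) r$image$h, numeric(1))
  expect_true(all(sides >= 64 & sides <= 96))
  # bit-identical rerun
  ds2 <- generate_dataset(spec)
  for (i in c(1, 17, 40))
    expect_identical(ds1[[i]]$image$pixels, ds2[[i]]$image$pixels)
  expect_error(synthetic_spec(size_range = c(8L, 64L)), "min_side")
  expect_error(synthetic_spec(anomaly_prevalence = 2), "prevalence")
})

test_that("anomaly prevalence follows the configured rate", {
  spec <- synthetic_spec(n_categories = 8, images_per_category = 25,
                         size_range = c(64L, 96L),
                         anomaly_prevalence = 0.5, seed = 19)
  ds <- generate_dataset(spec)
  n_anom <- sum(vapply(ds, function(r) r$anomaly_type != "none",
                       logical(1)))
  # central 99.9% interval of Binomial(200, 0.5)
  bounds <- qbinom(c(0.0005, 0.9995), 200, 0.5)
  expect_gte(n_anom, bounds[1])
  expect_lte(n_anom, bounds[2])
  # masks exist exactly for anomalous images and lie in bounds
  for (r in ds) {
    if (r$anomaly_type == "none") {
      expect_null(r$anomaly_mask)
    } else {
      expect_true(any(r$anomaly_mask))
      expect_equal(dim(r$anomaly_mask), dim(r$image$pixels))
    }
  }
})

test_that("blob anomalies are brighter than their local background", {
  spec <- synthetic_spec(n_categories = 4, images_per_category = 5,
                         size_range = c(96L, 128L),
                         anomaly_prevalence = 1, anomaly_types = "blob",
                         seed = 23)
  ds <- generate_dataset(spec)
  for (r in ds) {
    expect_equal(r$anomaly_type, "blob")
    inside <- mean(r$image$pixels[r$anomaly_mask])
    outside <- mean(r$image$pixels[!r$anomaly_mask])
    expect_gt(inside, outside + 40)
  }
})

test_that("descriptors separate categories better than chance", {
  # within-category similarity exceeds between-category on average
  cfg <- pipeline_config(r = 16L, rho = 16L, t = 4L, b = 32L)
  for (seed in 1:5) {
    ds <- generate_dataset(synthetic_spec(
      n_categories = 4, images_per_category = 4,
      size_range = c(96L, 160L), seed = seed))
    idx <- build_index(ds, cfg)
    sims <- tcrossprod(idx$descriptors /
                         sqrt(rowSums(idx$descriptors^2)))
    same <- outer(idx$labels, idx$labels, "==")
    diag(same) <- NA
    gap <- mean(sims[same & upper.tri(sims)], na.rm = TRUE) -
      mean(sims[!same & upper.tri(sims)], na.rm = TRUE)
    expect_gt(gap, 0)
  }
})

test_that("corruption models behave at their extremes", {
  img <- fx_small_dataset()[[2]]$image
  expect_identical(corrupt(img, "saltpepper", 0)$pixels, img$pixels)
  expect_identical(corrupt(img, "gaussian", 0)$pixels, img$pixels)
  allflip <- corrupt(img, "saltpepper", 1, seed = 3)
  expect_true(all(allflip$pixels %in% c(0, 255)))
  # both salt and pepper appear at full flip probability
  expect_gt(sum(allflip$pixels == 0), 0)
  expect_gt(sum(allflip$pixels == 255), 0)
  g <- corrupt(img, "gaussian", 100, seed = 3)
  expect_true(all(g$pixels >= 0 & g$pixels <= 255))
  expect_gt(sd(g$pixels - img$pixels), 5)
  # seeded reproducibility
  expect_identical(corrupt(img, "saltpepper", 0.2, seed = 5)$pixels,
                   corrupt(img, "saltpepper", 0.2, seed = 5)$pixels)
})

test_that("datasets round-trip through PNG files and the manifest", {
  ds <- generate_dataset(synthetic_spec(n_categories = 2,
                                        images_per_category = 2,
                                        size_range = c(48L, 64L),
                                        seed = 3))
  dir <- tempfile()
  manifest <- write_dataset(ds, dir)
  tab <- read.csv(manifest)
  expect_equal(nrow(tab), 4)
  back <- read_dataset(manifest)
  expect_equal(back[[1]]$label, ds[[1]]$category)
  # 8-bit PNG round trip is exact to within quantization
  expect_lt(max(abs(back[[1]]$pixels - ds[[1]]$image$pixels)), 0.51)
  unlink(dir, recursive = TRUE)
})

test_that("PGM images round-trip through both ASCII and binary forms", {
  px <- matrix(sample(0:255, 12 * 9, TRUE), 9, 12)
  p5 <- tempfile(fileext = ".pgm")
  write_gray_image(px, p5)
  expect_equal(read_gray_image(p5)$pixels, px, ignore_attr = TRUE)
  # hand-written ASCII P2 with a comment line
  p2 <- tempfile(fileext = ".pgm")
  writeLines(c("P2", "# comment", "3 2", "255",
               "0 128 255", "64 32 16"), p2)
  img <- read_gray_image(p2)
  expect_equal(img$pixels, matrix(c(0, 64, 128, 32, 255, 16), 2, 3),
               ignore_attr = TRUE)
  unlink(c(p5, p2))
})
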