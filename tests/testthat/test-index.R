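test_that("cosine similarity on non-negative vectors lands in [0, 1]", {
  expect_equal(similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(similarity(c(1, 1), c(1, 0)), 1 / sqrt(2))
  expect_equal(similarity(c(0, 0), c(1, 1)), 0)
  expect_error(similarity(c(1, 2), c(1, 2, 3)), "lengths")
  set.seed(6)
  for (i in 1:50) {
    x <- runif(8); y <- runif(8)
    s <- similarity(x, y)
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("the index holds one consistent record per image", {
  idx <- fx_small_index()
  ds <- fx_small_dataset()
  expect_equal(length(idx$ids), length(ds))
  expect_equal(ncol(idx$keys), 32)
  # every stored key equals the hash of its stored descriptor
  rekeys <- klsh_hash(idx$klsh, idx$descriptors)
  expect_equal(unname(rekeys), unname(idx$keys))
  # bucket membership is consistent with keys
  for (ks in names(idx$buckets))
    for (i in idx$buckets[[ks]])
      expect_equal(sincir:::key_string(idx$keys[i, ]), ks)
  expect_error(build_index(list()), "empty")
})

test_that("rebuilding with the same seed reproduces the index", {
  ds <- fx_small_dataset()
  cfg <- pipeline_config(r = 16L, rho = 16L, t = 4L, b = 32L, seed = 2L)
  idx1 <- fx_small_index()
  idx2 <- build_index(ds, cfg)
  expect_identical(idx1$descriptors, idx2$descriptors)
  expect_identical(idx1$keys, idx2$keys)
  expect_identical(idx1$klsh$W, idx2$klsh$W)
  expect_identical(idx1$fingerprint, idx2$fingerprint)
})

test_that("an indexed image retrieves itself at rank 1 with similarity 1", {
  idx <- fx_small_index()
  ds <- fx_small_dataset()
  for (i in c(1, 6, 16)) {
    res <- query_linear(idx, ds[[i]]$image, k = 3)
    expect_equal(res$ranked$id[1], ds[[i]]$image$id)
    expect_equal(res$ranked$sim[1], 1)
    expect_equal(res$candidates_examined, length(ds))
  }
})

test_that("linear ranking matches a brute-force sort oracle", {
  idx <- fx_small_index()
  img <- fx_small_dataset()[[5]]$image
  res <- query_linear(idx, img, k = length(idx$ids))
  q <- sincir:::query_descriptor(idx, img)
  sims <- apply(idx$descriptors, 1, similarity, y = q)
  oracle <- idx$ids[order(-sims, idx$ids)]
  expect_equal(res$ranked$id, oracle)
  expect_true(all(diff(res$ranked$sim) <= 1e-12))
  # k larger than the index returns everything
  expect_equal(nrow(query_linear(idx, img, k = 999)$ranked),
               length(idx$ids))
})

test_that("hashed query with exhaustive radius equals linear search", {
  idx <- fx_small_index()
  for (i in c(2, 9)) {
    img <- fx_small_dataset()[[i]]$image
    a <- query_linear(idx, img, k = 16)
    b <- query_hashed(idx, img, k = 16, max_radius = 32L)
    expect_identical(a$ranked$id, b$ranked$id)
    expect_equal(a$ranked$sim, b$ranked$sim)
    expect_lte(b$candidates_examined, length(idx$ids))
  }
})

test_that("radius-ordered expansion equals a brute-force Hamming scan", {
  idx <- fx_small_index()
  img <- fx_small_dataset()[[3]]$image
  res <- query_hashed(idx, img, k = 2, max_radius = 20L)
  q <- sincir:::query_descriptor(idx, img)
  qkey <- klsh_hash(idx$klsh, q)
  dists <- apply(idx$keys, 1, hamming, k2 = qkey)
  # recover the radius the expansion stopped at and compare candidate sets
  radius <- 0
  while (sum(dists <= radius) < max(2, 6) && radius < 20) radius <- radius + 1
  oracle <- idx$ids[dists <= radius]
  expect_equal(res$candidates_examined, length(oracle))
})

test_that("the index round-trips through its container", {
  idx <- fx_small_index()
  path <- tempfile(fileext = ".rds")
  save_index(idx, path)
  idx2 <- load_index(path)
  expect_identical(idx$descriptors, idx2$descriptors)
  expect_identical(idx$buckets, idx2$buckets)
  img <- fx_small_dataset()[[1]]$image
  expect_equal(query_linear(idx, img, k = 3)$ranked,
               query_linear(idx2, img, k = 3)$ranked)
  unlink(path)
})

test_that("query results serialize to CSV and JSON", {
  idx <- fx_small_index()
  res <- query_linear(idx, fx_small_dataset()[[1]]$image, k = 3)
  prefix <- tempfile()
  paths <- write_query_results(res, prefix, query_id = "q1")
  tab <- read.csv(paths[1])
  expect_equal(nrow(tab), 3)
  expect_equal(tab$rank, 1:3)
  expect_equal(tab$query_id, rep("q1", 3))
  unlink(paths)
})
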