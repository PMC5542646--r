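test_that("feature maps cover intensity plus four orientations", {
  img <- gray_image(matrix(runif(64 * 64, 0, 255), 64, 64))
  fm <- build_feature_maps(img, r = 16)
  expect_named(fm, c("intensity", "orient_0", "orient_45", "orient_90",
                     "orient_135"))
  for (m in fm) {
    expect_equal(dim(m), c(16, 16))
    expect_true(all(m >= 1e-6))
  }

  # constant image: intensity constant, orientation maps at the clamp floor
  fmc <- build_feature_maps(matrix(100, 64, 64), r = 16)
  expect_equal(max(fmc$intensity) - min(fmc$intensity), 0)
  for (nm in c("orient_0", "orient_45", "orient_90", "orient_135"))
    expect_true(all(fmc[[nm]] == 1e-6))
})

test_that("a vertical step edge energizes the 90-degree channel", {
  fm <- build_feature_maps(step_image(64), r = 16)
  edge_col <- 8:9
  expect_gt(mean(fm$orient_90[, edge_col]), 10 * mean(fm$orient_0))
  # response is concentrated in the edge column band
  expect_gt(mean(fm$orient_90[, edge_col]),
            10 * mean(fm$orient_90[, c(1:5, 12:16)]))
})

test_that("log dissimilarity is symmetric and zero on equal values", {
  M <- matrix(c(1, 1, 2, 1), 2, 2)
  expect_equal(log_dissimilarity(M, c(1, 1), c(2, 1)), 0)
  expect_equal(log_dissimilarity(M, c(1, 1), c(1, 2)), log(2))
  set.seed(4)
  Mr <- matrix(runif(16, 0.1, 5), 4, 4)
  for (i in 1:10) {
    a <- c(sample(4, 1), sample(4, 1)); b <- c(sample(4, 1), sample(4, 1))
    expect_equal(log_dissimilarity(Mr, a, b), log_dissimilarity(Mr, b, a))
  }
})

test_that("proximity kernel is Gaussian in the offset", {
  expect_equal(proximity(0, 0, 3), 1)
  expect_equal(proximity(3, 0, 3), exp(-1 / 2))
  expect_equal(proximity(1, 2, 2), exp(-5 / 8))
  expect_error(proximity(1, 1, 0), "positive")
  # monotone decrease in |a|
  vals <- proximity(0:5, 0, 2)
  expect_true(all(diff(vals) < 0))
})

test_that("activation graph weights match the elementwise definition", {
  M <- matrix(c(1, 1, 2, 1), 2, 2)  # M[1,1]=1 M[1,2]=2 M[2,1]=1 M[2,2]=1
  sigma <- 0.8
  g <- build_activation_graph(M, sigma)
  expect_equal(dim(g$weights), c(4, 4))
  expect_true(all(g$weights >= 0))
  # oracle: loop over all node pairs with the scalar primitives
  nodes <- cbind(rep(1:2, times = 2), rep(1:2, each = 2))  # column-major
  for (u in 1:4) for (v in 1:4) {
    expected <- log_dissimilarity(M, nodes[u, ], nodes[v, ]) *
      proximity(nodes[u, 1] - nodes[v, 1], nodes[u, 2] - nodes[v, 2], sigma)
    expect_equal(g$weights[u, v], expected)
  }
  # spot value: weight from (1,1) to (1,2) is ln 2 * F(0, -1)
  expect_equal(g$weights[1, 3], log(2) * exp(-1 / (2 * sigma^2)))

  expect_error(build_activation_graph(matrix(1, 50, 50)), "downsample")
})

test_that("constant maps give uniform equilibrium and 0.5 saliency", {
  g <- build_activation_graph(matrix(1, 4, 4), sigma = 1)
  expect_true(all(g$weights == 0))
  expect_equal(equilibrium(g), rep(1 / 16, 16))
  S <- saliency_map(matrix(100, 48, 48), r = 8)
  expect_true(all(S$values == 0.5))
})

test_that("power iteration matches the dense eigen oracle", {
  set.seed(11)
  for (trial in 1:20) {
    n <- sample(4:64, 1)
    W <- matrix(runif(n * n), n, n)
    pi_est <- equilibrium(W)
    expect_equal(sum(pi_est), 1, tolerance = 1e-9)
    P <- W / rowSums(W)
    e <- eigen(t(P))
    i1 <- which.max(Re(e$values))
    v <- Re(e$vectors[, i1]); v <- v / sum(v)
    expect_lt(max(abs(pi_est - v)), 1e-6)
  }
  # symmetric two-node chain
  expect_equal(equilibrium(matrix(c(0, 1, 1, 0), 2, 2)), c(0.5, 0.5))
})

test_that("mass concentration moves mass towards the activation peak", {
  A <- matrix(0.02, 4, 4); A[2, 3] <- 0.5
  A <- A / sum(A)
  out <- concentrate_mass(A, sigma = 1)
  expect_equal(sum(out), 1, tolerance = 1e-9)
  expect_gt(out[2, 3], A[2, 3])
  # uniform map is a fixed point
  U <- matrix(1 / 16, 4, 4)
  expect_equal(concentrate_mass(U, sigma = 1), U, tolerance = 1e-9)
})

test_that("combined saliency maps are rescaled to [0, 1] at image size", {
  m1 <- matrix(runif(64), 8, 8); m1 <- m1 / sum(m1)
  S <- combine_maps(list(m1), c(32, 32))
  expect_equal(dim(S$values), c(32, 32))
  expect_equal(range(S$values), c(0, 1))
  expect_equal(S$working, m1)
  # mean of identical maps equals the map
  S2 <- combine_maps(list(m1, m1, m1), c(32, 32))
  expect_equal(S2$working, m1)
  expect_error(combine_maps(list(), c(8, 8)), "at least one")
})

test_that("threshold is the saliency map mean", {
  expect_equal(threshold_tau(matrix(c(0.2, 0.6, 0.4, 0.8), 2, 2)), 0.5)
  expect_equal(threshold_tau(matrix(0.3, 5, 5)), 0.3)
  set.seed(2)
  S <- matrix(runif(100), 10, 10)
  expect_gte(threshold_tau(S), 0)
  expect_lte(threshold_tau(S), 1)
})

test_that("salient region masking follows the threshold exactly", {
  px <- matrix(runif(16 * 16, 1, 255), 16, 16)
  S <- matrix(runif(16 * 16), 16, 16)
  reg <- extract_salient(gray_image(px), S)
  tau <- mean(S)
  expect_identical(reg$mask, S >= tau)
  expect_equal(reg$masked, px * (S >= tau))
  expect_lte(sum(reg$masked != 0), sum(reg$mask))
  # bbox is the tight box of the mask
  rr <- range(which(rowSums(reg$mask) > 0))
  cc <- range(which(colSums(reg$mask) > 0))
  expect_equal(unname(reg$bbox), c(rr[1], cc[1], rr[2], cc[2]))

  # constant saliency keeps the whole image
  regc <- extract_salient(gray_image(px), matrix(0.4, 16, 16))
  expect_true(all(regc$mask))
  expect_equal(regc$masked, px)

  # block toy: tau = 0.5 keeps exactly the two high-valued blocks
  S2 <- matrix(c(0.2, 0.6, 0.4, 0.8), 2, 2)[rep(1:2, each = 4),
                                            rep(1:2, each = 4)]
  reg2 <- extract_salient(gray_image(matrix(9, 8, 8)), S2)
  expect_identical(unname(reg2$mask), S2 >= 0.5)
  expect_equal(sum(reg2$mask), 32)
})

test_that("tiny masks fall back to the whole image", {
  S <- matrix(0, 32, 32); S[1, 1] <- 1  # mean ~ 0.001, mask ~ 1 px
  reg <- extract_salient(gray_image(matrix(7, 32, 32)), S)
  expect_true(all(reg$mask))
})

test_that("orientation channels are exactly invariant to intensity shifts", {
  set.seed(20)
  px <- matrix(runif(64 * 64, 40, 160), 64, 64)
  fm1 <- build_feature_maps(px, r = 12)
  fm2 <- build_feature_maps(px + 40, r = 12)
  for (nm in c("orient_0", "orient_45", "orient_90", "orient_135"))
    expect_lt(sum(abs(fm1[[nm]] - fm2[[nm]])), 1e-12)
  # the intensity channel sees ratio contrast, so a constant shift only
  # compresses it: the combined working map moves a little, not wildly
  S1 <- saliency_map(px, r = 12)
  S2 <- saliency_map(px + 40, r = 12)
  expect_lt(sum(abs(S1$working - S2$working)), 0.05)
})
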