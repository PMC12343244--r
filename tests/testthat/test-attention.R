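# Dual-channel masked attention: mask semantics, oracle equivalence,
# residual/normalization wiring, and the final alpha combination.

test_that("an all-ones mask reduces to unmasked scaled dot-product attention", {
  set.seed(2)
  H <- matrix(rnorm(8), 4L, 2L)
  W <- replicate(3, matrix(rnorm(4), 2L), simplify = FALSE)
  masked <- channelAttention(H, matrix(1, 4L, 4L), W[[1]], W[[2]], W[[3]])
  plain <- channelAttention(H, matrix(1, 4L, 4L), W[[1]], W[[2]], W[[3]],
                            maskMode = "none")
  expect_equal(masked$output, plain$output)
})

test_that("zero queries give uniform attention rows (column mean of V)", {
  set.seed(4)
  H <- matrix(rnorm(12), 4L, 3L)
  Wv <- matrix(rnorm(9), 3L)
  res <- channelAttention(H, matrix(1, 4L, 4L), Wq = matrix(0, 3L, 3L),
                          Wk = matrix(rnorm(9), 3L), Wv = Wv, heads = 1L)
  V <- H %*% Wv
  expect_equal(res$attention[[1L]], matrix(0.25, 4L, 4L))
  for (i in 1:4) expect_equal(res$output[i, ], colMeans(V))
})

test_that("channel attention matches the two-loop oracle in every mode", {
  set.seed(6)
  for (trial in 1:10) {
    N <- sample(2:4, 1L)
    heads <- sample(c(1L, 2L), 1L)
    dc <- 4L
    H <- matrix(rnorm(N * dc), N, dc)
    mask <- matrix(sample(0:3, N * N, replace = TRUE), N, N)
    diag(mask) <- 0
    mask[N, ] <- 1; mask[, N] <- 1   # keep every row attendable
    Ws <- replicate(3, matrix(rnorm(dc * dc) * 0.7, dc), simplify = FALSE)
    for (mode in c("multiplicative", "additive_neg_inf", "none")) {
      got <- channelAttention(H, mask, Ws[[1]], Ws[[2]], Ws[[3]],
                              heads = heads, maskMode = mode)
      ref <- oracleChannelAttention(H, mask, Ws[[1]], Ws[[2]], Ws[[3]],
                                    heads = heads, maskMode = mode)
      expect_equal(got$output, ref, tolerance = 1e-6,
                   label = paste("mode", mode, "N", N, "heads", heads))
    }
  }
})

test_that("softmax rows sum to one in every head and mode", {
  set.seed(12)
  H <- matrix(rnorm(20), 5L, 4L)
  mask <- matrix(sample(0:2, 25L, replace = TRUE), 5L)
  mask[, 5L] <- 1
  for (mode in c("multiplicative", "additive_neg_inf")) {
    res <- channelAttention(H, mask, matrix(rnorm(16), 4L),
                            matrix(rnorm(16), 4L), matrix(rnorm(16), 4L),
                            heads = 2L, maskMode = mode)
    for (P in res$attention)
      expect_equal(rowSums(P), rep(1, 5L), tolerance = 1e-6)
  }
})

test_that("a gl layer with zero value weights is pure LayerNorm of the input", {
  set.seed(9)
  d <- 8L; N <- 3L
  H <- matrix(rnorm(N * d), N, d)
  A <- matrix(1, N, N) - diag(N)
  D <- A
  w <- list(Wq_g = matrix(rnorm(16), 4L), Wk_g = matrix(rnorm(16), 4L),
            Wv_g = matrix(0, 4L, 4L),
            Wq_l = matrix(rnorm(16), 4L), Wk_l = matrix(rnorm(16), 4L),
            Wv_l = matrix(0, 4L, 4L),
            gamma = matrix(1, 1L, d), beta = matrix(0, 1L, d))
  out <- glLayer(H, A, D, w, heads = 2L)$output
  ln <- getFromNamespace(".layerNormRows", "MotifFuse")
  expect_equal(out, ln(H, rep(1, d), rep(0, d)))
  # shape preserved when stacking
  expect_equal(dim(glLayer(out, A, D, w, heads = 2L)$output), c(N, d))
})

test_that("a single-node motif graph keeps the attention finite", {
  w <- list(Wq_g = matrix(1, 1L), Wk_g = matrix(1, 1L), Wv_g = matrix(1, 1L),
            Wq_l = matrix(1, 1L), Wk_l = matrix(1, 1L), Wv_l = matrix(1, 1L),
            gamma = matrix(1, 1L, 2L), beta = matrix(0, 1L, 2L))
  H <- matrix(c(0.3, -0.2), 1L, 2L)
  out <- glLayer(H, matrix(0, 1L, 1L), matrix(0, 1L, 1L), w, heads = 1L)
  expect_true(all(is.finite(out$output)))
})

test_that("alpha scales the refined signal into the final representation", {
  M <- c(1, 2, 3, 4)
  H <- matrix(rnorm(12), 3L, 4L)
  expect_equal(finalizeRepresentation(M, H, alpha = 0), M)
  expect_equal(finalizeRepresentation(M, H * 0, alpha = 5), M)
  expect_equal(finalizeRepresentation(M * 0, H, alpha = 1), H[3L, ])
  expect_equal(finalizeRepresentation(M, H, alpha = 0.5, pooling = "mean"),
               M + 0.5 * colMeans(H))
})

test_that("attention export yields labeled row-stochastic heads", {
  model <- tinyModel(attnLayers = 2L)
  att <- exportAttention(model, "Cc1ccc(N)cc1", layer = -1L)
  expect_length(att$global, 2L)   # heads per channel in the tiny config
  expect_length(att$local, 2L)
  for (P in c(att$global, att$local)) {
    expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-6)
    expect_equal(nrow(P), length(att$motifKeys) + 1L)
  }
  # default-size models export four heads per channel (eight matrices)
  big <- motifFuseModel(tinyVocab(),
                        motifFuseConfig(hiddenSize = 16L, depth = 1L,
                                        attnLayers = 1L), seed = 1L)
  attBig <- exportAttention(big, "Cc1ccccc1")
  expect_length(c(attBig$global, attBig$local), 8L)
  expect_error(exportAttention(model, "CCO", layer = 7L), "out of range")
})

test_that("the global attention row of a single-motif molecule is a 2-point distribution", {
  model <- tinyModel()
  att <- exportAttention(model, "C1CC1")
  P <- att$global[[1L]]
  expect_equal(dim(P), c(2L, 2L))
  row <- P[att$globalIndex, ]
  expect_equal(sum(row), 1, tolerance = 1e-9)
})
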