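test_that("the encoder maps any bag to N x 512 regardless of N and size", {
  enc <- build_encoder(encoder_spec("tinycnn"), seed = 1)
  for (sz in c(16, 32)) {
    for (n in c(1L, 5L)) {
      H <- encode_instances(noise_bag(n, size = sz, seed = n), enc)
      expect_equal(dim(H), c(n, 512L))
      expect_true(all(is.finite(H)))
    }
  }
})

test_that("duplicated images produce identical feature rows", {
  enc <- build_encoder(encoder_spec("tinycnn"), seed = 2)
  img <- matrix(runif(32 * 32), 32)
  bag <- image_bag("d", list(img, img), 1L)
  H <- encode_instances(bag, enc)
  expect_equal(H[1, ], H[2, ])
})

test_that("tinycnn features match an independent layer-by-layer convolution
           oracle", {
  enc <- build_encoder(encoder_spec("tinycnn"), seed = 3)
  set.seed(10)
  img <- matrix(runif(16 * 16), 16)
  H <- encode_instances(image_bag("o", list(img), 1L), enc)
  expect_equal(as.vector(H), oracle_tinycnn_features(enc, img),
               tolerance = 1e-10)

  # hand-set constant kernels on a constant image: still matches the oracle
  enc2 <- enc
  for (i in seq_along(enc2$layers)) {
    if (enc2$layers[[i]]$op == "conv") {
      enc2$layers[[i]]$W[] <- 0.01
      enc2$layers[[i]]$b[] <- 0.1
    }
  }
  cimg <- matrix(0.5, 16, 16)
  H2 <- encode_instances(image_bag("c", list(cimg), 1L), enc2)
  expect_equal(as.vector(H2), oracle_tinycnn_features(enc2, cimg),
               tolerance = 1e-10)
})

test_that("pretrained VGG13 raises a capability error suggesting tinycnn", {
  expect_error(build_encoder(encoder_spec("vgg13", pretrained = TRUE)),
               "tinycnn")
})

test_that("randomly initialized VGG13 still honors the shape contract", {
  enc <- build_encoder(encoder_spec("vgg13", pretrained = FALSE), seed = 1)
  H <- encode_instances(noise_bag(1, size = 32, seed = 4), enc)
  expect_equal(dim(H), c(1L, 512L))
})

test_that("attention pooling handles singleton and symmetric bags exactly", {
  p <- random_attention_params(seed = 5)
  h <- matrix(rnorm(512), 1, 512)
  res <- attention_pool(h, p)
  expect_equal(res$weights, 1.0)
  expect_equal(res$M, as.vector(h))

  H <- h[rep(1, 4), ]
  res4 <- attention_pool(H, p)
  expect_equal(res4$weights, rep(0.25, 4))
  expect_equal(res4$M, as.vector(h))
})

test_that("zero score weights reduce attention to exact mean pooling", {
  p <- random_attention_params(seed = 6)
  p$W2[] <- 0
  p$b2 <- 1.7
  set.seed(11)
  H <- matrix(rnorm(7 * 512), 7, 512)
  res <- attention_pool(H, p)
  expect_equal(res$weights, rep(1 / 7, 7))
  expect_equal(res$M, mean_pool(H), tolerance = 1e-12)
})

test_that("attention weights and bag feature match the scalar-loop oracle", {
  for (s in 1:5) {
    set.seed(s)
    n <- sample(1:6, 1)
    H <- matrix(rnorm(n * 512, sd = 2), n, 512)
    p <- attention_params(512, 128)
    got <- attention_pool(H, p)
    want <- oracle_attention(H, p)
    expect_equal(got$weights, want$a, tolerance = 1e-6)
    expect_equal(got$M, want$M, tolerance = 1e-6)
  }
})

test_that("softmax weights are a proper distribution for arbitrary scores", {
  for (s in 1:50) {
    set.seed(s + 100)
    n <- sample(1:12, 1)
    H <- matrix(rnorm(n * 512, sd = sample(c(0.1, 1, 50), 1)), n, 512)
    p <- attention_params(512, 128)
    a <- attention_pool(H, p)$weights
    expect_true(all(a > 0))
    expect_lt(abs(sum(a) - 1), 1e-6)
  }
})

test_that("max and mean pooling match hand arithmetic and loop oracles", {
  h <- matrix(rnorm(512), 1, 512)
  expect_equal(max_pool(h), as.vector(h))
  expect_equal(mean_pool(h), as.vector(h))

  H <- matrix(0, 2, 512)
  H[1, 1] <- 1
  H[2, 2] <- 1
  mx <- max_pool(H)
  expect_equal(mx[1:2], c(1, 1))
  expect_true(all(mx[3:512] == 0))
  expect_equal(mean_pool(H)[1:2], c(0.5, 0.5))

  set.seed(21)
  H <- matrix(rnorm(5 * 512), 5, 512)
  expect_equal(max_pool(H), oracle_max_pool(H))
  expect_equal(mean_pool(H), oracle_mean_pool(H), tolerance = 1e-12)
})

test_that("pooling an empty or non-finite feature matrix errors", {
  expect_error(max_pool(matrix(numeric(0), 0, 512)), "empty")
  expect_error(attention_pool(matrix(numeric(0), 0, 512),
                              random_attention_params()), "empty")
  H <- matrix(rnorm(512), 1, 512)
  H[3] <- NaN
  expect_error(mean_pool(H), "finite")
})

test_that("the bag head is a plain sigmoid over a dot product", {
  M <- rnorm(512)
  expect_equal(classify_bag(M, list(w = numeric(512), b = 0))$probability,
               0.5)
  set.seed(30)
  w <- rnorm(512)
  got <- classify_bag(M, list(w = w, b = 0.3))
  z <- sum(w * M) + 0.3
  expect_equal(got$logits, z, tolerance = 1e-7)
  expect_equal(got$probability, 1 / (1 + exp(-z)), tolerance = 1e-7)
  # monotone in the logit
  big <- classify_bag(M * 0 + 1, list(w = rep(1, 512), b = 0))
  expect_gt(big$probability, 0.999)
})

test_that("bag probability is invariant to instance permutation for every
           pooling mode", {
  bag <- noise_bag(5, size = 16, seed = 8)
  for (pool in c("attention", "max", "mean")) {
    m <- mil_model(pooling = pool, seed = 4)
    p0 <- predict_bag(m, bag)$probability
    set.seed(99)
    for (r in 1:5) {
      perm <- sample(length(bag$images))
      pb <- image_bag(bag$patient_id, bag$images[perm], bag$bag_label)
      expect_lt(abs(predict_bag(m, pb)$probability - p0), 1e-6)
    }
  }
})

test_that("a duplicated image gives the same probability as the singleton
           bag", {
  img <- matrix(runif(16 * 16), 16)
  one <- image_bag("a", list(img), 1L)
  five <- image_bag("a", rep(list(img), 5), 1L)
  for (pool in c("attention", "max", "mean")) {
    m <- mil_model(pooling = pool, seed = 9)
    expect_equal(predict_bag(m, one)$probability,
                 predict_bag(m, five)$probability, tolerance = 1e-9)
  }
})
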