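test_that("feature extraction is affine + ReLU with identity dropout off", {
  v <- c(0.5, 1.2, 0.3)
  id <- list(W = diag(3), b = numeric(3))
  expect_equal(feature_extract(v, id), v)

  vneg <- c(0.5, -1.2, 0.3)
  out <- feature_extract(vneg, id)
  expect_equal(out[2], 0)
  expect_equal(out[c(1, 3)], vneg[c(1, 3)])

  W <- matrix(c(1, 0, -1, 2, 1, 0.5, 0, -2, 1), 3, 3)
  b <- c(0.1, -0.2, 0.3)
  v <- c(1, -1, 2)
  hand <- pmax(c(sum(v * W[, 1]) + 0.1, sum(v * W[, 2]) - 0.2,
                 sum(v * W[, 3]) + 0.3), 0)
  expect_equal(feature_extract(v, list(W = W, b = b)), hand, tolerance = 1e-12)
  expect_error(feature_extract(c(1, 2), list(W = W, b = b)),
               class = "ppifusion_validation_error")
})

test_that("shared extraction weights treat both pair members identically", {
  set.seed(51)
  params <- list(W = matrix(rnorm(12), 4, 3), b = rnorm(3))
  v1 <- rnorm(4); v2 <- rnorm(4)
  expect_identical(feature_extract(v1, params), feature_extract(v1, params))
  # applying to (v1, v2) is two independent calls of the same map
  expect_identical(c(feature_extract(v1, params), feature_extract(v2, params)),
                   c(feature_extract(v1, params), feature_extract(v2, params)))
})

test_that("pair fusion obeys symmetry and length contracts", {
  set.seed(52)
  d <- 5L
  params <- attention_params(matrix(rnorm(d * d), d, d),
                             matrix(rnorm(d * d), d, d),
                             matrix(rnorm(d * d), d, d))
  f1 <- rnorm(d); f2 <- rnorm(d)
  fo <- fuse_pair(f1, f2, params)
  expect_length(fo$F, length(fo$F1) + length(fo$F2))
  expect_equal(fo$F, c(fo$F1, fo$F2))
  expect_equal(fo$F2, (f1 + f2) / 2)
  # mean branch invariant under swap
  fo_sw <- fuse_pair(f2, f1, params)
  expect_equal(fo_sw$F2, fo$F2)
  # equal inputs: mean branch returns the input
  fo_eq <- fuse_pair(f1, f1, params)
  expect_equal(fo_eq$F2, f1)
  expect_error(fuse_pair(f1, rnorm(3), params),
               class = "ppifusion_validation_error")
})

test_that("a 2-dimensional pair works through the fusion equations by hand", {
  # identity projections, d_k = 2
  params <- attention_params(diag(2), diag(2), diag(2))
  f1 <- c(1, 0); f2 <- c(0, 2)
  # scores s[t,u] = f_t . f_u / sqrt(2)
  s <- rbind(c(1, 0), c(0, 4)) / sqrt(2)
  w1 <- exp(s[1, ] - max(s[1, ])); w1 <- w1 / sum(w1)
  w2 <- exp(s[2, ] - max(s[2, ])); w2 <- w2 / sum(w2)
  o1 <- w1[1] * f1 + w1[2] * f2
  o2 <- w2[1] * f1 + w2[2] * f2
  fo <- fuse_pair(f1, f2, params)
  expect_equal(fo$F1, c(o1, o2), tolerance = 1e-10)
  expect_equal(fo$F2, c(0.5, 1), tolerance = 1e-12)
  expect_equal(fo$F, c(o1, o2, 0.5, 1), tolerance = 1e-10)
})

test_that("prediction head computes sigmoid of the layered forward pass", {
  # single layer forcing logit 0
  head <- list(layers = list(list(W = matrix(0, 3, 1), b = 0)))
  expect_equal(predict_pair(c(1, 2, 3), head), 0.5)

  # increasing final bias strictly increases the probability
  p1 <- predict_pair(c(1, 2, 3),
                     list(layers = list(list(W = matrix(1, 3, 1), b = -1))))
  p2 <- predict_pair(c(1, 2, 3),
                     list(layers = list(list(W = matrix(1, 3, 1), b = 0.5))))
  expect_gt(p2, p1)

  # two-layer toy head against a hand-computed pass
  W1 <- matrix(c(1, -1, 0.5, 0.2, 0.3, -0.7), 2, 3)
  b1 <- c(0.1, 0, -0.2)
  W2 <- matrix(c(0.4, -0.6, 1), 3, 1)
  b2 <- 0.05
  f <- c(0.8, -0.3)
  h <- pmax(as.vector(f %*% W1) + b1, 0)
  logit <- sum(h * W2) + b2
  got <- predict_pair(f, list(layers = list(list(W = W1, b = b1),
                                            list(W = W2, b = b2))))
  expect_equal(got, 1 / (1 + exp(-logit)), tolerance = 1e-10)
  expect_gt(got, 0); expect_lt(got, 1)

  bad <- list(layers = list(list(W = matrix(Inf, 2, 1), b = 0)))
  expect_error(predict_pair(c(0, 1), bad), "layer 1",
               class = "ppifusion_numerical_error")
})

test_that("analytic gradients match numerical gradients in both profiles", {
  ns <- asNamespace("ppifusion")
  set.seed(53)
  B <- 3L
  X1 <- matrix(rnorm(B * 6), B); X2 <- matrix(rnorm(B * 6), B)
  y <- c(1, 0, 1)
  for (mh in c(TRUE, FALSE)) {
    cfg <- model_config(input_dim = 6L, extractor_dim = 4L,
                        head_layers = c(5L, 1L), n_heads = 2L,
                        dropout_rate = 0, use_multihead = mh, seed = 7L)
    m <- init_model(cfg)
    loss_fn <- function(params) {
      mm <- structure(list(config = cfg, params = params),
                      class = "mpidnn_model")
      bce_loss(ns$model_forward(mm, X1, X2)$prob, y)
    }
    fw <- ns$model_forward(m, X1, X2, want_cache = TRUE)
    g <- ns$model_backward(m, fw$cache, (fw$prob - y) / B)
    eps <- 1e-6
    flat_names <- intersect(names(m$params),
                            c("ex_W", "ex_b", "fus_Wq", "fus_Wk", "fus_Wv",
                              "ha_Wq", "ha_Wk", "ha_Wv", "ha_Wo", "ha_bo"))
    for (nm in flat_names) {
      for (i in sample(length(m$params[[nm]]), min(4, length(m$params[[nm]])))) {
        pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
        num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
        expect_equal(g[[nm]][i], num, tolerance = 1e-5)
      }
    }
    for (l in seq_along(m$params$mlp_W)) {
      i <- sample(length(m$params$mlp_W[[l]]), 1)
      pp <- m$params; pp$mlp_W[[l]][i] <- pp$mlp_W[[l]][i] + eps
      pm <- m$params; pm$mlp_W[[l]][i] <- pm$mlp_W[[l]][i] - eps
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      expect_equal(g$mlp_W[[l]][i], num, tolerance = 1e-5)
    }
  }
})

test_that("evaluation-mode forward passes are pure and bitwise repeatable", {
  set.seed(54)
  cfg <- small_model_cfg(seed = 9L)
  m <- init_model(cfg)
  X1 <- matrix(rnorm(5 * 64), 5); X2 <- matrix(rnorm(5 * 64), 5)
  p1 <- model_predict(m, X1, X2)
  p2 <- model_predict(m, X1, X2)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_error(model_predict(m, X1[, 1:10], X2[, 1:10]),
               class = "ppifusion_validation_error")
})

test_that("weight initialization is seed-reproducible", {
  m1 <- init_model(small_model_cfg(seed = 5L))
  m2 <- init_model(small_model_cfg(seed = 5L))
  m3 <- init_model(small_model_cfg(seed = 6L))
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params$ex_W, m3$params$ex_W))
  # uniform bound 1/sqrt(fan_in)
  expect_lte(max(abs(m1$params$ex_W)), 1 / sqrt(64))
})
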