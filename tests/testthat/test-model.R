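# Network forward pass: shape contracts, convolution oracles, attention
# arithmetic, parameter counting, determinism, ablation isolation, and a
# finite-difference check of the full backward pass.

test_that("backbone and encoder shape contracts hold at the default widths", {
  cfg <- model_config(image_size = 64L, seed = 2L)
  params <- init_params(cfg)
  img <- rand_image(64)
  bb <- backbone_forward(img, params, cfg)
  expect_identical(dim(bb$f_b), c(16L, 16L, 256L))
  expect_identical(dim(bb$block1), c(64L, 64L, 64L))
  expect_identical(dim(bb$block2), c(32L, 32L, 128L))
  mf <- mfov_forward(bb$f_b, params, cfg)
  expect_identical(dim(mf$f_E), c(16L, 16L, 512L))
  for (k in 1:4) expect_identical(dim(mf$f_d[[k]]), c(16L, 16L, 64L))
  expect_identical(dim(mf$f_p), c(16L, 16L, 256L))
  de <- decoder_forward(mf$f_E, bb$block1, bb$block2, params, cfg)
  expect_identical(dim(de$f_U), c(64L, 64L, 64L))
  expect_error(backbone_forward(matrix(0.5, 30, 30), params, cfg),
               "divisible")
})

test_that("attention maps have contract shapes and open-interval values across sizes", {
  for (n in c(64L, 96L, 128L)) {
    cfg <- slim_model_config(image_size = n)
    params <- init_params(cfg)
    out <- model_forward(rand_image(n, seed = n), params, cfg)
    expect_length(out$m_c, 64L)
    expect_identical(dim(out$m_s), c(n, n))
    expect_identical(dim(out$m_p), c(n, n))
    expect_true(all(out$m_s > 0 & out$m_s < 1))
    expect_true(all(out$m_p > 0 & out$m_p < 1))
    expect_true(all(is.finite(out$m_c)))
    expect_gt(out$y_hat, 0); expect_lt(out$y_hat, 1)
    expect_identical(dim(out$f_U), c(n, n, 64L))
  }
})

test_that("dilated convolutions match a brute-force sliding-window oracle", {
  set.seed(11)
  for (dil in c(1L, 2L, 4L)) {
    x <- array(rnorm(64), c(8, 8, 1))
    warr <- array(rnorm(9), c(3, 3, 1, 1))
    got <- mfadnet:::conv_fwd(x, flat_w(warr), 0.3, 3, 3, dil)$out
    expect_equal(got, oracle_conv2d(x, warr, 0.3, dil), tolerance = 1e-6)
  }
  # multi-channel 7x7, the spatial-attention kernel size
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  warr <- array(rnorm(7 * 7 * 2), c(7, 7, 2, 1))
  got <- mfadnet:::conv_fwd(x, flat_w(warr), -0.1, 7, 7, 1L)$out
  expect_equal(got, oracle_conv2d(x, warr, -0.1), tolerance = 1e-6)
})

test_that("cascaded dilated encoder follows the concatenation recursion", {
  cfg <- tiny_model_config()
  params <- init_params(cfg)
  f_b <- array(abs(rnorm(2 * 2 * 4)), c(2, 2, 4))
  mf <- mfov_forward(f_b, params, cfg)
  # channel arithmetic: 4 * cd + C3
  expect_identical(dim(mf$f_E)[3], 4L * 2L + 4L)
  # with all dilated weights zero the dilated features vanish and
  # f_E = 0 (+) 0 (+) 0 (+) 0 (+) f_p
  p0 <- params
  for (k in 1:4) {
    p0[[paste0("md", k, "_w")]][] <- 0
    p0[[paste0("md", k, "_b")]][] <- 0
  }
  mf0 <- mfov_forward(f_b, p0, cfg)
  for (k in 1:4) expect_true(all(mf0$f_d[[k]] == 0))
  expect_equal(mf0$f_E[, , 9:12], mf0$f_p)
  # stride-1 same-padded 2x2 max pooling preserves shape and dominates input
  expect_identical(dim(mf0$f_p), dim(f_b))
  expect_true(all(mf0$f_p >= f_b - 1e-12))
  # spatially constant input with fixed weights gives spatially constant
  # dilated features away from the padding border
  cfg2 <- slim_model_config(image_size = 32L)
  p2 <- init_params(cfg2)
  fb2 <- array(rep(seq_len(8), each = 64), c(8, 8, 8))
  mf2 <- mfov_forward(fb2, p2, cfg2)
  inner <- mf2$f_d[[1]][3:6, 3:6, 1]
  expect_lt(max(abs(inner - inner[1])), 1e-10)
})

test_that("channel attention follows the max-plus-mean sigmoid arithmetic", {
  f_U <- array(0, c(2, 2, 64))
  f_U[, , 1] <- matrix(c(0, 1, 2, 3), 2, 2)
  f_U[, , 2] <- -1
  m_c <- channel_attention(f_U)
  expect_equal(m_c[1], 1 / (1 + exp(-4.5)), tolerance = 1e-6)
  expect_equal(m_c[2], 1 / (1 + exp(2)), tolerance = 1e-6)
  expect_identical(channel_attention(f_U, enabled = FALSE), rep(1, 64))
})

test_that("spatial attention matches the brute-force 7x7 oracle and ablation", {
  set.seed(13)
  f_U <- array(runif(8 * 8 * 64), c(8, 8, 64))
  warr <- array(rnorm(7 * 7 * 2, sd = 0.5), c(7, 7, 2, 1))
  m_s <- spatial_attention(f_U, flat_w(warr), 0.2)
  # oracle: channel max / mean maps -> 7x7 conv -> sigmoid
  cmax <- apply(f_U, c(1, 2), max)
  cmean <- apply(f_U, c(1, 2), mean)
  z <- oracle_conv2d(array(c(cmax, cmean), c(8, 8, 2)), warr, 0.2)
  expect_equal(m_s, 1 / (1 + exp(-z[, , 1])), tolerance = 1e-6)
  # zero conv weights -> uniform 0.5
  m_s0 <- spatial_attention(f_U, flat_w(array(0, c(7, 7, 2, 1))), 0)
  expect_true(all(abs(m_s0 - 0.5) < 1e-12))
  expect_identical(spatial_attention(f_U, NULL, NULL, enabled = FALSE),
                   matrix(1, 8, 8))
})

test_that("probability map fuses attention maps per the elementwise formula", {
  set.seed(17)
  f_U <- array(runif(2 * 2 * 64), c(2, 2, 64))
  m_c <- runif(64)
  m_s <- matrix(runif(4), 2, 2)
  w <- matrix(rnorm(64), 64, 1)
  b <- 0.1
  m_p <- probability_map(f_U, m_c, m_s, w, b)
  oracle <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    acc <- b
    for (c in 1:64) acc <- acc + m_s[i, j] * m_c[c] * f_U[i, j, c] * w[c, 1]
    oracle[i, j] <- 1 / (1 + exp(-acc))
  }
  expect_equal(m_p, oracle, tolerance = 1e-6)
  # zero 1x1 conv -> uniform 0.5; zero spatial map -> uniform sigmoid(bias)
  expect_true(all(abs(probability_map(f_U, m_c, m_s, 0 * w, 0) - 0.5)
                  < 1e-12))
  expect_true(all(abs(probability_map(f_U, m_c, 0 * m_s, w, 0.7)
                      - 1 / (1 + exp(-0.7))) < 1e-12))
})

test_that("classification head softmax identities hold", {
  cfg <- tiny_model_config()
  params <- init_params(cfg)
  m_p <- matrix(0.3, 8, 8)
  # all-zero weights: symmetric logits give 0.5
  p0 <- params
  for (nm in c("cls1_w", "cls1_b", "cls2_w", "cls2_b", "cls3_w", "cls3_b"))
    p0[[nm]][] <- 0
  expect_equal(classify(m_p, p0, cfg)$y_hat, 0.5, tolerance = 1e-12)
  # logit offset delta gives the logistic closed form
  p1 <- p0
  p1$cls3_b <- c(0.4, 0.4 + 1.3)
  expect_equal(classify(m_p, p1, cfg)$y_hat, 1 / (1 + exp(-1.3)),
               tolerance = 1e-9)
  # determinism
  expect_identical(classify(m_p, params, cfg)$y_hat,
                   classify(m_p, params, cfg)$y_hat)
  # shape error on wrong input size
  expect_error(classify(matrix(0.3, 4, 4), params, cfg), "expects")
})

test_that("parameter count matches closed-form arithmetic", {
  cfg <- model_config(image_size = 64L, seed = 1L)
  n <- count_parameters(cfg, by_tensor = TRUE)
  cls <- sum(n[c("cls1_w", "cls1_b", "cls2_w", "cls2_b", "cls3_w",
                 "cls3_b")])
  expect_identical(as.integer(cls),
                   4096L * 256L + 256L + 256L * 256L + 256L + 256L * 2L + 2L)
  expect_identical(as.integer(cls), 1115138L)
  expect_identical(count_parameters(cfg), count_parameters(cfg))
  # doubling cd touches only the encoder convs and the first decoder conv
  cfg2 <- model_config(image_size = 64L, cd = 128L)
  n2 <- count_parameters(cfg2, by_tensor = TRUE)
  changed <- names(n)[n != n2[names(n)]]
  expect_setequal(changed, c("md1_w", "md1_b", "md2_w", "md2_b", "md3_w",
                             "md3_b", "md4_w", "md4_b", "u1_w"))
})

test_that("forward pass is deterministic in eval mode and seeded in train mode", {
  cfg <- slim_model_config()
  params <- init_params(cfg)
  img <- rand_image(32, seed = 9)
  o1 <- model_forward(img, params, cfg)
  o2 <- model_forward(img, params, cfg)
  expect_identical(o1$m_p, o2$m_p)
  expect_identical(o1$y_hat, o2$y_hat)
  set.seed(31); t1 <- model_forward(img, params, cfg, train = TRUE)
  set.seed(31); t2 <- model_forward(img, params, cfg, train = TRUE)
  expect_identical(t1$m_p, t2$m_p)
  # dropout actually perturbs the training-mode forward
  set.seed(32); t3 <- model_forward(img, params, cfg, train = TRUE)
  expect_false(identical(t1$m_p, t3$m_p))
})

test_that("ablation switches isolate exactly the flagged component", {
  img <- rand_image(32, seed = 12)
  full <- model_forward(img, init_params(slim_model_config()),
                        slim_model_config())
  no_mc <- slim_model_config(use_channel_attention = FALSE)
  o_mc <- model_forward(img, init_params(no_mc), no_mc)
  # same seed: backbone/decoder identical, only the channel path changes
  expect_identical(o_mc$f_U, full$f_U)
  expect_identical(o_mc$m_s, full$m_s)
  expect_identical(o_mc$m_c, rep(1, 64))
  expect_false(identical(o_mc$m_p, full$m_p))

  no_ms <- slim_model_config(use_spatial_attention = FALSE)
  o_ms <- model_forward(img, init_params(no_ms), no_ms)
  expect_identical(o_ms$f_U, full$f_U)
  expect_identical(o_ms$m_c, full$m_c)
  expect_identical(o_ms$m_s, matrix(1, 32, 32))

  no_mfov <- slim_model_config(use_mfov = FALSE)
  o_mf <- model_forward(img, init_params(no_mfov), no_mfov)
  expect_identical(o_mf$f_b, full$f_b)   # backbone untouched
  expect_identical(o_mf$f_E, o_mf$f_b)   # bypass
  expect_identical(dim(o_mf$m_p), c(32L, 32L))
})

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_model_config()
  params <- init_params(cfg)
  img <- rand_image(8, seed = 21)
  w <- loss_weights()
  loss_of <- function(p, y) {
    out <- model_forward(img, p, cfg)
    mfadnet:::loss_bundle(out, y, w)$bundle$total
  }
  for (y in c(1, 0)) {
    out <- model_forward(img, params, cfg)
    lb <- mfadnet:::loss_bundle(out, y, w)
    g <- mfadnet:::model_backward(out, lb$dm_p, lb$dm_s, lb$dlogits, params,
                                  cfg)
    expect_setequal(names(g), names(params))
    set.seed(100 + y)
    eps <- 1e-6
    for (nm in names(params)) {
      ii <- sample(length(params[[nm]]), min(2, length(params[[nm]])))
      for (i in ii) {
        p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps
        p3 <- params; p3[[nm]][i] <- p3[[nm]][i] - eps
        num <- (loss_of(p2, y) - loss_of(p3, y)) / (2 * eps)
        expect_equal(g[[nm]][i], num, tolerance = 1e-3,
                     label = sprintf("grad %s[%d] (y=%d)", nm, i, y))
      }
    }
  }
})

test_that("every parameter receives gradient from a mixed batch", {
  cfg <- tiny_model_config()
  params <- init_params(cfg)
  w <- loss_weights()
  acc <- NULL
  for (y in c(1, 0)) {
    img <- rand_image(8, seed = 40 + y)
    out <- model_forward(img, params, cfg)
    lb <- mfadnet:::loss_bundle(out, y, w)
    g <- mfadnet:::model_backward(out, lb$dm_p, lb$dm_s, lb$dlogits, params,
                                  cfg)
    acc <- if (is.null(acc)) g else Map(`+`, acc, g[names(acc)])
  }
  for (nm in names(acc))
    expect_gt(sum(abs(acc[[nm]])), 0, label = paste("gradient of", nm))
})
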