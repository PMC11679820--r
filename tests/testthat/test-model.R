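# shared numerical-gradient helpers ---------------------------------------

num_grad_check <- function(model, B = 3L, n_probe = 4L, eps = 1e-5, seed = 99L) {
  set.seed(seed)
  T_len <- model$T_len
  D <- model$d_in
  x <- array(stats::rnorm(B * T_len * D), dim = c(B, T_len, D))
  y <- onehot(
    factor(sample(model$classes, B, replace = TRUE), levels = model$classes),
    model$classes
  )
  loss_fn <- function(params) {
    m <- model
    m$params <- params
    xent_loss(model_fw(m, x, train = FALSE)$probs, y) + model_l2(m)
  }
  out <- model_fw(model, x, train = FALSE)
  grads <- model_bw(model, out$cache, (out$probs - y) / B)
  worst <- 0
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    idx <- sample(length(p), min(n_probe, length(p)))
    for (i in idx) {
      p1 <- model$params
      p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- model$params
      p2[[nm]][i] <- p2[[nm]][i] - eps
      gn <- (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
      ga <- grads[[nm]][i]
      worst <- max(worst, abs(ga - gn) / max(1e-6, abs(ga) + abs(gn)))
    }
  }
  worst
}

small_tf_cfg <- function(num_blocks = 2L, ff_conv_kernel = 3L,
                         dropout_rate = 0, ...) {
  transformer_config(
    num_blocks = num_blocks, num_heads = 2L, key_dim = 4L, d_model = 8L,
    ff_conv_filters = 10L, ff_conv_kernel = ff_conv_kernel,
    dropout_rate = dropout_rate, mlp_units = 9L, ...
  )
}

# configuration validation --------------------------------------------------

test_that("invalid model configurations are rejected naming the field", {
  expect_error(transformer_config(num_heads = 0L), "num_heads")
  expect_error(transformer_config(dropout_rate = 1), "dropout_rate")
  expect_error(transformer_config(ff_conv_kernel = 2L), "ff_conv_kernel")
  expect_error(transformer_config(positional_encoding = "fourier"), "positional_encoding|arg")
  expect_error(recurrent_config(units = 0L), "units")
  expect_error(recurrent_config("rnn"), "arg")
  expect_error(train_config(split_fractions = c(0.5, 0.5, 0.5)), "split_fractions")
  expect_error(train_config(batch_size = 0L), "batch_size")
})

# forward-pass contracts -----------------------------------------------------

test_that("forward passes give one probability row per clip, summing to 1", {
  x <- array(stats::rnorm(4 * 5 * 6), dim = c(4, 5, 6))
  for (m in list(
    build_transformer(6L, 5L, small_tf_cfg(), seed = 1L),
    build_recurrent(6L, 5L, recurrent_config("lstm", units = 7L, dropout_rate = 0), seed = 2L),
    build_recurrent(6L, 5L, recurrent_config("gru", units = 7L, dropout_rate = 0), seed = 3L)
  )) {
    probs <- model_fw(m, x, train = FALSE)$probs
    expect_identical(dim(probs), c(4L, 7L))
    expect_rows_sum_to_one(probs)
    expect_true(all(probs > 0))
  }
})

test_that("evaluation mode is deterministic even with dropout configured", {
  m <- build_transformer(6L, 5L, small_tf_cfg(dropout_rate = 0.5), seed = 4L)
  x <- array(stats::rnorm(2 * 5 * 6), dim = c(2, 5, 6))
  p1 <- model_fw(m, x, train = FALSE)$probs
  set.seed(77) # a different RNG state must not matter in eval mode
  p2 <- model_fw(m, x, train = FALSE)$probs
  expect_identical(p1, p2)
  # training mode with dropout is stochastic
  set.seed(1)
  q1 <- model_fw(m, x, train = TRUE)$probs
  set.seed(2)
  q2 <- model_fw(m, x, train = TRUE)$probs
  expect_false(identical(q1, q2))
})

# gradients ------------------------------------------------------------------

test_that("transformer backprop matches finite differences", {
  m <- build_transformer(6L, 5L, small_tf_cfg(), seed = 1L)
  expect_lt(num_grad_check(m), 1e-3)
})

test_that("learned-positional-encoding transformer backprop matches finite differences", {
  m <- build_transformer(6L, 5L, transformer_config(
    num_blocks = 1L, num_heads = 1L, key_dim = 3L, d_model = 6L,
    ff_conv_filters = 8L, dropout_rate = 0, mlp_units = 5L,
    positional_encoding = "learned"
  ), seed = 4L)
  expect_lt(num_grad_check(m, seed = 101L), 1e-3)
})

test_that("LSTM and GRU backprop match finite differences", {
  lstm <- build_recurrent(6L, 5L, recurrent_config("lstm",
    units = 7L,
    num_layers = 2L, dropout_rate = 0
  ), seed = 2L)
  gru <- build_recurrent(6L, 5L, recurrent_config("gru",
    units = 7L,
    num_layers = 2L, dropout_rate = 0
  ), seed = 3L)
  expect_lt(num_grad_check(lstm, seed = 102L), 1e-4)
  expect_lt(num_grad_check(gru, seed = 103L), 1e-4)
})

# architecture probes ---------------------------------------------------------

test_that("without positional encoding the transformer is time-permutation invariant", {
  cfg <- small_tf_cfg(ff_conv_kernel = 1L, positional_encoding = "none")
  m <- build_transformer(6L, 5L, cfg, seed = 5L)
  set.seed(8)
  x <- array(stats::rnorm(2 * 5 * 6), dim = c(2, 5, 6))
  perm <- sample(5)
  xp <- x[, perm, , drop = FALSE]
  p0 <- model_fw(m, x, train = FALSE)$probs
  pp <- model_fw(m, xp, train = FALSE)$probs
  expect_equal(p0, pp, tolerance = 1e-10)

  # with sinusoidal encoding the same permutation changes the output
  ms <- build_transformer(6L, 5L, small_tf_cfg(ff_conv_kernel = 1L), seed = 5L)
  expect_gt(max(abs(
    model_fw(ms, x, train = FALSE)$probs - model_fw(ms, xp, train = FALSE)$probs
  )), 1e-6)
})

test_that("recurrent models are sensitive to temporal order", {
  m <- build_recurrent(6L, 5L, recurrent_config("gru", units = 7L, dropout_rate = 0), seed = 6L)
  set.seed(9)
  x <- array(stats::rnorm(2 * 5 * 6), dim = c(2, 5, 6))
  xr <- x[, 5:1, , drop = FALSE]
  expect_gt(max(abs(
    model_fw(m, x, train = FALSE)$probs - model_fw(m, xr, train = FALSE)$probs
  )), 1e-6)
})

test_that("parameter counts match the closed forms", {
  d <- 6L
  u <- 7L
  c7 <- 7L
  lstm <- build_recurrent(d, 5L, recurrent_config("lstm", units = u), seed = 1L)
  gru <- build_recurrent(d, 5L, recurrent_config("gru", units = u), seed = 1L)
  expect_identical(n_parameters(lstm), 4L * (d * u + u * u + u) + u * c7 + c7)
  expect_identical(n_parameters(gru), 3L * (d * u + u * u + u) + u * c7 + c7)

  dm <- 8L
  hk <- 2L * 4L # heads * key_dim
  f <- 10L
  k <- 3L
  mlp <- 9L
  tf <- build_transformer(d, 5L, small_tf_cfg(), seed = 1L)
  per_block <- 2L * dm + 3L * (dm * hk + hk) + (hk * dm + dm) + 2L * dm +
    (k * dm * f + f) + (f * dm + dm)
  expect_identical(
    n_parameters(tf),
    (d * dm + dm) + 2L * per_block + (dm * mlp + mlp) + (mlp * c7 + c7)
  )
})

# optimisation ---------------------------------------------------------------

test_that("cosine decay starts at the base rate and decreases monotonically", {
  lrs <- vapply(0:39, cosine_decay_lr, numeric(1), base = 0.01, max_epochs = 40L)
  expect_equal(lrs[1], 0.01, tolerance = 1e-12)
  expect_true(all(diff(lrs) < 0))
  expect_gte(min(lrs), 0)
  expect_lt(lrs[40], 0.01 * 0.01)
  # with a floor, the rate never drops below it
  lrs2 <- vapply(0:39, cosine_decay_lr, numeric(1),
    base = 0.01, max_epochs = 40L, floor = 0.002
  )
  expect_gte(min(lrs2), 0.002)
})

test_that("early stopping halts after patience epochs without improvement", {
  feats <- make_feats(6L, seed = 2L)
  m <- build_transformer(4L, 6L, small_tf_cfg(num_blocks = 1L, ff_conv_kernel = 1L), seed = 1L)
  cfg <- train_config(
    base_learning_rate = 0, lr_schedule = "constant",
    max_epochs = 50L, early_stopping_patience = 3L, seed = 0L
  )
  fit <- train_classifier(m, feats, feats, cfg)
  # epoch 1 sets the best; with lr 0 nothing improves afterwards
  expect_identical(nrow(fit$history), 4L)
  expect_identical(fit$best_epoch, 1L)
})

test_that("training is reproducible from the seed", {
  feats <- make_feats(5L, seed = 3L)
  sp <- split_clips(feats, train_config(seed = 1L, split_fractions = c(0.6, 0.2, 0.2)))
  cfg <- train_config(
    max_epochs = 3L, early_stopping_patience = 3L,
    batch_size = 4L, seed = 11L
  )
  m <- build_transformer(4L, 6L, small_tf_cfg(dropout_rate = 0.2, ff_conv_kernel = 1L), seed = 7L)
  f1 <- train_classifier(m, sp$train, sp$val, cfg)
  f2 <- train_classifier(m, sp$train, sp$val, cfg)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
})

test_that("a separable two-class toy problem is learned to perfect training accuracy", {
  feats <- make_feats(12L, sep = 2, seed = 4L)
  val <- make_feats(4L, sep = 2, seed = 5L)
  m <- build_transformer(4L, 6L, transformer_config(
    num_blocks = 1L, num_heads = 2L, key_dim = 4L, d_model = 8L,
    ff_conv_filters = 16L, dropout_rate = 0, mlp_units = 8L, num_classes = 2L
  ), seed = 1L)
  cfg <- train_config(
    base_learning_rate = 5e-3, max_epochs = 50L,
    early_stopping_patience = 50L, batch_size = 8L, seed = 0L
  )
  fit <- train_classifier(m, feats, val, cfg)
  expect_gte(max(fit$history$train_acc), 1)
  pred <- predict(fit, feats, type = "class")
  expect_identical(as.character(pred$.pred_class), feats$label)
})

test_that("optimizer update rules match single-step hand calculations", {
  params <- list(w = matrix(c(1, 2), 1), b = 0.5)
  grads <- list(w = matrix(c(0.1, -0.2), 1), b = 0.3)
  # SGD: p - lr * g
  o <- opt_init("sgd", params)
  st <- opt_step(o, params, grads, lr = 0.1)
  expect_equal(st$params$w, matrix(c(1, 2), 1) - 0.1 * matrix(c(0.1, -0.2), 1),
    tolerance = 1e-12
  )
  # Adam first step: update is -lr * sign-ish g / (|g| + eps-ish); check exactly
  o <- opt_init("adam", params)
  st <- opt_step(o, params, grads, lr = 0.1)
  b1 <- 0.9
  b2 <- 0.999
  eps <- 1e-7
  mhat <- grads$b # m / (1 - b1) with m = (1 - b1) g
  vhat <- grads$b^2
  expect_equal(as.numeric(st$params$b), 0.5 - 0.1 * mhat / (sqrt(vhat) + eps),
    tolerance = 1e-9
  )
  # AdamW decays the matrix weight but not the scalar bias
  o <- opt_init("adamw", params, weight_decay = 0.01)
  st <- opt_step(o, params, list(w = matrix(0, 1, 2), b = 0), lr = 0.1)
  expect_equal(st$params$w, params$w * (1 - 0.1 * 0.01), tolerance = 1e-9)
  expect_equal(as.numeric(st$params$b), 0.5, tolerance = 1e-12)
})

# splitting -------------------------------------------------------------------

test_that("split_clips stratifies, partitions, and is deterministic", {
  ds <- tiny_dataset(clips_per_class = 4L, seed = 20L)
  feats <- build_features(ds, seed = 1L)
  cfg <- train_config(split_fractions = c(0.5, 0.25, 0.25), seed = 3L)
  sp <- split_clips(feats, cfg)
  # partition: every clip in exactly one split
  ids <- c(sp$train$clip_id, sp$val$clip_id, sp$test$clip_id)
  expect_setequal(ids, feats$clip_id)
  expect_identical(anyDuplicated(ids), 0L)
  # stratified: each class contributes floor-based counts to train
  expect_true(all(table(sp$train$label) == 2L))
  expect_true(all(table(sp$val$label) == 1L))
  expect_true(all(table(sp$test$label) == 1L))
  # deterministic under the same config
  sp2 <- split_clips(feats, cfg)
  expect_identical(sp$train$clip_id, sp2$train$clip_id)
  # a class with too few clips errors
  short <- feats[-(which(feats$label == "lie")[1:2]), ] # leave 'lie' only 2 clips
  expect_error(split_clips(short, cfg), "class 'lie'")
})
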