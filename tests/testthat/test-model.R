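test_that("layer shape algebra matches the hand-derived closed form", {
  # depth 1, KS 5, KC 32: same-padding conv keeps 250, pool halves to 125;
  # flatten = 125 * 32
  s1 <- build_model(param_combo(5, 32, c(256, 256)))
  expect_equal(s1$flatten_len, 125 * 32)

  # the selected depth-3 architecture: 250 -> 125 -> 62 -> 31; 31 * 128
  s3 <- build_model(selected_combo())
  expect_equal(s3$layers$out_len, c(125, 62, 31))
  expect_equal(s3$layers$out_ch, c(64, 64, 128))
  expect_equal(s3$flatten_len, 31 * 128)

  # generic invariant: repeated floor-halving times the last kernel count,
  # for every combo in a small grid
  g <- param_grid(depths = 1:3, kernel_sizes = c(5, 9),
                  kernel_counts = c(4, 8), dense_counts = c(16, 32))
  for (d in 1:3) {
    for (cb in enumerate_combos(g, d)) {
      L <- 250
      for (i in seq_len(d)) L <- L %/% 2
      expect_equal(build_model(cb)$flatten_len,
                   L * cb$kernel_counts[d])
    }
  }

  # pooled length hitting zero is rejected, naming the offending layer
  expect_error(build_model(param_combo(c(3, 3), c(4, 4), c(8, 8)),
                           train_config(input_len = 3)),
               "layer 2")
  # dropout_keep = 1 disables feature dropping but builds fine
  expect_equal(build_model(param_combo(5, 4, c(8, 8),
                                       dropout_keep = 1))$dropout_keep, 1)

  expect_error(param_combo(4, 8, c(8, 8)), "odd")
  expect_error(param_combo(5, 8, c(8, 8, 8)), "two positive")
  expect_error(param_combo(c(5, 7), 8, c(8, 8)), "equal length")
})

test_that("compiled engine agrees with the pure-R reference forward pass", {
  ds <- generate_dataset(n_subjects = 1, per_pattern = 6, seed = 31)
  m <- train_cnn(ds, combo = param_combo(c(9, 5), c(6, 4), c(24, 12)),
                 cfg = train_config(epochs = 2, seed = 7))
  P_cpp <- predict(m, ds, type = "prob")
  net <- list(input_len = 250L, n_classes = 5L, dropout_keep = 1)
  P_ref <- respcnn:::network_forward(
    reference_params(m), net,
    respcnn:::standardize_windows(ds$values))$probs
  expect_equal(unname(P_cpp), P_ref, tolerance = 1e-4)
  expect_equal(unname(max.col(P_cpp)), unname(max.col(P_ref)))
})

test_that("training masters a linearly separable toy and is seeded", {
  toy <- toy_separable_set(n_per_class = 16, seed = 2)
  combo <- param_combo(5, 8, c(32, 16))
  cfg <- train_config(epochs = 15, seed = 3)
  m <- train_cnn(toy, combo = combo, cfg = cfg)
  expect_gt(m$history$train_acc[15], 0.99)

  # loss is non-increasing after a 2-epoch warm-up (small jitter allowed)
  loss <- m$history$train_loss
  expect_true(all(diff(loss[3:15]) < 0.05))

  # same seed twice: identical weights and history
  m2 <- train_cnn(toy, combo = combo, cfg = cfg)
  expect_identical(m$history, m2$history)
  expect_identical(m$weights, m2$weights)

  # the trained model classifies its own training data
  expect_equal(as.character(predict(m, toy)), as.character(toy$labels))

  expect_error(train_cnn(respcnn:::new_window_set(
    matrix(0, 0, 250), character(0), character(0))), "empty")
})

test_that("predictions are normalized, deterministic and batch-invariant", {
  toy <- toy_separable_set(n_per_class = 6, seed = 4)
  m <- train_cnn(toy, combo = param_combo(5, 4, c(16, 8)),
                 cfg = train_config(epochs = 5, seed = 1))
  P <- predict(m, toy, type = "prob")
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-6)
  expect_true(all(P >= 0))

  # batched prediction equals window-by-window prediction
  lab_batch <- predict(m, toy)
  lab_single <- do.call(c, lapply(seq_len(nrow(toy$values)), function(i) {
    as.character(predict(m, toy$values[i, , drop = FALSE]))
  }))
  expect_equal(as.character(lab_batch), lab_single)

  expect_error(predict(m, matrix(0, 2, 100)), "expects")

  # model round trip through serialization
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m3 <- load_model(path)
  expect_equal(as.character(predict(m3, toy)), as.character(lab_batch))
  unlink(path)
})

test_that("history length equals the epoch count with and without val", {
  toy <- toy_separable_set(n_per_class = 4, seed = 5)
  sp <- split_dataset(toy, seed = 1)
  m <- train_cnn(sp$train, sp$test, combo = param_combo(5, 4, c(8, 8)),
                 cfg = train_config(epochs = 3, seed = 1))
  expect_equal(nrow(m$history), 3)
  expect_false(anyNA(m$history$val_acc))
  m2 <- train_cnn(sp$train, combo = param_combo(5, 4, c(8, 8)),
                  cfg = train_config(epochs = 3, seed = 1))
  expect_true(all(is.na(m2$history$val_acc)))
})
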