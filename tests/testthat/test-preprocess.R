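test_that("Kalman filter matches the hand-stepped scalar recursion", {
  # three steps computed from the predict/update equations by hand:
  # p0=1, q=0.01, r=0.1, est0=0
  # step 1: p=1.01, g=1.01/1.11,  est = 0.909909...
  out <- kalman_filter(c(1, 2, 3), q = 0.01, r = 0.1, init_estimate = 0,
                       init_variance = 1)
  expect_equal(out[1], 1.01 / 1.11)
  expect_equal(out, kalman_oracle(c(1, 2, 3), 0.01, 0.1, 0, 1),
               tolerance = 1e-15)

  # property: step-for-step equivalence with the oracle on random inputs
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- sample(2:100, 1)
      x <- rnorm(n, sd = 5)
      q <- runif(1, 1e-3, 1)
      r <- runif(1, 0, 1)
      expect_equal(kalman_filter(x, q, r),
                   kalman_oracle(x, q, r, x[1], r + q), tolerance = 1e-12)
    })
  }
})

test_that("Kalman filter limits behave as expected", {
  # constant input: estimate converges to the constant
  out <- kalman_filter(rep(4.2, 1000), q = 0.01, r = 0.1)
  expect_lt(abs(out[1000] - 4.2), 1e-6)
  # r = 0: the measurement is fully trusted from the first update
  x <- c(3, -1, 7, 2)
  expect_equal(kalman_filter(x, q = 0.01, r = 0), x)
  expect_error(kalman_filter(numeric(0)), "non-empty")
  expect_error(kalman_filter(c(1, 2), q = 0), "q")
})

test_that("respiration extraction picks the modulated bin", {
  tr <- simulate_pattern("eupnea", 20, seed = 1)
  fr <- embed_in_radar_frames(tr, clutter_sd = 0, seed = 1)
  out <- extract_respiration(fr, filter = FALSE)
  expect_equal(out$selected_bin, fr$target_bin)
  expect_gt(cor(out$samples, tr$samples), 0.99)
  # the Kalman-filtered path still tracks the slow breathing signal
  outf <- extract_respiration(fr)
  expect_gt(cor(outf$samples, tr$samples), 0.98)

  # two modulated bins: a tolerance window that excludes the stronger far
  # bin must select the near one
  n <- 200
  bins <- matrix(0, n, 660)
  bins[, 8] <- sin(seq_len(n) / 5)        # bin 7 (0-based), at ~20 cm
  bins[, 101] <- 3 * sin(seq_len(n) / 3)  # bin 100, far stronger
  fr2 <- structure(list(frame_no = 0:(n - 1), timestamp = (0:(n - 1)) / 25,
                        bins = bins, fs = 25, bin_spacing_cm = 3,
                        target_bin = NA_integer_),
                   class = "radar_frames")
  expect_equal(extract_respiration(fr2, distance_cm = 20,
                                   tolerance_bins = 2)$selected_bin, 7)

  # all-constant frames: documented tie-break selects the lowest index
  fr3 <- fr2
  fr3$bins <- matrix(1, n, 660)
  out3 <- extract_respiration(fr3, distance_cm = 20, tolerance_bins = 2,
                              filter = FALSE)
  expect_equal(out3$selected_bin, 5)
  expect_equal(var(out3$samples), 0)

  expect_error(extract_respiration(fr2, distance_cm = 1e5), "outside")
})

test_that("window counts follow the closed form and windows are slices", {
  x <- sin(seq_len(660) / 7)
  ws <- window_series(x, window_spec(), label = "eupnea")
  # floor((660 - 250) / 12) + 1 = 35
  expect_equal(nrow(ws$values), 35)
  starts <- attr(ws, "starts")
  for (i in c(1, 17, 35)) {
    expect_equal(ws$values[i, ], x[(starts[i] + 1):(starts[i] + 250)])
  }
  expect_true(all(ws$labels == "eupnea"))  # label purity

  expect_equal(nrow(window_series(x[1:250], window_spec(),
                                  label = "apnea")$values), 1)

  # a 10-minute recording at 25 fps (15,000 samples) offers 1230 candidate
  # windows; the cap reduces them to exactly 500 by uniform stride
  long <- rnorm(15000)
  expect_equal(nrow(window_series(long, window_spec(), label = "motion",
                                  max_windows = 500)$values), 500)
  full <- window_series(long, window_spec(), label = "motion")
  expect_equal(nrow(full$values), (15000 - 250) %/% 12 + 1)

  expect_error(window_series(x[1:100], window_spec(), label = "eupnea"),
               "shorter")
  expect_error(window_spec(shift = 0), "shift")
})

test_that("stratified split is exact, disjoint and seeded", {
  ds <- generate_dataset(n_subjects = 2, per_pattern = 10, seed = 21)
  sp <- split_dataset(ds, train_fraction = 0.6, seed = 5)
  expect_equal(nrow(sp$train$values), 60)
  expect_equal(nrow(sp$test$values), 40)
  # per-class 12/8 at fraction 0.6 of 20
  expect_equal(unname(table(sp$train$labels)), rep(12L, 5),
               ignore_attr = TRUE)
  expect_equal(nrow(sp$train$values) + nrow(sp$test$values),
               nrow(ds$values))
  # disjointness via window fingerprints
  key <- function(v) apply(v, 1, function(r) paste(signif(r[1:5], 10),
                                                   collapse = ","))
  expect_length(intersect(key(sp$train$values), key(sp$test$values)), 0)

  sp2 <- split_dataset(ds, train_fraction = 0.6, seed = 5)
  expect_identical(sp$train$values, sp2$train$values)
  sp3 <- split_dataset(ds, train_fraction = 0.6, seed = 6)
  expect_false(identical(sp$train$values, sp3$train$values))

  # one window per class cannot be split: all go to training, with warning
  tiny <- generate_dataset(n_subjects = 1, per_pattern = 1, seed = 2)
  w <- capture_warnings(sp4 <- split_dataset(tiny, seed = 1))
  expect_length(w, 5)
  expect_match(w, "assigning all", all = TRUE)
  expect_equal(nrow(sp4$train$values), 5)
  expect_equal(nrow(sp4$test$values), 0)

  expect_error(split_dataset(ds, train_fraction = 1.2), "train_fraction")
})
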