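test_that("breath cycle geometry follows the rate and I:E ratio", {
  # 15 breaths/min at 25 Hz: 4 s cycle = 100 samples
  expect_length(simulate_breath_cycle(breath_params(rate = 15)), 100)

  # expiration share 2 at 12 breaths/min: 125-sample cycle, inspiration
  # occupies the first ceiling(125 / 3) = 42 samples
  cyc <- simulate_breath_cycle(breath_params(rate = 12, ie_ratio = 2))
  expect_length(cyc, 125)
  expect_equal(which.max(cyc), 42)
  expect_true(all(diff(cyc[1:42]) > 0))        # monotone rise
  expect_true(all(diff(cyc[42:125]) < 0))      # monotone fall
  expect_equal(max(cyc) - min(cyc), 1)         # peak-to-trough = amplitude

  # degenerate amplitude: flat zero cycle
  expect_equal(simulate_breath_cycle(breath_params(amplitude = 0)),
               rep(0, 94))

  expect_error(breath_params(rate = -1), "rate")
  expect_error(breath_params(ie_ratio = 3), "ie_ratio")
})

test_that("pattern traces have the requested length and are seeded", {
  tr <- simulate_pattern("eupnea", 60, seed = 42)
  expect_s3_class(tr, "respiration_trace")
  expect_length(tr$samples, 1500)
  expect_true(all(is.finite(tr$samples)))

  # bit-identical under the same seed, different under another
  tr2 <- simulate_pattern("eupnea", 60, seed = 42)
  expect_identical(tr$samples, tr2$samples)
  tr3 <- simulate_pattern("eupnea", 60, seed = 43)
  expect_false(identical(tr$samples, tr3$samples))

  expect_length(simulate_pattern("eupnea", 0, seed = 1)$samples, 0)
  expect_error(simulate_pattern("apnea", 5, seed = 1), "apnea")
  expect_error(simulate_pattern("eupnea", 60,
                                params = breath_params(rate = 30)),
               "outside")
  expect_error(simulate_pattern("eupnea", -1, seed = 1), "duration_s")
})

test_that("peak counting recovers the nominal rate within 1 breath/min", {
  cases <- list(list(class = "eupnea", rate = 16),
                list(class = "bradypnea", rate = 8),
                list(class = "tachypnea", rate = 30))
  for (case in cases) {
    for (seed in c(11, 12)) {
      tr <- simulate_pattern(case$class, 60,
                             params = breath_params(rate = case$rate),
                             noise_sd = 0.05, seed = seed)
      est <- peak_rate_oracle(tr$samples, tr$fs, case$rate)
      expect_lt(abs(est - case$rate), 1,
                label = sprintf("%s seed %d: |%.2f - %g|", case$class,
                                seed, est, case$rate))
    }
  }
})

test_that("apnea suppresses the excursion by at least 90%", {
  ap <- simulate_pattern("apnea", 30, noise_sd = 0.002, seed = 3)
  # amplitude bounded by 10% of the eupnea baseline excursion (1 unit)
  expect_lte(max(abs(ap$samples - mean(ap$samples))), 0.10)

  eu <- simulate_pattern("eupnea", 30, noise_sd = 0.01, seed = 3)
  ap2 <- simulate_pattern("apnea", 30, noise_sd = 0.01, seed = 3)
  expect_lt(var(ap2$samples), 0.02 * var(eu$samples))
})

test_that("motion transients dwarf the breathing amplitude", {
  for (seed in c(5, 6, 7)) {
    mo <- simulate_pattern("motion", 30, noise_sd = 0.02, seed = seed)
    expect_gt(diff(range(mo$samples)), 3)  # breathing alone spans ~1
  }
})

test_that("radar embedding places the trace at the distance bin", {
  tr <- simulate_pattern("eupnea", 10, seed = 1)
  fr <- embed_in_radar_frames(tr, distance_cm = 20, clutter_sd = 0,
                              seed = 2)
  expect_equal(dim(fr$bins), c(250, 660))
  expect_equal(fr$frame_no, 0:249)
  expect_equal(diff(fr$timestamp), rep(1 / 25, 249))
  # 20 cm at 3 cm/bin: target bin round(20/3) = 7
  expect_equal(fr$target_bin, 7)
  # noiseless round trip through the target bin
  expect_gt(cor(fr$bins[, 8], tr$samples), 0.99)
  # bin spacing 2.5 cm: round(20/2.5) = 8
  expect_equal(embed_in_radar_frames(tr, bin_spacing_cm = 2.5,
                                     seed = 1)$target_bin, 8)
  expect_error(embed_in_radar_frames(tr, distance_cm = 5000), "outside")
})

test_that("dataset generation follows the collection protocol", {
  ds <- generate_dataset(n_subjects = 1, per_pattern = 1, seed = 9)
  expect_equal(nrow(ds$values), 5)
  expect_setequal(as.character(ds$labels), respiration_classes())

  ds2 <- generate_dataset(n_subjects = 2, per_pattern = 3, seed = 9)
  expect_equal(nrow(ds2$values), 2 * 5 * 3)
  expect_equal(ncol(ds2$values), 250)
  expect_equal(as.integer(table(ds2$labels)), rep(6L, 5))
  meta <- attr(ds2, "meta")
  expect_equal(nrow(meta), 10)
  expect_true(all(meta$n_windows == 3))

  # same seed -> identical collection
  ds3 <- generate_dataset(n_subjects = 2, per_pattern = 3, seed = 9)
  expect_identical(ds2$values, ds3$values)
  expect_identical(ds2$labels, ds3$labels)
})

test_that("radar acquisition path preserves window labels and shapes", {
  ds <- generate_dataset(n_subjects = 1, per_pattern = 2, seed = 4,
                         via_radar = TRUE)
  expect_equal(nrow(ds$values), 10)
  expect_equal(ncol(ds$values), 250)
  expect_true(all(is.finite(ds$values)))
})
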