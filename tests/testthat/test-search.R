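test_that("combination counts follow the closed form", {
  g <- param_grid()
  expect_equal(combo_count(g, 1), 800)
  expect_equal(combo_count(g, 2), 40000)
  expect_equal(combo_count(g, 3), 2000000)

  # brute-force oracle on a small grid: |KS|=2, |KC|=1, |DLNC|=2, depth 2
  gs <- param_grid(depths = 1:2, kernel_sizes = c(5, 9),
                   kernel_counts = 8, dense_counts = c(16, 32))
  expect_equal(combo_count(gs, 2), 16)
  oracle <- expand.grid(ks1 = c(5, 9), ks2 = c(5, 9), d1 = c(16, 32),
                        d2 = c(16, 32))
  combos <- enumerate_combos(gs, 2)
  expect_length(combos, nrow(oracle))
  got <- unique(vapply(combos, function(cb)
    paste(cb$kernel_sizes[1], cb$kernel_sizes[2], cb$dense_neurons[1],
          cb$dense_neurons[2]), ""))
  want <- unique(with(oracle, paste(ks1, ks2, d1, d2)))
  expect_setequal(got, want)
})

test_that("enumeration order reproduces the published sequence numbers", {
  # the four iteration-best combinations published with their sequence
  # numbers in the 2,000,000-combo depth-3 grid decode exactly
  g <- param_grid()
  for (ref in published_best_combos()) {
    cb <- combo_at(g, 3, ref$seq_no + 1)  # seq numbers are zero-based
    expect_equal(cb$kernel_sizes, as.integer(ref$ks))
    expect_equal(cb$kernel_counts, as.integer(ref$kc))
    expect_equal(cb$dense_neurons, as.integer(ref$dense))
    expect_equal(cb$seq_no, ref$seq_no)
  }
  expect_error(combo_at(g, 1, 801), "outside")
})

test_that("subsampled enumeration is seeded and validated", {
  g <- param_grid()
  sub <- enumerate_combos(g, 2, subsample = 50, seed = 9)
  expect_length(sub, 50)
  seqs <- vapply(sub, `[[`, 0, "seq_no")
  expect_false(any(duplicated(seqs)))
  expect_identical(
    seqs, vapply(enumerate_combos(g, 2, subsample = 50, seed = 9), `[[`, 0,
                 "seq_no"))
  expect_error(enumerate_combos(g, 1, subsample = 1000), "subsample")
  expect_error(enumerate_combos(g, 3), "materialize")
})

test_that("depth search picks the argmax-mean depth with ties to shallow", {
  g <- param_grid(depths = 1:3, kernel_sizes = c(5, 9),
                  kernel_counts = c(4, 8), dense_counts = c(16, 32))
  # per-depth means injected by a mock trainer
  means <- c(0.874, 0.907, 0.926)
  res <- find_optimal_depth(g, function(cb) means[cb$depth])
  expect_equal(res$d_opt, 3)
  expect_equal(res$per_depth$mean_acc, means)
  expect_equal(res$per_depth$n_combos,
               c(combo_count(g, 1), combo_count(g, 2), combo_count(g, 3)))

  # constant accuracy everywhere: smallest depth wins the tie
  expect_equal(find_optimal_depth(g, function(cb) 0.5)$d_opt, 1)

  # pseudo-random mock: per-depth mean equals an independent re-computation
  tr <- mock_trainer()
  res2 <- find_optimal_depth(g, tr)
  for (d in 1:3) {
    oracle <- mean(vapply(enumerate_combos(g, d), tr, 0))
    expect_equal(res2$per_depth$mean_acc[d], oracle)
  }
})

test_that("failed trainer evaluations are excluded with a warning", {
  g <- param_grid(depths = 1, kernel_sizes = c(5, 9), kernel_counts = 4,
                  dense_counts = 16)
  flaky <- function(cb) {
    if (cb$kernel_sizes[1] == 9) stop("diverged") else 0.7
  }
  expect_warning(res <- find_optimal_depth(g, flaky), "failed")
  expect_equal(res$per_depth$n_failed, 1)
  expect_equal(res$per_depth$mean_acc, 0.7)
})

test_that("range search pools per-iteration bests into [min, max] ranges", {
  g <- param_grid(depths = 1, kernel_sizes = c(5, 9), kernel_counts = c(4, 8),
                  dense_counts = c(16, 32))
  # a unique known best: every range collapses to that combo's values
  best <- function(cb) if (cb$kernel_sizes[1] == 9 && cb$kernel_counts[1] == 4 &&
                           all(cb$dense_neurons == c(32, 16))) 0.95 else 0.5
  res <- find_optimal_ranges(g, 1, best, n_iterations = 1)
  expect_equal(res$ranges$ks, c(9, 9))
  expect_equal(res$ranges$kc, c(4, 4))
  expect_equal(res$ranges$dlnc, c(16, 32))

  # random per-iteration mock: ranges equal a brute-force re-scan of the
  # recorded bests, and adding iterations never shrinks a range
  tr <- function(cb, iteration) {
    ((cb$seq_no * 53 + iteration * 17) %% 97) / 97
  }
  r6 <- find_optimal_ranges(g, 1, tr, n_iterations = 6)
  ks_all <- unlist(lapply(r6$best_combos, `[[`, "kernel_sizes"))
  kc_all <- unlist(lapply(r6$best_combos, `[[`, "kernel_counts"))
  dl_all <- unlist(lapply(r6$best_combos, `[[`, "dense_neurons"))
  expect_equal(res6 <- r6$ranges,
               list(ks = range(ks_all), kc = range(kc_all),
                    dlnc = range(dl_all)))
  r3 <- find_optimal_ranges(g, 1, tr, n_iterations = 3)
  expect_true(r3$ranges$ks[1] >= r6$ranges$ks[1] &&
                r3$ranges$ks[2] <= r6$ranges$ks[2])
  expect_true(r3$ranges$dlnc[1] >= r6$ranges$dlnc[1] &&
                r3$ranges$dlnc[2] <= r6$ranges$dlnc[2])
  # ranges are always drawn from the grid's value sets
  expect_true(all(r6$ranges$ks %in% g$kernel_sizes))
  expect_true(all(r6$ranges$kc %in% g$kernel_counts))
  expect_true(all(r6$ranges$dlnc %in% g$dense_counts))
})

test_that("injected iteration bests reproduce the published optimal ranges", {
  # grid restricted to the values occurring in the published bests keeps
  # the enumeration small while containing all four combos
  g <- param_grid(depths = 3, kernel_sizes = c(21, 25, 29),
                  kernel_counts = c(64, 128, 256),
                  dense_counts = c(1024, 2048))
  refs <- published_best_combos()
  match_ref <- function(cb, ref) {
    all(cb$kernel_sizes == ref$ks) && all(cb$kernel_counts == ref$kc) &&
      all(cb$dense_neurons == ref$dense)
  }
  trainer <- function(cb, iteration) {
    ref <- refs[[(iteration - 1) %% length(refs) + 1]]
    if (match_ref(cb, ref)) 0.93 else 0.2
  }
  res <- find_optimal_ranges(g, 3, trainer, n_iterations = 10)
  expect_equal(res$ranges$ks, c(21, 29))
  expect_equal(res$ranges$kc, c(64, 256))
  expect_equal(res$ranges$dlnc, c(1024, 2048))
})

test_that("search summaries are tabular", {
  g <- param_grid(depths = 1:3, kernel_sizes = c(5, 9), kernel_counts = 4,
                  dense_counts = c(16, 32))
  ds <- find_optimal_depth(g, mock_trainer())
  expect_equal(dim(summarize_search(ds)), c(3, 4))
  rs <- find_optimal_ranges(g, 1, mock_trainer(), n_iterations = 10)
  s <- summarize_search(rs)
  expect_equal(nrow(s$iterations), 10)
  expect_equal(nrow(s$ranges), 3)
  expect_equal(s$ranges$parameter, c("KS", "KC", "DLNC"))
  expect_error(summarize_search(list()), "depth_search")
})
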