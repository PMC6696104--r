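# Shared fixtures and independent oracles, all built in code at test time.

# Five well-separated prototype waveforms (one per class) plus tiny noise:
# a linearly separable sanity task for classifiers.
toy_separable_set <- function(n_per_class = 20, seed = 1, len = 250) {
  t_ <- seq_len(len)
  protos <- list(
    eupnea    = sin(2 * pi * 3 * t_ / len),
    bradypnea = sin(2 * pi * 1.5 * t_ / len),
    tachypnea = sin(2 * pi * 6 * t_ / len),
    apnea     = 0.05 * sin(2 * pi * 12 * t_ / len),
    motion    = c(rep(0, len / 2), rep(4, len / 2)))
  withr::with_seed(seed, {
    vals <- do.call(rbind, lapply(respiration_classes(), function(cls) {
      do.call(rbind, lapply(seq_len(n_per_class), function(i) {
        protos[[cls]] + rnorm(len, 0, 0.02)
      }))
    }))
    respcnn:::new_window_set(
      vals, rep(respiration_classes(), each = n_per_class),
      rep("toy", nrow(vals)))
  })
}

# Independent scalar Kalman recursion, written directly from the
# predict/update equations (the oracle for kalman_filter).
kalman_oracle <- function(x, q, r, est, p) {
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    p <- p + q
    g <- p / (p + r)
    est <- est + g * (x[i] - est)
    p <- p * (1 - g)
    out[i] <- est
  }
  out
}

# Peak-counting rate oracle: local maxima above mid-level with a minimum
# separation of 40% of the nominal period; the rate estimate is the mean
# inter-peak interval.  Independent of the simulator's internals.
peak_rate_oracle <- function(x, fs, nominal_rate) {
  k <- max(1L, round(0.6 * fs))  # light smoothing, ~0.6 s
  xs <- stats::filter(x, rep(1 / k, k), sides = 2)
  xs[is.na(xs)] <- 0
  thr <- mean(xs) + 0.2 * sd(xs)
  min_dist <- round(0.4 * fs * 60 / nominal_rate)
  n <- length(xs)
  peaks <- integer(0)
  for (i in 2:(n - 1)) {
    if (xs[i] > thr && xs[i] >= xs[i - 1] && xs[i] > xs[i + 1]) {
      if (length(peaks) == 0 || i - peaks[length(peaks)] >= min_dist) {
        peaks <- c(peaks, i)
      }
    }
  }
  if (length(peaks) < 2) return(NA_real_)
  60 * fs * (length(peaks) - 1) / (peaks[length(peaks)] - peaks[1])
}

# Wrap compiled-engine weights into the structure the pure-R reference
# engine expects.
reference_params <- function(model) {
  Map(function(a, w) {
    list(type = a$type, W = w$W, b = as.numeric(w$b), KS = a$KS,
         act = a$act, flatten = isTRUE(a$flatten))
  }, model$spec$arch, model$weights)
}

# The four published iteration-best combinations of the repeated depth-3
# learning (kernel sizes / kernel counts per layer, dense-layer pair) and
# their sequence numbers in the full default grid.
published_best_combos <- function() {
  list(
    list(seq_no = 942110, ks = c(21, 25, 29), kc = c(256, 128, 64),
         dense = c(2048, 1024)),
    list(seq_no = 898926, ks = c(21, 21, 29), kc = c(128, 256, 128),
         dense = c(2048, 1024)),
    list(seq_no = 937339, ks = c(21, 21, 29), kc = c(256, 64, 256),
         dense = c(1024, 2048)),
    list(seq_no = 1098106, ks = c(25, 21, 29), kc = c(128, 128, 64),
         dense = c(1024, 1024)))
}
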