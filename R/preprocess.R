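# Preprocessing: scalar Kalman filtering, target-bin respiration extraction,
# sliding-window segmentation with time-shift augmentation, dataset split.

#' Scalar random-walk Kalman filter
#'
#' The minimal one-dimensional Kalman smoother consistent with two scalar
#' noise parameters: the state is the (slowly varying) chest displacement
#' modeled as a random walk with process-noise variance `q`; each raw radar
#' sample is a measurement with noise variance `r`.  Per sample the filter
#' predicts (`variance <- variance + q`) and updates
#' (`gain <- variance / (variance + r)`;
#' `estimate <- estimate + gain * (x - estimate)`;
#' `variance <- variance * (1 - gain)`).
#'
#' @param x Non-empty numeric signal.
#' @param q Process-noise variance (> 0). Default 0.01, the device's default
#'   setting.
#' @param r Measurement-noise variance (>= 0). Default 0.1, the device's
#'   default setting. `r = 0` trusts the measurement fully: the output
#'   equals the input from the first update on.
#' @param init_estimate Initial state estimate; defaults to the first
#'   measurement, which avoids a startup transient on signals with an
#'   arbitrary offset.
#' @param init_variance Initial state variance; defaults to `r + q`.
#' @return Filtered numeric vector, same length as `x`.
#' @examples
#' kalman_filter(c(1, 2, 3), q = 0.01, r = 0.1, init_estimate = 0,
#'               init_variance = 1)
#' @export
kalman_filter <- function(x, q = 0.01, r = 0.1, init_estimate = x[1],
                          init_variance = r + q) {
  if (length(x) == 0) stop("`x` must be a non-empty signal", call. = FALSE)
  stopifnot(is.numeric(x), all(is.finite(x)))
  stop_if_not_scalar_number(q, "q", positive = TRUE)
  stop_if_not_scalar_number(r, "r", nonneg = TRUE)
  est <- init_estimate
  p <- init_variance
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    p <- p + q                      # predict
    g <- p / (p + r)                # update
    est <- est + g * (x[i] - est)
    p <- p * (1 - g)
    out[i] <- est
  }
  out
}

#' Extract the respiration trace from a radar frame stream
#'
#' Chest motion modulates the range bin at the subject's distance.  Within
#' `+/- tolerance_bins` of the bin implied by `distance_cm`, the bin with
#' maximal temporal variance is selected (ties broken by lowest bin index)
#' and its time series is returned, Kalman-filtered by default.
#'
#' @param frames A `radar_frames` object (see [embed_in_radar_frames()]).
#' @param distance_cm Sensor--thorax distance in cm. Default 20.
#' @param tolerance_bins Half-width of the candidate-bin neighbourhood.
#'   Default 2.
#' @param q,r Kalman-filter parameters passed to [kalman_filter()]; set
#'   `filter = FALSE` to return the raw bin series.
#' @param filter Apply the Kalman filter to the selected bin. Default `TRUE`.
#' @return An unlabeled `respiration_trace`; the selected 0-based bin index
#'   is stored in its `selected_bin` field.
#' @examples
#' tr <- simulate_pattern("eupnea", 10, seed = 1)
#' fr <- embed_in_radar_frames(tr, clutter_sd = 0, seed = 1)
#' out <- extract_respiration(fr)
#' out$selected_bin
#' @export
extract_respiration <- function(frames, distance_cm = 20,
                                tolerance_bins = 2L, q = 0.01, r = 0.1,
                                filter = TRUE) {
  stopifnot(inherits(frames, "radar_frames"))
  if (nrow(frames$bins) == 0) stop("empty frame stream", call. = FALSE)
  n_bins <- ncol(frames$bins)
  center <- as.integer(round(distance_cm / frames$bin_spacing_cm))
  if (center < 0 || center > n_bins - 1L) {
    stop(sprintf("distance %g cm maps to bin %d, outside [0, %d]",
                 distance_cm, center, n_bins - 1L), call. = FALSE)
  }
  cand <- max(0L, center - tolerance_bins):min(n_bins - 1L,
                                               center + tolerance_bins)
  v <- apply(frames$bins[, cand + 1L, drop = FALSE], 2, stats::var)
  v[is.na(v)] <- 0  # single-frame streams: fall back to tie-break
  sel <- cand[which.max(v)]  # which.max takes the first (lowest-index) tie
  series <- frames$bins[, sel + 1L]
  if (filter) series <- kalman_filter(series, q = q, r = r)
  tr <- new_respiration_trace(series, frames$fs)
  tr$selected_bin <- sel
  tr
}

#' Window extraction parameters
#'
#' @param window_len Window length in samples. Default 250 (10 s at 25 Hz),
#'   the minimum span a respiratory-state monitor observes to call a state.
#' @param shift Time-shift between successive window starts, in samples
#'   (0 < shift <= window_len). Default 12: the nominal 0.5 s shift at
#'   25 fps is 12.5 samples, rounded down so windows align to sample
#'   boundaries (0.48 s, a 4% deviation).
#' @param fs Sampling rate in Hz. Default 25.
#' @return A `window_spec` list.
#' @export
window_spec <- function(window_len = 250L, shift = 12L, fs = 25) {
  window_len <- as.integer(window_len)
  shift <- as.integer(shift)
  stopifnot(window_len >= 1L)
  if (shift < 1L || shift > window_len) {
    stop("`shift` must satisfy 0 < shift <= window_len", call. = FALSE)
  }
  stop_if_not_scalar_number(fs, "fs", positive = TRUE)
  structure(list(window_len = window_len, shift = shift, fs = fs),
            class = "window_spec")
}

new_window_set <- function(values, labels, source) {
  structure(list(values = values,
                 labels = factor(as.character(labels),
                                 levels = .RESP_CLASSES),
                 source = as.character(source)),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows x %d samples\n", nrow(x$values),
              ncol(x$values)))
  print(table(x$labels))
  invisible(x)
}

#' Combine window sets
#'
#' @param ... `window_set` objects with equal window lengths.
#' @return A single `window_set` with rows stacked in argument order.
#' @export
combine_window_sets <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) > 0, all(vapply(sets, inherits, TRUE, "window_set")))
  new_window_set(do.call(rbind, lapply(sets, `[[`, "values")),
                 unlist(lapply(sets, function(s) as.character(s$labels))),
                 unlist(lapply(sets, `[[`, "source")))
}

# Row subset of a window set.
subset_window_set <- function(ws, idx) {
  new_window_set(ws$values[idx, , drop = FALSE],
                 as.character(ws$labels)[idx], ws$source[idx])
}

#' Cut a trace into time-shifted windows
#'
#' Sliding-window augmentation: windows start at sample offsets
#' `0, shift, 2 * shift, ...`, giving
#' `floor((T - window_len) / shift) + 1` windows from a `T`-sample trace.
#' When `max_windows` is smaller than that count, a uniform-stride
#' subselection over the candidate windows reduces it to exactly
#' `max_windows`.  Every window inherits the single label, so each training
#' example contains one pattern only.
#'
#' @param trace A `respiration_trace` or plain numeric vector.
#' @param spec A [window_spec()].
#' @param label Pattern label for all windows; defaults to the trace's own
#'   label. Required (non-`NA`) for labeled downstream use.
#' @param max_windows Optional cap on the number of windows.
#' @param source_id Provenance string; defaults to the trace's subject id.
#' @return A `window_set`: list with `values` (windows x window_len matrix),
#'   `labels` (factor) and `source` (character).
#' @examples
#' tr <- simulate_pattern("eupnea", 30, seed = 1)
#' ws <- window_series(tr, window_spec(), label = "eupnea")
#' nrow(ws$values)
#' @export
window_series <- function(trace, spec = window_spec(), label = NULL,
                          max_windows = NULL, source_id = NULL) {
  x <- if (inherits(trace, "respiration_trace")) trace$samples else
    as.numeric(trace)
  stopifnot(inherits(spec, "window_spec"))
  n <- length(x)
  L <- spec$window_len
  S <- spec$shift
  if (n < L) {
    stop(sprintf("trace has %d samples, shorter than window_len = %d", n, L),
         call. = FALSE)
  }
  if (is.null(label) && inherits(trace, "respiration_trace")) {
    label <- trace$label
  }
  if (is.null(source_id)) {
    source_id <- if (inherits(trace, "respiration_trace") &&
                     !is.na(trace$subject_id)) trace$subject_id else "trace"
  }
  count <- (n - L) %/% S + 1L
  starts <- (seq_len(count) - 1L) * S
  if (!is.null(max_windows)) {
    max_windows <- as.integer(max_windows)
    stopifnot(max_windows >= 1L)
    if (max_windows < count) {
      sel <- round(seq(1L, count, length.out = max_windows))
      starts <- starts[sel]
      count <- max_windows
    }
  }
  vals <- matrix(0, nrow = count, ncol = L)
  for (i in seq_len(count)) {
    vals[i, ] <- x[(starts[i] + 1L):(starts[i] + L)]
  }
  ws <- new_window_set(vals, rep(as.character(label), count),
                       rep(source_id, count))
  attr(ws, "starts") <- starts
  ws
}

#' Split a window set into training and test sets
#'
#' Seeded shuffle followed by a stratified (per-class) split: each class
#' contributes `round(train_fraction * n_class)` windows to training and the
#' remainder to test, matching the 6:4 protocol (2500 windows at fraction
#' 0.6 give 1500 training / 1000 test).  A class with fewer than 2 members
#' cannot be split and goes entirely to training, with a warning.
#'
#' @param ws A `window_set`.
#' @param train_fraction Fraction of each class assigned to training, in
#'   (0, 1). Default 0.6.
#' @param seed Optional integer seed for the shuffle.
#' @param stratified Stratify by class (default `TRUE`); otherwise a single
#'   global shuffle is split at `round(train_fraction * n)`.
#' @return `list(train = window_set, test = window_set)`; disjoint and
#'   exhaustive.
#' @examples
#' ds <- generate_dataset(n_subjects = 1, per_pattern = 4, seed = 1)
#' sp <- split_dataset(ds, seed = 2)
#' nrow(sp$train$values)
#' @export
split_dataset <- function(ws, train_fraction = 0.6, seed = NULL,
                          stratified = TRUE) {
  stopifnot(inherits(ws, "window_set"))
  n <- nrow(ws$values)
  if (n == 0) stop("empty window set", call. = FALSE)
  stop_if_not_scalar_number(train_fraction, "train_fraction")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie strictly in (0, 1)", call. = FALSE)
  }
  with_seed(seed, {
    if (stratified) {
      train_idx <- integer(0)
      for (cls in levels(ws$labels)) {
        idx <- which(ws$labels == cls)
        if (length(idx) == 0) next
        if (length(idx) < 2) {
          warning(sprintf(
            "class '%s' has %d window(s); assigning all to training", cls,
            length(idx)), call. = FALSE)
          train_idx <- c(train_idx, idx)
          next
        }
        idx <- sample(idx)
        n_train <- round(train_fraction * length(idx))
        train_idx <- c(train_idx, idx[seq_len(n_train)])
      }
    } else {
      idx <- sample(n)
      train_idx <- idx[seq_len(round(train_fraction * n))]
    }
    test_idx <- setdiff(seq_len(n), train_idx)
    list(train = subset_window_set(ws, sort(train_idx)),
         test = subset_window_set(ws, sort(test_idx)))
  })
}
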