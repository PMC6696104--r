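# Synthetic respiration-signal simulator.
#
# Chest displacement during quiet breathing rises over inspiration and falls
# over expiration, with an inspiration:expiration duration ratio of roughly
# 1:1.5 to 1:2.  One cycle is modeled as an asymmetric raised cosine: a
# half-cosine rise over the inspiratory fraction 1/(1+e) of the cycle and a
# half-cosine fall over the expiratory fraction e/(1+e), where e is the
# expiration share.  Cycles start and end at the trough, so concatenation is
# smooth and periodic.

#' Breathing waveform parameters
#'
#' @param rate Nominal breathing rate in breaths/min (> 0). Default 16,
#'   mid-eupnea.
#' @param amplitude Peak-to-trough chest-displacement excursion in arbitrary
#'   units (>= 0). Default 1.
#' @param ie_ratio Expiration share `e` of the inspiration:expiration
#'   duration ratio `1:e`, in \[1.5, 2\]. Default 1.75 (mid-range).
#' @param fs Sampling rate in Hz (> 0). Default 25, the radar frame rate.
#' @return A `breath_params` list.
#' @examples
#' breath_params(rate = 12, ie_ratio = 2)
#' @export
breath_params <- function(rate = 16, amplitude = 1, ie_ratio = 1.75,
                          fs = 25) {
  stop_if_not_scalar_number(rate, "rate", positive = TRUE)
  stop_if_not_scalar_number(amplitude, "amplitude", nonneg = TRUE)
  stop_if_not_scalar_number(ie_ratio, "ie_ratio", positive = TRUE)
  if (ie_ratio < 1.5 || ie_ratio > 2) {
    stop("`ie_ratio` (expiration share) must lie in [1.5, 2]", call. = FALSE)
  }
  stop_if_not_scalar_number(fs, "fs", positive = TRUE)
  structure(list(rate = rate, amplitude = amplitude, ie_ratio = ie_ratio,
                 fs = fs),
            class = "breath_params")
}

#' Simulate a single breathing cycle
#'
#' One period of the asymmetric raised-cosine chest-displacement waveform:
#' monotone half-cosine rise from trough to peak over the inspiratory
#' fraction `1/(1 + e)` of the cycle, then monotone half-cosine fall back to
#' the trough over the expiratory fraction `e/(1 + e)`, with
#' `e = params$ie_ratio`.
#'
#' @param params A [breath_params()] object.
#' @param seed Optional integer seed; the waveform itself is deterministic,
#'   the argument exists for signature compatibility with the stochastic
#'   simulator operations.
#' @return Numeric vector of `round(fs * 60 / rate)` samples starting at the
#'   trough (0) and peaking at `params$amplitude` at the end of inspiration
#'   (sample `ceiling(n / (1 + e))`).
#' @examples
#' cyc <- simulate_breath_cycle(breath_params(rate = 15, fs = 25))
#' length(cyc)  # 100 samples = 4 s at 25 Hz
#' @export
simulate_breath_cycle <- function(params = breath_params(), seed = NULL) {
  stopifnot(inherits(params, "breath_params"))
  n <- round(params$fs * 60 / params$rate)
  if (n < 2) {
    stop("cycle must span at least 2 samples; increase `fs` or lower `rate`",
         call. = FALSE)
  }
  e <- params$ie_ratio
  n_insp <- as.integer(ceiling(n / (1 + e)))
  n_exp <- n - n_insp
  a <- params$amplitude
  rise <- a / 2 * (1 - cos(pi * seq_len(n_insp) / n_insp))
  fall <- if (n_exp > 0) a / 2 * (1 + cos(pi * seq_len(n_exp) / n_exp)) else
    numeric(0)
  c(rise, fall)
}

new_respiration_trace <- function(samples, fs, label = NA_character_,
                                  subject_id = NA_character_, seed = NULL,
                                  params = NULL) {
  structure(list(samples = as.numeric(samples), fs = fs, label = label,
                 subject_id = subject_id,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 params = params),
            class = "respiration_trace")
}

#' @export
print.respiration_trace <- function(x, ...) {
  cat(sprintf(
    "<respiration_trace> %d samples @ %g Hz (%.1f s), label = %s\n",
    length(x$samples), x$fs, length(x$samples) / x$fs,
    ifelse(is.na(x$label), "<none>", x$label)))
  invisible(x)
}

#' @export
length.respiration_trace <- function(x) length(x$samples)

# Draw one jittered cycle rate: uniform within +/-10% of nominal, truncated
# to the class band for the rhythmic classes.
jitter_rate <- function(rate, class) {
  r <- rate * runif(1, 0.9, 1.1)
  if (class %in% names(.RATE_BANDS)) {
    band <- .RATE_BANDS[[class]]
    r <- min(max(r, band[1]), band[2])
  }
  r
}

#' Simulate a labeled respiration trace
#'
#' Concatenates breathing cycles with per-cycle rate jitter (uniform within
#' +/-10% of the nominal rate, truncated to the class band), applies
#' class-specific structure, and adds i.i.d. Gaussian noise:
#' \itemize{
#'   \item rhythmic classes (`eupnea`, `bradypnea`, `tachypnea`): the nominal
#'     `params$rate` must lie in the class band;
#'   \item `apnea`: the breathing excursion is suppressed to 5% of the
#'     baseline amplitude (>= 90% reduction), and `duration_s` must be at
#'     least 10 s;
#'   \item `motion`: eupnea-like baseline breathing plus 1--3 random
#'     step-and-exponential-decay transients per 10 s with amplitude 3--8
#'     times the breathing amplitude and random sign.
#' }
#'
#' @param class One of [respiration_classes()].
#' @param duration_s Trace duration in seconds (>= 0; >= 10 for apnea).
#' @param params [breath_params()]; for apnea and motion the rate is the
#'   underlying (suppressed / baseline) breathing rate.
#' @param noise_sd Standard deviation of additive Gaussian noise, in the same
#'   arbitrary displacement units as `params$amplitude`. Default 0.02.
#' @param seed Optional integer seed; identical arguments and seed give a
#'   bit-identical trace.
#' @param subject_id Provenance string stored on the trace.
#' @return A `respiration_trace` with `round(duration_s * fs)` samples.
#' @examples
#' tr <- simulate_pattern("eupnea", 60, seed = 1)
#' tr
#' @export
simulate_pattern <- function(class, duration_s, params = breath_params(),
                             noise_sd = 0.02, seed = NULL,
                             subject_id = NA_character_) {
  class <- match.arg(class, .RESP_CLASSES)
  stop_if_not_scalar_number(duration_s, "duration_s", nonneg = TRUE)
  stop_if_not_scalar_number(noise_sd, "noise_sd", nonneg = TRUE)
  stopifnot(inherits(params, "breath_params"))
  if (class == "apnea" && duration_s < .APNEA_MIN_DURATION_S) {
    stop(sprintf("apnea requires duration_s >= %d s (got %g)",
                 .APNEA_MIN_DURATION_S, duration_s), call. = FALSE)
  }
  if (class %in% names(.RATE_BANDS)) {
    band <- .RATE_BANDS[[class]]
    if (params$rate < band[1] || params$rate > band[2]) {
      stop(sprintf(
        "nominal rate %g breaths/min is outside the %s band [%g, %g]",
        params$rate, class, band[1], band[2]), call. = FALSE)
    }
  }
  n_total <- round(duration_s * params$fs)
  if (n_total == 0) {
    return(new_respiration_trace(numeric(0), params$fs, class, subject_id,
                                 seed, params))
  }

  with_seed(seed, {
    # Concatenate jittered cycles until the trace is long enough, then trim.
    x <- numeric(0)
    while (length(x) < n_total) {
      p_cycle <- params
      p_cycle$rate <- jitter_rate(params$rate, class)
      x <- c(x, simulate_breath_cycle(p_cycle))
    }
    x <- x[seq_len(n_total)]

    if (class == "apnea") {
      x <- x * .APNEA_AMPLITUDE_FACTOR
    } else if (class == "motion") {
      x <- x + motion_transients(n_total, params$fs, params$amplitude)
    }
    x <- x + rnorm(n_total, 0, noise_sd)
    new_respiration_trace(x, params$fs, class, subject_id, seed, params)
  })
}

# Step-and-decay body-movement transients: 1-3 per 10 s block, amplitude
# 3-8x the breathing amplitude with random sign, exponential decay with a
# 0.3-1.5 s time constant.  Called inside a seeded context.
motion_transients <- function(n, fs, amplitude) {
  out <- numeric(n)
  n_blocks <- max(1L, ceiling(n / (10 * fs)))
  t_idx <- seq_len(n)
  for (b in seq_len(n_blocks)) {
    lo <- (b - 1L) * 10L * fs + 1L
    hi <- min(n, b * 10L * fs)
    if (hi < lo) next
    k <- sample(1:3, 1)
    for (i in seq_len(k)) {
      t0 <- sample(lo:hi, 1)
      amp <- runif(1, 3, 8) * amplitude * sample(c(-1, 1), 1)
      tau <- runif(1, 0.3, 1.5) * fs
      seg <- t_idx >= t0
      out[seg] <- out[seg] + amp * exp(-(t_idx[seg] - t0) / tau)
    }
  }
  out
}

#' Embed a respiration trace into a radar frame stream
#'
#' Emulates the acquisition geometry: every trace sample becomes one radar
#' frame of `n_bins` range-bin amplitudes at `1/fs` second steps.  The bin
#' nearest the configured sensor--thorax distance carries the full trace
#' modulation; its immediate neighbours carry attenuated copies (0.5 at
#' +/-1 bin, 0.2 at +/-2 bins) to mimic the finite range resolution; every
#' bin additionally carries seeded i.i.d. Gaussian clutter.
#'
#' @param trace A `respiration_trace`.
#' @param distance_cm Sensor--thorax distance in cm (default 20, the
#'   acquisition setup distance).
#' @param clutter_sd Clutter noise standard deviation (default 0.01).
#' @param seed Optional integer seed for the clutter.
#' @param bin_spacing_cm Range-bin spacing in cm (default 3.0, within the
#'   device's 1.5--3.3 cm resolution band; 660 bins then span 19.8 m).
#' @param n_bins Number of range bins per frame (default 660).
#' @return A `radar_frames` object with fields `frame_no` (0-based),
#'   `timestamp` (s), `bins` (frames x bins matrix), `fs`, `bin_spacing_cm`
#'   and `target_bin` (0-based index `round(distance_cm / bin_spacing_cm)`).
#' @examples
#' tr <- simulate_pattern("eupnea", 10, seed = 1)
#' fr <- embed_in_radar_frames(tr, seed = 2)
#' dim(fr$bins)
#' @export
embed_in_radar_frames <- function(trace, distance_cm = 20, clutter_sd = 0.01,
                                  seed = NULL, bin_spacing_cm = 3.0,
                                  n_bins = 660L) {
  stopifnot(inherits(trace, "respiration_trace"))
  stop_if_not_scalar_number(distance_cm, "distance_cm", positive = TRUE)
  stop_if_not_scalar_number(clutter_sd, "clutter_sd", nonneg = TRUE)
  stop_if_not_scalar_number(bin_spacing_cm, "bin_spacing_cm", positive = TRUE)
  n_bins <- as.integer(n_bins)
  target_bin <- as.integer(round(distance_cm / bin_spacing_cm))
  if (target_bin < 0 || target_bin > n_bins - 1L) {
    stop(sprintf("distance %g cm maps to bin %d, outside [0, %d]",
                 distance_cm, target_bin, n_bins - 1L), call. = FALSE)
  }
  n <- length(trace$samples)
  with_seed(seed, {
    bins <- matrix(rnorm(n * n_bins, 0, clutter_sd), nrow = n, ncol = n_bins)
    gains <- c(0.2, 0.5, 1.0, 0.5, 0.2)
    offs <- -2:2
    for (i in seq_along(offs)) {
      b <- target_bin + offs[i]
      if (b >= 0 && b <= n_bins - 1L) {
        bins[, b + 1L] <- bins[, b + 1L] + gains[i] * trace$samples
      }
    }
    structure(list(frame_no = 0:(n - 1L),
                   timestamp = (0:(n - 1L)) / trace$fs,
                   bins = bins, fs = trace$fs,
                   bin_spacing_cm = bin_spacing_cm,
                   target_bin = target_bin),
              class = "radar_frames")
  })
}

#' @export
print.radar_frames <- function(x, ...) {
  cat(sprintf(
    "<radar_frames> %d frames x %d bins @ %g fps (target bin %d)\n",
    nrow(x$bins), ncol(x$bins), x$fs, x$target_bin))
  invisible(x)
}

#' Generate a labeled synthetic window dataset
#'
#' Emulates the data-collection protocol: `n_subjects` subjects each
#' contribute `per_pattern` 250-sample windows for each of the five pattern
#' classes.  Per subject, class-specific nominal rates, an amplitude factor
#' and an inspiration:expiration ratio are drawn from seeded distributions
#' (eupnea U(13.5, 18.5), bradypnea U(6, 10), tachypnea U(24, 40)
#' breaths/min; amplitude log-normal with sdlog 0.15; expiration share
#' U(1.5, 2)); one trace per subject and class is simulated, optionally
#' passed through the radar embed/extract round trip, and cut into
#' time-shifted windows capped at `per_pattern` by uniform-stride
#' subselection.
#'
#' @param n_subjects Number of simulated subjects (>= 1). Default 10.
#' @param per_pattern Windows per subject and pattern (>= 1). Default 50.
#' @param seed Integer seed; the whole collection is reproducible from it.
#' @param noise_sd Additive noise standard deviation passed to
#'   [simulate_pattern()]. Default 0.05 (5% of the unit amplitude).
#' @param duration_s Trace duration per subject/class; `NULL` (default)
#'   chooses the larger of 60 s and the minimum needed for `per_pattern`
#'   windows at the given window spec.
#' @param spec A [window_spec()] (250-sample windows, 12-sample shift).
#' @param via_radar If `TRUE`, each trace is embedded into radar frames and
#'   re-extracted (Kalman-filtered) before windowing, exercising the full
#'   acquisition path. Default `FALSE`.
#' @return A `window_set` (see [window_series()]) with
#'   `n_subjects * 5 * per_pattern` rows and a `meta` attribute: one
#'   data.frame row per subject/class trace (subject, class, rate,
#'   amplitude, ie_ratio, n_windows).
#' @examples
#' ds <- generate_dataset(n_subjects = 1, per_pattern = 2, seed = 1)
#' nrow(ds$values)
#' @export
generate_dataset <- function(n_subjects = 10, per_pattern = 50, seed = NULL,
                             noise_sd = 0.05, duration_s = NULL,
                             spec = window_spec(), via_radar = FALSE) {
  stopifnot(n_subjects >= 1, per_pattern >= 1)
  n_subjects <- as.integer(n_subjects)
  per_pattern <- as.integer(per_pattern)
  need_s <- (spec$window_len + (per_pattern - 1L) * spec$shift) / spec$fs
  if (is.null(duration_s)) duration_s <- max(60, ceiling(need_s * 1.2))
  if (duration_s < need_s) {
    stop(sprintf(
      "duration_s = %g s is too short for %d windows (needs >= %.1f s)",
      duration_s, per_pattern, need_s), call. = FALSE)
  }

  with_seed(seed, {
    sets <- vector("list", n_subjects * length(.RESP_CLASSES))
    meta <- vector("list", length(sets))
    k <- 0L
    for (s in seq_len(n_subjects)) {
      rates <- c(eupnea = runif(1, 13.5, 18.5),
                 bradypnea = runif(1, 6, 10),
                 tachypnea = runif(1, 24, 40))
      rates <- c(rates, apnea = unname(rates["eupnea"]),
                 motion = unname(rates["eupnea"]))
      amp <- exp(rnorm(1, 0, 0.15))
      ie <- runif(1, 1.5, 2)
      for (cls in .RESP_CLASSES) {
        p <- breath_params(rate = unname(rates[cls]), amplitude = amp,
                           ie_ratio = ie, fs = spec$fs)
        tr <- simulate_pattern(cls, duration_s, params = p,
                               noise_sd = noise_sd, seed = NULL,
                               subject_id = sprintf("S%02d", s))
        if (via_radar) {
          fr <- embed_in_radar_frames(tr, seed = NULL)
          tr2 <- extract_respiration(fr)
          tr2$label <- tr$label
          tr2$subject_id <- tr$subject_id
          tr <- tr2
        }
        k <- k + 1L
        sets[[k]] <- window_series(tr, spec = spec, label = cls,
                                   max_windows = per_pattern,
                                   source_id = sprintf("S%02d_%s", s, cls))
        meta[[k]] <- data.frame(subject = sprintf("S%02d", s), class = cls,
                                rate = unname(rates[cls]), amplitude = amp,
                                ie_ratio = ie,
                                n_windows = nrow(sets[[k]]$values),
                                stringsAsFactors = FALSE)
      }
    }
    ws <- do.call(combine_window_sets, sets)
    attr(ws, "meta") <- do.call(rbind, meta)
    attr(ws, "seed") <- if (is.null(seed)) NA_integer_ else as.integer(seed)
    attr(ws, "noise_sd") <- noise_sd
    ws
  })
}
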