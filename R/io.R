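# Readers/writers for the on-disk formats: radar record CSV (one row per
# frame: frame number, timestamp, 660 range-bin amplitudes), labeled window
# CSV (label, source, 250 value columns) with a YAML metadata sidecar, and
# YAML run configuration.  Amplitudes are written with 6 significant
# digits.

SIG_DIGITS <- 6L

#' Write a radar frame stream to CSV
#'
#' One row per frame: `frame_no`, `timestamp` (s) and one column per range
#' bin (`v001`..`v660` for the default frame layout).  Amplitudes are
#' written with 6 significant digits.
#'
#' @param frames A `radar_frames` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_radar_records <- function(frames, path) {
  stopifnot(inherits(frames, "radar_frames"))
  n_bins <- ncol(frames$bins)
  df <- data.table::data.table(frame_no = frames$frame_no,
                               timestamp = signif(frames$timestamp, 9))
  bins <- signif(frames$bins, SIG_DIGITS)
  colnames(bins) <- sprintf("v%03d", seq_len(n_bins))
  data.table::fwrite(cbind(df, data.table::as.data.table(bins)), path)
  invisible(path)
}

#' Read a radar frame stream from CSV
#'
#' Validates the record layout before parsing: every row must carry a frame
#' number, a timestamp and exactly `n_bins` amplitudes; a malformed row is
#' reported with its line number.
#'
#' @param path File written by [write_radar_records()] (or any file in the
#'   same layout).
#' @param n_bins Expected number of range bins per frame. Default 660.
#' @param bin_spacing_cm Range-bin spacing to attach to the stream (the CSV
#'   carries amplitudes only). Default 3.0.
#' @return A `radar_frames` object; `fs` is inferred from the median
#'   timestamp step.
#' @export
read_radar_records <- function(path, n_bins = 660L, bin_spacing_cm = 3.0) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  nf <- count.fields(path, sep = ",")
  expected <- n_bins + 2L
  bad <- which(nf != expected)
  if (length(bad) > 0) {
    stop(sprintf(
      "malformed radar record: line %d has %d fields, expected %d (frame_no, timestamp, %d bins)",
      bad[1], nf[bad[1]], expected, n_bins), call. = FALSE)
  }
  dt <- data.table::fread(path)
  if (nrow(dt) == 0) stop("empty radar record file", call. = FALSE)
  frame_no <- as.integer(dt[[1]])
  if (any(diff(frame_no) <= 0)) {
    stop("frame numbers must be strictly increasing", call. = FALSE)
  }
  ts <- as.numeric(dt[[2]])
  fs <- if (length(ts) > 1) 1 / median(diff(ts)) else 25
  bins <- as.matrix(dt[, -(1:2)])
  dimnames(bins) <- NULL
  structure(list(frame_no = frame_no, timestamp = ts, bins = bins,
                 fs = fs, bin_spacing_cm = bin_spacing_cm,
                 target_bin = NA_integer_),
            class = "radar_frames")
}

#' Write a labeled window dataset to CSV
#'
#' Columns: `label`, `source`, then one column per sample (`v001`..).  A
#' YAML sidecar `<path>.meta.yaml` records the generator seed, noise level
#' and per-trace metadata when the window set carries them (as
#' [generate_dataset()] output does).
#'
#' @param ws A `window_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_window_set <- function(ws, path) {
  stopifnot(inherits(ws, "window_set"))
  vals <- signif(ws$values, SIG_DIGITS)
  colnames(vals) <- sprintf("v%03d", seq_len(ncol(vals)))
  dt <- cbind(data.table::data.table(label = as.character(ws$labels),
                                     source = ws$source),
              data.table::as.data.table(vals))
  data.table::fwrite(dt, path)
  meta <- attr(ws, "meta")
  side <- list(n_windows = nrow(ws$values),
               window_len = ncol(ws$values),
               seed = attr(ws, "seed"),
               noise_sd = attr(ws, "noise_sd"))
  if (!is.null(meta)) side$traces <- lapply(seq_len(nrow(meta)), function(i)
    as.list(meta[i, ]))
  yaml::write_yaml(side, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a labeled window dataset from CSV
#'
#' @param path File written by [write_window_set()].
#' @return A `window_set`.
#' @export
read_window_set <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  dt <- data.table::fread(path)
  if (!all(c("label", "source") == names(dt)[1:2])) {
    stop("window CSV must start with columns `label`, `source`",
         call. = FALSE)
  }
  vals <- as.matrix(dt[, -(1:2)])
  dimnames(vals) <- NULL
  new_window_set(vals, dt$label, dt$source)
}

#' Assemble a run configuration
#'
#' All tunable parameters of a pipeline run in one serializable list,
#' mirroring the hyperparameter grid keys (CLD, KS, KC, DLNC) and the
#' acquisition constants.
#'
#' @param seed Run seed.
#' @param grid A [param_grid()].
#' @param window A [window_spec()].
#' @param kalman `list(q =, r =)` Kalman parameters.
#' @param train A [train_config()].
#' @param train_fraction Train share of the dataset split.
#' @param distance_cm Sensor--thorax distance.
#' @return A nested list of class `run_config`.
#' @export
run_config <- function(seed = 1L, grid = param_grid(),
                       window = window_spec(),
                       kalman = list(q = 0.01, r = 0.1),
                       train = train_config(seed = seed),
                       train_fraction = 0.6, distance_cm = 20) {
  structure(list(seed = seed,
                 grid = list(CLD = grid$depths, KS = grid$kernel_sizes,
                             KC = grid$kernel_counts,
                             DLNC = grid$dense_counts),
                 window = list(window_len = window$window_len,
                               shift = window$shift, fs = window$fs),
                 kalman = kalman,
                 train = list(epochs = train$epochs,
                              batch_size = train$batch_size,
                              lr = train$lr, input_len = train$input_len),
                 train_fraction = train_fraction,
                 distance_cm = distance_cm),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param cfg A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns the `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  structure(yaml::read_yaml(path), class = "run_config")
}
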