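# Two-stage hyperparameter search: stage one picks the convolutional-layer
# depth maximizing the mean recognition rate over the full per-depth grid;
# stage two repeats training N times at that depth and pools the per-family
# [min, max] over the per-iteration best combinations into optimal ranges.
#
# Combos are enumerated in a fixed mixed-radix lexicographic order: within
# a conv layer kernel size is the major digit and kernel count the minor
# one; layers are ordered outermost-first; the two dense-layer counts form
# the last two digits (first dense layer major).  Sequence numbers are this
# order's zero-based indices.

#' Hyperparameter search grid
#'
#' @param depths Candidate convolutional-layer depths (CLD). Default
#'   `c(1, 2, 3)`.
#' @param kernel_sizes Candidate kernel sizes (KS). Default
#'   `{5, 9, 13, ..., 41}`.
#' @param kernel_counts Candidate kernel counts (KC). Default
#'   `{32, 64, 128, 256, 512}`.
#' @param dense_counts Candidate dense-layer neuron counts (DLNC). Default
#'   `{256, 512, 1024, 2048}`.
#' @return A `param_grid` object.  With the defaults the per-depth combo
#'   counts are 800, 40,000 and 2,000,000.
#' @examples
#' combo_count(param_grid(), depth = 2)
#' @export
param_grid <- function(depths = c(1L, 2L, 3L),
                       kernel_sizes = seq(5L, 41L, by = 4L),
                       kernel_counts = c(32L, 64L, 128L, 256L, 512L),
                       dense_counts = c(256L, 512L, 1024L, 2048L)) {
  chk <- function(x, name) {
    x <- as.integer(x)
    if (length(x) == 0 || any(x < 1)) {
      stop(sprintf("`%s` must be a non-empty set of positive integers",
                   name), call. = FALSE)
    }
    x
  }
  structure(list(depths = chk(depths, "depths"),
                 kernel_sizes = chk(kernel_sizes, "kernel_sizes"),
                 kernel_counts = chk(kernel_counts, "kernel_counts"),
                 dense_counts = chk(dense_counts, "dense_counts")),
            class = "param_grid")
}

#' @export
print.param_grid <- function(x, ...) {
  cat("<param_grid>\n")
  cat("  CLD :", paste(x$depths, collapse = ", "), "\n")
  cat("  KS  :", paste(x$kernel_sizes, collapse = ", "), "\n")
  cat("  KC  :", paste(x$kernel_counts, collapse = ", "), "\n")
  cat("  DLNC:", paste(x$dense_counts, collapse = ", "), "\n")
  invisible(x)
}

#' Number of hyperparameter combinations at a given depth
#'
#' Closed form `(|KS| * |KC|)^depth * |DLNC|^2`: each convolutional layer
#' independently takes any (kernel size, kernel count) pair, and the two
#' dense layers independently take any neuron count.
#'
#' @param grid A [param_grid()].
#' @param depth Convolutional-layer depth.
#' @return The combination count (numeric, exact for counts below 2^53).
#' @examples
#' combo_count(param_grid(), 3)  # 2,000,000
#' @export
combo_count <- function(grid, depth) {
  stopifnot(inherits(grid, "param_grid"))
  depth <- as.integer(depth)
  stopifnot(depth >= 1)
  per_layer <- length(grid$kernel_sizes) * length(grid$kernel_counts)
  per_layer^depth * length(grid$dense_counts)^2
}

#' Decode a combination from its sequence number
#'
#' Inverts the lexicographic enumeration: `i` is the 1-based position in
#' enumeration order (the zero-based sequence number is `i - 1`).
#'
#' @param grid A [param_grid()].
#' @param depth Convolutional-layer depth.
#' @param i 1-based enumeration index in `[1, combo_count(grid, depth)]`.
#' @param dropout_keep Passed to [param_combo()].
#' @return The [param_combo()] at that position.
#' @examples
#' combo_at(param_grid(), 1, 1)
#' @export
combo_at <- function(grid, depth, i, dropout_keep = 0.6) {
  stopifnot(inherits(grid, "param_grid"))
  depth <- as.integer(depth)
  total <- combo_count(grid, depth)
  if (i < 1 || i > total) {
    stop(sprintf("index %s outside [1, %s]", format(i), format(total)),
         call. = FALSE)
  }
  nKC <- length(grid$kernel_counts)
  nD <- length(grid$dense_counts)
  per_layer <- length(grid$kernel_sizes) * nKC
  s <- i - 1
  d <- s %% nD^2
  q <- s %/% nD^2
  dense <- c(grid$dense_counts[d %/% nD + 1], grid$dense_counts[d %% nD + 1])
  ks <- integer(depth)
  kc <- integer(depth)
  for (layer in depth:1) {
    l <- q %% per_layer
    q <- q %/% per_layer
    ks[layer] <- grid$kernel_sizes[l %/% nKC + 1]
    kc[layer] <- grid$kernel_counts[l %% nKC + 1]
  }
  cb <- param_combo(ks, kc, dense, dropout_keep = dropout_keep)
  cb$seq_no <- s
  cb
}

#' Enumerate (or subsample) the combinations at a depth
#'
#' Materializes combinations in enumeration order, or a seeded uniform draw
#' without replacement of `subsample` of them (returned in ascending
#' sequence-number order).  Use [combo_count()] when only the cardinality is
#' needed; full materialization is refused above `max_materialize` combos.
#'
#' @param grid A [param_grid()].
#' @param depth Convolutional-layer depth.
#' @param subsample Optional number of combos to draw.
#' @param seed Seed for the subsample draw.
#' @param max_materialize Guard against accidental huge enumerations.
#'   Default 100,000.
#' @return List of [param_combo()] objects, each carrying its zero-based
#'   `seq_no`.
#' @examples
#' length(enumerate_combos(param_grid(), 1))  # 800
#' @export
enumerate_combos <- function(grid, depth, subsample = NULL, seed = NULL,
                             max_materialize = 1e5) {
  total <- combo_count(grid, depth)
  if (is.null(subsample)) {
    if (total > max_materialize) {
      stop(sprintf(
        "refusing to materialize %s combos (> %s); use `subsample` or raise `max_materialize`",
        format(total, big.mark = ","),
        format(max_materialize, big.mark = ",")), call. = FALSE)
    }
    idx <- seq_len(total)
  } else {
    subsample <- as.integer(subsample)
    if (subsample < 1 || subsample > total) {
      stop(sprintf("`subsample` must lie in [1, %s]",
                   format(total, big.mark = ",")), call. = FALSE)
    }
    idx <- with_seed(seed, sort(sample.int(total, subsample)))
  }
  lapply(idx, function(i) combo_at(grid, depth, i))
}

# Call a trainer that may or may not accept the iteration number.
call_trainer <- function(trainer, combo, iteration) {
  acc <- if (length(formals(trainer)) >= 2) trainer(combo, iteration) else
    trainer(combo)
  if (!is.numeric(acc) || length(acc) != 1 || is.na(acc) || acc < 0 ||
      acc > 1) {
    stop("trainer must return a single accuracy in [0, 1]", call. = FALSE)
  }
  acc
}

# Evaluate every combo, tolerating trainer failures (recorded as NA and
# excluded from summaries, with a warning).
evaluate_combos <- function(combos, trainer, iteration = 1L) {
  accs <- rep(NA_real_, length(combos))
  for (p in seq_along(combos)) {
    accs[p] <- tryCatch(call_trainer(trainer, combos[[p]], iteration),
                        error = function(e) {
                          warning(sprintf(
                            "trainer failed on combo %d: %s", p,
                            conditionMessage(e)), call. = FALSE)
                          NA_real_
                        })
  }
  accs
}

#' Stage one: find the optimal convolutional-layer depth
#'
#' For each candidate depth, evaluates every enumerated (or subsampled)
#' combination with `trainer` and records the per-depth mean recognition
#' rate; the optimal depth is the argmax of the means, ties resolved to the
#' smallest depth.
#'
#' @param grid A [param_grid()].
#' @param trainer Function mapping a [param_combo()] to an accuracy in
#'   \[0, 1\] (optionally accepting the iteration number as a second
#'   argument).  Typically [make_cnn_trainer()]; mock trainers make the
#'   search itself testable.
#' @param subsample Optional per-depth number of combos to evaluate (seeded
#'   uniform draw); `NULL` evaluates the full grid.
#' @param seed Seed for subsampling.
#' @return A `depth_search` result: `$per_depth` data.frame (depth,
#'   n_combos, n_failed, mean_acc), `$accs` (per-depth accuracy vectors,
#'   names = zero-based sequence numbers), `$d_opt`.
#' @examples
#' g <- param_grid(depths = 1:2, kernel_sizes = c(5, 9),
#'                 kernel_counts = 8, dense_counts = c(16, 32))
#' res <- find_optimal_depth(g, function(cb) 0.5 + 0.1 * cb$depth)
#' res$d_opt
#' @export
find_optimal_depth <- function(grid, trainer, subsample = NULL,
                               seed = NULL) {
  stopifnot(inherits(grid, "param_grid"), is.function(trainer))
  depths <- sort(grid$depths)
  accs <- vector("list", length(depths))
  rows <- vector("list", length(depths))
  for (di in seq_along(depths)) {
    d <- depths[di]
    combos <- enumerate_combos(grid, d, subsample = subsample,
                               seed = if (is.null(seed)) NULL else
                                 seed + di)
    a <- evaluate_combos(combos, trainer)
    names(a) <- vapply(combos, function(cb) format(cb$seq_no), "")
    accs[[di]] <- a
    rows[[di]] <- data.frame(depth = d, n_combos = length(a),
                             n_failed = sum(is.na(a)),
                             mean_acc = mean(a, na.rm = TRUE))
  }
  per_depth <- do.call(rbind, rows)
  structure(list(per_depth = per_depth, accs = accs,
                 d_opt = depths[which.max(per_depth$mean_acc)]),
            class = "depth_search")
}

#' @export
print.depth_search <- function(x, ...) {
  cat("<depth_search> optimal depth:", x$d_opt, "\n")
  print(x$per_depth, row.names = FALSE)
  invisible(x)
}

#' Stage two: find the optimal parameter ranges at a fixed depth
#'
#' Repeats the grid evaluation `n_iterations` times at depth `d_opt`; per
#' iteration the best-accuracy combination is recorded (ties resolved to
#' the first in enumeration order).  The optimal ranges are the per-family
#' `[min, max]` over the recorded best combos, with kernel sizes and
#' kernel counts pooled across all convolutional layers and the two
#' dense-layer counts pooled together.
#'
#' @inheritParams find_optimal_depth
#' @param d_opt The convolutional-layer depth to search at.
#' @param n_iterations Number of repeated learnings N. Default 10.
#' @return A `range_search` result: `$iterations` data.frame (iteration,
#'   seq_no, accuracy, combo description), `$best_combos` list, `$ranges`
#'   list of `c(min, max)` for `ks`, `kc` and `dlnc`.
#' @examples
#' g <- param_grid(depths = 1, kernel_sizes = c(5, 9), kernel_counts = 8,
#'                 dense_counts = c(16, 32))
#' res <- find_optimal_ranges(g, 1, function(cb) 0.9)
#' res$ranges
#' @export
find_optimal_ranges <- function(grid, d_opt, trainer, n_iterations = 10L,
                                subsample = NULL, seed = NULL) {
  stopifnot(inherits(grid, "param_grid"), is.function(trainer))
  n_iterations <- as.integer(n_iterations)
  stopifnot(n_iterations >= 1)
  best <- vector("list", n_iterations)
  rows <- vector("list", n_iterations)
  for (t in seq_len(n_iterations)) {
    combos <- enumerate_combos(grid, d_opt, subsample = subsample,
                               seed = if (is.null(seed)) NULL else
                                 seed + t)
    a <- evaluate_combos(combos, trainer, iteration = t)
    if (all(is.na(a))) {
      stop(sprintf("all trainer evaluations failed in iteration %d", t),
           call. = FALSE)
    }
    p <- which.max(a)  # first max in enumeration order
    best[[t]] <- combos[[p]]
    rows[[t]] <- data.frame(
      iteration = t, seq_no = combos[[p]]$seq_no, accuracy = a[p],
      combo = format_combo(combos[[p]]))
  }
  ranges <- list(
    ks = range(unlist(lapply(best, `[[`, "kernel_sizes"))),
    kc = range(unlist(lapply(best, `[[`, "kernel_counts"))),
    dlnc = range(unlist(lapply(best, `[[`, "dense_neurons"))))
  structure(list(iterations = do.call(rbind, rows), best_combos = best,
                 ranges = ranges, d_opt = d_opt),
            class = "range_search")
}

format_combo <- function(cb) {
  sprintf("KS %s | KC %s | DLNC %s",
          paste(cb$kernel_sizes, collapse = "/"),
          paste(cb$kernel_counts, collapse = "/"),
          paste(cb$dense_neurons, collapse = "/"))
}

#' @export
print.range_search <- function(x, ...) {
  cat(sprintf("<range_search> depth %d, %d iterations\n", x$d_opt,
              nrow(x$iterations)))
  print(x$iterations, row.names = FALSE)
  cat(sprintf("ranges: KS [%d, %d]  KC [%d, %d]  DLNC [%d, %d]\n",
              x$ranges$ks[1], x$ranges$ks[2], x$ranges$kc[1],
              x$ranges$kc[2], x$ranges$dlnc[1], x$ranges$dlnc[2]))
  invisible(x)
}

#' Tabular summaries of search results
#'
#' @param result A `depth_search` or `range_search` object.
#' @return For a depth search, its per-depth data.frame.  For a range
#'   search, `list(iterations = ..., ranges = ...)` with the ranges as a
#'   3-row data.frame (parameter, min, max).
#' @export
summarize_search <- function(result) {
  if (inherits(result, "depth_search")) {
    return(result$per_depth)
  }
  if (inherits(result, "range_search")) {
    return(list(
      iterations = result$iterations,
      ranges = data.frame(
        parameter = c("KS", "KC", "DLNC"),
        min = c(result$ranges$ks[1], result$ranges$kc[1],
                result$ranges$dlnc[1]),
        max = c(result$ranges$ks[2], result$ranges$kc[2],
                result$ranges$dlnc[2]))))
  }
  stop("`result` must be a depth_search or range_search object",
       call. = FALSE)
}

#' Build a CNN-backed trainer for the search algorithms
#'
#' Wraps [train_cnn()] into the `trainer` contract used by
#' [find_optimal_depth()] and [find_optimal_ranges()]: the returned
#' function trains a combo on `train`, evaluates on `val`, and returns the
#' validation average recognition rate.  The training seed is derived from
#' `seed`, the combo's sequence number and the iteration, so repeated
#' iterations differ (as repeated learnings with dropout do) while the
#' whole search stays reproducible.
#'
#' @param train,val `window_set`s (typically a 6:4 split).
#' @param cfg A [train_config()] template; its seed field is overridden per
#'   call.
#' @param seed Base seed.
#' @return `function(combo, iteration = 1)` returning an accuracy in
#'   \[0, 1\].
#' @export
make_cnn_trainer <- function(train, val, cfg = train_config(),
                             seed = 1L) {
  force(train); force(val); force(cfg); force(seed)
  function(combo, iteration = 1L) {
    cfg$seed <- (seed + 131L * iteration +
                   (if (is.null(combo$seq_no)) 0 else combo$seq_no)) %%
      2147483647
    model <- train_cnn(train, val = NULL, combo = combo, cfg = cfg)
    pred <- predict(model, val)
    rep <- recognition_report(confusion_matrix(val$labels, pred))
    rep$average_rate
  }
}
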