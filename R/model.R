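# The parameterized 1-D CNN classifier: per-layer (kernel size, kernel
# count) convolutions with ReLU and max-pooling, a flatten, dropout, two
# dense layers and a 5-way softmax output.

#' One concrete hyperparameter assignment
#'
#' A combination of the four searched hyperparameters: convolutional-layer
#' depth (implied by the number of kernel-size entries), per-layer kernel
#' size (KS) and kernel count (KC), and the two dense-layer neuron counts
#' (DLNC).
#'
#' @param kernel_sizes Odd positive integers, one per convolutional layer
#'   (length = depth >= 1).
#' @param kernel_counts Positive integers, one per convolutional layer.
#' @param dense_neurons Two positive integers, the neuron counts of the two
#'   dense layers.
#' @param dropout_keep Fraction of flattened features kept by dropout during
#'   training, in (0, 1]. Default 0.6 (60% of the features are used, 40%
#'   dropped); set to 1 to disable dropout.
#' @return A `param_combo` object.
#' @examples
#' param_combo(c(29, 25, 21), c(64, 64, 128), c(2048, 1024))
#' @export
param_combo <- function(kernel_sizes, kernel_counts, dense_neurons,
                        dropout_keep = 0.6) {
  kernel_sizes <- as.integer(kernel_sizes)
  kernel_counts <- as.integer(kernel_counts)
  dense_neurons <- as.integer(dense_neurons)
  if (length(kernel_sizes) < 1 ||
      length(kernel_counts) != length(kernel_sizes)) {
    stop("`kernel_sizes` and `kernel_counts` must have equal length >= 1",
         call. = FALSE)
  }
  if (any(kernel_sizes < 1) || any(kernel_sizes %% 2 == 0)) {
    stop("all kernel sizes must be odd positive integers", call. = FALSE)
  }
  if (any(kernel_counts < 1)) {
    stop("all kernel counts must be >= 1", call. = FALSE)
  }
  if (length(dense_neurons) != 2 || any(dense_neurons < 1)) {
    stop("`dense_neurons` must be two positive integers", call. = FALSE)
  }
  stop_if_not_scalar_number(dropout_keep, "dropout_keep", positive = TRUE)
  if (dropout_keep > 1) stop("`dropout_keep` must be <= 1", call. = FALSE)
  structure(list(depth = length(kernel_sizes), kernel_sizes = kernel_sizes,
                 kernel_counts = kernel_counts,
                 dense_neurons = dense_neurons,
                 dropout_keep = dropout_keep),
            class = "param_combo")
}

#' @export
print.param_combo <- function(x, ...) {
  cat(sprintf("<param_combo> depth %d | KS %s | KC %s | DLNC %s | keep %g\n",
              x$depth, paste(x$kernel_sizes, collapse = "/"),
              paste(x$kernel_counts, collapse = "/"),
              paste(x$dense_neurons, collapse = "/"), x$dropout_keep))
  invisible(x)
}

#' The architecture selected from the optimal parameter ranges
#'
#' The depth-3 combination used for the final performance evaluation,
#' chosen from within the optimal ranges: kernel sizes 29/25/21, kernel
#' counts 64/64/128, dense layers 2048/1024, dropout keep 0.6.
#'
#' @return A [param_combo()].
#' @export
selected_combo <- function() {
  param_combo(kernel_sizes = c(29L, 25L, 21L),
              kernel_counts = c(64L, 64L, 128L),
              dense_neurons = c(2048L, 1024L))
}

#' Training configuration
#'
#' @param epochs Number of training epochs (>= 1). Default 40.
#' @param batch_size Mini-batch size (>= 1). Default 10.
#' @param seed Integer seed for weight initialization, shuffling and
#'   dropout.
#' @param lr Adam learning rate. Default 1e-3.
#' @param input_len Window length in samples. Default 250.
#' @param n_classes Number of output classes. Default 5.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 40L, batch_size = 10L, seed = NULL,
                         lr = 1e-3, input_len = 250L, n_classes = 5L) {
  stopifnot(epochs >= 1, batch_size >= 1, input_len >= 1, n_classes >= 2)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = seed, lr = lr,
                 input_len = as.integer(input_len),
                 n_classes = as.integer(n_classes)),
            class = "train_config")
}

#' Build (but do not train) a 1-D CNN from a hyperparameter combination
#'
#' Assembles the layer stack: per convolutional layer a same-padding 1-D
#' convolution (kernel `1 x KS`, `KC` filters), ReLU and max-pooling
#' (size 2, stride 2); then flatten, dropout (keep fraction
#' `dropout_keep`), two ReLU dense layers and a softmax output.  The
#' pooled length after each layer is `floor(L / 2)`, so the flatten width
#' is `floor-halved input_len x last KC`; an architecture whose pooled
#' length reaches zero before the flatten is rejected with an error naming
#' the offending layer.
#'
#' @param combo A [param_combo()].
#' @param cfg A [train_config()].
#' @return A `cnn_spec`: the combo plus a per-layer shape trace
#'   (`$layers`: layer, type, out_len, out_ch), `$flatten_len` and
#'   `$n_params` (total weight and bias count).
#' @examples
#' build_model(selected_combo())
#' @export
build_model <- function(combo, cfg = train_config()) {
  stopifnot(inherits(combo, "param_combo"), inherits(cfg, "train_config"))
  L <- cfg$input_len
  C <- 1L
  arch <- list()
  trace <- list()
  for (i in seq_len(combo$depth)) {
    KS <- combo$kernel_sizes[i]
    KC <- combo$kernel_counts[i]
    arch[[length(arch) + 1L]] <-
      list(type = "conv", in_dim = KS * C, out_dim = KC, KS = KS,
           act = "relu")
    L <- L %/% 2L  # same-padding conv keeps L; pool halves it
    C <- KC
    if (L < 1L) {
      stop(sprintf(
        "pooled length reaches 0 after convolutional layer %d; input_len %d cannot support depth %d",
        i, cfg$input_len, combo$depth), call. = FALSE)
    }
    trace[[length(trace) + 1L]] <-
      data.frame(layer = i, type = "conv+pool", out_len = L, out_ch = C)
  }
  flatten_len <- L * C
  dims <- c(flatten_len, combo$dense_neurons, cfg$n_classes)
  for (j in 1:3) {
    arch[[length(arch) + 1L]] <-
      list(type = "dense", in_dim = dims[j], out_dim = dims[j + 1],
           KS = NA_integer_, act = if (j < 3) "relu" else "linear",
           flatten = (j == 1))
  }
  n_params <- sum(vapply(arch, function(a) a$in_dim * a$out_dim + a$out_dim,
                         0))
  structure(list(combo = combo, input_len = cfg$input_len,
                 n_classes = cfg$n_classes,
                 dropout_keep = combo$dropout_keep,
                 layers = do.call(rbind, trace), flatten_len = flatten_len,
                 arch = arch, n_params = n_params),
            class = "cnn_spec")
}

#' @export
print.cnn_spec <- function(x, ...) {
  cat(sprintf("<cnn_spec> input %d -> flatten %d -> %s -> %d classes (%s params)\n",
              x$input_len, x$flatten_len,
              paste(x$combo$dense_neurons, collapse = " -> "), x$n_classes,
              format(x$n_params, big.mark = ",")))
  print(x$layers, row.names = FALSE)
  invisible(x)
}

# Labels -> integer class indices over the canonical order, with validation.
labels_to_int <- function(labels) {
  f <- as_class_factor(labels)
  if (anyNA(f)) stop("labels contain NA", call. = FALSE)
  as.integer(f)
}

#' Train the 1-D CNN
#'
#' Minimizes multi-class cross-entropy with Adam over mini-batches.  Windows
#' are standardized per window (zero mean, unit variance) before entering
#' the network.  Initialization, shuffling and dropout are all driven by
#' `cfg$seed`, so a fixed seed reproduces the run exactly on one machine.
#' The training accuracy/loss recorded per epoch are the running mini-batch
#' averages; validation accuracy/loss are computed on `val` after each
#' epoch.
#'
#' @param train A `window_set` of training windows.
#' @param val Optional `window_set` for per-epoch validation.
#' @param combo The architecture, a [param_combo()]. Default
#'   [selected_combo()].
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return A `respcnn_model`: the trained weights, the `cnn_spec`, the
#'   per-epoch `history` data.frame (epoch, train_loss, train_acc,
#'   val_loss, val_acc) and the class ordering.
#' @examples
#' \donttest{
#' ds <- generate_dataset(n_subjects = 1, per_pattern = 6, seed = 1)
#' sp <- split_dataset(ds, seed = 1)
#' m <- train_cnn(sp$train, sp$test,
#'                combo = param_combo(5, 4, c(16, 8)),
#'                cfg = train_config(epochs = 2, seed = 1))
#' }
#' @export
train_cnn <- function(train, val = NULL, combo = selected_combo(),
                      cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(train, "window_set"))
  if (nrow(train$values) == 0) stop("empty training set", call. = FALSE)
  if (ncol(train$values) != cfg$input_len) {
    stop(sprintf("training windows have %d samples, expected input_len %d",
                 ncol(train$values), cfg$input_len), call. = FALSE)
  }
  spec <- build_model(combo, cfg)
  X <- standardize_windows(train$values)
  y <- labels_to_int(train$labels)
  has_val <- !is.null(val)
  if (has_val) {
    stopifnot(inherits(val, "window_set"))
    Xv <- standardize_windows(val$values)
    yv <- labels_to_int(val$labels)
  }
  res <- with_seed(cfg$seed, engine_train(
    spec$arch, X, y,
    if (has_val) Xv else NULL, if (has_val) yv else NULL,
    cfg$epochs, cfg$batch_size, cfg$lr, spec$dropout_keep,
    cfg$input_len, cfg$n_classes))
  history <- data.frame(epoch = seq_len(cfg$epochs),
                        train_loss = res$train_loss,
                        train_acc = res$train_acc,
                        val_loss = res$val_loss, val_acc = res$val_acc)
  if (verbose) {
    for (ep in seq_len(cfg$epochs)) {
      message(sprintf(
        "epoch %3d  loss %.4f  acc %.4f%s", ep, history$train_loss[ep],
        history$train_acc[ep],
        if (has_val) sprintf("  val_loss %.4f  val_acc %.4f",
                             history$val_loss[ep], history$val_acc[ep])
        else ""))
    }
  }
  structure(list(spec = spec, weights = res$weights, history = history,
                 classes = respiration_classes(), cfg = cfg),
            class = "respcnn_model")
}

#' @export
print.respcnn_model <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<respcnn_model> depth %d, %d epochs; final train acc %.3f%s\n",
    x$spec$combo$depth, nrow(x$history), last$train_acc,
    if (!is.na(last$val_acc)) sprintf(", val acc %.3f", last$val_acc)
    else ""))
  invisible(x)
}

#' Predict pattern classes with a trained 1-D CNN
#'
#' @param object A trained `respcnn_model`.
#' @param newdata A `window_set` or numeric matrix (windows in rows) with
#'   the model's input length.
#' @param type `"class"` (default) for argmax labels (ties resolved to the
#'   lowest class index) or `"prob"` for the n x 5 probability matrix
#'   (rows sum to 1).
#' @param ... Unused.
#' @return A factor of predicted classes, or a probability matrix.
#' @export
predict.respcnn_model <- function(object, newdata,
                                  type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "window_set")) newdata$values else
    as.matrix(newdata)
  if (length(dim(X)) != 2 || ncol(X) != object$spec$input_len) {
    stop(sprintf("windows have %d samples, model expects %d", ncol(X),
                 object$spec$input_len), call. = FALSE)
  }
  P <- engine_predict(object$spec$arch, object$weights,
                      standardize_windows(X), object$spec$input_len,
                      object$spec$n_classes)
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  factor(object$classes[max.col(P, ties.method = "first")],
         levels = object$classes)
}

#' Serialize / restore a trained model
#'
#' The architecture, weights and training history are written as one RDS
#' file with the `param_combo` embedded.
#'
#' @param model A `respcnn_model`.
#' @param path Output file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored `respcnn_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "respcnn_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "respcnn_model"))
  model
}
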