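# Confusion-matrix evaluation and classical baselines (LDA, SVM, MLP).

#' Confusion matrix over the five pattern classes
#'
#' @param true,predicted Equal-length label vectors (character or factor)
#'   over [respiration_classes()].
#' @return A 5 x 5 integer matrix of class `confusion_matrix`; rows are
#'   true classes, columns predicted, in canonical class order.
#' @examples
#' confusion_matrix(c("eupnea", "apnea"), c("eupnea", "eupnea"))
#' @export
confusion_matrix <- function(true, predicted) {
  if (length(true) != length(predicted)) {
    stop("`true` and `predicted` must have equal length", call. = FALSE)
  }
  tf <- as_class_factor(true)
  pf <- as_class_factor(predicted)
  m <- table(true = tf, predicted = pf)
  structure(unclass(m), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

#' Per-class and average recognition rates
#'
#' The recognition rate of a class is its recall,
#' `counts[i, i] / rowsum[i]`; the average recognition rate is the
#' unweighted mean over classes (with balanced test sets this equals
#' overall accuracy).  Classes absent from the test set (empty rows) are
#' excluded from the average with a warning.
#'
#' @param cm A [confusion_matrix()].
#' @param method_name Label stored in the report.
#' @return An `eval_report`: `$per_class_rate` (named numeric),
#'   `$average_rate`, `$matrix`, `$method`.
#' @examples
#' cm <- confusion_matrix(rep(respiration_classes(), each = 2),
#'                        rep(respiration_classes(), each = 2))
#' recognition_report(cm, "perfect")$average_rate
#' @export
recognition_report <- function(cm, method_name = "") {
  stopifnot(inherits(cm, "confusion_matrix"))
  rs <- rowSums(cm)
  if (all(rs == 0)) stop("confusion matrix is empty", call. = FALSE)
  rates <- diag(cm) / rs
  if (any(rs == 0)) {
    warning(sprintf(
      "class(es) with no test samples excluded from the average: %s",
      paste(rownames(cm)[rs == 0], collapse = ", ")), call. = FALSE)
  }
  structure(list(per_class_rate = rates,
                 average_rate = mean(rates[rs > 0]),
                 matrix = cm, method = method_name),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s: average recognition rate %.4f\n",
              if (nzchar(x$method)) x$method else "(unnamed)",
              x$average_rate))
  print(round(x$per_class_rate, 4))
  invisible(x)
}

#' Train and evaluate a classical baseline classifier
#'
#' Fits LDA (`MASS::lda`), a radial-basis SVM (`e1071::svm`, default
#' regularization) or a single-hidden-layer MLP (256 ReLU units, trained
#' with the same Adam / mini-batch protocol as the CNN) on the flattened,
#' per-window standardized training windows, and evaluates on the test
#' windows.
#'
#' @param name `"lda"`, `"svm"` or `"mlp"`.
#' @param train,test `window_set`s.
#' @param seed Seed for the stochastic methods (MLP initialization and
#'   shuffling; ignored by LDA/SVM, which are deterministic here).
#' @param mlp_hidden Hidden-layer width of the MLP baseline. Default 256.
#' @param epochs,batch_size MLP training protocol. Defaults 40 and 10.
#' @return An `eval_report` (see [recognition_report()]).
#' @examples
#' \donttest{
#' ds <- generate_dataset(n_subjects = 1, per_pattern = 6, seed = 1)
#' sp <- split_dataset(ds, seed = 1)
#' run_baseline("lda", sp$train, sp$test)$average_rate
#' }
#' @export
run_baseline <- function(name = c("lda", "svm", "mlp"), train, test,
                         seed = NULL, mlp_hidden = 256L, epochs = 40L,
                         batch_size = 10L) {
  name <- match.arg(tolower(name), c("lda", "svm", "mlp"))
  stopifnot(inherits(train, "window_set"), inherits(test, "window_set"))
  Xtr <- standardize_windows(train$values)
  ytr <- droplevels(train$labels)
  if (nlevels(ytr) < 2) {
    stop("training set contains fewer than 2 classes", call. = FALSE)
  }
  Xte <- standardize_windows(test$values)
  pred <- switch(
    name,
    lda = {
      fit <- MASS::lda(Xtr, grouping = ytr)
      as.character(predict(fit, Xte)$class)
    },
    svm = {
      fit <- e1071::svm(Xtr, ytr, kernel = "radial")
      as.character(predict(fit, Xte))
    },
    mlp = {
      as.character(mlp_predict(
        mlp_train(Xtr, labels_to_int(train$labels), hidden = mlp_hidden,
                  epochs = epochs, batch_size = batch_size, seed = seed),
        Xte))
    })
  rep <- recognition_report(confusion_matrix(test$labels, pred),
                            method_name = toupper(name))
  rep$settings <- switch(
    name,
    lda = "MASS::lda, default (moment) estimation",
    svm = "e1071::svm, radial kernel, cost 1, default gamma",
    mlp = sprintf(
      "dense %d-unit ReLU hidden layer, softmax output, Adam 1e-3, %d epochs, batch %d",
      mlp_hidden, epochs, batch_size))
  rep
}

# MLP baseline on the shared dense/Adam engine: one ReLU hidden layer and a
# softmax output, no dropout.
mlp_train <- function(X, y, hidden = 256L, epochs = 40L, batch_size = 10L,
                      seed = NULL, lr = 1e-3) {
  arch <- list(
    list(type = "dense", in_dim = ncol(X), out_dim = as.integer(hidden),
         KS = NA_integer_, act = "relu", flatten = FALSE),
    list(type = "dense", in_dim = as.integer(hidden),
         out_dim = length(.RESP_CLASSES), KS = NA_integer_, act = "linear",
         flatten = FALSE))
  res <- with_seed(seed, engine_train(
    arch, X, y, NULL, NULL, as.integer(epochs), as.integer(batch_size),
    lr, 1.0, ncol(X), length(.RESP_CLASSES)))
  list(weights = res$weights, arch = arch, input_len = ncol(X))
}

mlp_predict <- function(fit, X) {
  P <- engine_predict(fit$arch, fit$weights, X, fit$input_len,
                      length(.RESP_CLASSES))
  factor(.RESP_CLASSES[max.col(P, ties.method = "first")],
         levels = .RESP_CLASSES)
}

#' Compare the CNN against the classical baselines
#'
#' Convenience harness for the comparison experiment: trains the CNN on
#' `train`, evaluates it on `test`, runs the three baselines on the same
#' split, and collects all four `eval_report`s.
#'
#' @param train,test `window_set`s.
#' @param combo CNN architecture. Default [selected_combo()].
#' @param cfg CNN [train_config()].
#' @param seed Seed for the baselines' stochastic parts.
#' @return Named list of `eval_report`s (`cnn`, `lda`, `svm`, `mlp`) plus
#'   `$summary`, a data.frame of average recognition rates.
#' @export
compare_methods <- function(train, test, combo = selected_combo(),
                            cfg = train_config(seed = 1L), seed = 1L) {
  model <- train_cnn(train, val = test, combo = combo, cfg = cfg)
  cnn_rep <- recognition_report(
    confusion_matrix(test$labels, predict(model, test)),
    method_name = "1D CNN")
  reports <- list(cnn = cnn_rep)
  for (nm in c("lda", "svm", "mlp")) {
    reports[[nm]] <- run_baseline(nm, train, test, seed = seed)
  }
  reports$summary <- data.frame(
    method = vapply(reports[1:4], `[[`, "", "method"),
    average_rate = vapply(reports[1:4], `[[`, 0, "average_rate"),
    row.names = NULL)
  reports$model <- model
  reports
}
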