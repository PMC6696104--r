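# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards.  `seed = NULL` evaluates the code without touching the RNG, so
# callers can nest seeded operations inside an already-seeded context.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_if_not_scalar_number <- function(x, name, positive = FALSE,
                                      nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  }
  invisible(x)
}

# Standardize each row (window) to zero mean and unit variance; near-constant
# windows get a variance floor so apnea-like flat windows stay finite.
standardize_windows <- function(x) {
  x <- as.matrix(x)
  mu <- rowMeans(x)
  xc <- x - mu
  s <- sqrt(rowMeans(xc^2))
  s[s < 1e-8] <- 1e-8
  xc / s
}
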