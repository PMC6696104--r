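# Five-class respiration pattern registry.
#
# Rate bands follow the clinical definitions used throughout the package:
# eupnea owns the closed interval [12, 20] breaths/min, bradypnea is
# strictly below 12, tachypnea strictly above 20; apnea and motion are not
# rate-defined.  The classes are kept disjoint so labeling is deterministic.

.RESP_CLASSES <- c("eupnea", "bradypnea", "tachypnea", "apnea", "motion")

.RATE_BANDS <- list(
  eupnea    = c(12, 20),
  bradypnea = c(2, 12),   # lower bound is a physiological floor, upper open
  tachypnea = c(20, 60)   # lower open, upper a physiological ceiling
)

# Fraction of the eupnea amplitude retained during apnea.  The clinical
# definition is a >= 90% flow reduction sustained >= 10 s; the simulator
# retains 5% of the baseline excursion as residual effort.
.APNEA_AMPLITUDE_FACTOR <- 0.05
.APNEA_MIN_DURATION_S <- 10

#' Respiration pattern classes
#'
#' The five pattern classes recognized by the package, in the fixed order
#' used for labels, confusion matrices and network outputs: `eupnea`
#' (normal breathing, 12--20 breaths/min), `bradypnea` (< 12 breaths/min,
#' reduced depth), `tachypnea` (> 20 breaths/min, shallow), `apnea`
#' (>= 90% amplitude reduction sustained >= 10 s) and `motion` (large
#' aperiodic body-movement transients).
#'
#' @return Character vector of the five class names, in canonical order.
#' @examples
#' respiration_classes()
#' @export
respiration_classes <- function() .RESP_CLASSES

#' Breathing-rate band of a pattern class
#'
#' @param class One of the three rhythmic classes `"eupnea"`, `"bradypnea"`
#'   or `"tachypnea"`.  Apnea and motion are not rate-defined and raise an
#'   error.
#' @return Numeric length-2 vector `c(lower, upper)` in breaths/min.
#'   Eupnea's band is closed on both ends; bradypnea's is open above at 12
#'   and tachypnea's open below at 20 (the bounds returned here are the
#'   truncation limits used by the simulator).
#' @examples
#' rate_band("eupnea")
#' @export
rate_band <- function(class) {
  class <- match.arg(class, .RESP_CLASSES)
  band <- .RATE_BANDS[[class]]
  if (is.null(band)) {
    stop(sprintf("class '%s' has no breathing-rate band", class),
         call. = FALSE)
  }
  band
}

#' Classify a breathing rate into a rhythmic pattern class
#'
#' @param rate Breathing rate in breaths/min (> 0).
#' @return `"bradypnea"` for rates < 12, `"eupnea"` for rates in
#'   \[12, 20\], `"tachypnea"` for rates > 20.
#' @examples
#' classify_rate(16)
#' classify_rate(8)
#' @export
classify_rate <- function(rate) {
  stop_if_not_scalar_number(rate, "rate", positive = TRUE)
  if (rate < 12) "bradypnea" else if (rate <= 20) "eupnea" else "tachypnea"
}

# Coerce labels (character or factor) to a factor over the canonical class
# order, erroring on anything outside the five classes.
as_class_factor <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), .RESP_CLASSES)
  if (length(bad) > 0) {
    stop(sprintf("unknown pattern label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  factor(labels, levels = .RESP_CLASSES)
}
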