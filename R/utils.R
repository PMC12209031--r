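# internal validation helpers

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1], got %s",
                 name, deparse(substitute(x))), call. = FALSE)
  }
  as.numeric(x)
}

.check_pos <- function(x, name, strict = TRUE, integer = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop(sprintf("`%s` must be a single %s number", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  }
  if (integer) as.integer(x) else as.numeric(x)
}

.check_seed <- function(seed) {
  if (missing(seed) || is.null(seed) || !is.numeric(seed) ||
      length(seed) != 1L || is.na(seed)) {
    stop("a single integer `seed` is required; implicit randomness is not allowed",
         call. = FALSE)
  }
  as.integer(seed)
}

#' Response classes of the rodent gambling task
#'
#' Trial taxonomy used throughout the package: low-risk rewarded (`LR`),
#' low-risk non-rewarded (`LNo`), high-risk rewarded (`HR`), high-risk
#' non-rewarded (`HNo`). Omissions (no press within the trial limit) are a
#' fifth trial outcome but carry no lever-press event.
#'
#' @return Character vector of the four pressed-trial response classes.
#' @export
response_classes <- function() c("LR", "LNo", "HR", "HNo")

.trial_outcomes <- function() c(response_classes(), "omission")
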