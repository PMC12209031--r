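#' Choice preference index
#'
#' CPI = (low-risk presses − high-risk presses) / completed presses, where
#' completed = low + high (omissions are excluded from the denominator).
#' Ranges over \[−1, 1\]: +1 is exclusive low-risk (risk-averse) choice,
#' −1 exclusive high-risk (risk-prone) choice. When no trial in the input
#' was completed the index is undefined and `NA` is returned.
#'
#' @param trials Data frame with an `outcome` column, or a character
#'   vector of outcomes (`LR`, `LNo`, `HR`, `HNo`, `omission`).
#' @return A number in \[−1, 1\], or `NA` if no completed trials.
#' @export
choice_preference_index <- function(trials) {
  outcome <- if (is.data.frame(trials)) trials$outcome else as.character(trials)
  if (length(outcome) == 0L) stop("`trials` must be nonempty", call. = FALSE)
  bad <- setdiff(unique(outcome), .trial_outcomes())
  if (length(bad)) stop("unknown outcomes: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  n_low <- sum(outcome %in% c("LR", "LNo"))
  n_high <- sum(outcome %in% c("HR", "HNo"))
  n_completed <- n_low + n_high
  if (n_completed == 0L) return(NA_real_)
  (n_low - n_high) / n_completed
}

#' Per-block choice preference curve
#'
#' Tiles the trial sequence (omissions included in block membership) into
#' consecutive blocks of `block_size` trials and computes the CPI of each
#' block; a trailing partial block is kept and flagged. Blocks with zero
#' completed trials get an undefined (`NA`) CPI, rendered as a gap. The
#' curve is also returned smoothed with a 3-point centered moving mean.
#'
#' @param trials Session trial data frame (column `outcome`).
#' @param block_size Trials per block (default 10).
#' @param smooth_window Width of the moving-mean smoother (odd).
#' @return Data frame with columns `block`, `n_trials`, `n_completed`,
#'   `cpi`, `smoothed`, `partial`.
#' @export
preference_curve <- function(trials, block_size = 10, smooth_window = 3) {
  if (is.data.frame(trials) && nrow(trials) == 0L || length(trials) == 0L) {
    stop("empty session", call. = FALSE)
  }
  .check_pos(block_size, "block_size", integer = TRUE)
  outcome <- if (is.data.frame(trials)) trials$outcome else as.character(trials)
  n <- length(outcome)
  block <- (seq_len(n) - 1L) %/% block_size + 1L
  nb <- max(block)
  cpi <- n_tr <- n_comp <- numeric(nb)
  for (b in seq_len(nb)) {
    oc <- outcome[block == b]
    n_tr[b] <- length(oc)
    n_comp[b] <- sum(oc != "omission")
    cpi[b] <- choice_preference_index(oc)
  }
  data.frame(block = seq_len(nb), n_trials = n_tr, n_completed = n_comp,
             cpi = cpi, smoothed = smooth_curve(cpi, smooth_window),
             partial = n_tr < block_size)
}

#' Centered moving-mean smoothing
#'
#' 3-point (by default) centered moving mean. Edges use the available,
#' shrunken window so the curve keeps its length. Undefined (`NA`) entries
#' stay `NA` in the output and are excluded from their neighbours' means.
#'
#' @param values Numeric vector (may contain `NA`).
#' @param window Odd window width.
#' @return Smoothed vector of the same length.
#' @export
smooth_curve <- function(values, window = 3) {
  if (window < 1 || window %% 2 == 0) {
    stop("`window` must be odd and >= 1", call. = FALSE)
  }
  n <- length(values)
  h <- (window - 1L) %/% 2L
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(values[i])) next
    idx <- max(1L, i - h):min(n, i + h)
    out[i] <- mean(values[idx], na.rm = TRUE)
  }
  out
}

#' Omission rate of a session
#'
#' @param trials Session trial data frame or outcome vector.
#' @return Percentage of trials scored as omissions (0–100).
#' @export
omission_rate <- function(trials) {
  outcome <- if (is.data.frame(trials)) trials$outcome else as.character(trials)
  if (length(outcome) == 0L) stop("`trials` must be nonempty", call. = FALSE)
  100 * sum(outcome == "omission") / length(outcome)
}

#' Trial-by-trial response map
#'
#' One categorical code per trial, in trial order, for trial-by-trial
#' raster displays (low-risk trials conventionally drawn green/cyan,
#' high-risk red/orange, omissions black).
#'
#' @param trials Session trial data frame or outcome vector.
#' @return Character vector, one of `low_rewarded`, `low_unrewarded`,
#'   `high_rewarded`, `high_unrewarded`, `omission` per trial.
#' @export
response_map <- function(trials) {
  outcome <- if (is.data.frame(trials)) trials$outcome else as.character(trials)
  if (length(outcome) == 0L) stop("`trials` must be nonempty", call. = FALSE)
  map <- c(LR = "low_rewarded", LNo = "low_unrewarded",
           HR = "high_rewarded", HNo = "high_unrewarded",
           omission = "omission")
  unname(map[outcome])
}

#' Latency summary over completed trials
#'
#' @param trials Session trial data frame with `outcome` and `latency_s`.
#' @return List with `mean`, `sd`, `n` (completed trials); `mean` and `sd`
#'   are `NA` when no trial was completed.
#' @export
latency_summary <- function(trials) {
  stopifnot(is.data.frame(trials), all(c("outcome", "latency_s") %in% names(trials)))
  lat <- trials$latency_s[trials$outcome != "omission"]
  if (length(lat) == 0L) return(list(mean = NA_real_, sd = NA_real_, n = 0L))
  list(mean = mean(lat), sd = stats::sd(lat), n = length(lat))
}

#' Detect a mid-session preference switch
#'
#' Returns the first block whose smoothed CPI drops below zero — the point
#' where the animal's preference tips from the low-risk to the high-risk
#' lever — or `NA` if the curve never crosses.
#'
#' @param curve A [preference_curve()] data frame.
#' @return Integer block index or `NA`.
#' @export
detect_preference_switch <- function(curve) {
  stopifnot(is.data.frame(curve), "smoothed" %in% names(curve))
  idx <- which(!is.na(curve$smoothed) & curve$smoothed < 0)
  if (length(idx) == 0L) return(NA_integer_)
  as.integer(idx[1])
}
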