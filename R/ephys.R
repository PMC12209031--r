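#' PETH configuration
#'
#' Defaults follow the standard event-locked analysis used throughout the
#' package: a window from 5 s before to 10 s after the lever press, 50-ms
#' bins, and a 3-point Gaussian smoother.
#'
#' @param window_pre Seconds before the press (positive).
#' @param window_post Seconds after the press.
#' @param bin_width Bin width in seconds.
#' @param smooth_points Width of the truncated Gaussian kernel in bins
#'   (odd).
#' @return A `peth_config` object.
#' @export
peth_config <- function(window_pre = 5, window_post = 10, bin_width = 0.05,
                        smooth_points = 3) {
  .check_pos(window_pre, "window_pre")
  .check_pos(window_post, "window_post")
  .check_pos(bin_width, "bin_width")
  for (w in c(window_pre, window_post)) {
    k <- w / bin_width
    if (abs(k - round(k)) > 1e-9) {
      stop("window lengths must be integer multiples of `bin_width`",
           call. = FALSE)
    }
  }
  if (smooth_points < 1 || smooth_points %% 2 == 0) {
    stop("`smooth_points` must be odd", call. = FALSE)
  }
  structure(list(window_pre = window_pre, window_post = window_post,
                 bin_width = bin_width, smooth_points = as.integer(smooth_points)),
            class = "peth_config")
}

#' Compute a peri-event time histogram
#'
#' Bins spike times relative to each press of the requested response class
#' into half-open bins `[t, t + bin_width)` (press = 0; a spike exactly at
#' the press falls in the first post-press bin) and averages over events:
#' `mean_rate[b] = total count in bin b / (n_events * bin_width)`. Raw
#' summed counts are retained for conservation checks. Overlapping event
#' windows are allowed; each event contributes independently.
#'
#' @param spikes Sorted numeric vector of spike times (seconds), or a
#'   single element of a `spike_trains` list.
#' @param events Data frame with `press_time_s` and `outcome`.
#' @param class_filter Response class to lock to, or `NULL` for all
#'   events.
#' @param config A [peth_config()].
#' @param unit_id Optional unit identifier carried in the result.
#' @return A `peth` object: `bin_edges`, `bin_centers`, `counts`,
#'   `mean_rate`, `n_events`, `unit_id`, `response_class`, `config`,
#'   `empty`. When no event of the class exists, `empty = TRUE` and rates
#'   are `NA` (an explicit marker, not silent zeros).
#' @export
compute_peth <- function(spikes, events, class_filter = NULL,
                         config = peth_config(), unit_id = NA_character_) {
  stopifnot(inherits(config, "peth_config"))
  spikes <- as.numeric(spikes)
  if (is.unsorted(spikes)) stop("spike times must be sorted", call. = FALSE)
  ev <- events
  if (!is.null(class_filter)) ev <- ev[ev$outcome == class_filter, , drop = FALSE]
  nbins <- as.integer(round((config$window_pre + config$window_post) / config$bin_width))
  edges <- -config$window_pre + config$bin_width * (0:nbins)
  centers <- edges[-1] - config$bin_width / 2
  out <- list(bin_edges = edges, bin_centers = centers,
              counts = rep(0, nbins), mean_rate = rep(NA_real_, nbins),
              n_events = nrow(ev), unit_id = unit_id,
              response_class = if (is.null(class_filter)) "all" else class_filter,
              config = config, smoothed = FALSE, empty = nrow(ev) == 0L)
  class(out) <- "peth"
  if (out$empty) return(out)
  counts <- rep(0L, nbins)
  for (t in ev$press_time_s) {
    lo <- findInterval(t - config$window_pre, spikes) + 1L
    hi <- findInterval(t + config$window_post - 1e-12, spikes)
    if (hi < lo) next
    rel <- spikes[lo:hi] - t
    idx <- floor((rel + config$window_pre) / config$bin_width) + 1L
    idx <- idx[idx >= 1L & idx <= nbins]
    tab <- tabulate(idx, nbins)
    counts <- counts + tab
  }
  out$counts <- counts
  out$mean_rate <- counts / (out$n_events * config$bin_width)
  out
}

# normalized truncated-Gaussian kernel; edges renormalized over the bins
# actually available
.gauss_kernel <- function(points, sigma) {
  h <- (points - 1L) %/% 2L
  w <- exp(-((-h:h)^2) / (2 * sigma^2))
  w / sum(w)
}

.smooth_vec <- function(x, points, sigma) {
  n <- length(x)
  h <- (points - 1L) %/% 2L
  w <- .gauss_kernel(points, sigma)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    ww <- w[(lo - i + h + 1L):(hi - i + h + 1L)]
    out[i] <- sum(x[lo:hi] * ww) / sum(ww)
  }
  out
}

#' Gaussian smoothing of a PETH
#'
#' Convolves the mean-rate vector with a normalized Gaussian kernel
#' truncated to `smooth_points` bins (sigma defaults to one bin). Kernel
#' weights sum to 1, so a constant PETH is unchanged; at the edges the
#' kernel is renormalized over the available bins. Raw counts are kept
#' untouched.
#'
#' @param peth A `peth` object, or a bare numeric vector.
#' @param smooth_points Odd kernel width in bins.
#' @param sigma Kernel standard deviation in bins.
#' @return Smoothed `peth` (with `smoothed = TRUE`) or numeric vector.
#' @export
gaussian_smooth <- function(peth, smooth_points = 3, sigma = 1) {
  if (smooth_points < 1 || smooth_points %% 2 == 0) {
    stop("`smooth_points` must be odd", call. = FALSE)
  }
  if (is.numeric(peth)) return(.smooth_vec(peth, smooth_points, sigma))
  stopifnot(inherits(peth, "peth"))
  if (peth$empty) return(peth)
  peth$mean_rate <- .smooth_vec(peth$mean_rate, smooth_points, sigma)
  peth$smoothed <- TRUE
  peth
}

#' Baseline Z-scoring of a PETH
#'
#' Standardizes each bin as `z = (x - m) / SD`, with `m` and `SD` the mean
#' and (sample) standard deviation of the baseline bins — by default the
#' 5-s pre-press window `[-window_pre, 0)` of the same PETH. A zero
#' baseline SD flags the unit `degenerate_baseline` (z left `NA`) rather
#' than fabricating zeros; such units are excluded from Z-based summaries.
#'
#' @param peth A `peth` object.
#' @param baseline Length-2 numeric `c(from, to)` in press-relative
#'   seconds; bins with centers in `[from, to)` form the baseline.
#' @return A `zscored_peth` object: `z`, `baseline_mean`, `baseline_sd`,
#'   `degenerate`, plus the bin geometry and identifiers of the input.
#' @export
zscore_peth <- function(peth, baseline = NULL) {
  stopifnot(inherits(peth, "peth"))
  if (peth$empty) stop("cannot Z-score an empty PETH", call. = FALSE)
  if (is.null(baseline)) baseline <- c(-peth$config$window_pre, 0)
  in_base <- peth$bin_centers >= baseline[1] & peth$bin_centers < baseline[2]
  if (!any(in_base)) stop("empty baseline interval", call. = FALSE)
  m <- mean(peth$mean_rate[in_base])
  s <- stats::sd(peth$mean_rate[in_base])
  degenerate <- !is.finite(s) || s == 0
  z <- if (degenerate) rep(NA_real_, length(peth$mean_rate)) else
    (peth$mean_rate - m) / s
  structure(list(z = z, baseline_mean = m, baseline_sd = s,
                 degenerate = degenerate, bin_centers = peth$bin_centers,
                 bin_edges = peth$bin_edges, unit_id = peth$unit_id,
                 response_class = peth$response_class, config = peth$config),
            class = "zscored_peth")
}

#' Mean Z in a press-relative window
#'
#' @param zpeth A `zscored_peth`.
#' @param window Length-2 numeric window in press-relative seconds
#'   (default the 5-s post-press window).
#' @return Mean z over bins with centers in `[window[1], window[2])`, or
#'   `NA` for a degenerate baseline.
#' @export
mean_z <- function(zpeth, window = c(0, 5)) {
  stopifnot(inherits(zpeth, "zscored_peth"))
  if (zpeth$degenerate) return(NA_real_)
  sel <- zpeth$bin_centers >= window[1] & zpeth$bin_centers < window[2]
  mean(zpeth$z[sel])
}

#' Background firing rate
#'
#' Spontaneous firing rate over a fixed interval (default the 10-min
#' window used for background-activity comparisons): spike count divided
#' by interval length.
#'
#' @param spikes Numeric vector of spike times (seconds).
#' @param duration Interval length in seconds (> 0).
#' @param start Interval start (seconds).
#' @return Rate in Hz.
#' @export
background_rate <- function(spikes, duration = 600, start = 0) {
  .check_pos(duration, "duration")
  sum(spikes >= start & spikes < start + duration) / duration
}
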