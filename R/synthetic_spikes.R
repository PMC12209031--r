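#' Specification of a simulated unit
#'
#' A unit fires as an inhomogeneous Poisson process: `baseline_rate`
#' everywhere, multiplied by `gain_by_response[class]` during the 5-s
#' window after each lever press of that class. A gain of 1 means no
#' modulation; gains above 1 emulate reward-locked excitation, gains below
#' 1 the suppression typical of non-rewarded presses.
#'
#' @param unit_id Unit identifier (coerced to character).
#' @param baseline_rate Baseline firing rate in Hz (>= 0).
#' @param gain_by_response Named numeric vector of multiplicative gains for
#'   the four response classes; missing classes default to 1.
#' @param cluster_id Planted-cluster identifier (used by recovery tests).
#' @return A `unit_spec` object.
#' @export
unit_spec <- function(unit_id, baseline_rate,
                      gain_by_response = c(LR = 1, LNo = 1, HR = 1, HNo = 1),
                      cluster_id = NA) {
  .check_pos(baseline_rate, "baseline_rate", strict = FALSE)
  gains <- stats::setNames(rep(1, 4), response_classes())
  if (length(gain_by_response)) {
    bad <- setdiff(names(gain_by_response), response_classes())
    if (length(bad)) stop("unknown response class in gains: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (any(gain_by_response < 0)) stop("gains must be >= 0", call. = FALSE)
    gains[names(gain_by_response)] <- gain_by_response
  }
  structure(list(unit_id = as.character(unit_id),
                 baseline_rate = as.numeric(baseline_rate),
                 gain_by_response = gains,
                 cluster_id = cluster_id),
            class = "unit_spec")
}

# piecewise-constant rate segments for one unit given events; overlapping
# post-event windows are resolved in favour of the later event
.rate_segments <- function(unit, events, duration, window) {
  rate <- unit$baseline_rate
  if (nrow(events) == 0L || rate == 0 && all(unit$gain_by_response == 0)) {
    # still emit the baseline segment (rate may be > 0 with no events)
  }
  ev <- events[order(events$press_time_s), , drop = FALSE]
  breaks <- 0
  rates <- numeric(0)
  pos <- 0
  overlap_conflict <- FALSE
  nev <- nrow(ev)
  for (i in seq_len(nev)) {
    t0 <- ev$press_time_s[i]
    g <- unit$gain_by_response[[ev$outcome[i]]]
    end <- min(t0 + window, duration)
    nxt <- if (i < nev) ev$press_time_s[i + 1] else Inf
    if (nxt < end) {
      gi_next <- unit$gain_by_response[[ev$outcome[i + 1]]]
      if (gi_next != g) overlap_conflict <- TRUE
      end <- nxt
    }
    if (t0 > pos) { breaks <- c(breaks, t0); rates <- c(rates, rate) }
    if (end > max(pos, t0)) {
      breaks <- c(breaks, end)
      rates <- c(rates, rate * g)
    }
    pos <- max(pos, end)
  }
  if (pos < duration) { breaks <- c(breaks, duration); rates <- c(rates, rate) }
  list(breaks = breaks, rates = rates, conflict = overlap_conflict)
}

#' Simulate spike trains for a unit population
#'
#' Each unit is drawn as an inhomogeneous Poisson process with a
#' piecewise-constant intensity: baseline rate everywhere and
#' `baseline_rate * gain` during the `window` seconds after each event of
#' the corresponding response class. When consecutive post-event windows
#' overlap with conflicting gains the later event takes over at its press
#' time and a warning is emitted.
#'
#' @param units List of [unit_spec()] objects.
#' @param events Data frame with `press_time_s` and `outcome` columns.
#' @param duration Total recording duration in seconds; must cover all
#'   event windows.
#' @param seed Integer seed (mandatory).
#' @param window Post-event modulation window in seconds (default 5,
#'   mirroring the analysis window).
#' @return A named list (by unit id) of sorted spike-time vectors, class
#'   `spike_trains`.
#' @export
simulate_spikes <- function(units, events, duration, seed, window = 5) {
  seed <- .check_seed(seed)
  stopifnot(is.list(units), duration > 0)
  if (nrow(events) && max(events$press_time_s) > duration) {
    stop("`duration` must cover all events", call. = FALSE)
  }
  any_conflict <- FALSE
  trains <- withr::with_seed(seed, {
    lapply(units, function(u) {
      seg <- .rate_segments(u, events, duration, window)
      if (seg$conflict) any_conflict <<- TRUE
      lens <- diff(seg$breaks)
      counts <- stats::rpois(length(lens), seg$rates * lens)
      total <- sum(counts)
      if (total == 0L) return(numeric(0))
      ts <- rep(seg$breaks[-length(seg$breaks)], counts) +
        stats::runif(total) * rep(lens, counts)
      sort(ts)
    })
  })
  if (any_conflict) {
    warning("overlapping post-event windows with conflicting gains; ",
            "later event takes precedence", call. = FALSE)
  }
  names(trains) <- vapply(units, `[[`, character(1), "unit_id")
  structure(trains, class = "spike_trains", duration = duration)
}

#' Build a planted-cluster unit population
#'
#' Convenience constructor for recovery simulations: `n_per_cluster` units
#' per row of `gain_table`, each with the row's gains and a common
#' baseline rate.
#'
#' @param gain_table Matrix or data frame, one row per planted cluster,
#'   columns named by response class, entries multiplicative gains.
#' @param n_per_cluster Units per planted cluster.
#' @param baseline_rate Baseline firing rate in Hz shared by all units.
#' @return List of [unit_spec()] objects with `cluster_id` set to the row
#'   index.
#' @export
planted_units <- function(gain_table, n_per_cluster = 20, baseline_rate = 8) {
  gain_table <- as.matrix(gain_table)
  stopifnot(!is.null(colnames(gain_table)),
            all(colnames(gain_table) %in% response_classes()))
  units <- list()
  for (k in seq_len(nrow(gain_table))) {
    for (j in seq_len(n_per_cluster)) {
      units[[length(units) + 1L]] <- unit_spec(
        unit_id = sprintf("c%d_u%02d", k, j),
        baseline_rate = baseline_rate,
        gain_by_response = gain_table[k, ],
        cluster_id = k
      )
    }
  }
  units
}
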