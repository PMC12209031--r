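#' Task contingency of a gambling probe session
#'
#' The default contingency is the two-lever gambling schedule with balanced
#' expected value: the low-risk lever pays 1 pellet on 9 of 10 presses, the
#' high-risk lever 3 pellets on 3 of 10 presses. A trial not completed
#' within `trial_limit` seconds is an omission; completed trials are
#' followed by an `inter_trial` wait.
#'
#' @param low_risk_prob Reward probability of the low-risk lever.
#' @param low_risk_pellets Pellets dispensed on a rewarded low-risk press.
#' @param high_risk_prob Reward probability of the high-risk lever.
#' @param high_risk_pellets Pellets dispensed on a rewarded high-risk press.
#' @param n_trials Number of trials per probe session.
#' @param trial_limit Seconds allowed to press before the trial is scored
#'   as an omission.
#' @param inter_trial Seconds between consecutive trials.
#' @return A `task_contingency` object (validated list).
#' @export
task_contingency <- function(low_risk_prob = 0.9, low_risk_pellets = 1,
                             high_risk_prob = 0.3, high_risk_pellets = 3,
                             n_trials = 90, trial_limit = 15,
                             inter_trial = 10) {
  out <- list(
    low_risk_prob = .check_prob(low_risk_prob, "low_risk_prob"),
    low_risk_pellets = .check_pos(low_risk_pellets, "low_risk_pellets", integer = TRUE),
    high_risk_prob = .check_prob(high_risk_prob, "high_risk_prob"),
    high_risk_pellets = .check_pos(high_risk_pellets, "high_risk_pellets", integer = TRUE),
    n_trials = .check_pos(n_trials, "n_trials", integer = TRUE),
    trial_limit = .check_pos(trial_limit, "trial_limit"),
    inter_trial = .check_pos(inter_trial, "inter_trial", strict = FALSE)
  )
  structure(out, class = "task_contingency")
}

#' Behavioral agent parameters for session simulation
#'
#' A minimal stochastic agent standing in for a rat: on each trial it omits
#' with probability `p_omit`; otherwise it presses the low-risk lever with
#' probability `p_low_choice` (optionally drifting by `drift` per trial,
#' clipped to \[0, 1\]) and the high-risk lever otherwise. Press latencies
#' are truncated-normal on (0, trial_limit\].
#'
#' @param p_low_choice Per-trial probability of choosing the low-risk lever.
#' @param p_omit Per-trial probability of an omission (decided first).
#' @param latency_mean,latency_sd Mean and SD (seconds) of the latent
#'   normal latency distribution before truncation.
#' @param drift Additive per-trial change in `p_low_choice`; 0 keeps the
#'   preference stationary.
#' @param switch_trial Optional 1-based trial from which the low-risk
#'   choice probability becomes `p_low_after` (a two-regime agent
#'   emulating a mid-session preference shift).
#' @param p_low_after Low-risk choice probability from `switch_trial` on.
#' @return An `agent_params` object.
#' @export
agent_params <- function(p_low_choice = 0.8, p_omit = 0.05,
                         latency_mean = 2, latency_sd = 1, drift = 0,
                         switch_trial = NULL, p_low_after = NULL) {
  if (!is.numeric(latency_sd) || latency_sd < 0) {
    stop("`latency_sd` must be >= 0", call. = FALSE)
  }
  out <- list(
    p_low_choice = .check_prob(p_low_choice, "p_low_choice"),
    p_omit = .check_prob(p_omit, "p_omit"),
    latency_mean = .check_pos(latency_mean, "latency_mean"),
    latency_sd = as.numeric(latency_sd),
    drift = as.numeric(drift),
    switch_trial = if (is.null(switch_trial)) NULL else
      .check_pos(switch_trial, "switch_trial", integer = TRUE),
    p_low_after = if (is.null(p_low_after)) NULL else
      .check_prob(p_low_after, "p_low_after")
  )
  if (xor(is.null(out$switch_trial), is.null(out$p_low_after))) {
    stop("`switch_trial` and `p_low_after` must be given together",
         call. = FALSE)
  }
  structure(out, class = "agent_params")
}

#' Full simulation configuration
#'
#' Bundles the task contingency, the behavioral agent, the unit population,
#' and the mandatory seed. `session_padding` seconds of silence are kept
#' before the first and after the last event so every peri-event window
#' fits inside the recording.
#'
#' @param contingency A [task_contingency()].
#' @param agent An [agent_params()].
#' @param units List of [unit_spec()] objects (may be empty for
#'   behavior-only simulations).
#' @param seed Integer seed; required — no implicit randomness.
#' @param session_padding Seconds of padding; must be >= 10 so the 5-s
#'   pre-press and 10-s post-press windows fit.
#' @return A `sim_config` object.
#' @export
sim_config <- function(contingency = task_contingency(),
                       agent = agent_params(),
                       units = list(), seed,
                       session_padding = 10) {
  stopifnot(inherits(contingency, "task_contingency"),
            inherits(agent, "agent_params"))
  if (!is.list(units) || (length(units) && !all(vapply(units, inherits, TRUE, "unit_spec")))) {
    stop("`units` must be a list of unit_spec objects", call. = FALSE)
  }
  if (session_padding < 10) {
    stop("`session_padding` must be >= 10 s so every PETH window fits",
         call. = FALSE)
  }
  structure(list(contingency = contingency, agent = agent, units = units,
                 seed = .check_seed(seed),
                 session_padding = as.numeric(session_padding)),
            class = "sim_config")
}

# truncated normal on (lo, hi] via inverse CDF; sd = 0 collapses to the
# clipped mean
.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(min(max(mean, lo + 1e-9), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  pmin(pmax(stats::qnorm(u, mean, sd), lo + 1e-9), hi)
}

#' Simulate one gambling probe session
#'
#' Draws trial-by-trial behavior from the configured agent under the
#' configured contingency. Omission is decided first; completed trials get
#' a lever choice, a truncated-normal press latency, and a reward draw from
#' the chosen arm's probability. Event times are strictly increasing with
#' spacing at least `inter_trial`.
#'
#' @param config A [sim_config()].
#' @return List with `trials` (data frame: trial, side, arm, outcome,
#'   omission, latency_s, press_time_s), `events` (data frame:
#'   press_time_s, outcome — completed trials only), and `duration`
#'   (seconds, includes end padding).
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cg <- config$contingency
  ag <- config$agent
  n <- cg$n_trials
  withr::with_seed(config$seed, {
    p_base <- rep(ag$p_low_choice, n)
    if (!is.null(ag$switch_trial)) {
      p_base[seq_len(n) >= ag$switch_trial] <- ag$p_low_after
    }
    p_low <- pmin(pmax(p_base + ag$drift * (seq_len(n) - 1), 0), 1)
    omitted <- stats::runif(n) < ag$p_omit
    chose_low <- stats::runif(n) < p_low
    latency <- .rtrunc_norm(n, ag$latency_mean, ag$latency_sd, 0, cg$trial_limit)
    p_reward <- ifelse(chose_low, cg$low_risk_prob, cg$high_risk_prob)
    rewarded <- stats::runif(n) < p_reward
  })
  arm <- ifelse(omitted, "none", ifelse(chose_low, "low_risk", "high_risk"))
  outcome <- ifelse(omitted, "omission",
                    ifelse(chose_low,
                           ifelse(rewarded, "LR", "LNo"),
                           ifelse(rewarded, "HR", "HNo")))
  # fixed arena mapping: low-risk lever on the left chamber
  side <- ifelse(omitted, NA_character_, ifelse(chose_low, "left", "right"))
  latency[omitted] <- NA_real_

  # trial i occupies [start_i, start_i + latency_i] (or + trial_limit when
  # omitted), then an inter-trial wait
  dur <- ifelse(omitted, cg$trial_limit, latency)
  start <- config$session_padding +
    c(0, cumsum(dur[-n] + cg$inter_trial))
  press <- ifelse(omitted, NA_real_, start + latency)

  trials <- data.frame(
    trial = seq_len(n), side = side, arm = arm, outcome = outcome,
    omission = omitted, latency_s = latency, press_time_s = press,
    stringsAsFactors = FALSE
  )
  events <- data.frame(press_time_s = press[!omitted],
                       outcome = outcome[!omitted],
                       stringsAsFactors = FALSE)
  duration <- start[n] + dur[n] + config$session_padding
  list(trials = trials, events = events, duration = duration)
}

#' Evenly spaced event series with balanced response classes
#'
#' Deterministic calibration scaffold: `n_per_class` events of each
#' response class, interleaved cyclically and spaced `spacing` seconds
#' apart. Useful for simulations that must guarantee every unit sees every
#' class (agent-driven sessions can produce no low-risk non-rewarded
#' trials at all). The default spacing keeps each event's 5-s modulation
#' window and the next event's 5-s baseline disjoint.
#'
#' @param n_per_class Events per response class.
#' @param classes Response classes to interleave.
#' @param spacing Seconds between consecutive events.
#' @param start Time of the first event (>= 10 s so pre-windows fit).
#' @return Data frame with columns `press_time_s`, `outcome`.
#' @export
balanced_events <- function(n_per_class, classes = response_classes(),
                            spacing = 12, start = 10) {
  stopifnot(n_per_class >= 1, spacing > 0, start >= 10)
  n <- n_per_class * length(classes)
  data.frame(press_time_s = start + spacing * (seq_len(n) - 1),
             outcome = rep(classes, n_per_class),
             stringsAsFactors = FALSE)
}
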