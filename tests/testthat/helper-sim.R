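# shared fixtures built in code

# outcome vector with the given completed-trial composition
make_outcomes <- function(n_LR = 0, n_LNo = 0, n_HR = 0, n_HNo = 0, n_om = 0) {
  c(rep("LR", n_LR), rep("LNo", n_LNo), rep("HR", n_HR), rep("HNo", n_HNo),
    rep("omission", n_om))
}

make_trials <- function(outcomes, latency = 2) {
  n <- length(outcomes)
  data.frame(trial = seq_len(n), side = NA_character_,
             arm = ifelse(outcomes %in% c("LR", "LNo"), "low_risk",
                          ifelse(outcomes %in% c("HR", "HNo"), "high_risk", "none")),
             outcome = outcomes, omission = outcomes == "omission",
             latency_s = ifelse(outcomes == "omission", NA_real_, latency),
             stringsAsFactors = FALSE)
}

# minimal hand-built PETH object for arithmetic checks
make_peth <- function(mean_rate, bin_width = 1, window_pre = NULL,
                      unit_id = "u", response_class = "LR") {
  n <- length(mean_rate)
  if (is.null(window_pre)) window_pre <- floor(n / 2) * bin_width
  edges <- -window_pre + bin_width * (0:n)
  cfg <- peth_config(window_pre = window_pre,
                     window_post = n * bin_width - window_pre,
                     bin_width = bin_width)
  structure(list(bin_edges = edges, bin_centers = edges[-1] - bin_width / 2,
                 counts = mean_rate * bin_width, mean_rate = mean_rate,
                 n_events = 1L, unit_id = unit_id,
                 response_class = response_class, config = cfg,
                 smoothed = FALSE, empty = FALSE),
            class = "peth")
}

# simulate a planted-cluster population on a balanced event scaffold and
# return recovered vs planted labels
run_planted_recovery <- function(gain_table, seed, n_per_cluster = 20,
                                 baseline_rate = 8, n_per_class = 20,
                                 cut_threshold = 3) {
  units <- planted_units(gain_table, n_per_cluster, baseline_rate)
  ev <- balanced_events(n_per_class)
  dur <- max(ev$press_time_s) + 15
  trains <- simulate_spikes(units, ev, dur, seed = seed)
  peths <- list()
  for (uid in names(trains)) {
    for (cl in response_classes()) {
      peths[[length(peths) + 1L]] <- compute_peth(trains[[uid]], ev, cl,
                                                  unit_id = uid)
    }
  }
  feats <- build_features(peths)
  tree <- hierarchical_cluster(feats)
  labels <- cut_tree(tree, cut_threshold)
  planted <- vapply(units, `[[`, numeric(1), "cluster_id")
  names(planted) <- vapply(units, `[[`, character(1), "unit_id")
  list(recovered = labels, planted = planted[names(labels)],
       trains = trains, events = ev, peths = peths)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
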