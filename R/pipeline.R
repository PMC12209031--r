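#' Pipeline run configuration
#'
#' Every tunable defaults to the package's standard analysis values
#' (10-trial CPI blocks, −5..+10 s PETH at 50-ms bins with 3-point
#' Gaussian smoothing, Euclidean/average-linkage clustering cut at 3,
#' 0.5-Hz exclusion). Inputs come either from a [sim_config()] or from
#' CSV paths in the interchange schema.
#'
#' @param sim A [sim_config()], or `NULL` to read CSVs.
#' @param trials_csv,events_csv,spikes_csv,ct_csv Input paths (used when
#'   `sim` is `NULL`; `ct_csv` optionally alongside a simulation).
#' @param block_size CPI block size in trials.
#' @param peth A [peth_config()].
#' @param cluster A [cluster_config()].
#' @param expression `NULL`, or a list with `housekeeping` and `targets`
#'   (character vector of target genes).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return A `run_config` object.
#' @export
run_config <- function(sim = NULL, trials_csv = NULL, events_csv = NULL,
                       spikes_csv = NULL, ct_csv = NULL, block_size = 10,
                       peth = peth_config(), cluster = cluster_config(),
                       expression = NULL, out_dir = NULL) {
  if (is.null(sim) && (is.null(trials_csv) || is.null(events_csv))) {
    stop("either `sim` or trials/events CSV paths are required", call. = FALSE)
  }
  structure(list(sim = sim, trials_csv = trials_csv, events_csv = events_csv,
                 spikes_csv = spikes_csv, ct_csv = ct_csv,
                 block_size = block_size, peth = peth, cluster = cluster,
                 expression = expression, out_dir = out_dir),
            class = "run_config")
}

.config_hash <- function(config) {
  # hash the scientific configuration only: where outputs land must not
  # change what is computed
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              force = TRUE, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> behavior -> PETH/Z -> clustering ->
#' expression (optional), writes the CSV/JSON output bundle when an
#' output directory is configured, and stamps everything with the config
#' hash. Reruns with the same configuration (and seed) are bit-identical.
#'
#' @param config A [run_config()].
#' @return A report list with elements `behavior`, `peths`, `zpeths`,
#'   `features`, `clustering` (tree, labels, mean-Z, flexibility,
#'   exclusions), `expression`, `config_hash`, and `digests` (MD5 per
#'   written file) when outputs were written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  hash <- .config_hash(config)

  # ---- inputs -------------------------------------------------------------
  if (!is.null(config$sim)) {
    sess <- simulate_session(config$sim)
    trials <- sess$trials
    events <- sess$events
    duration <- sess$duration
    spikes <- if (length(config$sim$units)) {
      simulate_spikes(config$sim$units, events, duration,
                      seed = config$sim$seed + 1L)
    } else NULL
  } else {
    trials <- read_trials(config$trials_csv)
    events <- read_events(config$events_csv)
    spikes <- if (!is.null(config$spikes_csv)) read_spikes(config$spikes_csv) else NULL
    duration <- if (!is.null(spikes) && length(spikes)) {
      max(c(events$press_time_s + config$peth$window_post,
            unlist(spikes, use.names = FALSE))) + 1
    } else max(events$press_time_s) + config$peth$window_post + 1
  }

  # ---- behavior -----------------------------------------------------------
  curve <- preference_curve(trials, config$block_size)
  behavior <- list(
    preference_curve = curve,
    session_cpi = choice_preference_index(trials),
    omission_rate = omission_rate(trials),
    latency = latency_summary(trials),
    response_map = response_map(trials),
    switch_block = detect_preference_switch(curve)
  )

  # ---- ephys + clustering -------------------------------------------------
  peths <- zpeths <- list()
  features <- clustering <- NULL
  if (!is.null(spikes) && length(spikes) >= 2L) {
    rates <- vapply(spikes, function(ts) length(ts) / duration, numeric(1))
    keep <- exclude_low_firing(rates, config$cluster$min_rate_hz)
    for (uid in keep$kept) {
      for (cl in response_classes()) {
        p <- compute_peth(spikes[[uid]], events, cl, config$peth, unit_id = uid)
        peths[[length(peths) + 1L]] <- p
        if (!p$empty) {
          ps <- gaussian_smooth(p, config$peth$smooth_points)
          zpeths[[length(zpeths) + 1L]] <- zscore_peth(ps)
        }
      }
    }
    features <- build_features(peths)
    if (nrow(features$features) >= 2L) {
      tree <- hierarchical_cluster(features, config$cluster)
      labels <- cut_tree(tree, config$cluster$cut_threshold)
      mz <- cluster_mean_z(labels, zpeths)
      clustering <- list(
        tree = tree, labels = labels, cluster_mean_z = mz,
        flexibility = flexibility_score(mz),
        excluded = rbind(
          keep$excluded[, c("unit_id", "reason")],
          tree$excluded
        )
      )
    }
  }

  # ---- expression ---------------------------------------------------------
  expression <- NULL
  if (!is.null(config$expression)) {
    ct <- if (!is.null(config$ct_csv)) read_ct(config$ct_csv) else config$expression$ct
    if (is.null(ct)) stop("expression stage enabled but no Ct table provided",
                          call. = FALSE)
    hk <- config$expression$housekeeping %||% "GAPDH"
    targets <- config$expression$targets %||%
      setdiff(unique(ct$gene), hk)
    expression <- lapply(stats::setNames(targets, targets), function(g) {
      relative_expression(ct, housekeeping = hk, target = g)
    })
  }

  report <- list(trials = trials, events = events, behavior = behavior,
                 peths = peths, zpeths = zpeths, features = features,
                 clustering = clustering, expression = expression,
                 config = config, config_hash = hash)

  if (!is.null(config$out_dir)) {
    report$digests <- .write_bundle(report, config$out_dir)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_bundle <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- function(f) file.path(out_dir, f)
  write_trials(report$trials, p("trials.csv")); paths <- c(paths, p("trials.csv"))
  write_events(report$events, p("events.csv")); paths <- c(paths, p("events.csv"))
  utils::write.csv(report$behavior$preference_curve, p("preference_curve.csv"),
                   row.names = FALSE)
  paths <- c(paths, p("preference_curve.csv"))
  metrics <- list(config_hash = report$config_hash,
                  session_cpi = report$behavior$session_cpi,
                  omission_rate = report$behavior$omission_rate,
                  latency = report$behavior$latency,
                  switch_block = report$behavior$switch_block)
  writeLines(jsonlite::toJSON(metrics, auto_unbox = TRUE, digits = NA,
                              null = "null", na = "null"),
             p("metrics.json"))
  paths <- c(paths, p("metrics.json"))
  if (!is.null(report$clustering)) {
    tree <- report$clustering$tree
    utils::write.csv(data.frame(step = seq_along(tree$height),
                                left = tree$merge[, 1], right = tree$merge[, 2],
                                distance = tree$height, size = tree$size),
                     p("merge_tree.csv"), row.names = FALSE)
    utils::write.csv(data.frame(unit_id = names(report$clustering$labels),
                                cluster = unname(report$clustering$labels)),
                     p("labels.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(report$clustering$cluster_mean_z),
                     p("cluster_mean_z.csv"))
    utils::write.csv(data.frame(cluster = names(report$clustering$flexibility),
                                flexibility = unname(report$clustering$flexibility)),
                     p("flexibility.csv"), row.names = FALSE)
    fx <- report$features$features
    utils::write.csv(data.frame(unit_id = rownames(fx), as.data.frame(fx)),
                     p("features.csv"), row.names = FALSE)
    paths <- c(paths, p("merge_tree.csv"), p("labels.csv"),
               p("cluster_mean_z.csv"), p("flexibility.csv"), p("features.csv"))
  }
  if (!is.null(report$expression)) {
    per_sample <- do.call(rbind, lapply(report$expression, function(r) {
      cbind(gene = r$target, r$per_sample)
    }))
    utils::write.csv(per_sample, p("expression.csv"), row.names = FALSE)
    paths <- c(paths, p("expression.csv"))
  }
  digests <- tools::md5sum(paths)
  names(digests) <- basename(paths)
  writeLines(jsonlite::toJSON(as.list(digests), auto_unbox = TRUE),
             p("digests.json"))
  digests
}

#' Compare analysis periods cluster by cluster
#'
#' Per-cluster, per-class change in mean Z between two pipeline reports
#' (e.g. a control period and a pain period). Because each period is
#' clustered independently, clusters are matched by response-profile
#' similarity: each period-2 cluster is paired with the period-1 cluster
#' whose mean-Z row is nearest in Euclidean distance (an artifact
#' convention, flagged by a warning when cluster counts differ).
#'
#' @param control,pain Reports from [run_pipeline()] (or lists with a
#'   `clustering$cluster_mean_z` matrix).
#' @return Data frame: `pain_cluster`, `matched_control_cluster`,
#'   `class`, `control_z`, `pain_z`, `delta_z`.
#' @export
compare_periods <- function(control, pain) {
  mz1 <- control$clustering$cluster_mean_z
  mz2 <- pain$clustering$cluster_mean_z
  if (is.null(mz1) || is.null(mz2)) {
    stop("both reports must include clustering results", call. = FALSE)
  }
  if (nrow(mz1) != nrow(mz2)) {
    warning("cluster counts differ between periods; matching by nearest ",
            "mean-Z profile", call. = FALSE)
  }
  rows <- list()
  for (k in seq_len(nrow(mz2))) {
    d <- apply(mz1, 1, function(r) sqrt(sum((r - mz2[k, ])^2, na.rm = TRUE)))
    j <- which.min(d)
    for (cl in colnames(mz2)) {
      rows[[length(rows) + 1L]] <- data.frame(
        pain_cluster = rownames(mz2)[k],
        matched_control_cluster = rownames(mz1)[j],
        class = cl, control_z = mz1[j, cl], pain_z = mz2[k, cl],
        delta_z = mz2[k, cl] - mz1[j, cl], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
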