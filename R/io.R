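# CSV interchange schema: UTF-8, comma-separated, header row.
#   trials: trial, side, arm, outcome, omission, latency_s
#   events: press_time_s, outcome
#   spikes: unit_id, time_s
#   ct:     sample, group, gene, replicate, ct

#' Read and write pipeline CSV files
#'
#' Thin wrappers around [utils::read.csv()]/[utils::write.csv()] pinning
#' the interchange schema used by all pipeline stages.
#'
#' @param path File path.
#' @param trials,events,ct Data frames in the corresponding schema.
#' @param spikes Named list of spike-time vectors (`spike_trains`), or a
#'   long data frame with `unit_id`, `time_s`.
#' @return Readers return the parsed object; writers return the path,
#'   invisibly.
#' @name rgt_io
NULL

#' @rdname rgt_io
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials[, c("trial", "side", "arm", "outcome", "omission",
                              "latency_s")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname rgt_io
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial", "side", "arm", "outcome", "omission", "latency_s")
  if (!all(need %in% names(df))) {
    stop("trials CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname rgt_io
#' @export
write_events <- function(events, path) {
  utils::write.csv(events[, c("press_time_s", "outcome")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname rgt_io
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("press_time_s", "outcome") %in% names(df))) {
    stop("events CSV must have columns press_time_s, outcome", call. = FALSE)
  }
  df[order(df$press_time_s), , drop = FALSE]
}

#' @rdname rgt_io
#' @export
write_spikes <- function(spikes, path) {
  if (is.list(spikes) && !is.data.frame(spikes)) {
    spikes <- data.frame(
      unit_id = rep(names(spikes), lengths(spikes)),
      time_s = unlist(spikes, use.names = FALSE),
      stringsAsFactors = FALSE
    )
  }
  utils::write.csv(spikes[, c("unit_id", "time_s")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname rgt_io
#' @export
read_spikes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("unit_id", "time_s") %in% names(df))) {
    stop("spikes CSV must have columns unit_id, time_s", call. = FALSE)
  }
  trains <- lapply(split(df$time_s, df$unit_id), sort)
  structure(trains[unique(df$unit_id)], class = "spike_trains")
}

#' @rdname rgt_io
#' @export
write_ct <- function(ct, path) {
  utils::write.csv(ct[, c("sample", "group", "gene", "replicate", "ct")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname rgt_io
#' @export
read_ct <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "group", "gene", "replicate", "ct")
  if (!all(need %in% names(df))) {
    stop("ct CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}
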