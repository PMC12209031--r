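#' Simulate a replicate Ct table
#'
#' Draws Gaussian Ct replicates per sample and gene, emulating real-time
#' PCR runs performed in triplicate with a housekeeping gene present in
#' every sample.
#'
#' @param groups Named list: group name -> named list of genes, each a
#'   numeric vector `c(mean = , sd = )` of Ct cycles. Every group must
#'   include the housekeeping gene.
#' @param n_samples Samples per group.
#' @param n_replicates Technical replicates per sample and gene.
#' @param seed Integer seed (mandatory).
#' @param housekeeping Name of the housekeeping gene.
#' @return Data frame with columns `sample`, `group`, `gene`, `replicate`,
#'   `ct`.
#' @export
simulate_ct_table <- function(groups, n_samples, n_replicates = 3, seed,
                              housekeeping = "GAPDH") {
  seed <- .check_seed(seed)
  stopifnot(is.list(groups), length(groups) >= 1, n_samples >= 1,
            n_replicates >= 1)
  for (g in names(groups)) {
    genes <- groups[[g]]
    if (!housekeeping %in% names(genes)) {
      stop(sprintf("group '%s' is missing the housekeeping gene '%s'",
                   g, housekeeping), call. = FALSE)
    }
    for (gene in names(genes)) {
      p <- genes[[gene]]
      if (!all(c("mean", "sd") %in% names(p)) || p[["mean"]] <= 0 ||
          p[["sd"]] < 0) {
        stop(sprintf("gene '%s' in group '%s' needs c(mean > 0, sd >= 0)",
                     gene, g), call. = FALSE)
      }
    }
  }
  rows <- list()
  withr::with_seed(seed, {
    for (g in names(groups)) {
      for (s in seq_len(n_samples)) {
        sid <- sprintf("%s_s%02d", g, s)
        for (gene in names(groups[[g]])) {
          p <- groups[[g]][[gene]]
          ct <- stats::rnorm(n_replicates, p[["mean"]], p[["sd"]])
          rows[[length(rows) + 1L]] <- data.frame(
            sample = sid, group = g, gene = gene,
            replicate = seq_len(n_replicates), ct = ct,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  })
  do.call(rbind, rows)
}
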