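#' Delta-Ct relative gene expression
#'
#' Semi-quantitative relative expression by the delta-Ct method: per
#' sample, technical-replicate Ct values are averaged per gene, the delta
#' is `Ct_target - Ct_housekeeping`, and relative expression is
#' `2^(-delta_Ct)` (1 when target and housekeeping amplify at the same
#' cycle; halved per extra cycle of the target). Group means and SDs are
#' attached.
#'
#' @param ct_table Data frame with columns `sample`, `group`, `gene`,
#'   `replicate`, `ct`.
#' @param housekeeping Housekeeping (reference) gene id, e.g. `"GAPDH"`.
#' @param target Target gene id.
#' @return An `expression_result` list: `per_sample` (sample, group,
#'   ct_target, ct_housekeeping, delta_ct, rel_expr), `per_group` (group,
#'   n, mean, sd), `target`, `housekeeping`.
#' @export
relative_expression <- function(ct_table, housekeeping = "GAPDH", target) {
  stopifnot(is.data.frame(ct_table),
            all(c("sample", "group", "gene", "replicate", "ct") %in% names(ct_table)))
  if (missing(target)) stop("`target` gene is required", call. = FALSE)
  if (!target %in% ct_table$gene) {
    stop(sprintf("target gene '%s' not present in the Ct table", target),
         call. = FALSE)
  }
  samples <- unique(ct_table$sample)
  rows <- lapply(samples, function(s) {
    sub <- ct_table[ct_table$sample == s, , drop = FALSE]
    hk <- sub$ct[sub$gene == housekeeping]
    tg <- sub$ct[sub$gene == target]
    if (length(hk) == 0L) {
      stop(sprintf("sample '%s' is missing the housekeeping gene '%s'",
                   s, housekeeping), call. = FALSE)
    }
    if (length(tg) == 0L) {
      stop(sprintf("sample '%s' is missing the target gene '%s'", s, target),
           call. = FALSE)
    }
    d <- mean(tg) - mean(hk)
    data.frame(sample = s, group = sub$group[1],
               ct_target = mean(tg), ct_housekeeping = mean(hk),
               delta_ct = d, rel_expr = 2^(-d), stringsAsFactors = FALSE)
  })
  per_sample <- do.call(rbind, rows)
  per_group <- do.call(rbind, lapply(split(per_sample, per_sample$group), function(g) {
    data.frame(group = g$group[1], n = nrow(g), mean = mean(g$rel_expr),
               sd = stats::sd(g$rel_expr), stringsAsFactors = FALSE)
  }))
  rownames(per_group) <- NULL
  structure(list(per_sample = per_sample, per_group = per_group,
                 target = target, housekeeping = housekeeping),
            class = "expression_result")
}

#' Rank-based two-group comparison of relative expression
#'
#' Two-sided Mann–Whitney (Wilcoxon rank-sum) test between the two groups
#' of an [relative_expression()] result, delegating to
#' [stats::wilcox.test()].
#'
#' @param result An `expression_result`.
#' @return List with `statistic` (U), `p_value`, `groups`, `n`.
#' @export
compare_groups <- function(result) {
  stopifnot(inherits(result, "expression_result"))
  ps <- result$per_sample
  groups <- unique(ps$group)
  if (length(groups) != 2L) {
    stop("exactly two groups are required", call. = FALSE)
  }
  x <- ps$rel_expr[ps$group == groups[1]]
  y <- ps$rel_expr[ps$group == groups[2]]
  if (length(x) == 0L || length(y) == 0L) stop("a group is empty", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
  # completely tied samples degenerate to NaN; no evidence of a difference
  if (is.nan(wt$p.value)) wt$p.value <- 1
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       groups = groups, n = c(length(x), length(y)))
}
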