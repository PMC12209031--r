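#' Clustering configuration
#'
#' Defaults mirror the analysis conventions the package implements:
#' Euclidean distance between activity-ratio profiles, average linkage,
#' a dendrogram cut threshold of 3 on the linkage-distance scale, and a
#' 0.5-Hz low-firing exclusion threshold.
#'
#' @param metric Distance metric passed to [stats::dist()].
#' @param linkage Linkage method; only `"average"` is implemented.
#' @param cut_threshold Linkage distance below which merges are eligible
#'   for the gap-based cut (> 0).
#' @param min_rate_hz Session-wide firing-rate exclusion threshold.
#' @param row_standardize Standardize each unit's feature row to zero mean
#'   and unit SD before distances (off by default; the activity ratio is
#'   already the standardization).
#' @return A `cluster_config` object.
#' @export
cluster_config <- function(metric = "euclidean", linkage = "average",
                           cut_threshold = 3, min_rate_hz = 0.5,
                           row_standardize = FALSE) {
  if (!identical(linkage, "average")) {
    stop("only average linkage is implemented", call. = FALSE)
  }
  .check_pos(cut_threshold, "cut_threshold")
  .check_pos(min_rate_hz, "min_rate_hz", strict = FALSE)
  structure(list(metric = metric, linkage = linkage,
                 cut_threshold = cut_threshold, min_rate_hz = min_rate_hz,
                 row_standardize = isTRUE(row_standardize)),
            class = "cluster_config")
}

#' Activity-ratio feature matrix
#'
#' For each unit and response class, the feature is the ratio of the mean
#' firing rate 5 s after the lever press to the mean rate 5 s before it
#' (the baseline), computed from raw (unsmoothed) PETHs. A unit whose
#' pre-press mean is zero has no finite ratio and is excluded with reason
#' `zero_baseline`; a class with no events is recorded as `NA` (never
#' imputed) and handled downstream.
#'
#' @param peths List of `peth` objects (one per unit per response class).
#' @param ratio_window Half-width of the pre/post averaging windows in
#'   seconds.
#' @return List with `features` (units x classes matrix, `NA` for missing
#'   classes) and `excluded` (data frame `unit_id`, `reason` for
#'   zero-baseline units, which are dropped from the matrix).
#' @export
build_features <- function(peths, ratio_window = 5) {
  stopifnot(length(peths) > 0)
  ids <- unique(vapply(peths, `[[`, character(1), "unit_id"))
  classes <- response_classes()
  feat <- matrix(NA_real_, length(ids), length(classes),
                 dimnames = list(ids, classes))
  zero_baseline <- character(0)
  for (p in peths) {
    stopifnot(inherits(p, "peth"))
    if (p$empty || !p$response_class %in% classes) next
    pre <- p$bin_centers >= -ratio_window & p$bin_centers < 0
    post <- p$bin_centers >= 0 & p$bin_centers < ratio_window
    m_pre <- mean(p$mean_rate[pre])
    m_post <- mean(p$mean_rate[post])
    if (m_pre == 0) {
      zero_baseline <- union(zero_baseline, p$unit_id)
      next
    }
    feat[p$unit_id, p$response_class] <- m_post / m_pre
  }
  excluded <- data.frame(unit_id = zero_baseline,
                         reason = rep("zero_baseline", length(zero_baseline)),
                         stringsAsFactors = FALSE)
  keep <- setdiff(ids, zero_baseline)
  if (length(keep) == 0L) stop("no units with a finite activity ratio",
                               call. = FALSE)
  list(features = feat[keep, , drop = FALSE], excluded = excluded)
}

#' Exclude low-firing units
#'
#' Units whose session-wide mean rate is strictly below `min_rate_hz` are
#' excluded (kept if equal to the threshold), minimizing the impact of
#' low-firing units on the clustering.
#'
#' @param rates Named numeric vector of session-wide mean rates (Hz).
#' @param min_rate_hz Threshold in Hz.
#' @return List with `kept` (names) and `excluded` (data frame `unit_id`,
#'   `rate_hz`, `reason`).
#' @export
exclude_low_firing <- function(rates, min_rate_hz = 0.5) {
  stopifnot(is.numeric(rates), !is.null(names(rates)))
  low <- rates < min_rate_hz
  list(kept = names(rates)[!low],
       excluded = data.frame(unit_id = names(rates)[low],
                             rate_hz = unname(rates[low]),
                             reason = rep("low_firing", sum(low)),
                             stringsAsFactors = FALSE))
}

#' Agglomerative average-linkage clustering
#'
#' Full agglomerative merge tree under average linkage (unweighted
#' pair-group mean, via the Lance–Williams update) on Euclidean distances
#' between feature rows. Ties in the minimum inter-cluster distance are
#' broken deterministically in favour of the lowest pair of cluster
#' positions, so dendrograms are reproducible across platforms. Units with
#' a missing response class are excluded with reason `missing_class`
#' rather than imputed.
#'
#' @param features Units x classes numeric matrix (rownames = unit ids),
#'   or the list returned by [build_features()].
#' @param config A [cluster_config()].
#' @return An `rgt_hclust` object: `merge` (hclust convention: negative =
#'   singleton observation, positive = prior merge step), `height`
#'   (linkage distance per merge, nondecreasing), `size` (merged cluster
#'   size), `labels` (unit ids), `excluded` (data frame of dropped units).
#' @export
hierarchical_cluster <- function(features, config = cluster_config()) {
  stopifnot(inherits(config, "cluster_config"))
  excluded_prior <- data.frame(unit_id = character(0), reason = character(0),
                               stringsAsFactors = FALSE)
  if (is.list(features) && !is.matrix(features)) {
    excluded_prior <- features$excluded[, c("unit_id", "reason")]
    features <- features$features
  }
  stopifnot(is.matrix(features))
  complete <- stats::complete.cases(features)
  excluded <- rbind(excluded_prior,
                    data.frame(unit_id = rownames(features)[!complete],
                               reason = rep("missing_class", sum(!complete)),
                               stringsAsFactors = FALSE))
  x <- features[complete, , drop = FALSE]
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 units with complete features to cluster",
                   call. = FALSE)
  if (config$row_standardize) {
    x <- t(scale(t(x)))
  }
  D <- as.matrix(stats::dist(x, method = config$metric))
  diag(D) <- Inf
  ids <- -seq_len(n)          # hclust convention
  sizes <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  msize <- integer(n - 1L)
  for (s in seq_len(n - 1L)) {
    m <- min(D)
    cand <- which(D == m, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    height[s] <- m
    merge[s, ] <- sort(c(ids[i], ids[j]))
    # average-linkage Lance-Williams update
    newd <- (sizes[i] * D[i, ] + sizes[j] * D[j, ]) / (sizes[i] + sizes[j])
    D[i, ] <- newd; D[, i] <- newd; D[i, i] <- Inf
    sizes[i] <- sizes[i] + sizes[j]
    msize[s] <- sizes[i]
    ids[i] <- s
    keep <- setdiff(seq_len(nrow(D)), j)
    D <- D[keep, keep, drop = FALSE]
    ids <- ids[keep]; sizes <- sizes[keep]
  }
  if (any(diff(height) < -1e-9)) {
    warning("non-monotone merge heights under average linkage", call. = FALSE)
  }
  structure(list(merge = merge, height = height, size = msize,
                 labels = rownames(x), n = n, excluded = excluded,
                 config = config),
            class = "rgt_hclust")
}

#' @export
as.hclust.rgt_hclust <- function(x, ...) {
  # order: leaf sequence from recursive traversal of the merge tree
  ord_of <- function(k) {
    if (k < 0) return(-k)
    c(ord_of(x$merge[k, 1]), ord_of(x$merge[k, 2]))
  }
  structure(list(merge = x$merge, height = x$height,
                 order = ord_of(nrow(x$merge)), labels = x$labels,
                 method = "average", dist.method = x$config$metric),
            class = "hclust")
}

#' Gap-based dendrogram cut
#'
#' Formalizes the cut rule "largest increase in distance among merges
#' below a linkage threshold": among the successive merge distances
#' strictly below `cut_threshold`, find the largest gap between
#' consecutive merges and cut immediately below the merge that opens it
#' (the earliest such gap wins on ties). A gapless regime (all
#' sub-threshold gaps ~0, e.g. all pairwise distances equal) applies every
#' sub-threshold merge; if no merge distance is below the threshold, all
#' units stay singletons.
#'
#' @param tree An `rgt_hclust` object.
#' @param cut_threshold Linkage-distance threshold (default 3).
#' @param gap_tol Gaps below this are treated as zero.
#' @return Integer cluster labels named by unit id, numbered by first
#'   appearance in the unit order.
#' @export
cut_tree <- function(tree, cut_threshold = 3, gap_tol = 1e-9) {
  stopifnot(inherits(tree, "rgt_hclust"))
  h <- tree$height
  n <- tree$n
  sub <- which(h < cut_threshold)
  if (length(sub) == 0L) {
    k_apply <- 0L
  } else {
    m <- max(sub)                     # heights nondecreasing: prefix
    if (m >= 2L) {
      gaps <- diff(h[seq_len(m)])
      if (max(gaps) <= gap_tol) {
        k_apply <- m                  # gapless regime: merge everything
      } else {
        k_apply <- which.max(gaps)    # cut below merge k_apply + 1
      }
    } else {
      k_apply <- m
    }
  }
  # union-find over the first k_apply merges
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  reps <- integer(nrow(tree$merge))
  for (s in seq_len(k_apply)) {
    l <- tree$merge[s, 1]; r <- tree$merge[s, 2]
    a <- if (l < 0) -l else reps[l]
    b <- if (r < 0) -r else reps[r]
    ra <- find(a); rb <- find(b)
    parent[rb] <- ra
    reps[s] <- ra
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- match(roots, unique(roots))
  stats::setNames(as.integer(labels), tree$labels)
}

#' Per-cluster mean Z by response class
#'
#' For each cluster and response class, the mean over member units of the
#' unit's mean Z in the post-press window — the magnitude of the encoded
#' choice response. Units flagged `degenerate_baseline` are skipped; a
#' cluster/class cell with no Z-valid unit is `NA`.
#'
#' @param labels Named integer vector from [cut_tree()].
#' @param zpeths List of `zscored_peth` objects (one per unit per class).
#' @param window Post-press averaging window in seconds.
#' @return Clusters x classes numeric matrix.
#' @export
cluster_mean_z <- function(labels, zpeths, window = c(0, 5)) {
  classes <- response_classes()
  ks <- sort(unique(labels))
  out <- matrix(NA_real_, length(ks), length(classes),
                dimnames = list(paste0("cluster", ks), classes))
  unit_z <- list()
  for (zp in zpeths) {
    if (!zp$unit_id %in% names(labels)) next
    key <- paste(zp$unit_id, zp$response_class, sep = "\r")
    unit_z[[key]] <- mean_z(zp, window)
  }
  for (ki in seq_along(ks)) {
    in_k <- names(labels)[labels == ks[ki]]
    for (cl in classes) {
      vals <- unlist(unit_z[paste(in_k, cl, sep = "\r")], use.names = FALSE)
      vals <- vals[!is.na(vals)]
      if (length(vals)) out[ki, cl] <- mean(vals)
    }
  }
  out
}

#' Encoding-flexibility score of a cluster
#'
#' Number of response classes a cluster encodes, quantified as the count
#' of classes whose absolute mean Z meets the threshold (default 1.96, the
#' two-sided 5% normal bound). Missing classes are not counted.
#'
#' @param z_row Numeric vector of per-class mean Z (length 4, `NA`
#'   allowed), or a clusters x classes matrix (scored row-wise).
#' @param z_threshold Absolute-Z threshold.
#' @return Integer score(s) in 0..4.
#' @export
flexibility_score <- function(z_row, z_threshold = 1.96) {
  if (is.matrix(z_row)) {
    return(apply(z_row, 1, flexibility_score, z_threshold = z_threshold))
  }
  as.integer(sum(abs(z_row) >= z_threshold, na.rm = TRUE))
}
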