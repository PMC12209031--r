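# Independent brute-force average-linkage oracle: keeps explicit member
# sets and recomputes every inter-cluster average from the ORIGINAL
# pairwise distance matrix at every step (no Lance-Williams update).
# Ties broken by the lowest minimum-member-index pair.
oracle_average_linkage <- function(x, metric = "euclidean") {
  d0 <- as.matrix(stats::dist(x, method = metric))
  n <- nrow(d0)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(n - 1L)
  partitions <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    m <- length(clusters)
    best <- NULL
    for (a in seq_len(m - 1L)) {
      for (b in (a + 1L):m) {
        dav <- mean(d0[clusters[[a]], clusters[[b]]])
        key <- c(min(clusters[[a]]), min(clusters[[b]]))
        better <- is.null(best) || dav < best$d - 1e-12 ||
          (abs(dav - best$d) <= 1e-12 &&
             (key[1] < best$key[1] ||
                (key[1] == best$key[1] && key[2] < best$key[2])))
        if (better) best <- list(a = a, b = b, d = dav, key = key)
      }
    }
    heights[s] <- best$d
    merged <- sort(c(clusters[[best$a]], clusters[[best$b]]))
    clusters[[best$a]] <- merged
    clusters[[best$b]] <- NULL
    partitions[[s]] <- lapply(clusters, sort)
  }
  list(heights = heights, partitions = partitions)
}

# partition (list of member index sets) after the first k merges of an
# rgt_hclust tree, as a canonical sorted list
tree_partition <- function(tree, k) {
  n <- tree$n
  groups <- as.list(seq_len(n))
  alive <- rep(TRUE, n + nrow(tree$merge))
  store <- vector("list", nrow(tree$merge))
  for (s in seq_len(k)) {
    get <- function(id) if (id < 0) -id else store[[id]]
    l <- tree$merge[s, 1]; r <- tree$merge[s, 2]
    store[[s]] <- sort(c(get(l), get(r)))
  }
  # collect roots: singletons never merged + merge nodes never used later
  used <- c(tree$merge[seq_len(k), ])
  singletons <- setdiff(seq_len(n), -used[used < 0])
  merges_alive <- setdiff(seq_len(k), used[used > 0])
  parts <- c(lapply(singletons, identity), store[merges_alive])
  parts[order(vapply(parts, min, numeric(1)))]
}

canon_partition <- function(parts) {
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, min, numeric(1)))]
}
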