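test_that("average linkage on collinear points matches hand computation", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  tr <- hierarchical_cluster(x)
  expect_equal(tr$height, c(1, 1, 10))
  expect_equal(tree_partition(tr, 2), list(c(1, 2), c(3, 4)))
  # identical rows merge at distance zero
  y <- matrix(c(1, 1, 2, 1, 1, 2), ncol = 3, byrow = TRUE,
              dimnames = list(c("u", "v"), c("LR", "HR", "HNo")))
  expect_equal(hierarchical_cluster(y)$height, 0)
  expect_error(hierarchical_cluster(y[1, , drop = FALSE]), "at least 2")
})

test_that("merge trees equal the brute-force average-linkage oracle", {
  for (seed in 1:25) {
    x <- withr::with_seed(seed, {
      n <- sample(2:7, 1)
      matrix(rnorm(n * 4), n, 4,
             dimnames = list(paste0("u", 1:n), response_classes()))
    })
    tr <- hierarchical_cluster(x)
    or <- oracle_average_linkage(x)
    expect_equal(tr$height, or$heights, tolerance = 1e-12)
    for (s in seq_along(or$heights)) {
      expect_equal(tree_partition(tr, s), canon_partition(or$partitions[[s]]))
    }
    # cross-check against the reference hclust implementation
    expect_equal(tr$height,
                 stats::hclust(dist(x), method = "average")$height,
                 tolerance = 1e-12)
  }
})

test_that("partitions are invariant to unit order", {
  x <- withr::with_seed(42, matrix(rnorm(40), 10, 4,
                                   dimnames = list(paste0("u", 1:10),
                                                   response_classes())))
  lab1 <- cut_tree(hierarchical_cluster(x), 1.5)
  perm <- withr::with_seed(7, sample(10))
  lab2 <- cut_tree(hierarchical_cluster(x[perm, ]), 1.5)
  lab2 <- lab2[names(lab1)]
  # same partition up to label renaming
  expect_equal(adjusted_rand(lab1, lab2), 1)
})

test_that("gap-based cut follows the largest sub-threshold gap", {
  # heights {0.1, 0.12, 2.9}: largest gap opens before 2.9 -> 2 clusters
  x <- matrix(c(0, 0.1, 0.21, 3), ncol = 1,
              dimnames = list(paste0("u", 1:4), NULL))
  tr <- hierarchical_cluster(x)
  expect_true(all(tr$height < 3))
  labs <- cut_tree(tr, 3)
  expect_equal(max(labs), 2)
  expect_equal(unname(labs), c(1, 1, 1, 2))

  # equidistant points: gapless regime, all sub-threshold merges applied
  eq <- matrix(c(0, 0, 1, 0, 0.5, sqrt(3) / 2), ncol = 2, byrow = TRUE,
               dimnames = list(paste0("u", 1:3), NULL))
  expect_equal(max(cut_tree(hierarchical_cluster(eq), 3)), 1)

  # nothing below threshold: all singletons
  expect_equal(max(cut_tree(tr, 0.05)), 4)
})

test_that("low-firing exclusion keeps units at the threshold", {
  rates <- c(a = 0.4, b = 0.5, c = 2.0)
  ex <- exclude_low_firing(rates, 0.5)
  expect_equal(ex$kept, c("b", "c"))
  expect_equal(ex$excluded$unit_id, "a")
  expect_equal(exclude_low_firing(rates, 0)$kept, c("a", "b", "c"))
  # monotone: raising the threshold never adds units
  thresholds <- c(0, 0.3, 0.5, 1, 3)
  kept <- lapply(thresholds, function(th) exclude_low_firing(rates, th)$kept)
  for (i in seq_len(length(kept) - 1)) {
    expect_true(all(kept[[i + 1]] %in% kept[[i]]))
  }
})

test_that("activity ratios reflect planted gains; degenerate units are excluded", {
  ev <- balanced_events(20)
  dur <- max(ev$press_time_s) + 15
  units <- list(unit_spec("gain3", 10, c(HR = 3)),
                unit_spec("flat", 10),
                unit_spec("mute", 0))
  tr <- simulate_spikes(units, ev, dur, seed = 13)
  peths <- list()
  for (uid in names(tr)) {
    for (cl in response_classes()) {
      peths[[length(peths) + 1L]] <- compute_peth(tr[[uid]], ev, cl,
                                                  unit_id = uid)
    }
  }
  f <- build_features(peths)
  expect_equal(f$features["gain3", "HR"], 3, tolerance = 0.25)
  expect_equal(unname(f$features["flat", ]), rep(1, 4), tolerance = 0.25)
  expect_equal(f$excluded$reason, "zero_baseline")
  expect_false("mute" %in% rownames(f$features))
})

test_that("units missing a response class are dropped with a reason", {
  ev <- balanced_events(5, classes = c("LR", "HR", "HNo"))  # no LNo events
  units <- list(unit_spec("u1", 8), unit_spec("u2", 8, c(HR = 3)),
                unit_spec("u3", 8, c(LR = 2)))
  tr <- simulate_spikes(units, ev, max(ev$press_time_s) + 15, seed = 3)
  peths <- list()
  for (uid in names(tr)) {
    for (cl in response_classes()) {
      peths[[length(peths) + 1L]] <- compute_peth(tr[[uid]], ev, cl,
                                                  unit_id = uid)
    }
  }
  f <- build_features(peths)
  expect_true(all(is.na(f$features[, "LNo"])))
  expect_error(hierarchical_cluster(f), "at least 2")
})

test_that("cluster mean Z aggregates unit responses per class", {
  z_hi <- make_peth(c(rep(c(8, 12), 5), rep(20, 10)), bin_width = 0.5,
                    window_pre = 5, unit_id = "a", response_class = "HR")
  z_lo <- make_peth(c(rep(c(8, 12), 5), rep(0, 10)), bin_width = 0.5,
                    window_pre = 5, unit_id = "b", response_class = "HR")
  zp <- list(zscore_peth(z_hi), zscore_peth(z_lo))
  one <- cluster_mean_z(c(a = 1L), zp[1])
  expect_equal(one["cluster1", "HR"], mean_z(zp[[1]]))
  # +z and -z of equal magnitude average to zero
  both <- cluster_mean_z(c(a = 1L, b = 1L), zp)
  expect_equal(both["cluster1", "HR"],
               (mean_z(zp[[1]]) + mean_z(zp[[2]])) / 2)
  expect_true(all(is.na(both["cluster1", c("LR", "LNo", "HNo")])))
})

test_that("flexibility counts classes above the Z threshold", {
  expect_equal(flexibility_score(c(0, 0, 0, 0)), 0L)
  expect_equal(flexibility_score(c(2.5, 2.1, -3.0, 0.1)), 3L)
  expect_equal(flexibility_score(c(2.5, NA, -3.0, 0.1), z_threshold = 0), 3L)
  m <- rbind(cluster1 = c(2, 0, 0, 0), cluster2 = c(2, -2, 2, 2))
  colnames(m) <- response_classes()
  expect_equal(unname(flexibility_score(m)), c(1L, 4L))
})

test_that("planted two-cluster structure is recovered by the default cut", {
  gains <- rbind(c(3, 1, 1, 1), c(1, 3, 1, 1))
  colnames(gains) <- response_classes()
  rec <- run_planted_recovery(gains, seed = 101, n_per_cluster = 10,
                              n_per_class = 15)
  expect_equal(adjusted_rand(rec$recovered, rec$planted), 1)
})
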