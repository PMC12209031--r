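test_that("choice preference index matches hand arithmetic", {
  expect_equal(choice_preference_index(make_outcomes(n_LR = 10)), 1)
  expect_equal(choice_preference_index(make_outcomes(n_LR = 5, n_HR = 5)), 0)
  expect_equal(choice_preference_index(make_outcomes(n_LR = 8, n_HR = 2)), 0.6)
  # omissions excluded from the denominator
  expect_equal(choice_preference_index(make_outcomes(n_LR = 4, n_HR = 2, n_om = 4)),
               2 / 6)
  # undefined when nothing was completed
  expect_true(is.na(choice_preference_index(make_outcomes(n_om = 10))))
  # rewarded and unrewarded presses count the same lever
  expect_equal(choice_preference_index(make_outcomes(n_LR = 3, n_LNo = 5, n_HR = 2)),
               (8 - 2) / 10)
})

test_that("CPI is antisymmetric under low/high label swap", {
  swap <- c(LR = "HR", LNo = "HNo", HR = "LR", HNo = "LNo",
            omission = "omission")
  for (seed in 1:20) {
    oc <- withr::with_seed(seed, sample(c("LR", "LNo", "HR", "HNo", "omission"),
                                        30, replace = TRUE))
    a <- choice_preference_index(oc)
    b <- choice_preference_index(unname(swap[oc]))
    if (is.na(a)) expect_true(is.na(b)) else expect_equal(a, -b)
  }
})

test_that("preference curve blocks the trial sequence, omissions included", {
  expect_equal(preference_curve(make_outcomes(n_LR = 90))$cpi, rep(1, 9))
  alt <- rep(c("LR", "HR"), 45)
  expect_equal(preference_curve(alt)$cpi, rep(0, 9))

  blocks <- c(make_outcomes(n_LR = 10), make_outcomes(n_LR = 5, n_HR = 5),
              make_outcomes(n_HR = 10))
  expect_equal(preference_curve(blocks)$cpi, c(1, 0, -1))

  # omission-heavy blocks: CPI of completed subset unchanged, membership by
  # trial position
  oc <- c(make_outcomes(n_LR = 4, n_HR = 2, n_om = 4), make_outcomes(n_om = 10))
  pc <- preference_curve(oc)
  expect_equal(pc$cpi[1], 2 / 6)
  expect_true(is.na(pc$cpi[2]))
  expect_equal(pc$n_completed, c(6, 0))

  # trailing partial block is kept and flagged
  pc2 <- preference_curve(make_outcomes(n_LR = 25))
  expect_equal(nrow(pc2), 3)
  expect_equal(pc2$partial, c(FALSE, FALSE, TRUE))
  expect_error(preference_curve(character(0)), "empty")
})

test_that("moving-mean smoothing shrinks at edges and propagates NA", {
  expect_equal(smooth_curve(rep(0.4, 7)), rep(0.4, 7))
  expect_equal(smooth_curve(c(0, 3, 0)), c(1.5, 1.0, 1.5))
  expect_equal(smooth_curve(5), 5)
  expect_error(smooth_curve(1:4, window = 2), "odd")
  # NA stays NA and is dropped from neighbouring means
  expect_equal(smooth_curve(c(1, NA, 3)), c(1, NA, 3))
  expect_equal(smooth_curve(c(1, 2, NA, 4)), c(1.5, 1.5, NA, 4))
})

test_that("omission rate is a percentage of all trials", {
  expect_equal(omission_rate(make_outcomes(n_LR = 10)), 0)
  expect_equal(omission_rate(make_outcomes(n_LR = 40, n_HR = 41, n_om = 9)), 10)
  expect_equal(omission_rate(make_outcomes(n_om = 5)), 100)
})

test_that("response map is a length-preserving recoding of outcomes", {
  oc <- make_outcomes(n_LR = 2, n_LNo = 1, n_HR = 3, n_HNo = 1, n_om = 2)
  rm_ <- response_map(oc)
  expect_length(rm_, length(oc))
  expect_equal(rm_[1], "low_rewarded")
  expect_equal(sum(rm_ == "omission"), 2)
  # round-trip: a degenerate simulated session maps to its planted outcomes
  cfg <- sim_config(contingency = task_contingency(high_risk_prob = 0),
                    agent = agent_params(p_low_choice = 0, p_omit = 0),
                    seed = 2)
  s <- simulate_session(cfg)
  expect_true(all(response_map(s$trials) == "high_unrewarded"))
  # counts reconcile with the omission rate
  expect_equal(100 * sum(rm_ == "omission") / length(rm_), omission_rate(oc))
})

test_that("latency summary covers completed trials only", {
  tr <- make_trials(make_outcomes(n_LR = 3, n_om = 2))
  tr$latency_s[1:3] <- c(1, 2, 3)
  ls <- latency_summary(tr)
  expect_equal(ls$mean, 2)
  expect_equal(ls$n, 3)
  expect_equal(latency_summary(make_trials(make_outcomes(n_LR = 4)))$sd, 0)
  all_om <- latency_summary(make_trials(make_outcomes(n_om = 3)))
  expect_true(is.na(all_om$mean))
  expect_equal(all_om$n, 0L)
})
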