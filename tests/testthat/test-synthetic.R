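test_that("degenerate probabilities force a single outcome", {
  cfg <- sim_config(contingency = task_contingency(low_risk_prob = 1),
                    agent = agent_params(p_low_choice = 1, p_omit = 0),
                    seed = 1)
  s <- simulate_session(cfg)
  expect_equal(nrow(s$trials), 90L)
  expect_true(all(s$trials$outcome == "LR"))

  cfg2 <- sim_config(agent = agent_params(p_omit = 1), seed = 1)
  s2 <- simulate_session(cfg2)
  expect_true(all(s2$trials$outcome == "omission"))
  expect_equal(nrow(s2$events), 0L)
})

test_that("lever choice frequency matches the agent's probability", {
  cfg <- sim_config(contingency = task_contingency(n_trials = 10000),
                    agent = agent_params(p_low_choice = 0.8, p_omit = 0),
                    seed = 11)
  s <- simulate_session(cfg)
  frac_low <- mean(s$trials$arm == "low_risk")
  se <- sqrt(0.8 * 0.2 / 10000)
  expect_lt(abs(frac_low - 0.8), 3 * se)
})

test_that("sessions are seed-deterministic and conserve trial counts", {
  cfg <- sim_config(agent = agent_params(p_low_choice = 0.7, p_omit = 0.1),
                    seed = 5)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1, s2)

  tab <- table(factor(s1$trials$outcome,
                      levels = c("LR", "LNo", "HR", "HNo", "omission")))
  expect_equal(sum(tab), 90)
  expect_equal(sum(tab[c("LR", "LNo", "HR", "HNo")]) + tab[["omission"]], 90)
  expect_equal(nrow(s1$events), sum(!s1$trials$omission))
})

test_that("event times are strictly increasing with inter-trial spacing", {
  cfg <- sim_config(agent = agent_params(p_omit = 0.2), seed = 9)
  s <- simulate_session(cfg)
  gaps <- diff(s$events$press_time_s)
  expect_true(all(gaps > 0))
  expect_true(all(gaps >= cfg$contingency$inter_trial))
  lat <- s$trials$latency_s[!s$trials$omission]
  expect_true(all(lat > 0 & lat <= cfg$contingency$trial_limit))
})

test_that("a seed is mandatory for every generator", {
  expect_error(sim_config(seed = NULL), "seed")
  expect_error(simulate_spikes(list(unit_spec("u", 1)),
                               balanced_events(1), 100, seed = NA),
               "seed")
  expect_error(simulate_ct_table(list(g = list(GAPDH = c(mean = 20, sd = 0))),
                                 n_samples = 1, seed = NULL),
               "seed")
})

test_that("silent units yield empty trains; spike counts follow Poisson law", {
  ev <- balanced_events(2)
  silent <- unit_spec("s", 0, c(LR = 0, LNo = 0, HR = 0, HNo = 0))
  tr <- simulate_spikes(list(silent), ev, 200, seed = 3)
  expect_length(tr[["s"]], 0)

  # 10 Hz homogeneous unit, 600 s: mean ~ 6000, variance ~ mean
  u <- unit_spec("u", 10)
  counts <- vapply(1:200, function(sd) {
    length(simulate_spikes(list(u), ev[0, ], 600, seed = sd)[["u"]])
  }, numeric(1))
  expect_lt(abs(mean(counts) - 6000), 3 * sqrt(6000 / 200))
  expect_lt(abs(var(counts) - 6000), 4 * 6000 * sqrt(2 / 199))
})

test_that("post-press gain raises the PETH rate by the planted factor", {
  ev <- balanced_events(25)
  u <- unit_spec("u", 10, c(HR = 3))
  tr <- simulate_spikes(list(u), ev, max(ev$press_time_s) + 15, seed = 21)
  p <- compute_peth(tr[["u"]], ev, "HR", unit_id = "u")
  pre <- mean(p$mean_rate[p$bin_centers < 0])
  post <- mean(p$mean_rate[p$bin_centers >= 0 & p$bin_centers < 5])
  expect_gt(post / pre, 2.5)
  expect_lt(post / pre, 3.5)
  expect_false(is.unsorted(tr[["u"]]))
  expect_true(all(tr[["u"]] >= 0 & tr[["u"]] <= max(ev$press_time_s) + 15))
})

test_that("overlapping windows with conflicting gains warn and later event wins", {
  ev <- data.frame(press_time_s = c(20, 22), outcome = c("HR", "LNo"))
  u <- unit_spec("u", 5, c(HR = 3, LNo = 0.2))
  expect_warning(simulate_spikes(list(u), ev, 60, seed = 2), "later event")
})

test_that("Ct tables honour SD = 0 and require the housekeeping gene", {
  groups <- list(ctl = list(GAPDH = c(mean = 20, sd = 0),
                            D1r = c(mean = 21, sd = 0)))
  ct <- simulate_ct_table(groups, n_samples = 2, seed = 4)
  expect_true(all(ct$ct[ct$gene == "D1r"] == 21))
  expect_equal(sum(ct$gene == "GAPDH"), 2 * 3)   # triplicates by default

  res <- relative_expression(ct, target = "D1r")
  expect_equal(res$per_sample$rel_expr, c(0.5, 0.5))

  expect_error(
    simulate_ct_table(list(ctl = list(D1r = c(mean = 21, sd = 0))),
                      n_samples = 1, seed = 1),
    "housekeeping")
})
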