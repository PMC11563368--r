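test_that("series equilibrium is zero for a slack or just-taut MTU", {
  belly <- muscle_belly()
  tendon <- tmm_tendon()
  # a = 0 and MTU at optimum CE length + slack length: zero-force equilibrium
  eps <- equilibrium_tendon_strain(0.10 + 0.20, 0, belly, tendon, 0.20, 0.10)
  expect_equal(eps, 0)
  # clearly slack MTU
  expect_equal(
    equilibrium_tendon_strain(0.25, 0, belly, tendon, 0.20, 0.10), 0)
})

test_that("equilibrium residual is below tolerance and strain rises with length", {
  belly <- muscle_belly()
  tendon <- tmm_tendon()
  set.seed(5)
  for (i in 1:50) {
    l_ce_opt <- runif(1, 0.05, 0.3)
    l_see_0 <- runif(1, 0.1, 0.4)
    a <- runif(1, 0.1, 1)
    l1 <- (l_ce_opt + l_see_0) * runif(1, 1.0, 1.05)
    l2 <- l1 * 1.02
    e1 <- equilibrium_tendon_strain(l1, a, belly, tendon, l_see_0, l_ce_opt)
    e2 <- equilibrium_tendon_strain(l2, a, belly, tendon, l_see_0, l_ce_opt)
    expect_gt(e2, e1)  # strain strictly increases with MTU length
    # residual check at the returned strain
    l_ce <- l1 - l_see_0 * (1 + e1 / 100)
    resid <- belly_force(belly, l_ce, l_ce_opt, a) - tendon_force(tendon, e1)
    if (e1 > 0) expect_lt(abs(resid), 1e-8)
  }
})

test_that("slack reduction increases equilibrium strain, grid-search oracle agrees", {
  belly <- muscle_belly()
  tendon <- tmm_tendon()
  l_ce_opt <- 0.10
  l_see_0 <- 0.361
  l_mtu <- l_ce_opt + l_see_0
  a <- 0.4
  e_full <- equilibrium_tendon_strain(l_mtu, a, belly, tendon, l_see_0, l_ce_opt)
  l_red <- apply_slack_reduction(l_see_0, 0.20)
  e_red <- equilibrium_tendon_strain(l_mtu, a, belly, tendon, l_red, l_ce_opt)
  expect_gt(e_red, e_full)

  # independent oracle: dense grid over strain, minimise |residual|
  grid <- seq(0, 20, by = 1e-3)
  resid <- vapply(grid, function(e) {
    l_ce <- l_mtu - l_red * (1 + e / 100)
    abs(belly_force(belly, l_ce, l_ce_opt, a) - tendon_force(tendon, e))
  }, numeric(1))
  expect_lt(abs(grid[which.min(resid)] - e_red), 2e-3)
})

test_that("initial strain is non-decreasing in the slack-reduction fraction", {
  pre <- vapply(seq(0, 0.25, by = 0.05), function(fr) {
    tr <- generate_trace(scenario_spec(slack_reduction = fr))
    tr$tendon_strain[1]
  }, numeric(1))
  expect_true(all(diff(pre) >= 0))
  # without slack reduction the only strain at t = 0 is activation-induced
  expect_lt(pre[1], 1)
})

test_that("traces are deterministic given spec and seed", {
  spec <- scenario_spec(noise_sd = 0.05, seed = 99)
  t1 <- generate_trace(spec)
  t2 <- generate_trace(spec)
  expect_identical(t1$tendon_strain, t2$tendon_strain)
  expect_identical(t1$mtu_force, t2$mtu_force)
  t3 <- generate_trace(scenario_spec(noise_sd = 0.05, seed = 100))
  expect_false(identical(t1$tendon_strain, t3$tendon_strain))
})

test_that("default gait scenario passes the audit; slack-reduced fails minor-only", {
  muscle <- default_audit_muscle()
  line <- reference_threshold_line()
  thr <- derive_minor_threshold(fit_linear_region(muscle$tendon), line)$x

  ok <- generate_trace(scenario_spec())
  rep_ok <- audit_model(ok, tsic_thresholds = thr)
  expect_true(rep_ok$passes)

  bad <- generate_trace(scenario_spec(slack_reduction = 0.20))
  expect_gt(bad$tendon_strain[1], 0)          # tendon pre-strain at t = 0
  expect_lt(bad$tendon_strain[1], thr)        # but below the threshold
  rep_bad <- audit_model(bad, tsic_thresholds = thr)
  expect_false(rep_bad$passes)
  expect_setequal(rep_bad$events$criterion, c("TSIC", "MSIC"))
  expect_true(all(rep_bad$events$grade == "minor"))
  expect_true(all(rep_bad$events$muscle == "gastrocnemius_like"))
  # the TSIC crossing happens during the cycle, not at the first sample
  tsic_t <- rep_bad$events$t_cross[rep_bad$events$criterion == "TSIC"]
  expect_gt(tsic_t, 0.83)

  # a healthy muscle simulated alongside stays uninjured
  both <- list(ok, bad)
  rep_both <- audit_model(both, tsic_thresholds = thr)
  expect_identical(unique(rep_both$events$muscle), "gastrocnemius_like")
})

test_that("pass-regime scenarios stay quiet across seeded parameter draws", {
  muscle <- default_audit_muscle()
  thr <- derive_minor_threshold(fit_linear_region(muscle$tendon),
                                reference_threshold_line())$x
  set.seed(21)
  for (i in 1:20) {
    spec <- scenario_spec(
      amplitude = runif(1, 0.002, 0.008),
      activation_base = runif(1, 0, 0.1),
      activation_peak = runif(1, 0.2, 0.6),
      phase = runif(1, 0, 2 * pi),
      sample_rate = sample(c(100, 200, 400), 1)
    )
    tr <- generate_trace(spec, muscle)
    rep_i <- audit_model(tr, tsic_thresholds = thr)
    expect_true(rep_i$passes)
  }
})

test_that("the overstretch ramp drives the muscle into injury", {
  muscle <- default_audit_muscle()
  thr <- derive_minor_threshold(fit_linear_region(muscle$tendon),
                                reference_threshold_line())$x
  spec <- scenario_spec(kind = "overstretch_ramp", t_start = 0,
                        duration = 1.2, amplitude = 0.10,
                        activation_base = 0.1)
  tr <- generate_trace(spec, muscle)
  expect_true(all(diff(tr$tendon_strain) >= 0))  # monotone loading
  rep_ramp <- audit_model(tr, tsic_thresholds = thr)
  expect_false(rep_ramp$passes)
  expect_true("TSIC" %in% rep_ramp$events$criterion)
})
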