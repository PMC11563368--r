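test_that("first-crossing detection interpolates between samples", {
  expect_true(is.na(detect_first_crossing(0:5, rep(0.5, 6), 1)))
  expect_equal(detect_first_crossing(c(0, 1), c(0, 2), 1), 0.5)
  # a sample exactly at the threshold counts as crossed
  expect_equal(detect_first_crossing(c(0, 1, 2), c(0, 1, 2), 1), 1)
  # crossing already at the first sample
  expect_equal(detect_first_crossing(c(3, 4), c(9, 9), 1), 3)
  expect_error(detect_first_crossing(0:2, 0:3, 1), "equal length")

  # gait-window strain ramp: inverse linear interpolation
  tr <- ramp_trace()
  t_cross <- detect_first_crossing(tr$time, tr$tendon_strain, 5.16)
  expect_equal(t_cross, 0.83 + (5.16 - 3.84) / (5.45 - 3.84) * 0.25,
               tolerance = 1e-9)
  expect_equal(t_cross, 1.035, tolerance = 1e-3)
})

test_that("first-crossing detection matches a brute-force scan", {
  set.seed(7)
  for (i in 1:1000) {
    n <- sample(3:12, 1)
    time <- cumsum(runif(n, 0.1, 1))
    values <- runif(n, -1, 1)
    thr <- runif(1, -1, 1)
    got <- detect_first_crossing(time, values, thr)
    want <- oracle_first_crossing(time, values, thr)
    if (is.na(want)) expect_true(is.na(got)) else expect_equal(got, want)
  }
})

test_that("TSIC grading reports at most one minor event with peak strain", {
  zero <- mtu_trace(time = c(0, 1), tendon_strain = c(0, 0))
  expect_equal(nrow(assess_tsic(zero, 4.77)), 0L)

  tr <- ramp_trace()  # pre-strained gastrocnemius-like ramp, peak 5.45%
  ev <- assess_tsic(tr, 5.16)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$grade, "minor")
  expect_equal(ev$criterion, "TSIC")
  expect_equal(ev$peak_value, 5.45)
  expect_equal(ev$t_cross, 1.035, tolerance = 1e-3)

  # under the more compliant tendon's threshold the same trace is uninjured
  expect_equal(nrow(assess_tsic(tr, 8.67)), 0L)

  expect_error(assess_tsic(tr, -1), "positive")
})

test_that("MSIC grading scales with f_max and activity", {
  # zero force: no events
  expect_equal(nrow(assess_msic(force_trace(c(0, 0, 0)))), 0L)

  # constant force of 3.5 f_max ruptures at the trace start
  ev <- assess_msic(force_trace(rep(3500, 3), f_max = 1000))
  expect_true("rupture" %in% ev$grade)
  expect_equal(ev$t_cross[ev$grade == "rupture"], 0)
  expect_true(all(ev$beyond_validated[ev$grade != "minor"]))

  # ramp to 2 f_max with minor = f_max (c0 = 1, c1 = 0), a = 0:
  # minor crossing where force reaches f_max, no rupture
  tr <- force_trace(seq(0, 2000, length.out = 5), f_max = 1000)
  ev <- assess_msic(tr, msic_thresholds(minor = c(1, 0), major = c(2.5, 0)))
  expect_identical(ev$grade, "minor")
  expect_equal(ev$t_cross, 0.5)
  expect_equal(ev$peak_value, 2000)
})

test_that("MSIC threshold misconfiguration and missing activity are handled", {
  tr <- force_trace(c(0, 10), f_max = 1000)
  bad <- msic_thresholds(minor = c(2.5, 0), major = c(1, 0))
  expect_error(assess_msic(tr, bad), "ordering")
  # rupture ordering violated for high activity
  bad2 <- msic_thresholds(minor = c(1, 0), major = c(2, 2))
  expect_error(assess_msic(tr, bad2), "ordering")

  no_act <- mtu_trace(time = c(0, 1), mtu_force = c(0, 10),
                      muscle = muscle_param_set("m", f_max = 1000,
                                                l_ce_opt = 0.1, l_see_0 = 0.2))
  expect_warning(assess_msic(no_act), "full activity")
})

test_that("MSIC events are equivariant under joint force/f_max rescaling", {
  tr1 <- force_trace(seq(0, 2500, length.out = 9), f_max = 1000,
                     activity = seq(0, 1, length.out = 9))
  tr2 <- force_trace(7 * seq(0, 2500, length.out = 9), f_max = 7000,
                     activity = seq(0, 1, length.out = 9))
  thr <- msic_thresholds(minor = c(0.6, 0.4), major = c(1.5, 0.5))
  ev1 <- assess_msic(tr1, thr)
  ev2 <- assess_msic(tr2, thr)
  expect_identical(ev1$grade, ev2$grade)
  expect_equal(ev1$t_cross, ev2$t_cross)
  expect_equal(7 * ev1$peak_value, ev2$peak_value)
})

test_that("raising the TSIC threshold never adds events or hastens them", {
  set.seed(11)
  tt <- seq(0, 1, length.out = 40)
  strain <- 3 + 2.5 * sin(2 * pi * tt) + cumsum(rnorm(40, 0, 0.05))
  tr <- mtu_trace(time = tt, tendon_strain = pmax(strain, 0))
  thresholds <- seq(0.5, 8, by = 0.25)
  prev_n <- Inf
  prev_t <- -Inf
  for (thr in thresholds) {
    ev <- assess_tsic(tr, thr)
    expect_lte(nrow(ev), prev_n)
    if (nrow(ev) == 1L) {
      expect_gte(ev$t_cross, prev_t)
      prev_t <- ev$t_cross
    }
    prev_n <- nrow(ev)
  }
})

test_that("audit passes iff no trace crosses any threshold", {
  quiet <- mtu_trace(time = c(0, 1), tendon_strain = c(0, 0),
                     mtu_force = c(0, 0), activity = c(0, 0),
                     muscle = muscle_param_set("quiet", f_max = 100,
                                               l_ce_opt = 0.1, l_see_0 = 0.2))
  rep0 <- audit_model(quiet, tsic_thresholds = 4.77)
  expect_true(rep0$passes)
  expect_equal(nrow(rep0$events), 0L)

  # events are ordered by (muscle, time) across traces
  m_a <- muscle_param_set("a_muscle", f_max = 100, l_ce_opt = 0.1, l_see_0 = 0.2)
  m_b <- muscle_param_set("b_muscle", f_max = 100, l_ce_opt = 0.1, l_see_0 = 0.2)
  tr_b <- mtu_trace(time = c(0, 1), tendon_strain = c(0, 10),
                    mtu_force = c(350, 350), activity = c(1, 1), muscle = m_b)
  tr_a <- mtu_trace(time = c(0, 1), tendon_strain = c(6, 6),
                    mtu_force = c(0, 0), activity = c(1, 1), muscle = m_a)
  rep1 <- audit_model(list(tr_b, tr_a), tsic_thresholds = 4.77)
  expect_false(rep1$passes)
  expect_identical(rep1$events$muscle, sort(rep1$events$muscle))
  ord <- order(rep1$events$muscle, rep1$events$t_cross)
  expect_identical(ord, seq_len(nrow(rep1$events)))

  # named per-muscle thresholds
  rep2 <- audit_model(list(tr_a), tsic_thresholds = c(a_muscle = 7))
  expect_true(rep2$passes)
})
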