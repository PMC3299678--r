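test_that("triangular action potential gives ramp-geometry APDs", {
  fx <- generate_fixtures("triangle_ap")  # 1-ms upstroke, 300-ms ramp
  # hand computation: level crossing at t = 1 + 0.9*300; upstroke clock
  # reference is the midpoint of the steepest 0.5-ms interval, t = 0.25
  expect_equal(apd(fx$time, fx$v, 0.9), 270.75, tolerance = 1e-8)
  expect_equal(apd(fx$time, fx$v, 0.5), 150.75, tolerance = 1e-8)
  # level 0 degenerates to (almost) the peak time
  expect_lt(apd(fx$time, fx$v, 0), 1.5)
})

test_that("two-segment plateau AP matches hand-computed crossings", {
  fx <- generate_fixtures("plateau_ap")   # 40 -> 0 over 200 ms, 0 -> -80 over 100
  # APD90 level -68 mV crossed at t = 286; APD50 level -20 mV at t = 226;
  # upstroke reference at t = 0.25 (midpoint of the steepest interval)
  expect_equal(apd(fx$time, fx$v, 0.9), 285.75, tolerance = 1e-8)
  expect_equal(apd(fx$time, fx$v, 0.5), 225.75, tolerance = 1e-8)
})

test_that("apd is monotone in the repolarization level", {
  tr <- control_beat()
  levels <- c(0.3, 0.5, 0.7, 0.9)
  a <- vapply(levels, function(l) apd(tr$time, tr$Vm, l), numeric(1))
  expect_true(all(diff(a) > 0))
})

test_that("apd flags missing repolarization and missing upstroke", {
  fx <- generate_fixtures("plateau_ap")
  short <- fx[fx$time <= 150, ]           # still on the plateau
  expect_error(apd(short$time, short$v, 0.9), "repolarization")
  flat <- data.frame(time = 0:100, v = rep(-80, 101))
  expect_error(apd(flat$time, flat$v), "no elicited")
})

test_that("exponential Ca transient has decay time log(10)/k", {
  k <- 0.01
  fx <- generate_fixtures("exp_ca", rate = k)
  m <- ca_transient_metrics(fx$time, fx$ca)
  expect_equal(m$tau_ca, log(10) / k, tolerance = 1e-3)
  expect_equal(m$diastolic, 1e-4)
  expect_equal(m$systolic, 5e-4)
})

test_that("flat or monotone-rising Ca traces are rejected", {
  t <- seq(0, 500, by = 1)
  expect_error(ca_transient_metrics(t, rep(1e-4, length(t))), "flat")
  expect_error(ca_transient_metrics(t, 1e-4 + 1e-7 * t), "decay")
})

test_that("NCX reversal time is the interpolated zero crossing", {
  fx <- generate_fixtures("ncx", t_cross = 120)
  expect_equal(t_ncxrp(fx$time, fx$incx), 120, tolerance = 1e-8)
  expect_error(t_ncxrp(fx$time, -abs(fx$incx)), "no outward")
})

test_that("EAD detector finds the constructed bump and ignores ripple", {
  fx <- generate_fixtures("ead_ap", bump_mv = 10, bump_t = 400)
  ev <- detect_eads(fx$time, fx$v)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$t_max, 400, tolerance = 5)
  expect_gt(ev$amplitude, 1)
  # monotone repolarization: no events
  base <- generate_fixtures("plateau_ap")
  expect_identical(nrow(detect_eads(base$time, base$v)), 0L)
  # sub-threshold ripple: no events
  ripple <- generate_fixtures("ead_ap", bump_mv = 0.5, bump_t = 400)
  expect_identical(nrow(detect_eads(ripple$time, ripple$v)), 0L)
})

test_that("biomarkers are invariant to time shift and resampling", {
  y <- initial_state("control_1hz")
  p <- default_parameters()
  t1 <- pace_one_beat(y, p, cl = 1000, dt_out = 0.1)
  t2 <- pace_one_beat(y, p, cl = 1000, dt_out = 0.2)
  a1 <- apd(t1$time, t1$Vm); a2 <- apd(t2$time, t2$Vm)
  expect_lt(abs(a1 - a2), 0.1)
  m1 <- ca_transient_metrics(t1$time, t1$Cai)
  m2 <- ca_transient_metrics(t2$time, t2$Cai)
  expect_lt(abs(m1$tau_ca - m2$tau_ca) / m1$tau_ca, 1e-3)
  # uniform time shift
  expect_equal(apd(t1$time + 500, t1$Vm), a1, tolerance = 1e-9)
})

test_that("biomarker_set summarises a steady-state beat coherently", {
  bm <- biomarker_set(control_beat())
  expect_gte(bm$APD90, bm$APD50)
  expect_gte(bm$triangulation, 0)
  expect_gt(bm$ca_systolic, bm$ca_diastolic)
  expect_gt(bm$tau_ca, 0)
  expect_gte(bm$casr_systolic, bm$casr_diastolic)
  expect_identical(bm$ead_count, 0L)
})
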