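test_that("hL steady-state sigmoid has midpoint, saturation and closed form", {
  p <- default_parameters()
  expect_equal(hL_inf(p[["hL_vhalf"]], p), 0.5)
  expect_equal(hL_inf(-1e4, p), 1)
  expect_equal(hL_inf(1e4, p), 0)
  v <- c(-100, -80, -60)
  expect_equal(hL_inf(v, p), 1 / (1 + exp((v + 91) / 6.1)))
  # monotone decreasing
  vv <- seq(-120, 20, by = 1)
  expect_true(all(diff(hL_inf(vv, p)) < 0))
})

test_that("hL gate relaxes exponentially toward its steady state", {
  p <- default_parameters()
  v <- -30
  expect_equal(step_hL(hL_inf(v, p), v, p), 0)
  # after one time constant the gap to equilibrium shrinks by a factor e
  h0 <- 0.9
  gap0 <- h0 - hL_inf(v, p)
  gap1 <- hL_relax(p[["tau_hL"]], h0, v, p) - hL_inf(v, p)
  expect_equal(gap1, gap0 / exp(1))
})

test_that("numerical hL integration matches the closed form to 1e-6", {
  p <- default_parameters()
  v <- -40
  out <- deSolve::lsoda(
    y = c(h = 1), times = seq(0, 500, by = 1),
    func = function(t, y, parms) list(step_hL(y, v, p)),
    rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(out[, "h"] - hL_relax(out[, "time"], 1, v, p))), 1e-6)
})

test_that("INaL vanishes at the reversal potential and with zero conductance", {
  p <- default_parameters()
  expect_identical(compute_INaL(65, 0.9, 0.5, 65, p), 0)
  p0 <- default_parameters(GNaL = 0)
  expect_identical(compute_INaL(-20, 0.9, 0.5, 65, p0), 0)
  # sign follows driving force
  expect_lt(compute_INaL(-20, 0.9, 0.5, 65, p), 0)
  expect_gt(compute_INaL(80, 0.9, 0.5, 65, p), 0)
})

test_that("late current decays single-exponentially under clamp", {
  vc <- run_voltage_clamp(default_parameters(), hold_ms = 5000,
                          step_ms = 1200)
  tr <- vc$trace
  w <- tr$time >= 100 & tr$time <= 800
  li <- log(-tr$INaL[w])
  fit <- lm(li ~ tr$time[w])
  expect_gt(summary(fit)$r.squared, 0.999)
  # decay constant equals tau_hL (V far below hL activation: pure decay)
  expect_equal(-1 / coef(fit)[[2]], 233, tolerance = 0.02)
})

test_that("clamp ratio scales linearly with the late conductance", {
  r1 <- run_voltage_clamp(default_parameters(), step_ms = 100)
  r2 <- run_voltage_clamp(default_parameters(GNaL = 0.03), step_ms = 100)
  expect_equal(r2$ratio / r1$ratio, 2, tolerance = 0.01)
})
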