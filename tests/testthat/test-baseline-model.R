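test_that("quiescent rest state is a fixed point of the dynamics", {
  y <- initial_state("rest")
  d <- compute_derivatives(y, default_parameters(), stim = 0)
  expect_lt(abs(d$ydot[["Vm"]]), 1e-3)
  # slow Na+ balance is the last to settle; everything else essentially still
  expect_lt(max(abs(d$ydot[setdiff(names(d$ydot), "Vm")])), 1e-3)
})

test_that("unstimulated model stays at rest over 10 simulated seconds", {
  y <- initial_state("rest")
  tr <- integrate_model(y, default_parameters(), duration = 10000,
                        dt_out = 1000)
  expect_lt(max(abs(tr$Vm - y[["Vm"]])), 0.01)
})

test_that("zero late-Na+ conductance yields zero INaL everywhere", {
  p0 <- default_parameters(GNaL = 0)
  tr <- pace_one_beat(initial_state(), p0, cl = 400, dt_out = 1)
  expect_true(all(tr$INaL == 0))
  d <- compute_derivatives(initial_state(), p0)
  expect_identical(d$currents[["INaL"]], 0)
})

test_that("recorded current decomposition is self-consistent", {
  tr <- control_beat()
  res <- check_current_consistency(tr[tr$time > 5, ], default_parameters(),
                                   stim = 0)
  expect_lt(res[["sum_residual"]], 1e-6)
  expect_lt(res[["dvdt_residual"]], 1e-6)
})

test_that("gates stay bounded and concentrations positive when paced", {
  tr <- control_beat()
  gates <- c("m", "h", "j", "xkr", "xks", "xtos", "ytos", "xtof", "ytof",
             "d", "f", "fcaBj", "fcaBsl", "RyRr", "RyRo", "RyRi", "hL")
  for (g in gates) {
    expect_true(all(tr[[g]] >= -1e-9 & tr[[g]] <= 1 + 1e-6), info = g)
  }
  concs <- c("CaSR", "Naj", "Nasl", "Nai", "Ki", "Caj", "Casl", "Cai")
  for (cc in concs) expect_true(all(tr[[cc]] > 0), info = cc)
  # RyR states partition with the hidden fourth state
  expect_true(all(tr$RyRr + tr$RyRo + tr$RyRi <= 1 + 1e-9))
})

test_that("zero-duration integration returns empty trace and initial state", {
  y <- initial_state()
  tr <- integrate_model(y, default_parameters(), duration = 0)
  expect_identical(nrow(tr), 0L)
  expect_identical(final_state(tr), y)
})

test_that("one beat is invariant to tightening solver tolerances", {
  y <- initial_state("control_1hz")
  p <- default_parameters()
  a1 <- apd(control_beat()$time, control_beat()$Vm, 0.9)
  tr2 <- pace_one_beat(y, p, cl = 1000,
                       solver = list(rtol = 1e-9, atol = 1e-11))
  a2 <- apd(tr2$time, tr2$Vm, 0.9)
  expect_lt(abs(a1 - a2), 0.1)
})

test_that("repeated runs from the same state are bit-identical", {
  y <- initial_state()
  p <- default_parameters()
  t1 <- pace_one_beat(y, p, cl = 300, dt_out = 1)
  t2 <- pace_one_beat(y, p, cl = 300, dt_out = 1)
  expect_identical(t1$Vm, t2$Vm)
  expect_identical(final_state(t1), final_state(t2))
})

test_that("invalid states and parameters are rejected", {
  y <- initial_state()
  y[["Vm"]] <- NaN
  expect_error(compute_derivatives(y, default_parameters()), "non-finite")
  expect_error(default_parameters(GNaL = -1), "negative")
  expect_error(default_parameters(nonsense = 2), "unknown parameter")
  expect_error(default_parameters(tau_hL = 0), "tau_hL")
  y2 <- initial_state()[-5]
  expect_error(compute_derivatives(y2, default_parameters()), "full named state")
})

test_that("state snapshots round-trip bit-identically through CSV", {
  y <- initial_state("control_1hz")
  f <- tempfile(fileext = ".csv")
  write_state(y, f)
  expect_identical(read_state(f), y)
})
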