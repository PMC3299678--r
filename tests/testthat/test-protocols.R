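test_that("voltage clamp reports a zero ratio without late conductance", {
  vc <- run_voltage_clamp(default_parameters(GNaL = 0), hold_ms = 1000,
                          step_ms = 100)
  expect_equal(vc$ratio, 0, tolerance = 1e-10)
  expect_lt(vc$i_nat_peak, -100)          # transient current still present
})

test_that("clamp steps shorter than 40 ms are rejected", {
  expect_error(run_voltage_clamp(default_parameters(), step_ms = 30),
               "40 ms")
})

test_that("clamped potential follows the command waveform", {
  vc <- run_voltage_clamp(default_parameters(), hold_ms = 500, step_ms = 60)
  expect_true(all(vc$trace$Vm == -20))
})

test_that("steady-state pacing is a fixed point of its criterion", {
  crit <- steady_state_criterion()
  r1 <- run_to_steady_state(default_parameters(), 1, criterion = crit)
  # re-running from the converged state confirms within the minimum
  # number of beats the window criterion can certify
  r2 <- run_to_steady_state(default_parameters(), 1, state = r1$state,
                            criterion = crit)
  expect_identical(r2$criterion_fired, "steady")
  expect_identical(r2$beats, crit$window + 1L)
  expect_lt(abs(r2$biomarkers$APD90 - r1$biomarkers$APD90), 0.1)
})

test_that("halving the steady-state thresholds barely moves APD90", {
  r1 <- run_to_steady_state(default_parameters(), 1)
  tight <- steady_state_criterion(dapd_ms = 0.025, dnai_mm = 5e-5)
  r2 <- run_to_steady_state(default_parameters(), 1, criterion = tight)
  expect_lt(abs(r1$biomarkers$APD90 - r2$biomarkers$APD90), 0.2)
})

test_that("non-capture is reported with the diastolic potential", {
  weak <- default_stimulus()
  weak$amplitude <- 0.5
  expect_error(
    run_to_steady_state(default_parameters(), 1, stim = weak),
    "no action potential")
})

test_that("sodium clamp holds every Na+ compartment fixed", {
  r <- run_na_clamp(default_parameters(), 1, clamp_mm = 8,
                    criterion = quick_criterion(10))
  tr <- r$trace
  expect_true(all(tr$Nai == 8))
  expect_true(all(tr$Naj == 8))
  expect_true(all(tr$Nasl == 8))
  expect_error(run_na_clamp(default_parameters(), 1, clamp_mm = -1),
               "positive")
})

test_that("na-clamp at the run's own steady state reproduces biomarkers", {
  free <- run_to_steady_state(default_parameters(), 1)
  clamped <- run_na_clamp(default_parameters(), 1,
                          clamp_mm = free$state[["Nai"]],
                          state = free$state,
                          criterion = quick_criterion(20))
  expect_equal(clamped$biomarkers$APD90, free$biomarkers$APD90,
               tolerance = 0.01)
  expect_equal(clamped$biomarkers$ca_systolic, free$biomarkers$ca_systolic,
               tolerance = 0.01)
})

test_that("rate dependence requires two frequencies and is zero when equal", {
  expect_error(run_rate_dependence(default_parameters(), frequencies = 1),
               "two frequencies")
  r <- run_rate_dependence(default_parameters(), frequencies = c(1, 1),
                           criterion = quick_criterion(10))
  expect_equal(r$delta_apd, 0, tolerance = 0.1)
})

test_that("staircase state carry-over changes the end-stage sodium", {
  p <- default_parameters()
  carry <- run_staircase(p, frequencies = c(1, 2), stage_s = 20,
                         carry_state = TRUE)
  restart <- run_staircase(p, frequencies = c(1, 2), stage_s = 20,
                           carry_state = FALSE)
  expect_false(isTRUE(all.equal(carry$summary$nai[2],
                                restart$summary$nai[2])))
})

test_that("protocol runs are deterministic end to end", {
  p <- default_parameters()
  a <- run_staircase(p, frequencies = c(1, 2), stage_s = 5)
  b <- run_staircase(p, frequencies = c(1, 2), stage_s = 5)
  expect_identical(a$summary, b$summary)
})

test_that("windowed flux blocks act only inside the beat window", {
  p <- hf_parameters()
  r <- run_ead_protocol(p, beats = 8, block = "irel",
                        block_mode = "window", block_window = 3:7)
  expect_identical(nrow(r$beat_table), 8L)
  expect_true(all(r$beat_table$repolarized))
})
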