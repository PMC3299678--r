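#!/usr/bin/env Rscript

# Regenerates the steady-state snapshots shipped in inst/extdata/ from
# scratch: quiescent rest (500 s unstimulated), then deep 1-Hz steady
# states of the control and basic failing models.  Run from the package
# root with the package installed.

suppressPackageStartupMessages(library(hfcell))

seed_state <- initial_state("rest")   # shipped snapshot or built-in seed
rest <- final_state(integrate_model(seed_state, default_parameters(),
                                    duration = 5e5, dt_out = 5e5,
                                    record = FALSE, solver = list(hmax = 10)))
write_state(rest, "inst/extdata/state_rest.csv")

deep <- steady_state_criterion(dapd_ms = 0.005, window = 10,
                               dnai_mm = 1e-5, max_beats = 3000)
ctl <- run_to_steady_state(default_parameters(), 1, state = rest,
                           criterion = deep)
write_state(ctl$state, "inst/extdata/state_control_1hz.csv")
message(sprintf("control: %d beats, APD90 %.2f ms", ctl$beats,
                ctl$biomarkers$APD90))

hf <- run_to_steady_state(hf_parameters(), 1, state = ctl$state,
                          criterion = deep)
write_state(hf$state, "inst/extdata/state_hf_1hz.csv")
message(sprintf("failing: %d beats, APD90 %.2f ms", hf$beats,
                hf$biomarkers$APD90))
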