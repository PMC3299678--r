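# Shared cheap runs reused across test files (memoised once per session).

fast_solver <- list(rtol = 1e-7, atol = 1e-9)

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# one steady-state control beat at fine resolution (from shipped snapshot)
control_beat <- function() {
  cached("control_beat", {
    pace_one_beat(initial_state("control_1hz"), default_parameters(),
                  cl = 1000)
  })
}

# quick steady-state criterion for ordinal checks
quick_criterion <- function(max_beats = 60) {
  steady_state_criterion(dapd_ms = 0.05, window = 5, dnai_mm = 1e-4,
                         max_beats = max_beats)
}
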