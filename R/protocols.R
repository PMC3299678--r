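#' Voltage-clamp protocol for the late Na+ current
#'
#' Holds the membrane at `hold_mv` (default -120 mV) long enough for full
#' availability of the late Na+ gate (default 5 s, > 20 time constants),
#' then steps to `step_mv` (default -20 mV) while integrating all gating
#' and concentration equations under the clamp.  The late-to-peak ratio is
#' the late Na+ current measured 40 ms after the step divided by the peak
#' transient Na+ current, expressed in percent.
#'
#' @param params parameter vector.
#' @param state starting state; default the paced control snapshot.
#' @param hold_mv,step_mv command potentials (mV).
#' @param hold_ms,step_ms phase durations (ms); `step_ms` must be at least
#'   40 ms for the ratio to be defined.
#' @param dt_out output interval during the step (ms); the first 60 ms are
#'   sampled at 0.01 ms to resolve the transient peak.
#' @return list with `trace` (step phase), `ratio` (percent), `i_nal_40`
#'   and `i_nat_peak` (A/F).
#' @export
run_voltage_clamp <- function(params = default_parameters(),
                              state = initial_state(),
                              hold_mv = -120, step_mv = -20,
                              hold_ms = 5000, step_ms = 2500,
                              dt_out = 0.5) {
  if (step_ms < 40) stop("clamp step shorter than 40 ms: ratio undefined")
  pc <- params
  pc["vclamp"] <- 1
  y <- state
  y["Vm"] <- hold_mv
  hold <- integrate_model(y, pc, duration = hold_ms, dt_out = hold_ms,
                          record = FALSE)
  y1 <- final_state(hold)
  y1["Vm"] <- step_mv
  fine <- integrate_model(y1, pc, duration = 60, dt_out = 0.01)
  coarse <- integrate_model(final_state(fine), pc, duration = step_ms - 60,
                            t0 = 60, dt_out = dt_out)
  tr <- rbind(fine[fine$time < 60, , drop = FALSE], coarse)
  class(tr) <- c("hfcell_trace", "data.frame")
  attr(tr, "final_state") <- final_state(coarse)
  i_nat_peak <- min(tr$INa)
  i40 <- approx(tr$time, tr$INaL, xout = 40)$y
  ratio <- if (i_nat_peak == 0) 0 else 100 * i40 / i_nat_peak
  list(trace = tr, ratio = ratio, i_nal_40 = i40, i_nat_peak = i_nat_peak)
}

#' Default steady-state pacing criterion
#'
#' Pacing stops when the absolute beat-to-beat APD90 change stays below
#' `dapd_ms` over `window` consecutive beats and the beat-to-beat change
#' of bulk cytosolic Na+ stays below `dnai_mm`, or at `max_beats`.
#'
#' @param dapd_ms APD90 tolerance (ms).
#' @param window consecutive beats required.
#' @param dnai_mm Na+ tolerance (mM per beat).
#' @param max_beats hard beat limit.
#' @return criterion list.
#' @export
steady_state_criterion <- function(dapd_ms = 0.05, window = 5,
                                   dnai_mm = 1e-4, max_beats = 1000) {
  list(dapd_ms = dapd_ms, window = window, dnai_mm = dnai_mm,
       max_beats = max_beats)
}

#' Pace to steady state
#'
#' Paces the model with the standard rectangular stimulus at a fixed
#' frequency until the steady-state criterion fires, then records one
#' final beat at fine resolution (0.1 ms) for biomarker extraction.
#'
#' @param params parameter vector.
#' @param frequency pacing frequency (Hz), in (0.1, 5).
#' @param state starting state.
#' @param criterion see [steady_state_criterion()].
#' @param stim stimulus definition, see [default_stimulus()].
#' @param solver solver settings.
#' @return list with `trace` (final fine beat), `state` (final),
#'   `beats` (number paced before the recorded beat), `apd_series`,
#'   `nai_series`, `biomarkers` (from the final beat) and
#'   `criterion_fired` (`"steady"` or `"beat_limit"`).
#' @export
run_to_steady_state <- function(params = default_parameters(),
                                frequency = 1,
                                state = initial_state(),
                                criterion = steady_state_criterion(),
                                stim = default_stimulus(),
                                solver = list()) {
  stopifnot(frequency > 0.1, frequency < 5)
  cl <- 1000 / frequency
  y <- state
  apds <- numeric(0)
  nais <- numeric(0)
  streak <- 0
  beats <- 0
  fired <- "beat_limit"
  repeat {
    tr <- pace_one_beat(y, params, cl = cl, stim_amp = stim$amplitude,
                        stim_dur = stim$duration, dt_out = 1,
                        solver = solver)
    yn <- final_state(tr)
    beats <- beats + 1
    a <- tryCatch(apd(tr$time, tr$Vm, 0.9), error = function(e) NA_real_)
    if (beats == 1 && is.na(a) && max(tr$Vm) <= 0) {
      stop(sprintf("no action potential elicited (diastolic V = %.1f mV)",
                   tr$Vm[1]))
    }
    dnai <- abs(yn[["Nai"]] - y[["Nai"]])
    prev <- if (length(apds)) apds[length(apds)] else NA_real_
    ok <- !is.na(a) && !is.na(prev) && abs(a - prev) < criterion$dapd_ms &&
      dnai < criterion$dnai_mm
    streak <- if (ok) streak + 1 else 0
    apds <- c(apds, a)
    nais <- c(nais, yn[["Nai"]])
    y <- yn
    if (streak >= criterion$window) { fired <- "steady"; break }
    if (beats >= criterion$max_beats) break
  }
  fine <- pace_one_beat(y, params, cl = cl, stim_amp = stim$amplitude,
                        stim_dur = stim$duration, dt_out = 0.1,
                        solver = solver)
  list(trace = fine, state = final_state(fine), beats = beats,
       apd_series = apds, nai_series = nais,
       biomarkers = biomarker_set(fine), criterion_fired = fired)
}

#' Frequency staircase protocol
#'
#' Consecutive pacing stages at increasing frequency with state carried
#' over between stages (as in the source protocol), reporting for each
#' stage the last-beat diastolic and systolic cytosolic Ca2+ and the
#' end-stage bulk Na+.
#'
#' @param params parameter vector.
#' @param frequencies staircase frequencies (Hz).
#' @param stage_s stage duration in simulated seconds (600 s = 10 min is
#'   the protocol value; shorter stages are for quick ordinal checks).
#' @param state starting state.
#' @param stim,solver as in [run_to_steady_state()].
#' @param carry_state carry the state across stages (`TRUE`, the
#'   protocol); `FALSE` restarts every stage from `state`.
#' @return list with `summary` (data.frame: frequency, ca_systolic,
#'   ca_diastolic, nai), `traces` (final beat per stage) and `state`.
#' @export
run_staircase <- function(params = default_parameters(),
                          frequencies = c(0.5, 1, 1.5, 2, 2.5),
                          stage_s = 600,
                          state = initial_state(),
                          stim = default_stimulus(), solver = list(),
                          carry_state = TRUE) {
  stopifnot(all(frequencies > 0), stage_s > 0)
  y <- state
  rows <- list()
  traces <- list()
  for (f in frequencies) {
    if (!carry_state) y <- state
    cl <- 1000 / f
    nbeats <- max(1, round(stage_s * f) - 1)
    for (k in seq_len(nbeats)) {
      tr <- pace_one_beat(y, params, cl = cl, stim_amp = stim$amplitude,
                          stim_dur = stim$duration, dt_out = cl,
                          solver = solver, record = FALSE)
      y <- final_state(tr)
    }
    fine <- pace_one_beat(y, params, cl = cl, stim_amp = stim$amplitude,
                          stim_dur = stim$duration, dt_out = 0.2,
                          solver = solver)
    y <- final_state(fine)
    rows[[as.character(f)]] <- data.frame(
      frequency = f,
      ca_systolic = max(fine$Cai),
      ca_diastolic = fine$Cai[1],
      nai = y[["Nai"]])
    traces[[as.character(f)]] <- fine
  }
  list(summary = do.call(rbind, c(rows, make.row.names = FALSE)),
       traces = traces, state = y)
}

#' Steady-state APD rate dependence
#'
#' Paces to steady state at each frequency (each run starting from
#' `state`) and reports APD90 per frequency plus the rate-dependence
#' index: the APD90 at the slowest rate minus the APD90 at the highest
#' tested frequency.
#'
#' @param params parameter vector.
#' @param frequencies at least two pacing frequencies (Hz); protocol
#'   default 0.5, 1, 1.25 and 1.6 Hz.
#' @param state,criterion,stim,solver as in [run_to_steady_state()].
#' @return list with `apd90` (named by frequency), `delta_apd` (ms),
#'   `runs` (per-frequency steady-state results, each holding the final
#'   beat trace with the late Na+, NCX and pump currents and Na+ levels).
#' @export
run_rate_dependence <- function(params = default_parameters(),
                                frequencies = c(0.5, 1, 1.25, 1.6),
                                state = initial_state(),
                                criterion = steady_state_criterion(),
                                stim = default_stimulus(),
                                solver = list()) {
  if (length(frequencies) < 2) stop("need at least two frequencies")
  runs <- lapply(frequencies, function(f) {
    run_to_steady_state(params, frequency = f, state = state,
                        criterion = criterion, stim = stim, solver = solver)
  })
  apd90 <- vapply(runs, function(r) r$biomarkers$APD90, numeric(1))
  names(apd90) <- frequencies
  slow <- apd90[[which.min(frequencies)]]
  fast <- apd90[[which.max(frequencies)]]
  list(apd90 = apd90, delta_apd = slow - fast, runs = runs)
}

#' Pace with intracellular Na+ clamped
#'
#' Holds all intracellular Na+ compartments fixed at `clamp_mm` (their
#' derivatives are zeroed) while pacing at the given rate; used to
#' separate the direct rate dependence of the late Na+ current from the
#' indirect effect of Na+ accumulation.
#'
#' @param params parameter vector.
#' @param frequency pacing frequency (Hz).
#' @param clamp_mm clamped Na+ concentration (mM), > 0.
#' @param state,criterion,stim,solver as in [run_to_steady_state()].
#' @return as [run_to_steady_state()].
#' @export
run_na_clamp <- function(params = default_parameters(), frequency = 1,
                         clamp_mm,
                         state = initial_state(),
                         criterion = steady_state_criterion(),
                         stim = default_stimulus(), solver = list()) {
  if (clamp_mm <= 0) stop("clamp value must be positive")
  pc <- params
  pc["naclamp"] <- 1
  y <- state
  y[c("Naj", "Nasl", "Nai")] <- clamp_mm
  run_to_steady_state(pc, frequency = frequency, state = y,
                      criterion = criterion, stim = stim, solver = solver)
}

#' EAD induction protocol
#'
#' Paces at 1 Hz under a reduced-repolarization-reserve condition
#' (typically failing-heart remodeling plus 50% block of the rapid
#' delayed rectifier and a 30% increase of the L-type Ca2+ current) and
#' reports per-beat EAD events and repolarization status.  Optional 50%
#' blocks of SR release or NCX can be continuous or restricted to a
#' window of 5 consecutive stimulated beats.
#'
#' @param params fully remodeled parameter vector (including overlays).
#' @param beats number of paced beats.
#' @param state starting state (default the failing-model snapshot).
#' @param block one of `"none"`, `"irel"`, `"incx"`: which flux to block
#'   at 50%.
#' @param block_mode `"continuous"` or `"window"` (beats
#'   `block_window`).
#' @param block_window integer beat indices for the windowed block.
#' @param stim,solver as in [run_to_steady_state()].
#' @param ead_threshold,ead_offset EAD detector settings, see
#'   [detect_eads()].
#' @return list with `beat_table` (beat, ead_count, repolarized, apd90),
#'   `events`, `trace` (last beat, fine), and `any_ead` over the last 10
#'   beats.
#' @export
run_ead_protocol <- function(params, beats = 30,
                             state = initial_state("hf_1hz"),
                             block = c("none", "irel", "incx"),
                             block_mode = c("continuous", "window"),
                             block_window = 6:10,
                             stim = default_stimulus(), solver = list(),
                             ead_threshold = 1, ead_offset = 50) {
  block <- match.arg(block)
  block_mode <- match.arg(block_mode)
  blocked <- params
  if (block == "irel") blocked["ks_rel"] <- params[["ks_rel"]] * 0.5
  if (block == "incx") blocked["IbarNCX"] <- params[["IbarNCX"]] * 0.5
  y <- state
  tab <- data.frame(beat = integer(0), ead_count = integer(0),
                    repolarized = logical(0), apd90 = numeric(0))
  events <- list()
  tr <- NULL
  for (k in seq_len(beats)) {
    use_block <- block != "none" &&
      (block_mode == "continuous" || k %in% block_window)
    pk <- if (use_block) blocked else params
    tr <- pace_one_beat(y, pk, cl = 1000, stim_amp = stim$amplitude,
                        stim_dur = stim$duration, dt_out = 0.5,
                        solver = solver)
    y <- final_state(tr)
    t <- tr$time
    ead <- detect_eads(t, tr$Vm, threshold = ead_threshold,
                       start_offset = ead_offset)
    a90 <- tryCatch(apd(t, tr$Vm, 0.9), error = function(e) NA_real_)
    repol <- !is.na(a90) && min(tr$Vm[t > max(t) - 100]) < -60
    tab <- rbind(tab, data.frame(beat = k, ead_count = nrow(ead),
                                 repolarized = repol, apd90 = a90))
    if (nrow(ead)) events[[as.character(k)]] <- cbind(beat = k, ead)
  }
  last10 <- tab[tab$beat > beats - 10, ]
  list(beat_table = tab,
       events = if (length(events)) do.call(rbind, events) else NULL,
       trace = tr,
       any_ead = any(last10$ead_count > 0))
}
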