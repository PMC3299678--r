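#' Evaluate the model right-hand side at one state
#'
#' Returns the time derivative of every state variable together with the
#' full membrane-current decomposition (A/F) and SR fluxes (mM/ms).  The
#' evaluation is deterministic and side-effect free; the recorded
#' decomposition satisfies `dVm/dt = -(Iion - Istim)` exactly.
#'
#' @param state named state vector, see [initial_state()].
#' @param params named parameter vector, see [default_parameters()].
#' @param stim applied stimulus current (A/F, depolarizing positive).
#' @return list with components `ydot` (named derivatives) and `currents`
#'   (named current/flux decomposition).
#' @examples
#' d <- compute_derivatives(initial_state("rest"), default_parameters())
#' d$currents[["INaL"]]
#' @export
compute_derivatives <- function(state, params = default_parameters(),
                                stim = 0) {
  validate_state(state)
  validate_parameters(params)
  p <- unclass(params)
  p["stim_amp"] <- stim
  res <- .Call(C_gpb_eval, as.double(unname(state)), as.double(unname(p)))
  list(ydot = setNames(res$ydot, .state_names),
       currents = setNames(res$currents, .current_names))
}

.default_solver <- function() {
  list(rtol = 1e-8, atol = 1e-10, hmax = 1, dt_out = 0.1)
}

#' Integrate the myocyte model
#'
#' Runs the stiff adaptive integrator (`deSolve::lsoda` on the compiled
#' right-hand side) over one time window with a constant applied stimulus
#' and returns the sampled trace plus the final state.  Protocol drivers
#' chain calls to this function (stimulus on / stimulus off segments,
#' beat after beat), so the stimulus is constant within a call.
#'
#' @param state initial named state vector.
#' @param params named parameter vector.
#' @param duration window length (ms); 0 returns an empty trace.
#' @param stim constant applied current over the window (A/F).
#' @param t0 time stamp of the window start (ms), used for trace labelling.
#' @param dt_out output sampling interval (ms).
#' @param solver list of solver settings (`rtol`, `atol`, `hmax`); missing
#'   entries fall back to the defaults (rtol 1e-8, atol 1e-10, hmax 1 ms).
#' @param record if `FALSE`, only first/last rows are sampled (fast pacing
#'   to steady state).
#' @return object of class `hfcell_trace`: a data.frame with `time`, all
#'   state columns and all current columns, with the final state in
#'   attribute `"final_state"`.
#' @export
integrate_model <- function(state, params = default_parameters(),
                            duration, stim = 0, t0 = 0, dt_out = 0.1,
                            solver = list(), record = TRUE) {
  validate_state(state)
  validate_parameters(params)
  stopifnot(is.numeric(duration), length(duration) == 1, duration >= 0)
  sv <- modifyList(.default_solver(), solver)
  if (duration == 0) {
    tr <- empty_trace()
    attr(tr, "final_state") <- state
    class(tr) <- c("hfcell_trace", "data.frame")
    return(tr)
  }
  p <- unclass(params)
  p["stim_amp"] <- stim
  times <- if (record) seq(0, duration, by = dt_out) else c(0, duration)
  if (times[length(times)] < duration) times <- c(times, duration)
  atol <- rep(sv$atol, length(.state_names))
  out <- deSolve::lsoda(
    y = unname(state), times = times, func = "hfcell_derivs",
    parms = unname(p), dllname = "hfcell", initfunc = "hfcell_init",
    nout = length(.current_names), rtol = sv$rtol, atol = atol,
    hmax = sv$hmax, maxsteps = 500000
  )
  if (attr(out, "istate")[1] < 0) {
    stop(sprintf(
      "solver failure at t = %.3f ms (last valid time %.3f ms)",
      t0 + out[nrow(out), 1], t0 + out[nrow(out), 1]))
  }
  m <- as.data.frame(out)
  names(m) <- c("time", .state_names, .current_names)
  m$time <- m$time + t0
  fin <- setNames(as.numeric(out[nrow(out), 1 + seq_along(.state_names)]),
                  .state_names)
  class(m) <- c("hfcell_trace", "data.frame")
  attr(m, "final_state") <- fin
  m
}

empty_trace <- function() {
  tr <- as.data.frame(matrix(numeric(0), nrow = 0,
                             ncol = 1 + length(.state_names) +
                                    length(.current_names)))
  names(tr) <- c("time", .state_names, .current_names)
  tr
}

#' Final state of a trace
#'
#' @param trace an `hfcell_trace` as returned by [integrate_model()] or a
#'   protocol driver.
#' @return named state vector at the last sampled time.
#' @export
final_state <- function(trace) {
  fs <- attr(trace, "final_state")
  if (is.null(fs)) stop("trace carries no final state")
  fs
}

#' Pace one beat
#'
#' One cycle of rectangular-pulse stimulation: stimulus on for
#' `stim_dur` ms, then free run to the end of the cycle length.
#'
#' @param state initial state at the moment of stimulus onset.
#' @param params parameter vector.
#' @param cl cycle length (ms).
#' @param stim_amp stimulus amplitude (A/F); default [default_stimulus()].
#' @param stim_dur stimulus duration (ms).
#' @param dt_out output interval (ms).
#' @param solver solver settings, see [integrate_model()].
#' @param record sample the full beat (`TRUE`) or endpoints only.
#' @return `hfcell_trace` covering `[0, cl]` with final state attached.
#' @export
pace_one_beat <- function(state, params = default_parameters(), cl = 1000,
                          stim_amp = default_stimulus()$amplitude,
                          stim_dur = default_stimulus()$duration,
                          dt_out = 0.1, solver = list(), record = TRUE) {
  stopifnot(cl > stim_dur)
  seg1 <- integrate_model(state, params, duration = stim_dur,
                          stim = stim_amp, t0 = 0, dt_out = dt_out,
                          solver = solver, record = record)
  seg2 <- integrate_model(final_state(seg1), params,
                          duration = cl - stim_dur, stim = 0, t0 = stim_dur,
                          dt_out = dt_out, solver = solver, record = record)
  tr <- rbind(seg1[seg1$time < stim_dur, , drop = FALSE], seg2)
  class(tr) <- c("hfcell_trace", "data.frame")
  attr(tr, "final_state") <- final_state(seg2)
  tr
}

#' Stimulus definition
#'
#' Rectangular current pulse used by all pacing protocols: 5 ms duration,
#' amplitude 1.5x the diastolic threshold of the control model (threshold
#' determined once at baseline with [find_threshold()] and held fixed
#' across conditions so that biomarker differences between conditions are
#' attributable to remodeling, not to stimulus changes).
#'
#' @return list with `amplitude` (A/F) and `duration` (ms).
#' @export
default_stimulus <- function() {
  # diastolic threshold of the control model at rest: 4.375 A/F (5-ms pulse)
  list(amplitude = 1.5 * 4.375, duration = 5)
}

#' Diastolic stimulus threshold
#'
#' Bisects the minimal rectangular 5-ms pulse amplitude that elicits an
#' action potential (peak Vm > 0 mV) from the given state.
#'
#' @param state starting state (diastole).
#' @param params parameter vector.
#' @param lo,hi bracketing amplitudes (A/F).
#' @param tol bisection tolerance (A/F).
#' @return threshold amplitude (A/F).
#' @export
find_threshold <- function(state = initial_state(),
                           params = default_parameters(),
                           lo = 0, hi = 40, tol = 0.25) {
  elicits <- function(amp) {
    tr <- pace_one_beat(state, params, cl = 60, stim_amp = amp,
                        dt_out = 0.5, solver = list(rtol = 1e-6, atol = 1e-8))
    max(tr$Vm) > 0
  }
  if (!elicits(hi)) stop("upper bracket does not elicit an AP")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (elicits(mid)) hi <- mid else lo <- mid
  }
  hi
}
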