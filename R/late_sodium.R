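#' Late Na+ current: steady-state inactivation
#'
#' Steady-state value of the late Na+ inactivation gate `h_L`, a
#' monotonically decreasing sigmoid of membrane potential,
#' \deqn{h_{L\infty}(V) = 1 / (1 + e^{(V - V_{1/2})/k})}
#' with half-inactivation voltage `hL_vhalf` (default -91 mV) and slope
#' `hL_k` (default 6.1 mV).
#'
#' @param v membrane potential (mV), vectorized.
#' @param params parameter vector carrying `hL_vhalf` and `hL_k`.
#' @return h_L steady state in (0, 1).
#' @export
hL_inf <- function(v, params = default_parameters()) {
  1 / (1 + exp((v - params[["hL_vhalf"]]) / params[["hL_k"]]))
}

#' Late Na+ current: inactivation gate kinetics
#'
#' First-order relaxation of the `h_L` gate,
#' \deqn{dh_L/dt = (h_{L\infty}(V) - h_L)/\tau_{hL}.}
#' At fixed voltage the exact solution is the single exponential
#' \deqn{h_L(t) = h_{L\infty} + (h_L(0) - h_{L\infty}) e^{-t/\tau_{hL}},}
#' returned by `hL_relax()`.  The default time constant is 233 ms (37 C);
#' a Q10 of 2.2 relates it to the room-temperature measurement, but no
#' other temperature is simulated.
#'
#' @param h_L current gate value in \[0, 1\].
#' @param v membrane potential (mV).
#' @param params parameter vector.
#' @return `step_hL()`: the time derivative of `h_L` (1/ms).
#' @export
step_hL <- function(h_L, v, params = default_parameters()) {
  stopifnot(all(h_L >= 0 & h_L <= 1))
  (hL_inf(v, params) - h_L) / params[["tau_hL"]]
}

#' @rdname step_hL
#' @param t elapsed time at fixed voltage (ms), vectorized.
#' @param h_L0 gate value at `t = 0`.
#' @return `hL_relax()`: gate value at time `t` under clamped voltage.
#' @export
hL_relax <- function(t, h_L0, v, params = default_parameters()) {
  hinf <- hL_inf(v, params)
  hinf + (h_L0 - hinf) * exp(-t / params[["tau_hL"]])
}

#' Late Na+ current
#'
#' Ohmic late Na+ current with the baseline fast-Na+ activation gate
#' reused (cubed) as activation -- no separate activation ODE -- and the
#' dedicated slow inactivation gate `h_L`:
#' \deqn{I_{NaL} = g_{NaL}\, m^3\, h_L\, (V - E_{Na}).}
#' Zero at the reversal potential; sign follows `V - E_Na`.
#'
#' @param v membrane potential (mV).
#' @param m fast Na+ activation gate in \[0, 1\].
#' @param h_L late inactivation gate in \[0, 1\].
#' @param e_na Na+ Nernst potential (mV).
#' @param params parameter vector carrying `GNaL` (mS/uF).
#' @return current (A/F).
#' @export
compute_INaL <- function(v, m, h_L, e_na, params = default_parameters()) {
  stopifnot(all(m >= 0 & m <= 1), all(h_L >= 0 & h_L <= 1))
  params[["GNaL"]] * m^3 * h_L * (v - e_na)
}
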