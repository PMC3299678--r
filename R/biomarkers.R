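# Linear interpolation of the first downward crossing of `level` in
# signal y after index `from`; returns NA when there is none.
.cross_down <- function(t, y, level, from = 1) {
  n <- length(y)
  if (from >= n) return(NA_real_)
  idx <- from:(n - 1)
  hit <- idx[y[idx] >= level & y[idx + 1] < level]
  if (!length(hit)) return(NA_real_)
  i <- hit[1]
  t[i] + (y[i] - level) * (t[i + 1] - t[i]) / (y[i] - y[i + 1])
}

# Index of maximum upstroke velocity (APD clock reference).
.upstroke_index <- function(t, v) {
  dv <- diff(v) / diff(t)
  which.max(dv)
}

# Upstroke time: midpoint of the steepest sampling interval, which keeps
# the reference stable under resampling.
.upstroke_time <- function(t, v) {
  i <- .upstroke_index(t, v)
  (t[i] + t[i + 1]) / 2
}

#' Action potential duration
#'
#' Duration of one action potential at a fractional repolarization level:
#' time from the maximum upstroke velocity to the crossing of
#' `V_peak - level * (V_peak - V_diastolic)`, with the diastolic potential
#' taken at the start of the beat (just before the stimulus) and linear
#' interpolation between samples.  `level = 0.9` gives APD90.
#'
#' @param time,v time (ms) and membrane potential (mV) of one beat,
#'   starting at stimulus onset.
#' @param level repolarization fraction in \[0, 1\].
#' @return duration (ms).  Raises a `repolarization_failure` condition if
#'   the potential never reaches the level within the beat.
#' @export
apd <- function(time, v, level = 0.9) {
  stopifnot(length(time) == length(v), length(v) > 2)
  vdia <- v[1]
  ipk <- which.max(v)
  vpk <- v[ipk]
  if (vpk <= 0) stop("no elicited action potential (peak V <= 0 mV)")
  tup <- .upstroke_time(time, v)
  vth <- vpk - level * (vpk - vdia)
  tc <- .cross_down(time, v, vth, from = ipk)
  if (is.na(tc)) {
    stop(structure(class = c("repolarization_failure", "error", "condition"),
                   list(message = sprintf(
                     "no %.0f%% repolarization before end of beat", 100 * level),
                     call = sys.call(-1))))
  }
  tc - tup
}

#' Calcium transient metrics
#'
#' Diastolic level (value at beat start, just before the stimulus), peak
#' systolic level, and decay time `tau_ca`: the time from the transient
#' peak until the signal first falls to 10% of the transient amplitude
#' above diastole, linearly interpolated.
#'
#' @param time,ca time (ms) and Ca2+ concentration (mM) of one beat.
#' @param decay_fraction residual fraction defining the decay time
#'   (default 0.1).
#' @return list with `systolic`, `diastolic` (mM) and `tau_ca` (ms).
#' @export
ca_transient_metrics <- function(time, ca, decay_fraction = 0.1) {
  stopifnot(length(time) == length(ca), length(ca) > 2)
  dia <- ca[1]
  ipk <- which.max(ca)
  sys <- ca[ipk]
  if (sys - dia <= 0) stop("flat trace: no Ca2+ transient")
  level <- dia + decay_fraction * (sys - dia)
  tc <- .cross_down(time, ca, level, from = ipk)
  if (is.na(tc)) stop("transient does not decay to the target level")
  list(systolic = sys, diastolic = dia, tau_ca = tc - time[ipk])
}

#' NCX reversal time
#'
#' Within-beat time at which the Na+/Ca2+ exchanger current reverses from
#' outward (reverse mode, positive) to inward (forward mode, negative):
#' the first interpolated positive-to-negative zero crossing after the
#' post-upstroke outward maximum, reported relative to the start of the
#' beat (stimulus onset).
#'
#' @param time,incx time (ms) and NCX current (A/F) of one beat.
#' @param after ignore samples before this time (ms); with the default 0
#'   the search starts at the outward peak of the whole beat.
#' @return crossing time (ms).  Errors when the current never reverses.
#' @export
t_ncxrp <- function(time, incx, after = 0) {
  stopifnot(length(time) == length(incx), length(incx) > 2)
  w <- which(time >= after)
  imax <- w[which.max(incx[w])]
  if (incx[imax] <= 0) stop("NCX current has no outward phase: no reversal")
  tc <- .cross_down(time, incx, 0, from = imax)
  if (is.na(tc)) stop("NCX current does not reverse within the beat")
  tc - time[1]
}

#' Detect early afterdepolarizations
#'
#' An EAD is a local minimum of the membrane potential followed by a local
#' maximum, occurring after the initial upstroke (search starts
#' `start_offset` ms after it) and before 90% repolarization, with an
#' upward deflection exceeding `threshold` mV.  If the beat never reaches
#' 90% repolarization (repolarization failure), the search window extends
#' to the end of the beat, so sustained plateau oscillations are also
#' reported as events.
#'
#' @param time,v time (ms) and membrane potential (mV) of one beat.
#' @param threshold minimum upward deflection (mV).
#' @param start_offset dead time after the upstroke (ms).
#' @return data.frame with one row per event: `t_min`, `t_max` (ms),
#'   `amplitude` (mV).  Zero rows when no EAD is present.
#' @export
detect_eads <- function(time, v, threshold = 1, start_offset = 50) {
  stopifnot(length(time) == length(v))
  iup <- .upstroke_index(time, v)
  vdia <- v[1]
  vpk <- max(v)
  v90 <- vpk - 0.9 * (vpk - vdia)
  t_end <- .cross_down(time, v, v90, from = which.max(v))
  # without true repolarization (sustained depolarization, V never back
  # below -60 mV) the whole beat is searched, so plateau oscillations of a
  # non-repolarizing cell are still reported
  if (is.na(t_end) || v90 > -60) t_end <- time[length(time)]
  t_start <- time[iup] + start_offset
  events <- data.frame(t_min = numeric(0), t_max = numeric(0),
                       amplitude = numeric(0))
  n <- length(v)
  i <- which(time >= t_start)[1]
  if (is.na(i) || i < 2) return(events)
  while (i < n) {
    if (time[i] > t_end) break
    if (v[i] <= v[i - 1] && v[i] < v[i + 1]) {       # local minimum
      ahead <- i + which(diff(v[i:n]) < 0)[1] - 1     # next local maximum
      if (!is.na(ahead) && time[ahead] <= t_end + 1e-9 &&
          v[ahead] - v[i] > threshold) {
        events <- rbind(events, data.frame(
          t_min = time[i], t_max = time[ahead],
          amplitude = v[ahead] - v[i]))
        i <- ahead + 1
        next
      }
    }
    i <- i + 1
  }
  events
}

#' Extract the full biomarker set from one steady-state beat
#'
#' Collects every scalar electrophysiological characteristic measured in
#' the heart-failure analysis from a finely sampled single-beat trace:
#' APD90 and APD50 with their difference (triangulation), cytosolic Ca2+
#' transient metrics, SR Ca2+ extrema, end-diastolic Na+, NCX reversal
#' time and EAD count.
#'
#' @param trace single-beat `hfcell_trace` (columns `time`, `Vm`, `Cai`,
#'   `CaSR`, `Nai`, `INCX`).
#' @return one-row data.frame of class `hfcell_biomarkers`.
#' @export
biomarker_set <- function(trace) {
  t <- trace$time - trace$time[1]
  v <- trace$Vm
  a90 <- tryCatch(apd(t, v, 0.9), repolarization_failure = function(e) NA_real_)
  a50 <- tryCatch(apd(t, v, 0.5), repolarization_failure = function(e) NA_real_)
  cam <- tryCatch(ca_transient_metrics(t, trace$Cai),
                  error = function(e) list(systolic = NA_real_,
                                           diastolic = NA_real_,
                                           tau_ca = NA_real_))
  tn <- tryCatch(t_ncxrp(t, trace$INCX), error = function(e) NA_real_)
  ead <- nrow(detect_eads(t, v))
  out <- data.frame(
    APD90 = a90, APD50 = a50, triangulation = a90 - a50,
    ca_systolic = cam$systolic, ca_diastolic = cam$diastolic,
    tau_ca = cam$tau_ca,
    casr_systolic = max(trace$CaSR), casr_diastolic = min(trace$CaSR),
    nai = trace$Nai[1], t_ncxrp = tn, ead_count = ead
  )
  class(out) <- c("hfcell_biomarkers", "data.frame")
  out
}
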