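---
title: "Methods: model, protocols, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model, protocols, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`hfcell` simulates a single human endocardial ventricular myocyte as a
stiff 40-state ODE system: Hodgkin-Huxley gating for the fast Na+,
transient-outward, rapid and slow delayed-rectifier K+ and L-type Ca2+
channels; a four-state ryanodine-receptor release scheme; Na+ and Ca2+
buffering (troponin, calmodulin, myosin, SR membrane, sarcolemmal and
calsequestrin buffers); and three membrane-adjacent compartments
(junctional cleft, subsarcolemmal space, bulk cytosol) exchanging Na+
and Ca2+ with each other and with the SR.  Intracellular K+ is held
fixed, following the convention of the published endocardial baseline
formulation this package transcribes (its endocardial parameter set:
the transient-outward current is almost entirely the slow component).
The right-hand side lives in compiled C (`src/gpb_model.c`) and is
integrated with `deSolve::lsoda`.

The package's own contribution on top of the baseline is the late Na+
current,

$$ I_{NaL} = g_{NaL}\, m^3\, h_L\,(V - E_{Na}), \qquad
   \frac{dh_L}{dt} = \frac{h_{L\infty}(V) - h_L}{\tau_{hL}}, \qquad
   h_{L\infty}(V) = \frac{1}{1 + e^{(V+91)/6.1}} $$

with the baseline fast-Na+ activation gate reused (cubed) as
activation — no separate activation ODE — and a single-exponential
inactivation.  Defaults: `GNaL` = 0.015 mS/uF and `tau_hL` = 233 ms at
37 C (the room-temperature inactivation time constant scaled by a Q10
of 2.2; no other temperature is simulated, so the correction is a
documented constant, not an operation).  The half-inactivation voltage
(-91 mV) and slope (6.1 mV) are configurable because the source
formulation reports them only by citation.  Under the voltage-clamp
protocol (hold -120 mV, step to -20 mV, late current read 40 ms after
the step and divided by the peak transient current) this conductance
yields a late-to-peak ratio of about 0.1%, which is the calibration
the default was fitted to.  The clamp is simulated at model
temperature throughout; if the corresponding experiments were at room
temperature the simulated decay is accordingly faster, a caveat rather
than a switch.

## Heart-failure remodeling

`basic_hf_spec()` encodes chronic remodeling of the failing human
ventricular myocyte as an ordered, composable table of parameter
transforms: doubled late-Na+ conductance and inactivation time
constant, transient-outward current reduced to 40%, inward rectifier
scaled by 0.68, Na+/K+ pump reduced by 10%, background Na+ current
removed, background Ca2+ current x1.53, Na+/Ca2+ exchanger x1.75,
SERCA halved, SR leak x5, and the SR-luminal half-activation of
release lowered from 0.45 to 0.4 mM.

Two of these factors are exposed as arguments (`leak_factor`,
`cab_factor`) because reported values conflict between the narrative
and tabular descriptions of this remodeling in the literature.  We
resolved both by the single reading under which every tabulated
"increase" entry is the *new value in percent of baseline* — the
reading that makes the exchanger entry (175) agree with its stated
+75%, the late-current entry (200) with its stated doubling, and the
release-sensitivity entry (-11%) with the stated 0.4 mM.  That same
convention gives x1.53 for the background Ca2+ current and x5 for the
SR leak.

Acute overlays (`overlay_spec()`) compose multiplicatively on top of a
remodeled specification: fractional block of the rapid delayed
rectifier, fractional increase of the L-type current, scaling of the
late Na+ conductance relative to the *current* spec (so "doubled" on
the failing model means x4 versus baseline), and 50% blocks of SR
release or NCX, continuous or restricted to 5 consecutive beats.
A parameter vector remembers which provenance labels have been applied
and rejects double application.

### Sensitivity variants

The two-point sensitivity analysis varies one remodeled parameter at a
time to its *no-change* value (the non-failing baseline) and to its
*double-change* value.  Double change doubles the tabulated percent
change: an up-regulation to factor f becomes 2f (late Na+ conductance
x2 to x4, exchanger x1.75 to x3.5), a down-regulation by d percent
becomes 2d percent, floored at zero (pump 0.9 to 0.8, transient
outward 0.4 to 0).  We chose value-doubling over deviation-doubling
(which would give x3 for the late current) because the reported APD90
prolongation for the late-Na+ double change (+22%) is matched by the
x4 variant with the inactivation time constant held at its failing
value (+21% in this implementation) and not by the x3 variant (+15%).
For the same reason the inactivation time constant is treated as its
own sensitivity parameter (its own row in the remodeling table) rather
than co-varied with the conductance; a caller who wants joint
variation can pass both rows through `sensitivity_variant()`.

The sensitivity index divides the percent-change span by `delta_a`,
the span of the parameter's multiplier between the two variants in
units of the non-failing value (pump: |0.8 - 1.0| = 0.2).  The index
is only interpreted after per-row normalization, but contrary to what
one might expect the normalized ranking is *not* invariant to this
convention, because `delta_a` differs between parameters.  We keep the
baseline-units convention; with it the [Na+]i row is dominated by the
pump and the NCX-reversal row by SERCA, as reported.  The APD90 row
ranks the inward rectifier alongside the pump above the late current
in this implementation — see Limitations.

## Protocols and numerical choices

* **Stimulus.**  Rectangular current pulse, 5 ms, amplitude 1.5x the
  diastolic threshold of the control model (threshold 4.375 A/F,
  bisected once with `find_threshold()`), held fixed across all
  conditions so that biomarker differences are attributable to
  remodeling, not stimulus changes.  The source experiments do not
  state a stimulus; this is the package's choice.
* **Steady state.**  Pacing stops when APD90 moves less than 0.05 ms
  per beat over 5 consecutive beats *and* bulk Na+ moves less than
  1e-4 mM per beat, or at 1000 beats; which criterion fired is
  recorded.  The source states only "after achieving steady-state
  conditions"; the thresholds are the package's.  Tests verify that
  halving them changes APD90 by less than 0.2 ms.  Protocol runs
  default to starting from 1-Hz steady-state snapshots stored in
  `inst/extdata/` (generated by this package itself and regenerable
  with `scripts/make_snapshots.R`), which shortens the transient
  without changing the converged result.
* **Solver.**  `lsoda`, relative tolerance 1e-8, absolute tolerance
  1e-10, maximum step 1 ms; 0.1-ms output sampling for measurement
  beats and 1-ms sampling while converging.  APD and EAD detection
  need sub-millisecond resolution; a tolerance-halving test bounds the
  APD90 discretization error below 0.1 ms.
* **Staircase.**  Consecutive stages at 0.5, 1, 1.5, 2, 2.5 Hz with
  state carried over, 10 simulated minutes per stage by the protocol
  definition; the test suite uses 2-minute stages for ordinal checks
  only (the vignette-level quantities in the acceptance script do not
  use the staircase).  Carrying state between stages is load-bearing:
  a test asserts that restarting each stage from rest changes the
  end-stage Na+.
* **Problem sizes.**  The acceptance script paces each condition to
  the steady-state criterion (typically 150-300 beats from the shipped
  snapshots, about 850 beats for the four-frequency rate protocol);
  the test-suite sensitivity matrix caps runs at 600 beats, which is
  converged for every parameter except the slow Na+-coupled ones,
  whose residual drift is below the criterion threshold.

## Biomarkers

APD is measured from the maximum-upstroke-velocity time (midpoint of
the steepest sampling interval, stable under resampling) to the linear
interpolated crossing of `V_peak - level*(V_peak - V_diastolic)`, with
the diastolic potential taken just before the stimulus.  The Ca2+
decay time is the time from the transient peak to 10% of the
amplitude above diastole.  The NCX reversal time is the first
interpolated outward-to-inward zero crossing after the post-upstroke
outward maximum (the early sub-millisecond sign flips during the
upstroke are not the reversal the measure is after).  SR Ca2+
"systolic" and "diastolic" fields hold the beat maximum and minimum
respectively, keeping the systolic >= diastolic invariant shared with
the cytosolic pair.

An EAD is a local minimum followed by a local maximum of V between
50 ms after the upstroke and 90% repolarization, with an upward
deflection above 1 mV (both configurable; the source gives no numeric
criterion).  A beat counts as repolarized only if V returns below
-60 mV before the next stimulus; on non-repolarizing beats the whole
beat is searched, so sustained plateau oscillations are reported as
events rather than silently ignored.

## What the synthetic fixtures do and do not show

`generate_fixtures()` builds piecewise-linear and exponential
AP/Ca2+/current traces whose biomarker values exist in closed form,
plus a two-variable excitable system for integrator exercises.  They
pin down the extractors' geometry (crossings, interpolation,
thresholds) exactly, but they contain none of the model's stiffness,
compartment coupling or beat-to-beat memory; passing them says nothing
about physiological fidelity, which is carried by the steady-state
regression checks in `tests/testthat/test-acceptance.R`.

## Validation against an independent encoding

`validate_derivatives()` compares the compiled right-hand side against
a user-supplied table of probe states and reference derivatives (long
CSV), intended for cross-checking against an independent encoding of
the baseline model (e.g. a CellML translation).  No such encoding
ships with the package, so this check is an interface, not a test;
the in-repo guarantees are internal: the recorded current
decomposition sums to the recorded total within 1e-6 A/F, `dV/dt`
equals minus that total plus the stimulus, gates stay in [0,1] and
concentrations positive over all protocol runs, the quiescent state is
a fixed point, and results are invariant to solver-tolerance and
sampling changes.

## Known limitations

* The quantitative surface is faithful to a few percent for APD-based
  measures (doubling the late current prolongs steady APD90 by ~11%;
  the failing model prolongs APD90 by ~26% versus ~24% reported) but
  systematically underestimates the largest late-current enhancements
  (x10 gives ~71% versus 78% reported) and the depression of the
  systolic Ca2+ transient in failure (~50% of normal versus 41%
  reported).
* The Na+/K+-pump-to-APD coupling is weaker than reported: the pump
  double change shifts APD90 by about -5% here versus -22% in the
  source, so the APD90 sensitivity row ranks the inward rectifier
  above the late current.  A 10% pump reduction raises bulk Na+ by
  only ~0.35 mM in this transcription.
* The EAD induction condition (failing model + 50% rapid-rectifier
  block + 30% L-type increase at 1 Hz) sits past the
  repolarization-failure boundary here for *all* late-current levels:
  the cell settles into a depolarized oscillating state rather than
  showing discrete EADs only when the late current is doubled.  The
  oscillations are reported as EAD events; the contrast "no EADs at
  the basic failing late current" and the release-block suppression
  are not reproduced, while NCX-block suppression is.
* At 0.5 Hz the failing model's diastolic Ca2+ falls slightly below
  the normal model's at steady state; the reported ordering (failing
  diastolic higher at every rate) holds from 1 Hz upward.
* No epicardial or mid-myocardial variants, no CaMKII signalling, no
  Markov channel models, no tissue coupling, no abrupt-rate-change
  (dynamic restitution) protocols, and no pharmacology beyond the
  fractional blocks above.
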