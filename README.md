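# hfcell

Single-cell electrophysiology of the human endocardial ventricular
myocyte with an explicit **late sodium current** (I<sub>NaL</sub>) and
composable **heart-failure remodeling**, for researchers studying
repolarization, Na<sup>+</sup>/Ca<sup>2+</sup> homeostasis and
triggered arrhythmias in failing hearts.

The failing ventricular myocyte shows a prolonged action potential, a
blunted and slowly decaying Ca<sup>2+</sup> transient, elevated
intracellular Na<sup>+</sup>, and a propensity for early
afterdepolarizations (EADs).  A slowly inactivating component of the
Na<sup>+</sup> current is a suspected driver of several of these
changes.  `hfcell` implements:

* a compiled 40-state compartmental baseline model of the endocardial
  human action potential (Hodgkin–Huxley gating, four-state SR release,
  junctional/subsarcolemmal/cytosolic Na<sup>+</sup> and Ca<sup>2+</sup>
  compartments), extended with

  I<sub>NaL</sub> = g<sub>NaL</sub> · m³ · h<sub>L</sub> · (V − E<sub>Na</sub>),  dh<sub>L</sub>/dt = (h<sub>L∞</sub>(V) − h<sub>L</sub>)/τ<sub>hL</sub>,  h<sub>L∞</sub>(V) = 1/(1 + e<sup>(V+91)/6.1</sup>)

  with g<sub>NaL</sub> = 0.015 mS/µF and τ<sub>hL</sub> = 233 ms at 37 °C
  (the conductance calibrated so that a −120 → −20 mV clamp gives a
  late-to-peak Na<sup>+</sup> current ratio of ≈ 0.1%);
* named remodeling specifications: the basic heart-failure model
  (I<sub>NaL</sub> and τ<sub>hL</sub> ×2, I<sub>to</sub> ×0.4,
  I<sub>K1</sub> ×0.68, I<sub>NaK</sub> ×0.9, I<sub>Nab</sub> = 0,
  I<sub>Cab</sub> ×1.53, NCX ×1.75, SERCA ×0.5, SR leak ×5,
  EC<sub>50,SR</sub> → 0.4 mM), per-parameter sensitivity variants,
  ±15% perturbations, and acute overlays (I<sub>Kr</sub> block,
  I<sub>CaL</sub> increase, I<sub>NaL</sub> scaling, windowed
  I<sub>rel</sub>/NCX blocks);
* the standard protocols: voltage clamp, steady-state pacing, frequency
  staircase, APD rate dependence, Na<sup>+</sup> clamp, EAD induction;
* biomarker extraction (APD90/APD50, triangulation, Ca<sup>2+</sup>
  transient metrics, SR Ca<sup>2+</sup>, Na<sup>+</sup> load, NCX
  reversal time, EAD detection) and a two-point sensitivity matrix
  D<sub>c,p,x</sub> = 100·(C<sub>p,x</sub> − C<sub>HF</sub>)/C<sub>HF</sub>,
  S<sub>c,p</sub> = (D<sub>c,p,2</sub> − D<sub>c,p,1</sub>)/Δ<sub>a</sub>,
  normalized per characteristic.

## Worked example

```r
library(hfcell)

# late/peak Na+ current ratio under voltage clamp (-120 -> -20 mV)
vc <- run_voltage_clamp(default_parameters(), step_ms = 500)
sprintf("late/peak Na ratio: %.3f%%", vc$ratio)
#> late/peak Na ratio: 0.090%

# control vs failing myocyte at 1 Hz steady state
ctl <- run_to_steady_state(default_parameters(), frequency = 1)
hf  <- run_to_steady_state(hf_parameters(), frequency = 1,
                           state = initial_state("hf_1hz"))
ctl$biomarkers[c("APD90", "APD50", "ca_systolic", "tau_ca", "nai")]
#> control: APD90 329.2 ms | APD50 271.8 ms | peak Ca 0.42 uM | tau_Ca 384 ms | Nai 8.30 mM
hf$biomarkers[c("APD90", "APD50", "ca_systolic", "tau_ca", "nai")]
#> failing: APD90 414.5 ms | APD50 328.8 ms | peak Ca 0.21 uM | tau_Ca 616 ms | Nai 8.95 mM

100 * (hf$biomarkers$APD90 - ctl$biomarkers$APD90) / ctl$biomarkers$APD90
#> 25.9
```

The failing model prolongs APD90 by ~26%, halves the Ca²⁺ transient,
slows its decay from ~384 to ~616 ms and raises diastolic Na⁺ —
the hallmark electrophysiological phenotype of the failing human
myocyte.  `run_rate_dependence()`, `run_staircase()` and
`run_ead_protocol()` drive the frequency-dependence and arrhythmia
experiments; `run_sensitivity_analysis()` + `build_matrix()` produce
the normalized sensitivity matrix.  A thin command-line front end is
installed as `exec/hfcell` (subcommands `clamp`, `pace`, `staircase`,
`rate`, `naclamp`, `ead`, `sensitivity`, `validate`).

See `vignettes/methods.Rmd` for the model equations, remodeling
conventions, numerical choices and known limitations.

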