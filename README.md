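# respgate

Intra-beam respiratory motion, baseline drift and gated-dose analysis for
respiratory-gated lung SBRT.

## What this is for

In respiratory-gated lung SBRT the beam is on only inside a gating window
defined on a breathing signal, either on the normalized cycle time (*phase
gating*) or on the signal amplitude normalized to the first few cycles
(*amplitude gating*). The window is calibrated once at the start of a beam
and never revisited, so when the end-expiration target position drifts
during delivery — as it does, predominantly caudally and most strongly for
lower-lobe targets — the beam keeps firing while the target occupies
different positions from cycle to cycle. `respgate` is a toolkit for
medical physicists studying that failure mode:

* **Baseline drift** per respiratory cycle: the expiration point of each
  cycle is detected per direction (AP/CC/LR) and the drift is quantified as

  `Δ_n = |A_EP(n+1) − A_EP(n)| / (t_EP(n+1) − t_EP(n))   [mm/s]`,

  with per-beam mean/max/p95 summaries.
* **Gating simulation**: phase and amplitude windows (clinical defaults:
  expiration 35–65% of phase or 0–30% of amplitude, etc.), beam-on masks,
  duty cycles, and residual target motion per cycle inside the window.
* **Dosimetric consequence** by the van Herk dose-probability convolution:
  the beam-on target-position PDF per axis is convolved with an analytic
  plateau–penumbra reference plan (23 mm spherical CTV + 5 mm PTV margin,
  48 Gy prescribed to the 80% isodose, so D_max = 60 Gy), yielding the
  blurred DVH, D2/D98/D50 and the ICRU 83 homogeneity index
  `HI = (D2 − D98)/D50`.
* **A synthetic cohort generator**: no patient traces are distributed, so
  the package generates quasi-periodic breathing with per-cycle
  amplitude/period variability, tracking noise and controllable,
  lobe-dependent baseline drift, emulating a published 10-patient /
  148-beam cohort (amplitude 10.1 ± 2.2 mm, cycle 3.0 ± 0.6 s, beams of
  2–3 min). Everything is seed-deterministic.

## A worked example

One beam with lower-lobe-like caudal drift (−0.4 mm/s sustained on CC):

```r
library(respgate)
spec <- waveform_spec(duration_s = 120, base_amplitude_mm = c(4, 10, 2.5),
                      base_period_s = 3, drift_rate_mm_per_s = c(0, -0.4, 0),
                      amplitude_cv = 0.15, period_cv = 0.15,
                      noise_sd_mm = 0.2, seed = 42)
trace <- generate_trace(spec)

compute_baseline_drift(detect_expiration_points(trace, "cc"))
#> Baseline drift profile (CC): 39 cycle pairs
#>   mean 0.403, max 0.661, p95 0.542 mm/s
```

The per-beam mean drift (0.403 mm/s) recovers the generator's setting. The
gating comparison shows the clinically relevant asymmetry — with a fixed
amplitude calibration and an open-ended lower threshold, amplitude-gated
expiration follows the drifting target (large residual motion, 92% duty
cycle), while amplitude-gated transition/inspiration windows progressively
empty and keep residual motion far below phase gating:

```r
compare_gating_methods(trace)
#> Residual motion by gating method and respiratory phase [mm]
#>     method       phase ap_mm  cc_mm lr_mm residual_3d_mm duty_cycle
#>      phase  expiration 1.497  3.077 1.088          3.591     0.2997
#>      phase  transition 2.483  6.129 1.672          6.821     0.3008
#>      phase inspiration 1.735  4.212 1.303          4.738     0.2977
#>  amplitude  expiration 4.447 10.298 2.938         11.596     0.9200
#>  amplitude  transition 0.385  0.607 0.241          0.758     0.0503
#>  amplitude inspiration 0.104  0.293 0.118          0.332     0.0175

gated_dose_analysis(trace, "phase", "expiration")
#> Gated dose analysis: phase gating, expiration phase
#>   HI 0.937 (reference 0.032), P_CTV 0.948, duty cycle 0.30
```

The blurred homogeneity index (0.937 against 0.032 for the static plan)
quantifies how much of the dose plateau this beam's drift erodes.

The full pipeline — cohort generation, drift summary, residual-motion
table, HI table, JSON summary — runs with

```r
run_pipeline(run_config(seed = 1), out_dir = "respgate_run")
```

or from a shell via `Rscript inst/cli/respgate.R all --seed 1 --out run`.

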