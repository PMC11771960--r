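# hemigait

Bilateral spinal rhythm-generator model and gait-timing analysis for
lateral-hemisection locomotor studies.

## What problem this addresses, and for whom

A lateral thoracic hemisection cuts the descending pathways on one side of
the spinal cord. The contralesional hindlimb keeps its supraspinal drive;
the ipsilesional hindlimb is left to be paced by somatosensory feedback.
For motor-control and spinal-cord-injury researchers, `hemigait` provides:

* a **circuit model** of two spinal rhythm generators — flexor (F) and
  extensor (E) persistent-sodium conditional bursters coupled through
  inhibitory relays — connected across the midline by commissural pathways
  (V0D, V2a–V0V–Ini, V3, V3E), driven by supraspinal drives
  (α for flexion, γ for extension) and by two stance-phase feedback signals
  (SF-E1, hip-flexor stretch; SF-E2, extensor force), with feedback gated
  by drive-dependent presynaptic inhibition, `gain = max(0, 1 − k_PSI α)`;
* **lesion transforms** (`intact`, `right_/left_hemisected`, `transected`)
  that remove a side's drives and thereby open its feedback gate;
* a **simulation engine** (compiled Dormand–Prince 5(4)) with flexion
  event detection, cycle/stance/swing/duty metrics, belt-speed sweeps
  (tied and split protocols) and swing–stance crossing localization;
* an **operating-regime classifier** (state-machine / flexor-driven /
  classical half-center / non-oscillating);
* a **gait-event analysis pipeline** for experimental-style per-limb
  contact and stance-end timestamps, and a **seeded synthetic generator**
  of such data, so the pipeline is fully testable offline.

Burster dynamics follow
`C dV/dt = −g_NaP m∞(V) h (V−E_Na) − g_L (V−E_L) − g_SynE (V−E_SynE) −
g_SynI (V−E_SynI)` with slow inactivation
`dh/dt = (h∞(V) − h)/τ_h(V)`; unit output is piecewise-linear in V
between −50 and 0 mV. See the methods vignette
(`vignettes/hemigait-methods.Rmd`) for the full model account.

## Worked example

Simulate the right-hemisected model on a split-belt treadmill (left belt
fixed at 0.4, right belt stepped 0.5 → 1.0), extract per-cycle timing, and
locate where ipsilesional swing overtakes stance:

```r
library(hemigait)
net  <- build_network()                      # intact bilateral circuit
hemi <- apply_lesion(net, "right_hemisected")

sweep <- speed_sweep(hemi, "split_ls_rf", betas = seq(0.5, 1.0, 0.1))
sweep[sweep$side == "right",
      c("beta_R", "cycle_s", "stance_s", "swing_s", "duty_factor")]
#>  beta_R cycle_s stance_s swing_s duty_factor
#>     0.5   0.821    0.472   0.349       0.575
#>     0.6   0.498    0.256   0.242       0.513
#>     0.7   0.578    0.275   0.303       0.476
#>     0.8   0.570    0.263   0.308       0.461
#>     0.9   0.565    0.252   0.313       0.446
#>     1.0   0.564    0.248   0.316       0.440

find_crossing(sweep, side = "right")
#> [1] 0.6318144
```

The ipsilesional limb's stance shortens as its belt speeds up while swing
stays long: the two cross at β_R ≈ 0.63 and the duty factor falls below
50% — the model's signature split-belt limp. Two companion probes:

```r
oscillation_threshold(net)$threshold   # smallest bilateral drive that
#> [1] 0.2445312                       # sustains rhythm without feedback

classify_regime(hemi, "right", belt_condition("tied", 0.5))$regime
#> [1] "state_machine"                 # feedback-paced lesioned side
```

The synthetic-data route mirrors the experimental analysis end to end:

```r
res <- cmd_synth_analyze(synth_params(), out_dir = "out")  # events -> metrics
res$comparison$crossings                                   # -> comparisons
```

A command-line front end is installed at
`system.file("cli/hemigait.R", package = "hemigait")` with verbs `sweep`,
`classify`, `synth`, `analyze`.

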