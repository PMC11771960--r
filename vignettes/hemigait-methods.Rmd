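---
title: "Modeling spinal control of locomotor phase durations after lateral hemisection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling spinal control of locomotor phase durations after lateral hemisection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

During treadmill locomotion, cycle, stance and swing durations of each
hindlimb are set by an interplay of three elements: spinal rhythm-generating
circuits, descending (supraspinal) drives, and somatosensory feedback from
the moving limb. A lateral thoracic hemisection severs the descending
pathways on one side only, producing an informative asymmetry: the
contralesional side keeps its supraspinal drive while the ipsilesional side
is left to be paced by sensory feedback. `hemigait` implements a bilateral
spinal circuit model of this situation, plus the analysis pipeline that
turns simulated (or synthetic experimental-style) gait events into
speed-dependent duration curves for tied-belt and split-belt protocols.

## The circuit model

Each side carries a rhythm generator (RG): a flexor (F) and an extensor (E)
half-center, mutually inhibiting through relay interneurons InF and InE.
The two RGs are coupled across the midline by commissural pathways:

* V0D: F → V0D → contralateral F, inhibitory (alternation),
* V2a–V0V–Ini: F → V2a → V0V → contralateral Ini → F, net inhibitory
  (alternation, drive-assisted),
* V3: F → V3 → contralateral F, excitatory,
* V3E: E (and SF-E2 feedback) → V3E → contralateral E, excitatory
  (crossed weight support).

F and E are *conditional bursters* with persistent-sodium dynamics:

$$C\dot V = -\bar g_{NaP}\, m_\infty(V)\, h\,(V-E_{Na}) - g_L (V-E_L)
  - g_{SynE}(t)(V-E_{SynE}) - g_{SynI}(t)(V-E_{SynI}),$$

with $m_\infty(V) = [1+e^{-(V-\theta_m)/\sigma_m}]^{-1}$, slow inactivation
$\dot h = (h_\infty(V) - h)/\tau_h(V)$,
$h_\infty(V) = [1+e^{(V-\theta_h)/\sigma_h}]^{-1}$ and
$\tau_h(V) = \tau_0 / \cosh((V-\theta_h)/2\sigma_h)$. Relay units follow the
same equation without the sodium term. Unit output is the piecewise-linear
$f(V)$: 0 below $-50$ mV, 1 above $0$ mV, linear in between. Synaptic
conductances are weighted sums of presynaptic outputs, constant drive terms,
and gated feedback terms.

The flexor half-center is the rhythmogenic element. With the shipped
parameters (`default_config()`) it is quiescent without input, bursts
intrinsically for tonic excitatory conductances of roughly 0.13–0.45 nS
(cycle period falling from ≈1.2 s to ≈0.6 s as drive grows, burst duration
0.30–0.38 s growing with drive), and holds a stable tonic plateau above
≈0.45 nS. The extensor half-center has a depolarized leak reversal, so it
is tonically active at rest — stance is the default state, maintained even
without any supraspinal drive — and its faster inactivation
($\tau_0 = 300$ ms) makes extensor output sag over the course of a stance
phase, mimicking the gradual hand-over from extensor tone to the
swing-initiating transition.

### Drives, feedback, gating

Flexor-directed drives $\alpha_L, \alpha_R$ excite the ipsi- and (weakly)
contralateral F and two commissural populations; extensor-directed drives
$\gamma = 0.5$ excite the ipsilateral E. On intact sides
$\alpha = \min(\beta + 0.1,\ 1.1)$ tracks belt speed $\beta$ (the animal's
voluntary speed compensation; see *Design choices* for why the map carries
an offset). Hemisected sides receive identically zero drives.

Two sensory feedback signals operate during extension:

* **SF-E1** (hip-flexor stretch proxy): $k_{E1}\,\beta\,\min(\chi, 1)$,
  where the stance clock $\chi$ ramps over $T_{ramp} = 1$ s while the
  ipsilateral flexor is silent and resets at flexion onset. It excites the
  ipsilateral F (promoting stance→swing) and inhibits the contralateral F
  through Ini.
* **SF-E2** (extensor force proxy): $k_{E2} f(V_E)$, reinforcing the
  ipsilateral E and exciting the contralateral E via V3E.

Both vanish whenever the ipsilateral extensor output is zero. Every
feedback entry is gated by presynaptic inhibition from the ipsilateral
drive: gain $= \max(0, 1 - k_{PSI}\alpha)$ with $k_{PSI} = 2$. A
hemisection therefore has two effects at once: the lesioned side loses its
drives *and* its feedback acts at full gain.

### Operating regimes

`classify_regime()` operationalizes the three-regime taxonomy. Freezing
phasic feedback at zero: if the side stops cycling, it is a *state machine*
(feedback-triggered transitions) provided the full model oscillates, or
*non-oscillating* otherwise. If it still cycles, the flexor half-center is
isolated at the mean excitatory conductance it received in situ: intrinsic
bursting there means *flexor-driven*; otherwise the rhythm needs the mutual
inhibition of the pair — *classical half-center*. "Oscillation" means at
least three alternating flexor bursts within a 30 s window after a 10 s
transient. With the default calibration the intact model is flexor-driven
from drive ≈0.25 upward, the transected model is a pure state machine at
all belt speeds, and the right-hemisected model splits: left RG
flexor-driven, right RG state machine.

## What the hemisected model does, and why

* **Tied belt.** The right (ipsilesional) side is paced by its ungated
  SF-E1 ramp; strong V0D crossed inhibition (7 nS weight) keeps the two
  sides in strict 1:1 alternation, so cycle durations track the intact
  model within ≈4%. The full-gain SF-E1 kick at flexion onset, decaying
  with the clock reset time constant (0.52 s), pushes the flexor
  transiently toward its tonic band: right swing lengthens by 25–40 ms and
  right stance shortens at every speed — the limp.
* **Split, left slow / right fast.** The right ramp scales with the fast
  belt, so right stance falls steeply with $\beta_R$ while swing stays
  long: swing and stance cross at $\beta_R \approx 0.63$ and the right
  duty factor drops to ≈0.44 at $\beta_R = 1.0$.
* **Split, left fast / right slow.** The slow right side is shielded from
  the speed increase; all per-side durations stay within 15% of the intact
  model across the grid.

## Tunable parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `k_PSI` | 2 | 1/drive | presynaptic attenuation slope; gain hits 0 at $\alpha = 0.5$ |
| `k_E1`, `k_E2` | 1, 1 | – | feedback gains; set to 0 to freeze feedback |
| `T_ramp` | 1.0 | s | stance-clock ramp time (SF-E1 growth rate) |
| `tau_reset` | 0.52 | s | clock decay during flexion; sets the SF-E1 tail that prolongs ipsilesional swing |
| `weights$a_F`, `a_Fc` | 0.35, 0.14 | nS/drive | ipsi/contra drive onto F; total sized so the no-feedback oscillation threshold sits near 0.25 and the flexor stays in its bursting window over the speed range |
| `weights$V0D_F` | 7.0 | nS | crossed inhibition; enforces 1:1 left-right entrainment after hemisection |
| `weights$E1_F` | 1.6 | nS | SF-E1 onto F; sets the feedback-paced stance duration and hence the split-belt crossing speed |
| solver `rtol`, `atol`, `max_step` | 1e-8, 1e-10, 5 ms | – | reproducibility to plotting precision |

## Synthetic gait data

The generator (`generate_gait_data()`) emulates the *structure* of the
experimental data — per-limb paw-contact and stance-end timestamps for
cats walking tied-belt 0.4–1.0 m/s and split-belt with the slow belt at
0.4 m/s — not any individual animal. Cycle duration follows a power law
$T(v) = a v^{-k}$ (defaults $a = 0.72$ s, $k = 0.45$), tied-belt swing a
gentle linear decline $S(v) = c_0 + c_1 v$ ($0.25 - 0.03 v$ s); in split
conditions the cycle uses the belt-average speed and the fast limb's swing
is the cycle fraction $w_0 + w_1 (v_f - 0.4)$ ($w_0 = 0.275$,
$w_1 = 0.35$, chosen so that the default hemisection effect reproduces the
calibration pattern below while intact fast-limb swing never exceeds
stance). Hemisection effects are applied per condition: ipsilesional swing
multiplier $\delta_{sw} = 1.35$ (fast or tied belt; cycle preserved, stance
absorbs), a smaller $\delta_{sw,slow} = 1.08$ when the ipsilesional limb is
on the slow belt, and a contralesional stance additive
$\delta_{st} = 0.05$ s. With these defaults the synthetic hemisected
right limb's swing exceeds its stance from 0.7 m/s upward in the left-slow
/ right-fast condition — and never in the intact state.

Noise is multiplicative lognormal per cycle phase (log-SD 0.05) with a
lognormal subject effect (log-SD 0.05) on the cycle amplitude only; the
variance components are placeholders, since the true experimental ones
are unknown. Draws are consumed in a fixed enumeration order, so a seed pins
the output byte-for-byte and changing one effect size leaves every
unaffected limb's draws untouched. What a green test establishes is that
the analysis pipeline recovers known generating parameters and detects
injected asymmetries of realistic size — not that the generator matches any
real animal's variance structure.

## Numerical choices

* Dormand–Prince 5(4) adaptive integration, relative tolerance $10^{-8}$,
  absolute $10^{-10}$, maximum step 5 ms, outputs on a 1 ms grid; state
  clamps keep $h \in [0,1]$.
* The stance clock's "reset at flexion onset" is implemented as a fast
  exponential decay (time constant `tau_reset`) rather than a
  discontinuous jump, keeping the vector field integrable by a standard
  stepper; the decaying SF-E1 tail this produces in early swing is also
  the mechanism that sustains the ipsilesional flexor burst after
  hemisection.
* Flexion onset/offset are threshold crossings of $f(V_F)$ at 0.05 with
  linear sub-step interpolation, a 50 ms same-type debounce, and a 10 s
  discarded transient; at least 3 complete cycles are required.
* Speed sweeps warm-start each grid point from the previous point's final
  state; per-point failures become flagged rows.
* Swing/stance crossings are linear interpolations of
  $\mathrm{swing}-\mathrm{stance}$ between grid rows; multiple sign
  changes are all returned, with a warning.

## Design choices made where the design was open

* **Drive map offset.** With a strict identity map $\alpha = \beta$ the
  presynaptic gate is partially open only at $\beta < 0.5$, leaving a
  sliver of feedback that makes the intact cycle curve non-monotone with a
  peak at $\beta = 0.5$ — and that peak sits in 2:1 resonance with the
  feedback-paced lesioned side, locking the tied hemisected model into
  double-stepping at exactly $\beta = 0.5$ (robust to cold/warm starts and
  feedback-weight changes). The shipped map $\alpha = \min(\beta + 0.1,
  1.1)$ keeps the gate closed throughout the belt range, which both
  matches the "pattern defined by supraspinal drives" reading of the
  intact state and restores 1:1 entrainment at every tied speed.
* **Extensor excitability.** The choice to make E tonically active at rest
  (depolarized $E_L$) rather than drive-dependent is what lets the
  transected model keep stance without any supraspinal input, a
  prerequisite for the state-machine regime.
* **Relay of crossed SF-E1 inhibition** is routed through Ini (shared with
  the V0V pathway); the V3E pathway receives both extensor output and
  SF-E2.

## Known limitations

* The intact model's speed-dependence is compressed relative to cat
  data: cycle spans roughly 0.79–0.75 s over
  $\beta = 0.4$–$1.0$ (stance 0.48→0.42 s) instead of ≈1.1→0.6 s, and
  stance flattens (≤1% rise) between $\beta = 0.9$ and 1.0 where the
  flexor approaches its tonic band. Qualitative orderings (stance falls,
  swing grows mildly) are preserved; absolute durations at the slow end
  are short.
* In the split left-slow/right-fast condition at $\beta_R \ge 0.6$ the
  model settles into 2:1 right:left stepping, whereas hemisected cats show
  equal cycles with a very long ipsilesional swing; the ipsilesional
  limb's own swing/stance crossing and sub-50% duty factor are
  nevertheless reproduced from its own cycles.
* Single-unit "populations", no musculoskeletal layer, no pattern-formation
  layer, no forelimbs, no post-injury plasticity: the model explains
  timing, not kinematics or recovery.
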