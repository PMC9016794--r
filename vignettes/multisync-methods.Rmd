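---
title: "Methods: censusing coexisting synchronization modes of coupled cellular oscillators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: censusing coexisting synchronization modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Two cellular oscillators — the circadian clock and the cell-division cycle —
influence each other in both directions: clock transcription factors (BMAL1
in particular) induce the Cdk1-inhibiting kinase Wee1, while Cdk1 activity
globally represses transcription around mitosis, clock genes included. A
bidirectionally coupled pair of limit-cycle oscillators usually synchronizes
to a single rhythm with one common period. In some coupling regimes,
however, several *distinct* synchronized rhythms coexist at the same
parameter values — different common periods, amplitudes and waveforms, each
with its own basin of attraction. Detecting that coexistence
(multi-synchronization, the oscillatory analogue of multistability) requires
deliberately sampling initial conditions, because any single simulation
shows only one attractor.

`multisync` packages the full workflow: the coupled model, deterministic
integration with exact coupling-onset events, attractor identification, and
the sweep protocols that expose coexistence (onset-time sweeps, parameter
hysteresis, pulse-induced switching, entrainment maps).

## The oscillator stand-ins

The published coexistence phenomenon was demonstrated in a detailed coupled
model of some 62 variables whose equations live outside this package. We
deliberately work with small stand-ins that preserve the coupling
architecture and the free-running periods; external models plug in through
the same `oscillator_model` contract (an R derivative closure plus named
input/output ports), so nothing downstream is specific to the stand-ins.
Consequences of that choice are discussed under *Limitations*.

### Clock limb

`make_goodwin_clock()` is the classic three-stage transcriptional
negative-feedback loop: mRNA `M` → cytosolic protein `P` → nuclear repressor
`I` ⊣ `M`. Synthesis of `M` is repressed by `I` through a Hill function and
multiplied by the mitotic-repression input port `R` (neutral value 1); all
degradations are Michaelian; concentrations are in µM, rates in µM/h. The
output port `clock_readout` exposes `P`, the BMAL1 proxy.

Two deliberate choices:

* **Hill exponent n = 8** (rather than the textbook 4). With n = 4 the
  limit cycle, though present, is so weakly attracting that inter-peak
  intervals still wander by ~0.02 h after 2000 h of integration, which
  defeats a periodicity test with a 10⁻³ coefficient-of-variation
  threshold at any practical sweep length. With n = 8 the cycle attracts
  within a few hundred hours (inter-peak SD ~5·10⁻⁵ h).
* **Time-scale calibration by exact rescaling.** Every rate is divided by a
  factor τ, so the period satisfies T(τ) = τ·T(1) *exactly*. We measured
  T(1) = 32.332342 h once (rtol 10⁻¹⁰, 6000 h run, 4000 h discarded) and
  fixed τ = 24/T(1). No bisection is needed; the measured period is
  24.00 ± 10⁻³ h.

### Cell-cycle limb

`make_cdk_cycle()` is a minimal mitotic-oscillator cascade of the
Goldbeter (1991) type: cyclin `C` accumulates at a constant rate and is
degraded via the protease activator `X`; Cdk1-like activity `A` is switched
on by cyclin through a Michaelian activation step and off at a rate
increased by the Wee1-like inhibitor `W`; `X` is activated by `A`. The
activation/inactivation steps operate near saturation (Michaelis constants
0.005 on fractional variables), which makes the oscillator relaxation-like:
fast mitotic transitions separated by slow cyclin accumulation — the reason
the integrator must be stiff-capable.

The Wee1 limb is `dW/dt = (k_sw + v_sw·S^h_w/(K_w^h_w + S^h_w) − k_dw·W)/ε`
with basal synthesis k_sw = 0.115 µM/h (5% of the reference induction rate
v_sw = 2.3), decay k_dw = 0.5 /h, and `S` the clock signal on the input
port (neutral 0). `W` raises the Cdk1 inactivation rate by the factor
`(1 + α·W)`.

* **Wee1 potency α = 0.3 µM⁻¹.** At α = 1 a saturating clock signal drives
  the inactivation rate up ~5-fold and the coupled pair fragments into
  complex or chaotic oscillations across the whole coupling-strength range
  we scanned; no mono-synchronization region exists. α = 0.3 still
  suppresses the cycle under constant saturating induction (the documented
  behaviour) but leaves a broad, robust 1:1 locking band under periodic
  induction.
* **ε calibration**: as for the clock, ε_ref = 19.1/T(1) with
  T(1) = 26.044732 h, giving a free-running period of 19.10 h exactly up to
  integrator error. ε is exposed so users can detune the cell cycle.

### Coupling

`make_coupled()` concatenates the two systems. Under active coupling the
cycle's port receives `S = P(t)` and the clock's mRNA synthesis is
multiplied by `R = K_ICdk1^g_r/(K_ICdk1^g_r + A^g_r)`. Defaults h_w = 4
(switch-like induction) and g_r = 2 (graded repression); K_w = 0.5 µM is
the midpoint of the clock protein's oscillation range. Which clock species
Cdk1 represses is not constrained by the phenomenology we target; we repress
mRNA synthesis only, the natural reading of transcriptional repression in a
single-gene clock model. Setting `v_sw = 0` and `K_ICdk1 → ∞` recovers the
uncoupled pair exactly (asserted in tests).

The two coupling limbs move the periods in opposite directions — constant
repression *shortens* the clock period (R = 0.4 gives 19.7 h), while Wee1
induction delays mitosis — so a common period between (or near) 19.1 and
24 h is dynamically reachable. The shipped strong-coupling reference
(`strong_coupling_spec()`: v_sw = 2 µM/h, K_ICdk1 = 0.5 µM) sits in the
middle of the mono-synchronization band found by scanning (v_sw, K_ICdk1);
there every one of the 601 reference onset times locks 1:1 at a common
period of 24.35 h.

### The analytic oracle

`make_normal_form(radii, omega0, shear, relax)` is the planar system with
radial dynamics `dr/dt = −k·r·∏(r² − ρᵢ²)` and angular velocity
`ω₀ + βr²`. Periods (`2π/(ω₀ + βρᵢ²)`), amplitudes (ρᵢ) and basins
(delimited by the even-indexed, unstable radii) are known in closed form,
so every census, pulse map and hysteresis window the package produces can
be checked exactly. Defaults keep radii ≤ 2.5 and k = 10⁻² so that the
degree-2m radial polynomial stays numerically tame. The hysteresis fixture
`make_ring_hysteresis()` uses the radial polynomial
`(r² − 1)((r² − c)² − µ)`, whose outer stable/unstable cycle pair collides
in a saddle-node of cycles at µ = 0 — a closed-form bistable window
(0, µ_max] for the sweep detector.

## Estimators

**Period** (`estimate_period`): strict local maxima refined by a quadratic
fit through the three surrounding samples; period = mean inter-peak
interval, with the SD of intervals reported. On sinusoids sampled at 0.05 h
the error is below 0.01 h (tested for periods 6–30 h), matching the 0.01 h
reporting precision used throughout.

**Regime** (`classify_regime`): `steady_state` if the post-transient range
is below 10⁻⁶; `periodic` if the interval coefficient of variation is
< 10⁻³ *and* successive peak heights agree within 1%; `complex_periodic` if
intervals and heights repeat with a pattern of 2–8 cycles; `aperiodic`
otherwise — diagnosis by elimination, which is all a census needs (Lyapunov
exponents are out of scope). Too few peaks on a clearly non-flat signal is
an explicit insufficient-data error rather than a silent label.

**Fingerprint** (`fingerprint`): the unit of attractor identity — period,
per-variable amplitude over the final full cycle, and a one-cycle waveform
cut at a fixed anchor (first upward crossing of the reference variable's
half-range level), resampled to W = 256 points and min–max normalized per
variable.

**Distance** (`attractor_distance`): the maximum of (i) relative period
difference, (ii) largest per-variable relative amplitude difference, and
(iii) the minimum over cyclic shifts of the RMS difference of normalized
waveforms. The shift minimization uses FFT circular cross-correlation
(exact and O(W log W); the brute-force O(W²) scan is what made early
601-fingerprint censuses intractable). The amplitude term is essential:
concentric limit cycles of the normal form with β = 0 share both the period
and the normalized wave shape and differ *only* in amplitude. The distance
is a semimetric (symmetric, non-negative, zero on identical inputs);
shift-invariance holds exactly for whole-grid-point shifts and to within
resampling error (~3·10⁻³ at W = 256) otherwise.

**Synchronization** (`check_sync`): periods of the two readouts estimated
independently; locked with ratio p:q (coprime, ≤ 4) when
|p·T_A − q·T_B|/(q·T_B) < 10⁻², the peak counts over the window are
consistent with p:q, and neither interval series drifts. p:q is the
frequency ratio f_A:f_B, so a 24 h clock with a 12 h cycle is "1:2". A
suppressed (non-oscillating) variable yields a flagged not-applicable
verdict, not an error, because strong coupling can legitimately silence one
oscillator.

**Clustering** (`cluster_modes`): single linkage under the distance above,
implemented as union-find over the graph of pairs within the threshold
(default 0.01). This is order-independent, ties at the threshold merge
(conservative mode counting), and connected pairs short-circuit the
distance evaluation, which keeps 601-fingerprint censuses at seconds.
Cluster representatives are the median-period members; cluster ids are
ordered by period rounded to 0.01 h, then by mean amplitude — the rounding
matters because exactly degenerate periods (β = 0) would otherwise be
ordered by float noise.

## Protocols

**Onset sweep** (`onset_sweep`): the free-running pair is integrated once;
states at each onset time on the inclusive grid (reference: 1000 → 1030 h
by 0.05 h, 601 runs) seed coupled integrations. Per run the transient
(default 40 putative cycles of the slower free period, 960 h) is discarded
and 15 cycles are analysed; locked periodic runs are fingerprinted and
clustered; the census reports per-mode counts, basin fractions and the
none/mono/bi/tri/higher classification. Unlocked runs are sub-labelled
`unsynchronized` (each limb periodic, quasiperiodic composite),
`complex_periodic` or `aperiodic`.

**Synchronization diagram** (`synchronization_diagram`): an onset sweep per
(v_sw, K_ICdk1) cell with a coarser onset grid (default 31 points over the
same 30 h window — the full 601-point grid per cell is cost without
information for region classification). Mode identity across cells comes
from jointly re-clustering all cell representatives, so the period
surfaces are globally consistent. Cell failures are recorded, never fatal.

**Hysteresis** (`hysteresis_sweep`): stepwise up-ramp then down-ramp with
state carry-over and fingerprinting at each step; the disagreement window
(branch distance above the cluster threshold) evidences coexistence. The
backward branch can be started from a supplied state (`y0_backward`)
because carry-over alone cannot reach an attractor the forward branch never
visited — exactly the situation in the saddle-node fixture, where the
forward branch stays on the inner cycle throughout. Loss of oscillation is
recorded as a steady-state fingerprint.

**Arnold map** (`arnold_map`): per (forcing period, amplitude) cell the
forced model runs from several phases of the free cycle; verdicts are p:q
locks of the response to the drive, cells with phase-dependent verdicts are
flagged as tongue overlap (coexisting entrainment modes). The default
amplitude grid starts at 0 as a built-in null row.

**Pulse map** (`pulse_switch_map`): from a source cycle, a pulse of each
magnitude at each phase (phase 0 anchored like fingerprints, at the
upward half-range crossing); destinations are assigned by nearest reference
fingerprint. The zero-magnitude row must return the source mode — a
self-test of the assignment machinery.

## Numerical choices

* Tolerances rtol 10⁻⁸ / atol 10⁻¹⁰, lsoda (switches to BDF in the stiff
  mitotic phases), dense output at 0.05 h. Halving tolerances moves
  reported periods by far less than the 0.01 h reporting precision
  (asserted in tests).
* Coupling onset and pulses are handled by stopping and restarting the
  integrator at the event time — never by a discontinuous right-hand side
  inside one adaptive step — so error control survives the event.
* The shipped models carry compiled (C) right-hand sides used through
  deSolve's compiled-code interface; the generic R-closure path remains for
  user models and is asserted to agree with the compiled path to < 10⁻⁵.
  Interpreted integration is ~100× slower, which matters at 601 runs per
  sweep.
* Negative concentrations abort integration (no silent clipping); pulses
  that would push a concentration negative are validation errors.
* Census initial conditions should avoid sitting exactly on unstable
  invariant circles, where the basin assignment is mathematically
  undefined; grids in tests and the acceptance script are chosen off those
  circles.

## What the generator emulates — and what it does not

The stand-ins reproduce the architecture of the published phenomenon (the
two coupling limbs, the free periods 24 h and 19.1 h, the onset-time basin
sampling) and a genuine mono-synchronization regime, as well as complex
periodic and aperiodic failure regimes at unfavourable coupling. They are
*not* the 62-variable model: its multi-synchronization windows (two or
three coexisting locked modes at one parameter point, with periods such as
22.99/23.52/26.43 h) live in a parameter geometry this 7-variable stand-in
pair is not guaranteed to share, and we have not located a bi- or
tri-synchronization window for it. Multi-mode censusing is therefore
exercised and validated on the analytic normal form, where coexistence is
exact and countable; the coupled-system machinery is identical code. Runs
with the full model are supported through the plugin contract. Molecular
noise, delays and stochastic switching between coexisting modes are out of
scope throughout.

Passing tests show that the *instruments* are correct (periods to 0.01 h,
censuses matching closed-form basins and periods, hysteresis windows to one
grid step); they do not show that any particular biological system is
multi-synchronized — that conclusion always requires the detailed model of
the system in question.

## Problem sizes

The test suite integrates ~10⁴ model-hours overall (about two minutes on
one CPU): censuses use 15–20 initial states × 400 h; the reference onset
sweep runs 601 × 1320 h of the 7-variable coupled system; the entrainment
map 12 × 5 × 2 runs × 900 h of the 3-variable clock. The acceptance script
re-runs the same protocols in about a minute.
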