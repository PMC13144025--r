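---
title: "The cruspark model: stochastic RyR2/IP3R2 calcium sparks on a dyadic lattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cruspark model: stochastic RyR2/IP3R2 calcium sparks on a dyadic lattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cruspark)
```

## The model

`cruspark` simulates local sarcoplasmic-reticulum (SR) Ca2+ release — Ca2+
sparks — from a single cardiac calcium release unit (CRU). The spatial
domain is the dyadic cleft, discretised as a lattice of 30 nm x 30 nm
sub-volumes of 1.8e-14 uL each (a ~20-nm cleft height). Each lattice site
may hold one channel: a type-2 ryanodine receptor (RyR2) or a type-2 IP3
receptor (IP3R2), both releasing Ca2+ from a junctional-SR (JSR)
compartment of matching sub-volume into the dyadic space.

Two coupled pieces advance on one fixed time step:

**Fields.** Dyadic and JSR [Ca2+] obey 2D reaction-diffusion equations
solved with an explicit Euler / 5-point Laplacian scheme. The dyadic field
gains channel fluxes `J = n_open * P * (c_jsr - c_ds) / V_ds` for each
channel species, net release from three explicit buffers (calmodulin,
sarcolemmal membrane, SR membrane; mass-action on/off kinetics), and
diffusion with coefficient `d_myo`. The JSR field loses the channel
fluxes and gains luminal diffusion plus first-order refill
`(ca_nsr - c_jsr) / tau_refill` from a fixed network-SR store (850 uM,
8 ms); the whole JSR right-hand side is scaled by a constant rapid
buffering factor `beta` that stands in for calsequestrin binding.

**Channels.** RyR2s are two-state and stochastic: a closed channel opens
with probability `dt * k+ * exp(EJ * num_net)` where
`k+ = kplus_max * c_ds^4 / (c_ds^4 + K_r^4)` is Hill-type in local dyadic
Ca2+ against a luminally regulated threshold
`K_r = max(k_r_max - alpha_r * c_jsr, 1 uM)`, and `exp(EJ * num_net)` is
allosteric coupling to the 4-connected RyR2 neighbours (`num_net` = open
minus closed neighbours for an opening transition, negated for closing, so
coupling favours conformity). Open channels close with probability
`dt * k- * exp(EJ * num_net)`. IP3R2s follow a six-state Markov model with
two modes: a low-open-probability *park* mode (states 4-5, open state 5)
and a high-open-probability *drive* mode (states 1, 2, 3, 6, open state 6),
connected by Ca2+- and IP3-dependent intermodal rates `q24` and `q42`; all
other rates are fixed constants (`q12` = 1.14 ms^-1 ... `V42` =
100 ms^-1). IP3R2s carry no allosteric coupling.

A trial starts from rest (dyadic Ca2+ at `c_rest` = 0.1 uM, JSR at
850 uM, buffers equilibrated, IP3R2 states drawn from their stationary
law), forces one RyR2 open at t = 0 (centermost by default), and runs for
200 ms. A trial counts as a spark when the peak simultaneous open-channel
count (RyR2 + IP3R2) exceeds 5; spark *fidelity* is the fraction of
qualifying trials. Morphology metrics are the Ca2+ mass (trapezoidal area
under the total release current, pA*ms = fC), the spark duration (time
between the 10%-of-maximum crossings of the spatially averaged dyadic
Ca2+ trace, linearly interpolated and baseline-corrected at the first
sample), and the maximum simultaneous open count. Episodes in which all
channels close and reopen later count as separate sparks; two or more
qualifying episodes in one trial form a *multi-spark*.

## Geometries

Healthy (control) CRUs place RyR2s on a centred checkerboard — nearest
neighbours on the 42.4-nm diagonal, never edge-sharing. Heart-failure-like
CRUs emulate the cluster fragmentation and dispersion seen by
super-resolution imaging of failing myocytes: `make_fragmented()` grows
compact 4-connected blobs around seed points spaced by `spread`, keeping a
minimum inter-cluster gap (default 120 nm) so the requested cluster count
survives the 100-nm linking criterion of `compute_stats()`. IP3R2s are
interspersed uniformly at random over free sites within the RyR2 bounding
box (+1 site), re-randomised per trial in the batch protocols. The
generators *emulate the statistics* of imaged CRUs (fewer channels per
cluster, shorter nearest-neighbour distances in HF); they do not
reproduce any particular imaged CRU, and raw super-resolution image
processing is out of scope. Externally derived channel maps can be
supplied through the `kind,ix,iy` CSV interface.

## Parameters and provenance

`param_registry()` tabulates every constant with units and a provenance
tag. Three groups:

* **Printed model constants**: the nine fixed IP3R2 rates, the
  single-channel currents (0.16 pA RyR2, 0.05 pA IP3R2, both specified at
  an 850-uM JSR-to-dyad gradient), the sub-volume 1.8e-14 uL, the NSR
  store (850 uM) and refill time constant (8 ms). Channel permeabilities
  are derived from the currents by `P = i / (2 F dC)`; the inverse map
  reproduces the currents exactly.
* **Literature-range values**: buffer kinetics (calmodulin 24 uM,
  sarcolemmal 900 uM, SR membrane 47 uM with standard on/off rates) and
  the Hill coefficient 4 for RyR2 activation.
* **Chosen / calibrated values**: the RyR2 gating constants and diffusion
  coefficients are not printed in the model description we implement
  (they live in an unavailable supplement), so the package ships its own
  calibrated defaults: `d_myo` = 0.1 um^2/ms and `d_jsr` = 0.35 um^2/ms
  (free-Ca2+ range; luminal diffusion enters scaled by `beta` = 0.2),
  `kplus_max` = 0.12 ms^-1, `kminus` = 1.0 ms^-1, `k_r_max` = 155 uM with
  `alpha_r` = 0.1294 (so K_r(850 uM) = 45 uM), `EJ` = 0.1. The
  calibration targets were behavioural: a resting CRU must be quiescent
  (opening rate ~1e-15 ms^-1 at rest), sparks must terminate by JSR
  depletion well inside a 200-ms trial, and forcing one RyR2 open in a
  50-RyR2 checkerboard must yield spark fidelity of order 10-25%. With
  the defaults the baseline fidelity is ~0.13, spark mass ~7 fC and
  duration ~30-40 ms. The steep luminal dependence (large `k_r_max`,
  large `alpha_r`) is what terminates sparks: as local JSR depletes, K_r
  rises past the dyadic Ca2+ a channel actually sees and the recruitment
  cascade starves.

### The IP3R2 intermodal parameterization

The six-state model's intermodal rates are
`q24 = a24 + V24 (1 - m24 h24)` and `q42 = a42 + V42 m42 h42`. The
published closed forms for the gates were not available to this
implementation, so `cruspark` ships its own Hill-form parameterization,
isolated in `ip3r_modal_gates()` so it can be swapped in one place:
activation gates `m` rise with Ca2+ (half-points 1 uM), inactivation
gates `h` fall (half-points 50 and 80 uM), the parking rate `a24` falls
with IP3 and the recruiting rate `a42` and the drive-recruitment gate
`g` (folded into `m42`) rise with IP3. `g` and `a42` are quartic in IP3
so that the drive mode is essentially inaccessible at trace IP3 but
fully recruited at 10 uM. The free constants were calibrated once
against the behaviour the model description states: open probability
biphasic in Ca2+, peaking between 1 and 10 uM Ca2+ at [IP3] = 1 uM and
at or below 100 uM Ca2+ at [IP3] = 10 uM, higher peak P_O at higher
IP3, park-mode P_O ~1e-3 and drive-mode P_O ~0.68 (both fixed by the
printed rate table), and no opening at all without IP3. A consequence of
the quartic IP3 gates is that at the 0.1-uM basal IP3 of the standard
protocols the IP3R2 contribution to spark statistics is small; the
IP3R2-count trend is strongest at 1-10 uM IP3.

Two printed inconsistencies are resolved the physically consistent way:
the equation for `q42` prints `V24` where the constant table and text fix
`V42` = 100 ms^-1 (implemented with `V42`), and the buffer-flux equation
as printed would make Ca2+ binding a *source* of free dyadic Ca2+
(implemented so binding removes free Ca2+).

## Numerical choices

* **Time step.** One shared `dt` for channels and fields, auto-derived as
  the minimum of the diffusion stability bound
  `0.5 dx^2 / (4 max(d_myo, beta d_jsr))` and the gating guards (worst-case
  per-channel transition probability <= 0.1). With defaults this gives
  `dt` ~ 1e-3 ms; both guards are enforced, and a user-supplied `dt` that
  violates them is rejected before the run starts. Halving `dt` changes
  spatially averaged trajectories by well under 1%.
* **Boundaries.** The dyadic rim is Dirichlet at `c_rest` — the escape
  path to bulk cytosol without which sparks could not collapse — and the
  JSR rim is no-flux. Both are configurable; the closed (no-flux,
  refill-off, `beta` = 1) configuration conserves total Ca2+ to
  round-off and is used by the conservation tests.
* **Stochastics.** One uniform draw per channel per step, from two
  independent deterministic streams (RyR2 and IP3R2) seeded from the
  trial seed, so a trial is bit-reproducible from (seed, config,
  geometry) and an IP3R2-free trial is bit-identical to the same-seed
  trial whose IP3R2s can never open (e.g. at [IP3] = 0). Per-trial seeds
  in the batch protocols derive from (base seed, condition index, trial
  index).
* **[IP3] = 0.** The channel cannot open without IP3: at exactly zero
  IP3 the IP3R2s are held in the closed park state and conduct nothing.
  (The stationary solver flags the chain as reducible and returns the
  mode-restricted law.)
* **Detection rule.** "Triggered at least 4 other channels" and the
  printed threshold `> 5` differ by one channel; the printed formula
  (peak simultaneous open count > 5) is the default and the `>= 5`
  reading is a config switch. The open count is the instantaneous
  simultaneous total, not a cumulative count of distinct channels.
* **Duration metric.** The 10% threshold is applied to the spatially
  averaged dyadic trace (a fluorescence-like proxy; the spatial maximum
  is available as an option) after subtracting the first-sample baseline,
  with linear interpolation of the crossings.
* **Rounding.** Fractional IP3R2 counts (e.g. 25% of 50 RyR2s) round
  half-up: 12.5 -> 13.

## What the tests do and do not show

The test suite checks the machinery against independent oracles at small
scale: exhaustive neighbour scans, union-find / graph-component cluster
oracles, binomial and matrix-exponential laws for 1-2 channel systems,
closed-form buffer and refill relaxation, exact Ca2+ conservation, MSD =
4Dt diffusion, run-length and quadrature oracles for the spark metrics,
and bit-reproducibility. The trend experiment runs at reduced scale (50
trials per condition, N_IP3R in {0, 2, 5, 10} at [IP3] = 10 uM on the
50-RyR2 checkerboard, full 200-ms trials) and checks the rank
correlation of fidelity with IP3R2 count plus the exact no-IP3
invariance. The full protocol sizes (100-500 trials per condition, the
full condition grids) are the package defaults and run unattended in
minutes-to-hours; results in hand were produced at the reduced scale.

Passing these tests shows the simulator implements the stated model
faithfully at the shipped parameters. It does not show that the shipped
parameters reproduce any particular measured myocyte: the geometries are
synthetic emulations, the RyR2 constants and the IP3R2 modal gates are
calibrated stand-ins, and quantities that depend on them (absolute
fidelities, masses, durations, multi-spark counts) should be read as
model behaviour, not as predictions for a specific preparation.

## Known limitations

* 2D single-CRU domain: no inter-CRU coupling or wave propagation.
* Triggering is by forced RyR2 opening only; there is no L-type channel
  and no sarcolemmal Ca2+ entry, no SERCA dynamics beyond the first-order
  refill, and no RyR2 phosphorylation/oxidation modifiers.
* `beta` is a constant; saturable luminal buffering is not modelled.
* IP3 is a constant input; production and degradation are out of scope.
* Multi-spark counts at baseline are small but nonzero with the shipped
  parameters; the lingering dyadic Ca2+ after termination decays slowly
  (buffered diffusion to the rim), which makes re-ignition somewhat more
  likely than in preparations where bulk escape is faster.
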