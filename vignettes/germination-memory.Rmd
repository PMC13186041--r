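---
title: "A minimal kinetic network for spore germination memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A minimal kinetic network for spore germination memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`sporemem` simulates nutrient-triggered germination of *Bacillus subtilis*
spores with the smallest network that reproduces population-level memory of
germinant exposure. Per spore there are five molecular species
(copies/spore): inactive and active germinant receptors (`Ri`, `Ra`) and
SpoVA channels in three states — closed inactive (`Cc`), closed activated
(`Cca`) and open (`Co`). Germinant at concentration `S(t)` (mM) converts
`Ri` to `Ra` reversibly; active receptors activate closed channels;
activated channels open; and open channels promote further opening through a
cooperative Hill term, balanced by first-order closure:

$$\frac{dC_o}{dt} = k_3 C_{ca} + k_4\frac{C_o^n}{C_o^n+\theta^n} - k_5 C_o.$$

With `n > 1` the production/decay balance is bistable: a low branch where a
few open channels linger and decay, and a high branch near the full channel
complement. A germinant pulse pushes some spores' `Co` past the unstable
point, after which opening is autocatalytic and irreversible — the model's
notion of commitment. Spores left *below* the unstable point keep a slowly
decaying stock of open channels (`β = k5 + k2·Ra` is small), so a second
pulse starts from a primed state and triggers spores the first one could
not. That sub-threshold persistence, plus incompletely relaxed `Ra`, is the
memory. The generic one-variable switch behind this design is exposed in
`switch_fixed_points()`.

Germination of a spore is declared when `Co` first reaches a threshold
(default 50 copies/spore); that crossing time is `T_open`, the model proxy
for the onset of rapid CaDPA release. The threshold value is an arbitrary
but fixed convention: nothing pins it experimentally, and the bistable
blow-up is so fast that any threshold between a few tens and a few thousand
channels gives nearly identical crossing times.

Each spore is deterministic. All population heterogeneity enters through
the initial receptor count `Ri0`, drawn once per spore from a gamma
distribution (shape `a`, scale `b`) — the empirically observed form for
low-copy membrane proteins — while the channel complement is fixed at
`c_total = 6500` for every spore. A percentage-germination curve is the
cumulative distribution of `T_open` over the ensemble; spores that never
cross have infinite `T_open` and stay in the denominator.

## Parameters and units

The system is solved in minutes, mM and molecules/spore. No units are
attached to the rate constants by the original formulation; they are fixed
here by the protocol timings (minutes) and germinant concentrations (mM),
and documented as an assumption. Exponent notation is read literally in
these units (`k4 = 195e2` is 19500 molecules/min).

| parameter | default | units | role |
|---|---|---|---|
| `k1` | 14e-3 (wild type), 350e-5 (10 mM L-valine fits) | mM⁻¹ min⁻¹ | germinant binding |
| `k_minus1` | 100e-3 | min⁻¹ | receptor deactivation |
| `k2` | 25e-7 | molecule⁻¹ min⁻¹ | GR → channel activation |
| `k3` | 60e-3 | min⁻¹ | activated-closed → open |
| `k4` | 195e2 | molecules·min⁻¹ | maximum cooperative opening rate |
| `k5` | 305e-2 | min⁻¹ | open-channel closure |
| `n` | 3 | — | Hill coefficient (cooperativity) |
| `theta` | 20 | molecules | Hill half-saturation |
| `c_total` | 6500 | molecules | SpoVA channels per spore |
| `germination_threshold` | 50 | molecules | defines `T_open` |

`preset_config()` bundles the four canonical study conditions:
`valine_memory` (gamma mean 1100 / sd 220, two 5-min 3.5 mM pulses at 0 and
30 min), `wt_broad` (exponential distribution `a = 1`, `b = 1100`, two
2-min 10 mM pulses), `gera_over` (`a = 67`, `b = 50`, mean 3350, same
pulses) and `gr_scan` (uniform 600–1800 receptor axis, step 50). The
`valine_memory` gamma parameters are not free: they are the unique solution
of mean `= ab = 1100` and sd `= √a·b = 220`, giving `a = 25`, `b = 44`.

Note the high fixed point of the open-channel dynamics is `k4/k5 ≈ 6394`
(Hill term saturated), so germinating trajectories plateau just below the
nominal 6,500-channel complement; the quoted "plateau at 6,500" is the
complement itself, which the curve approaches to within ~1.6%.

## What the ensemble generator emulates — and what it does not

`run_ensemble()` reproduces the *in silico* experiment design: 500
independent gamma draws of `Ri0`, identical kinetics and channel numbers
across spores, one deterministic ODE solve per spore. It captures
germination heterogeneity that is attributable to receptor copy-number
variation, and nothing else. Real spore populations add measurement noise,
spore-to-spore variation in channel numbers and rate constants, GR subtype
mixtures (GerA/GerB/GerK are not distinguished here), cortex-lytic enzyme
kinetics downstream of CaDPA release, and commitment phenomena at the
microscopy level. A passing ensemble test therefore shows that the network
plus gamma heterogeneity reproduces the published population curves — not
that these other sources of variability are negligible.

Because ensemble observables are single 500-draw Monte Carlo realizations,
they carry binomial sampling error (± roughly 2 percentage points at one
standard error for mid-range fractions). Reproduction tests use a ±3-point
band around published values, read as a closed interval, with the seed fixed
in advance; published single-cycle values can themselves sit a standard
error or two from the model's asymptotic expectation.

## Numerical choices

* **Integration.** `deSolve::lsoda`, relative and absolute tolerance 1e-8,
  restarted at every pulse edge so the square-wave input never sits inside
  an adaptive step. Output grid 0.05 min for single spores and scans,
  0.1 min inside ensembles (the crossing refinement below keeps `T_open`
  resolution independent of the output grid).
* **Threshold crossing.** First output point with `Co ≥ threshold` brackets
  the crossing; the bracketing interval is re-integrated at 0.002-min
  resolution and interpolated linearly, giving `T_open` to well under the
  0.01-min contract. The comparison is `≥` (closed); at solver resolution
  the distinction from strict `>` is invisible.
* **Classification.** A crossing before the second pulse starts is
  `first_pulse`; at or after it, `second_pulse` (a crossing inside the
  second pulse window counts as second-pulse — subpopulations are split by
  which pulse triggers them). `T_lag = T_open − T_block` is computed
  against the end of the most recent pulse that started before the crossing.
* **Release-interval proxy.** Experiments measure the rapid-release
  interval via CaDPA; the model has no efflux flux, so
  `release_interval()` reports the time from threshold crossing to `Co`
  first reaching 95% of `c_total`. This is an operationalization, not a
  published formula.
* **Conservation.** `Ri + Ra` and `Cc + Cca + Co` are conserved by
  construction of the right-hand side; trajectories hold both sums to
  better than 1e-6 of the channel complement, which doubles as a solver
  health check.
* **Hill term at the origin.** Defined as exactly 0 at `Co = 0` (and `Co`
  is clamped at 0 inside the Hill evaluation against tiny solver
  undershoots), so the dormant state is an exact fixed point.
* **Fixed-point analysis.** `switch_fixed_points()` scans
  `[0, (P+ks)/kd]` on a 4000-point grid for sign changes of the net rate
  and refines each bracket with `uniroot`; stability is the sign of a
  centred numerical derivative. Steady-state analysis only — the full
  dynamics live in the five-state system.

## Design decisions on genuinely open points

* **Pulse spacing for 2-min pulses.** "Separated by 30 min" is read
  start-to-start (pulses [0,2] and [30,32]), matching the explicit
  "0 < t < 5 and 30 < t < 35" convention of the 5-min experiments. The
  gap-of-30 reading ([0,2], [32,34]) would add two minutes of memory decay
  before the second pulse.
* **Horizon.** 60 min, covering both pulse responses; the corresponding
  experiments ran 60–90 min.
* **"Approaches 68%".** The cumulative curve value is measured at the
  horizon and as a percentage of the *whole* population (CDF reading); the
  alternative "68% of remaining spores" reading is not used. The
  first-pulse asymptote is measured at the second-pulse start.
* **First-pulse band.** For the receptor scan, the wider quoted band
  (first-pulse germination from 1400 up to 1800 GRs/spore) is adopted over
  the narrower 1400–1600 variant.
* **Alternative memory regime.** With `k_minus1 = 225e-3` and
  `k2 = 45e-7` (other constants unchanged) active receptors relax to
  < 1% of their first-pulse peak before t = 30, yet mid-band spores
  (~1050–1280 receptors) still germinate only after the second pulse: the
  memory is then carried entirely by sub-threshold open channels. The
  second-pulse band's edges shift relative to the default regime, so the
  property is tested in the middle of the band, not at its edges.
* **Membrane geometry.** The ellipsoid area formula `2π(s² + ls)` with the
  default semi-axes (l = 837, s = 554 nm) gives 4,841,911 nm², ~0.13% above
  the published 4,835,800 nm²; both are exposed and the published value can
  be passed via `A_im` to reproduce the published density (744 nm² per
  channel) exactly. The germinosome patch radius defaults to 400 nm, which
  reproduces the published patch area of 502,655 nm² even though a 300-nm
  fluorescence FWHM is also quoted; the radius is an explicit argument, not
  a hidden constant. The channel capacity is reported as a ceiling ("at
  most").
* **Continuous copy numbers.** Gamma draws and state variables are
  continuous reals; the deterministic mass-action equations make no use of
  integrality, so no rounding is applied anywhere.

## Problem sizes

Ensembles use the standard 500-spore cycle; the receptor scan is 25
deterministic solves; oracle cross-checks in the test suite run a fixed-step
RK4 at dt = 0.001 min over the 60-min horizon. The full test suite and the
reproduction script each run in a few minutes on a single CPU.

## Known limitations

The model stops at channel opening: no CaDPA efflux flux, no cortex-lytic
enzyme stage, no distinction among GR subtypes or germinants, no stochastic
channel gating (heterogeneity is entirely receptor-copy-number driven), and
no spore-to-spore variation in rate constants or channel numbers. Rate
constants are effective values chosen to reproduce double-pulse curves;
other parameter combinations can produce the same qualitative memory, and
the binding/unbinding constants in particular are not experimentally
anchored.
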