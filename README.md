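# sporemem

Kinetic network model of memory in *Bacillus subtilis* spore germination.

Dormant spores germinate when nutrient germinants (e.g. L-valine) bind
germinant receptors (GRs) in the spore inner membrane; the signal is relayed
to SpoVA channels whose opening releases the spore's CaDPA depot and commits
the spore to germinate. Spore populations show **memory**: after a short
germinant pulse that triggers only part of the population, a second identical
pulse 30 min later triggers far more spores than the first one did.

`sporemem` implements a minimal deterministic network that reproduces this
behaviour, for microbiologists and modellers studying germination
heterogeneity and commitment. Five state variables per spore (copies/spore):

* `Ri`, `Ra` — inactive / active germinant receptors,
* `Cc`, `Cca`, `Co` — closed, activated-closed and open SpoVA channels,

coupled by mass-action kinetics with a cooperative positive feedback on
channel opening:

```
dRi/dt  = -k1*S*Ri + k-1*Ra
dRa/dt  = +k1*S*Ri - k-1*Ra
dCc/dt  = -k2*Ra*Cc - k4*Co^n/(Co^n + θ^n) + k5*Co
dCca/dt =  k2*Ra*Cc - k3*Cca
dCo/dt  =  k3*Cca + k4*Co^n/(Co^n + θ^n) - k5*Co
```

`S(t)` is a square-wave germinant input (mM). The Hill term (`n = 3`,
`θ = 20`) makes the open-channel count bistable: sub-threshold open channels
decay slowly after a pulse (rate `β = k5 + k2*Ra`), and that persistent
sub-threshold activation *is* the memory that primes the second pulse. A
spore germinates when `Co` first reaches 50 copies (`T_open`). Population
heterogeneity comes solely from gamma-distributed initial GR copy numbers
(shape `a`, scale `b`; mean `ab`, sd `√a·b`); a percentage-germination curve
is the cumulative distribution of `T_open` over a 500-spore ensemble.

## Worked example: the double-pulse memory experiment

Two 5-min pulses of 3.5 mM germinant at t = 0 and t = 30 min, GR copy
numbers gamma-distributed with mean 1100 and sd 220:

```r
library(sporemem)

cfg <- preset_config("valine_memory", n_spores = 500, seed = 1)
res <- run_ensemble(ensemble_config(cfg$gamma, cfg$params, cfg$protocol,
                                    n_spores = 500, seed = 1))
res
#> Ensemble of 500 spores (seed 1):
#>   first_pulse       71  (14.2%)
#>   second_pulse     262  (52.4%)
#>   no_germination   167  (33.4%)

pulse_summary(res)[c("first_window_pct", "horizon_pct")]
#> $first_window_pct
#> [1] 14.2
#> $horizon_pct
#> [1] 66.6

res$fit
#> Gamma MLE fit: shape 24.9137 [21.8459, 27.9815], scale 44.3285 [38.8147, 49.8422]
#>   estimated mean 1104.4, sd 221.3 molecules/spore
```

About 14% of spores germinate on the first pulse, but 52% more follow the
second, identical pulse — the ~4-fold memory effect. A single spore with
1500 receptors germinates already during the first-pulse response:

```r
tr <- integrate_spore(1500, cfg$params, cfg$protocol)
tr
#> Spore trajectory: Ri0 = 1500, 1201 time points over [0, 60] min
#>   T_open = 13.366 min (Co >= 50)
release_interval(tr)   # minutes from threshold to ~full channel opening
#> [1] 1.104822
```

Deterministic receptor scans (`gr_copy_scan`) recover three contiguous
subpopulations on the 600–1800 axis: no germination up to 950 GRs/spore,
second-pulse-only germination from 1000, first-pulse germination from 1400.
Closed-form reductions are available as calculators, e.g. the steady-state
active-receptor occupancy `k1*S/(k-1 + k1*S)`:

```r
100 * steady_state_occupancy(350e-5, 10, 100e-3)
#> [1] 25.92593
im_geometry(A_im = 4835800)$germinosome_capacity  # channels in a germinosome
#> [1] 676
```

A thin command-line wrapper is installed at `inst/scripts/germsim.R`
(subcommands `simulate`, `ensemble`, `scan-gr`, `scan-conc`, `scan-var`,
`analytic`, `compare`).

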