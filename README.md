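# zipkinetics

Kinetic modelling of the bivalent interaction between the ZBP1
(IMP1/IGF2BP1) KH3-KH4 di-domain and the bipartite beta-actin Zipcode RNA.

ZBP1 localises beta-actin mRNA by binding a 28-nt Zipcode element through
two KH domains that recognise two distinct short sequences on the same RNA.
Individually the domains bind weakly (Kd ~ 1 uM); coupled, they reach
~20 nM. The package implements the six-species mass-action network that
explains this avidity: either domain binds first (`R + P <-> C3` or `C4`),
then the free domain captures its site intramolecularly, looping the RNA
into a closed complex (`C3 <-> CC <-> C4`), or a second protein occupies
the free site (`C3/C4 + P <-> D`, a 2:1 complex). The intramolecular
ring-closure rates are derived from the measured single-domain kinetics and
the overall dissociation constant:

    kC3 = Kd4 * koff3 / Kd_overall,   kC4 = Kd3 * koff4 / Kd_overall,

which automatically satisfies detailed balance (`kC4/kC3 = kon4/kon3`).
The effective off-rate of the closed complex under wash-out follows the
escape approximation `koff3*koff4/(koff3 + kC4) + koff3*koff4/(koff4 + kC3)`.

It is intended for quantitative RNA-protein biochemists and modellers who
want to simulate bivalent (avidity-driven) binding, derive looping rates
from measurable constants, and fit BLI sensorgrams with the standard 1:1
Langmuir workflow (kobs slope -> kon, response titration -> Kd,
koff = Kd*kon with a direct dissociation cross-check).

## What's inside

* `kinetic_parameters()`, `derive_closing_rates()`,
  `cycle_consistency_ratio()`, `effective_dissociation_rate()` — the
  reaction scheme and its analytic companions;
* `simulate_timecourse()`, `run_to_equilibrium()`,
  `dissociation_timecourse()` — fixed-step fourth-order Runge-Kutta
  integration (compiled core) with stability validation and a clamped
  wash-out protocol;
* `steady_state_solve()`, `detailed_balance_state()`, `apparent_kd()`,
  `protein_sweep()`, `closing_rate_sweep()` — algebraic equilibria and the
  concentration / closure-rate sweeps;
* `exponential_fit()`, `kon_from_kobs()`, `kd_from_responses()`,
  `analyze_bli_dataset()` — the BLI kinetic-fitting pipeline;
* `simulate_sensorgram()`, `generate_bli_dataset()` — seeded synthetic
  sensorgrams with known ground truth for parameter-recovery studies;
* `load_config()`, `run_scenario()` and a thin CLI
  (`inst/cli/zipkinetics.R`) for reproducing the named simulation
  scenarios from YAML/JSON configs with unit-tagged values.

## Worked example

```r
library(zipkinetics)

d <- zipcode_defaults()   # measured rates + cellular concentration estimates
eq <- run_to_equilibrium(d$params, d$conditions,
                         integrator_settings(t_end = 1000))
eq
#> Equilibrium summary
#>   fraction bound      = 0.9067
#>   apparent Kd         = 2.054e-08 M (20.5 nM)
#>   time to equilibrium = 129.8 s
#> Species state (M):
#>           R           P          C3          C4          CC           D
#> "3.731e-11" "1.996e-07" "4.858e-12" "8.022e-12" "3.488e-10" "1.044e-12"
```

At 0.2 uM protein and 0.4 nM RNA, 91% of the RNA is bound and nearly all
of it (0.349 of 0.363 nM bound) sits in the looped closed complex `CC`;
the apparent Kd of ~20.5 nM emerges from micromolar single-domain
affinities purely through the ring-closure coupling. Equilibrium is
reached at ~130 s.

```r
ds <- generate_bli_dataset("didomain", noise_sd = 0, seed = 1)
analyze_bli_dataset(ds$sensorgrams)
#> BLI kinetic analysis (1:1 Langmuir)
#>   kon            = 1.6e+05 1/(M*s)
#>   Kd             = 2.062e-08 M (20.6 nM)
#>   koff = Kd*kon  = 0.0033 1/s
#>   koff (direct)  = 0.0033 1/s  [accuracy confirmed]
#>   Rmax           = 1 RU
```

The pipeline recovers the generator's ground truth exactly on noiseless
data; the two independent koff routes agree, as the cross-check flag
reports.

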