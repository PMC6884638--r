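# helixkin

Kinetic modelling of helix-catalyzed N-carboxyanhydride (NCA) ring-opening
polymerization.

## The problem

Polypeptides grown from NCAs in low-dielectric solvents (dichloromethane and
the like) polymerize with two-stage kinetics: slow growth while the chain is
a random coil, then strong acceleration once it folds into an alpha-helix.
The accepted mechanism is enzyme-mimetic — the dangling N–H hydrogen-bond
donors at the helical N terminus reversibly bind an incoming NCA, and the
ring-opening then proceeds inside the complex, a Michaelis–Menten cycle with
the helix terminus as active site. For anyone designing or analysing such
polymerizations, the practical questions are quantitative: what do conversion
curves look like as a function of initial monomer concentration `[M]0` and
feed ratio `[M]0/[I]0`, what molecular-weight distribution (MWD) and
dispersity should the product have, and can the rate constants be estimated
from multi-condition kinetic data?

`helixkin` answers these with a population-balance model over chains indexed
by degree of polymerization (DP). With `M` the monomer, `P_i` a chain of
DP `i` and `C_i` its helix–monomer complex:

    coil stage  (i <  s):  P_i + M --k1-->  P_{i+1}
    helix stage (i >= s):  P_i + M  <==>   C_i --kr--> P_{i+1}
                                kon / koff

The package provides:

- stiff ODE simulation of the full chain ladder (compiled right-hand sides,
  sparse stiff solver) with exact chain- and mass-conservation checks;
- conversion observables, dimensionless-time representation
  `tau = t*k1*[M]0`, and two-stage apparent rate constants;
- chain-length distributions with `DPn`, `DPw`, `Mn`, `Mw`, dispersity,
  short-chain mass fractions, Poisson references and GPC-like traces;
- an exact Gillespie stochastic counterpart used as validation oracle;
- a seeded synthetic-data generator emulating NMR-sampled conversion curves;
- global multi-dataset fitting with shared (`kr`, `s`) and per-dataset
  (`k1`, `K = kon/koff`) parameters, integer grid search for the critical
  helix length `s`, and residual-resampling bootstrap intervals.

## Worked example

```r
library(helixkin)

params <- rate_params(k1 = 0.02, kon = 10, koff = 2, kr = 0.2, s = 10)
ic     <- initial_conditions(M0 = 0.4, ratio = 100)
net    <- build_network(params, ic)

traj <- simulate_kinetics(net)          # runs to ~99.9% conversion
time_to_conversion(net, 0.98)
#> [1] 3046.383
apparent_rate_constants(conversion(traj))
#> Apparent rate constants: stage 1 = 0.03635, stage 2 = 0.4476 1/(M s)
#>   stage-2/stage-1 ratio = 12.3
mw_moments(chain_length_distribution(traj))
#> DPn = 99.99, DPw = 132.98; Mn = 22023, Mw = 29223 g/mol; D = 1.3269
#> short chains (DP < s): 1.14% by mass
design_mw(100)
#> [1] 22
```

Reading: at these constants the polymerization reaches 98% conversion in
~51 minutes, the helix stage runs ~12x faster than the coil stage in
apparent-rate terms, and the number-average molar mass lands on the 22.0 kDa
design target. The dispersity of 1.33 is a genuine prediction of this
parameter set: ~1% of the mass stalls as short coils (DP < 10) when the
accelerated stage outruns them, which inflates `Mw/Mn` above the near-Poisson
value of the single-stage mechanism.

Parameter estimation from a synthetic nine-condition panel
(`[M]0` = 0.2/0.3/0.4 M x ratios 50/100/150, noise sd 0.01):

```r
panel <- generate_panel(params, noise = noise_model(sigma_add = 0.01, seed = 1))
fit   <- global_fit(panel, fit_spec(s_grid = 8:12, n_starts = 4, seed = 1))
fit
#> Global two-stage fit: 9 dataset(s), SSE = 0.030123
#>   critical length s = 10 (grid 8..12)
#>    parameter dataset            label estimate
#> 1          s      NA           shared 10.00000
#> 2         kr      NA           shared  0.18416
#> 3         k1       1  M0=0.2|ratio=50  0.02038
#> ...
```

The critical length is recovered exactly and every per-dataset `k1` sits
within ~3% of the generating value 0.02; `binding_free_energy(5.4)` converts
a fitted `K` into kcal/mol for comparison with binding calculations.

A command-line front end wrapping the same functions lives in
`inst/cli/helixkin.R` (subcommands `simulate`, `mwd`, `generate`, `fit`,
`recover`).

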