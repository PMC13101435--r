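# perosense

**Degradation-as-signal digital twin for enzyme-coupled optical glucose
sensors.**

Halide-perovskite-inspired films are usually dismissed as too unstable for
deployment. `perosense` models the opposite design philosophy: let
controlled chemical degradation *be* the transduction mechanism. A thin
sensing film is functionalised with glucose oxidase (GOx); enzymatic
oxidation of glucose produces hydrogen peroxide, peroxide accelerates
oxidative breakdown of the film, and the glucose concentration is read out
as the *rate of optical signal loss*. The package is a screening-level
digital twin for scientists designing such sensors: it maps which
degradation kinetics, film geometries and read-out times give clinically
useful glucose discrimination, before any material is synthesised.

## Model

The intact fraction `C(t)` of the sensing layer decays as a
pseudo-first-order process whose rate is affine in glucose (mM):

```
k_deg(G) = k0 + kG·G,        C(t) = exp(−k_deg(G)·t)
S(t)     = S0·C(t)^β                      (optical read-out)
```

- `k0` (min⁻¹) — basal degradation; `kG` (min⁻¹·mM⁻¹) — the lumped
  glucose-to-degradation coupling; `β` — optical nonlinearity exponent.
- Rates are parameterised from two *design-target half-lives* via
  `t½ = ln 2 / k_deg`: a basal half-life at `G = 0` and an accelerated one
  at a reference glucose level.
- A transient GOx tier replaces the constant rate with
  `k(t) = k0 + α_H·H_s(t)`, where surface peroxide obeys
  `dH_s/dt = v(G) − k_cons·H_s` with Michaelis–Menten production
  `v(G) = Vmax·G/(K_M + G)`.
- A 1D reaction–diffusion tier resolves peroxide transport
  `∂H/∂t = D_H ∂²H/∂x² − k_cons·H` across the film thickness (explicit
  finite differences, CFL-limited step, ghost-point zero-flux substrate
  boundary) and averages `C(x,t)^β` into the macroscopic signal.
- Discrimination of two glucose levels under additive Gaussian signal
  noise `σ_S` uses the sensitivity index `d′(t) = ΔS(t)/(√2·σ_S)` and the
  optimal-threshold error `P_error = Φ(−d′/2)`.

## Worked example

The reference operating point targets a basal half-life of 480 min and an
accelerated half-life of 30 min at 200 mg/dL, with `β = 1.5`:

```r
library(perosense)

kin <- params_from_halflives(halflife_spec(480, 30, 200, units = "mgdl"),
                             beta = 1.5)
kin
#> <kinetic_params> k0 = 0.00144406 /min (basal t1/2 = 480 min),
#>                  kG = 0.00195121 /min/mM, beta = 1.5, S0 = 1

half_life(kin, mgdl_to_mM(70))   # 76.8  -> ~77 min at 70 mg/dL
half_life(kin, mgdl_to_mM(300))  # 20.4  -> ~20 min at 300 mg/dL

optimal_readout(kin, 100, 200, noise_model(0.02))
#> <pair_metrics> 100 vs 200 mg/dL: dS_max = 0.229 at t_opt = 38.9 min,
#>                d' = 8.09, error = 0.002604% (accuracy 100%)

mc <- monte_carlo_classify(kin, 100, 200, t_read = 30, N = 2000, seed = 1)
mc$accuracy
#> [1] 1
```

Reading: the two clinically distinct glucose levels 100 and 200 mg/dL
separate best about 39 min after exposure, where their signal difference
(0.23 on the normalised scale) is 8 noise units wide — a theoretical
misclassification probability below 0.01%, confirmed by a 2000-sample
Monte Carlo threshold classifier at a 30-min single-shot read-out.

The design-space scan ranks half-life/exponent combinations by the mean
error across the pairs (100,140), (140,200), (100,200) mg/dL within a
60-min read-out window:

```r
scan <- design_scan()
scan$best
#> <design_point> (t_base, t_ref, beta) = (480, 30, 1.5): avg error 1.38%
```

## Command line

```sh
perosense simulate    --out runs/sweep
perosense discriminate --seed 3 --out runs/disc
perosense film1d      --set "film.L_nm=300;run.t_max_min=90" --out runs/film
perosense calibrate   --input trajectories.csv --out runs/cal
```

(the script installs to `exec/perosense` inside the library; add it to
`PATH` or invoke it with `Rscript`). Commands: `simulate`, `gox-compare`,
`film1d`, `discriminate`, `montecarlo`, `design-scan`, `calibrate`. All
accept `--config FILE` (YAML), `--set key.path=value` overrides, `--seed`
and `--out`; every run writes a JSON run record so outputs are
reproducible bit-for-bit from (config, seed).

## Documentation

The methods vignette (`vignettes/degradation-sensing.Rmd`) describes the
model tiers, their assumptions, every tunable parameter with units and
defaults, the numerical schemes and tolerances, and the package's design
choices and limitations.
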