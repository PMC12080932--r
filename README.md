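# thrombosim

Multiscale simulation of donor-specific thrombus growth under flow, in R.

During thrombosis, platelets deposit on exposed collagen, activate, and
recruit more platelets through released agonists — a process shaped jointly
by hemodynamics, solute transport, stochastic adhesion, and each donor's
platelet signaling phenotype. `thrombosim` couples four solvers on one
voxel lattice to simulate this at desk scale:

* **Flow** — quasi-static incompressible Newtonian flow by the lattice
  Boltzmann method (BGK, D2Q9/D3Q19), with no-slip on walls and on every
  bound platelet, re-solved as the deposit grows.
* **Agonist transport** — finite-volume convection–diffusion–reaction for
  ADP and thromboxane A₂, with sources at activated platelets
  (first-order dense-granule ADP release, constant TXA₂ synthesis).
* **Platelet kinetics** — rejection-free lattice kinetic Monte Carlo:
  convective-diffusive motion (`D_p/dx² + max(0, u·ê)/dx`), flux-matched
  inlet insertion at 1.5×10⁵ μL⁻¹ with a marginated near-wall excess, and
  activation- and shear-dependent bonds
  `attach = k⁰ F W(γ)`, `detach = k⁰ F⁻¹ exp(γ/γ_c)/W(γ)`, where `W(γ)`
  is the von Willebrand factor switch across 3000–8000 s⁻¹.
* **Signaling** — per-platelet intracellular calcium from donor-specific
  feed-forward networks (two 12-node layers) driven by six agonist inputs
  (ADP, convulxin, thrombin, U46619, iloprost, GSNO) and calcium feedback
  at lags 1–128 s; activation state ξ(t) = ∫([Ca²⁺]ᵢ−[Ca²⁺]₀)dt maps to
  adhesiveness through a Hill function
  F(ξ) = α_min + (α_max−α_min) ξⁿ/(ξⁿ+ξ₅₀ⁿ), and dense-granule release
  fires when ξ crosses ξ_crit.

Because the human pairwise-agonist-scanning (PAS) calcium data behind the
original donor models are not public, the package ships a synthetic donor
generator: parameterized calcium responses to single and pairwise agonist
exposures with donor-to-donor heterogeneity, on which the networks are
trained and against which they are validated (the generator doubles as an
independent oracle). Scenario configurations cover agonist inhibition
(`no-adp`, `no-txa2`, `no-both`), endothelial antagonists (`gsno`,
`iloprost`) and wall tissue factor (`tf`, via a reduced thrombin curve).

## Worked example

```r
library(thrombosim)

# one synthetic donor -> PAS traces -> trained calcium surrogate
cfg   <- cohort_config()
donor <- generate_donor(cfg, seed = 101, cvx_multiplier = 2)
pas   <- simulate_pas_traces(donor, NULL, cfg, seed = 101)
model <- train_donor_nn(pas, training_seed = 101)
round(mean(model$validation$holdout_nrmse), 3)
#> [1] 0.086

# venous vessel, control scenario, 3 simulated minutes
hill <- hill_params(xi50 = 26, xi_crit = 79)
model$hill <- hill
cfgsim <- simulation_config(
  domain_spec("cylinder", spacing_um = 16, dim = 2),
  inlet_wall_shear = 200, donor = model, scenario = "control",
  duration = 180, seed = 42, hill = hill)
traj <- run_simulation(cfgsim)
compute_metrics(traj)[c("n_final", "tau_crit", "centroid_x_um")]
#> $n_final
#> [1] 50
#> $tau_crit
#> [1] 60
#> $centroid_x_um
#> [1] 240.64
```

50 platelets are bound after three minutes; the first dense-granule
release (collagen-driven) happens at 60 s — this strong responder sits at
the fast end of the one-to-four-minute activation span; and the deposit's
centroid sits at 241 μm, upstream of the collagen patch midpoint (250 μm)
— the venous deposition pattern. A full cohort study
(`generate_cohort()` → `train_donor_nn()` → `calibrate_thresholds()` →
`run_scenario_matrix()`) reproduces the scenario potency ordering
control ≥ no-TXA₂ ≥ no-ADP ≥ no-both, iloprost as the strongest
antagonist (no release for any donor), and higher deposition with wall
tissue factor for every donor.

A thin command-line front end over the same functions is installed at
`inst/cli/thrombosim.R` (`make-donors`, `calibrate`, `run`, `cohort`).
The methods vignette (`vignettes/thrombosim-methods.Rmd`) documents the
models, parameter choices and desk-scale limitations.

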