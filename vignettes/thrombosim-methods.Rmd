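---
title: "thrombosim: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{thrombosim: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`thrombosim` simulates platelet deposition and thrombus growth in small
voxelized vessels by coupling four solvers on one lattice: quasi-static
blood flow (lattice Boltzmann), soluble agonist transport
(finite-volume convection–diffusion–reaction), stochastic platelet motion
and adhesion (rejection-free lattice kinetic Monte Carlo), and
donor-specific platelet calcium signaling (small feed-forward neural
networks with lagged feedback). This vignette explains the models, the
parameters that matter, the numerical choices, and the limits of what the
desk-scale test suite demonstrates.

## Geometries and lattice conventions

Two vessel archetypes are built by `build_domain()`:

* a straight cylindrical (venous) vessel, 0.5 mm long and 0.12 mm in
  diameter, with a semicylindrical collagen patch 0.25 mm long centered on
  the wall, driven at an inlet wall shear rate of 200 s⁻¹;
* a stenotic (arterial) vessel, 1 mm long and 0.12 mm in inlet diameter,
  whose central 0.5 mm narrows smoothly (a C¹ cosine bump — standard in
  stenotic-flow modeling and free of voxel staircase corners) to 25% of the
  inlet flow area, expressing collagen over up to half its circumference,
  driven at 1000 s⁻¹.

Nodes are cell-centered at spacing `dx`; a node is fluid when its center
lies strictly inside the nominal boundary, so the bounce-back wall sits
half a link beyond the last fluid node. One platelet occupies one node.
In 2D mode the domain is the axial–radial center plane of the 3D vessel,
so the 75% area reduction appears as a halving of the local gap. Flow is
along +x; node indices are 0-based in physical coordinates.

## Flow

Blood is incompressible and Newtonian (kinematic viscosity
3.1×10⁻⁶ m²/s). The BGK lattice Boltzmann solver (D2Q9/D3Q19) applies
full-way bounce-back on walls and bound platelets, a prescribed
parabolic/Poiseuille profile at the inlet whose wall shear rate is the
configured value, and non-equilibrium extrapolation boundaries (imposed
velocity with extrapolated density at the inlet; imposed reference density
at the outlet). The local shear-rate magnitude is computed from the
non-equilibrium moments, not by differencing velocities; the test suite
cross-checks it against a centered finite-difference oracle.

Two numerical choices matter:

* **Mach-targeted time step.** These flows are steady and at Reynolds
  numbers of order 0.1–2, so the solver chooses its time step to map the
  fastest expected velocity to a target lattice speed
  (`lb_control(u_lattice_max)`), which amounts to solving at a reduced
  effective viscosity (Re of order one). For such flows the steady velocity
  field is essentially Reynolds-independent, while transients wash out
  orders of magnitude faster. The step is fixed over a run so warm restarts
  stay exact; if the growing clot outruns the occlusion headroom the solver
  falls back to a cold restart with a rescaled step.
* **Bounded quasi-static re-solves.** The steady flow changes only when
  the bound-platelet boundary changes, so re-solves are triggered by
  deposition count or elapsed time *and only if occupancy changed*; each
  warm re-solve runs under an iteration budget (`max_iter_warm`) and keeps
  re-converging across successive updates. Fully converged cold solves are
  used wherever a flow field is quantitatively asserted.

## Agonist transport

ADP and TXA₂ obey ∂c/∂t + ∇·(uc) = D∇²c + S with first-order upwind
advection and central diffusion in flux form (exactly conservative and
positivity-preserving under the CFL bound), no-flux walls, zero inlet
concentration and convective outflow. Bound-platelet nodes remain
zero-velocity pore cells: released agonist accumulates inside the porous
clot, which is where the signaling happens.

Release: a platelet whose activation state crosses ξ_crit releases its
dense-granule ADP by first-order kinetics (total `Q_ADP_uM` = 100 μM in
its own cell volume, rate `k_rel` = 0.05 s⁻¹) and synthesizes TXA₂ at a
constant rate (`q_TXA2_uMs` = 0.1 μM/s) while bound and activated. A voxel
is read as a platelet-rich volume element, so the concentration
parametrization is invariant under lattice coarsening. These magnitudes
are not available at this granularity; they were
calibrated once so that (i) the autocrine loop is functional (local ADP of
order its EC50 near an activated monolayer) and (ii) the relative scenario
effects reproduce the reported ordering, and they are used identically
across all scenarios so relative comparisons are meaningful.

Three engineering choices: transport advances on the 1 s signaling clock
(its inputs — sources and the quasi-static velocity — only change there);
it runs on a subdomain box from just upstream of the collagen patch to
~150 μm downstream (at Péclet numbers of 10³–10⁴ nothing that passes the
downstream margin ever returns); and advective face velocities are capped
at `u_cap_mms` = 25 mm/s — the only regions above the cap are
concentration-free jet cores where washout is effectively instantaneous at
either speed, and the cap keeps the explicit substep count set by the
signaling-relevant near-wall flow rather than by the stenotic jet.

## Platelet kinetics

Mobile platelets hop on the lattice with rates
`D_p/dx² + max(0, u·ê)/dx` (effective diffusivity
D_p = 2.5×10⁻⁷ cm²/s, RBC-augmented). Insertion at the inlet is a Poisson
stream matching the platelet flux with bulk concentration 1.5×10⁵ μL⁻¹,
with a near-wall excess profile `1 + (E−1)exp(−d/δ)` (E = 4, δ = 10 μm)
normalized so the mixing-cup average equals the bulk value, and positions
sampled from the flux-weighted density.

Adhesion and detachment:

* attach = `k_att⁰ · F · W(γ)`, with a larger prefactor for
  platelet–collagen capture (`k_att0_col` = 500 s⁻¹ vs `k_att0` = 2 s⁻¹);
  for platelet–platelet bonds the effective F is the larger of the arriving
  platelet's and the best adjacent bound platelet's adhesiveness —
  activated substrate recruits passive platelets, which is what
  monolayer-first growth requires;
* detach = `k_det⁰ · (1/F) · exp(γ/γ_c) / W(γ)` with γ_c = 1200 s⁻¹, the
  slip-bond exponent saturated at 8, and γ evaluated as the surface
  traction (the largest shear over adjacent fluid nodes — a bound
  platelet's own node is a no-slip solid with no local shear);
* `W(γ)` is the vWF switch: exactly 1 at zero shear, rising to `W_max`=20
  across the 3000–8000 s⁻¹ window. It multiplies capture *and* divides
  rupture: elongated vWF both recruits and retains platelets at
  pathological shear. Without the retention term, apex platelets are shed
  before collagen can activate them and deposition peaks on the upstream
  shoulder instead of the apex.

The rate database keeps per-platelet event rates in a Fenwick tree
(O(log N) selection, local updates after each event); scheduled insertions
merge into the event clock; detachment triggers a support cascade so no
bound platelet floats free. Every random number comes from R's RNG, so
runs are bit-reproducible from `(config, seed)`.

`k_att0_col` and `k_det0_col` were set so a quiescent collagen surface at
200 s⁻¹ acquires its monolayer within tens of seconds while the monolayer
itself is stable over the simulated six minutes; `k_att0`, `k_det0` and
γ_c were set so passive (α_min) platelets churn on ~50–100 s timescales,
activated platelets persist, and venous clots stay mural rather than
occluding — the behavior the reference simulations show.

## Donor signaling

Each donor is a feed-forward network (two tanh layers of 12 nodes) that
maps the six agonist inputs at time t (ADP, convulxin, thrombin, U46619,
iloprost, GSNO; doses pass through a saturating receptor-occupancy
transform c/(c+ref)) plus calcium at t−1, −2, −4, −8, −16, −32, −64,
−128 s (basal-padded before platelet entry) to calcium at t+1. Collagen
contact enters as convulxin 10 nM; local TXA₂ as U46619 = 15×[TXA₂];
thrombin only under the tissue-factor scenario, as a reduced
lag-then-rise generation curve (plateau 6 nM at 1 TF molecule/μm²,
anchored so the cohort TF enhancement falls in the reported +20–100%
band).

Activation integrates supra-basal calcium exactly as written,
ξ(t) = ∫([Ca²⁺]ᵢ − [Ca²⁺]₀)dt — negative excursions subtract; there is no
rectification. Adhesiveness is the Hill map
F(ξ) = α_min + (α_max−α_min)ξⁿ/(ξⁿ+ξ₅₀ⁿ) with α_min = 0.01, α_max = 1,
n = 2. Calibration ties ξ₅₀ = ξ_crit/3: integrin activation precedes
dense-granule secretion, so a platelet is already strongly adhesive when
it starts releasing.

## The synthetic donor cohort

Human pairwise-agonist-scanning (PAS) training data are not available, so
the package generates them: per donor, dose–response amplitudes (Hill),
rise–decay kinetics, pairwise synergies and inhibitor IC50s drawn
log-normally around cohort medians, with the convulxin amplitude
stratified geometrically (4× strongest/weakest) so the cohort spans weak
to strong collagen responders. The panel covers basal, all six inputs at
0.1/1/10× their reference dose, and all 15 pairs over the 3×3 dose
product, 256 s at 1 s resolution, with additive measurement noise.

The generator's kinetics encode one deliberate biological asymmetry: ADP
is the dominant secondary agonist (amplitude 0.45 μM, decay 150 s —
sustained P2Y12 signaling) while TXA₂/U46619 is weaker and more transient
(0.22 μM, 60 s). The time-integral of the calcium kernel is what drives
the activation state, so this asymmetry is what makes ADP inhibition
bite harder than TXA₂ inhibition, as reported for real donors.

Training is minibatch Adam (batch 2048, 6000 epochs, step-decayed
learning rate) on next-second prediction, with the basal record
up-weighted so the resting state is a trained fixed point, and per-epoch
Gaussian jitter on the lag inputs (decaying over the run). The jitter is
the important trick: it teaches the one-step map to contract toward the
trace manifold, which is what keeps 256 s closed-loop rollouts stable.
20% of pairwise conditions are held out per donor; closed-loop rollout
NRMSE on them averages ≈0.08–0.22 per donor (cohort mean ≈0.12),
normalized by the condition's dynamic range floored at 10% of the donor's
full-panel range. The hardest conditions are agonist × intermediate-dose
inhibitor pairs, where the network must interpolate a multiplicative
interaction from few examples; individual conditions there can reach
NRMSE ≈0.5–1. An oracle mode that queries the generator directly
(`donor_oracle_model()`) lets the simulator quantify what surrogate error
does to deposition: matched runs agree within 15% on final counts.

Threshold calibration rolls every trained network under constant
convulxin 10 nM and bisects a single cohort-wide ξ_crit so the fastest
donor crosses at ~60 s; the constructed heterogeneity then spreads the
cohort's crossing times to ~60–270 s, matching the reported one-to-four
minute span, with every donor crossing within six minutes.

## Scenarios

`control`, `no-adp`, `no-txa2`, `no-both` (inhibition is imposed by
zeroing the corresponding network input, mimicking clopidogrel/aspirin),
`gsno` and `iloprost` (constant antagonist exposure, 2 μM and 20 nM —
within the trained dose range), and `tf` (intra-clot thrombin from the
reduced generation curve, applied to bound platelets). Scenario runs share
the master seed per donor, so paired runs are identical until the first
signaling divergence and scenario effects are low-variance at desk scale.

## Problem sizes and what the tests show

The reference geometries at 3 μm resolve the vessels at production
quality for flow (the acceptance checks verify wall shear and Poiseuille
profiles there), but coupled growth runs at 3 μm over six minutes are
cluster-scale. The shipped verification suite therefore runs the coupled
scenario matrix at desk scale: 16 μm lattice (six cells across the
lumen), 180 s duration, 10 donors × 7 scenarios with paired seeds, and
platelet insertion restricted to the half of the inlet cross-section
adjacent to the reactive wall (platelets inserted beyond that cannot reach
the bottom-wall collagen within their transit time at these Péclet
numbers, so the restriction removes only pass-through events). The
stenotic spatial check runs one strong-responder donor at 8 μm for 180 s.

What passes at this scale: the flow and transport solvers against closed
forms and conservation identities; the KMC machinery against analytic
Markov oracles; the calibrated activation-time span; the scenario potency
ordering (control ≥ no-TXA₂ ≥ no-ADP ≥ no-both in cohort means, iloprost
strongest antagonist with no release anywhere, TF enhancement for every
donor); and the deposition geography (venous clots upstream of the patch
midpoint, stenotic clots at the high-shear apex).

Known desk-scale limitations: clots are one node thick per platelet, so
the packing-density contrast between tightly packed arterial and porous
venous clots is not represented — consequently the reported
order-of-magnitude excess of intra-clot agonist in the stenotic case does
not reproduce (matched-donor peak intra-clot ADP here is a few μM in both
geometries, with the venous case higher); mobile platelets do not perturb
the flow; red cells enter only through the effective platelet diffusivity
and the near-wall excess; and the fibrin/coagulation cascade is reduced to
the thrombin curve. Synthetic donors are calibrated to reproduce the
behavioral ranges reported for healthy donors, not any individual human
donor.
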