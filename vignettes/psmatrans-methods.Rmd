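---
title: "Modeling Lu-177 PSMA-617 transport in solid tumors with psmatrans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling Lu-177 PSMA-617 transport in solid tumors with psmatrans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package models

`psmatrans` simulates the delivery of a receptor-targeted radioligand —
Lu-177 labeled PSMA-617, used in radioligand therapy of prostate cancer —
into a solid tumor embedded in normal tissue. The simulation has three
coupled layers:

1. **Interstitial fluid flow.** Tissue is treated as a porous medium: the
   interstitial fluid velocity obeys Darcy's law, `v = -K grad(p_i)`, and
   mass conservation `div(v) = phi_B - phi_L`, with a Starling source
   `phi_B = Lp (S/V)[p_B - p_i - sigma_s (pi_B - pi_i)]` describing fluid
   filtration from capillaries and a lymphatic sink
   `phi_L = LpL (SL/V)[p_i - p_L]` active only in normal tissue — solid
   tumors lack functional lymphatics, which is the classic mechanism behind
   their elevated interstitial fluid pressure (IFP). Flow is steady: it is
   solved once per geometry.
2. **Ligand transport.** Six concentration fields evolve on the frozen flow
   field: free, receptor-bound and internalized ligand, each in a
   radiolabeled ("hot") and an unlabeled ("cold") version. Free ligand is
   advected and diffuses, exchanges with plasma across the vessel wall
   (convective and diffusive terms, with a trans-capillary Peclet
   correction `Pe/(e^Pe - 1)`), is removed by lymphatics in normal tissue,
   and binds reversibly (`k_on`, `k_off`) to free surface receptors. Bound
   ligand internalizes (`k_int`) with a volume-fraction factor `FV_i/FV_c`
   that converts between per-interstitium and per-cell concentrations so
   that *amounts* are conserved; internalized ligand is released/cleared at
   `k_rel` (an outflow — the released material is not returned to another
   tracked pool). Radioactive decay (`lambda`) moves every hot species into
   its cold counterpart, so hot+cold sums are decay-free.
3. **Receptor trafficking.** Four per-voxel receptor pools — free and
   occupied, each on the surface or in endosomes — with constitutive
   endocytosis (`k_ec`), ligand-induced internalization (`k_int`),
   recycling (`k_rec`), lysosomal degradation (`k_deg`, with sorting
   fractions `f1`, `f2`), constitutive synthesis (`V_r`) and
   ligand-induced synthesis (`k_syn`). Receptors are cell-bound and do not
   move between voxels.

The vascular input is an explicit plasma curve: a bolus decays as
`(A/V) exp(-alpha t)`; a constant-rate infusion of duration `T` uses the
matching piecewise form, continuous at `t = T`, and both integrate to
`A/(V alpha)`. Plasma is a boundary condition, not a compartment: tissue
uptake does not feed back on the plasma curve, because the fitted
clearance `alpha` already subsumes whole-body disposition.

The figure of merit is the **time-integrated activity** (TIA, MBq·min) of
a region: the labeled amount (interstitial free+bound weighted by `FV_i`,
internalized weighted by `FV_c`) converted to activity through the Lu-177
decay constant and integrated over the simulated 50 h by trapezoid.
Absolute TIA scales with tumor volume; ratios and argmax locations across
runs on the same phantom do not, and those are the quantities the
experiment helpers report.

## Geometry: synthetic phantoms

Patient geometries are replaced by synthetic voxel phantoms: a labeled 3-D
grid (0 = outside, 1 = normal tissue, 2 = tumor) with voxel-center
coordinates `origin + index * spacing`. `make_spherical_phantom()` builds
the default surrogate — a 0.5 cm tumor sphere centered in a cube of normal
tissue — and `make_ellipsoidal_phantom()` adds reproducible lobed
perturbations for irregular shapes. Phantoms can be written to and read
from NIfTI masks (`write_mask()`/`read_mask()`; spacing is stored in mm as
the format expects, the package works in cm).

What the phantom captures: the two-tissue partition, the no-lymphatics
tumor core, the 10:1 tumor:normal receptor density contrast, and the
interface where pressure gradients and velocities concentrate. What it
does not capture: real tumor shape irregularity (beyond the lobed option),
heterogeneous vascularity (S/V is uniform per tissue), and absolute organ
volumes — so passing tests on phantoms validates mechanism and ordering
claims, not patient-specific absolute dosimetry.

Experiment defaults are desk-scale by design: sweeps use a 20^3 grid
(half-width 1.0 cm, 0.1 cm spacing, 8,000 voxels; about 20 s per 50 h
simulation), while the IFP verification uses a 3 cm cube at 0.05 cm
(60^3, 216,000 unknowns). A 0.1 cm voxel resolves the pressure *plateau*
but not the thin (~0.03 cm) boundary layer at the tumor rim; the central
IFP, which is the validated quantity, changes by under 3% on refinement.

## Parameters and units

All parameters live in a single registry (`parameter_registry()`), are
entered in the units in which they are commonly quoted (rates in 1/min,
pressures in mmHg, conductivities in cm/mmHg/s), and are converted once at
load time to a canonical system — cm, s, Pa, nmol/L — with unit tags that
`param_value()` checks on access. Pressure conversion uses
1 mmHg = 133.322 Pa exactly. Key defaults:

| parameter | default | unit | role |
|---|---|---|---|
| `D_eff` | 8.7e-7 | cm^2/s | ligand diffusivity |
| `k_on`, `k_off` | 0.046, 0.046 | L/nmol/min, 1/min | binding (K_d = 1 nmol/L) |
| `k_int` | 0.001 | 1/min | internalization of occupied receptors |
| `k_rel` | 2e-4 | 1/min | release of internalized ligand |
| `k_ec`, `k_rec`, `k_syn` | 0.007, 0.15, 0.0118 | 1/min | trafficking |
| `k_deg` | 2.9891e-4 | 1/s | endosomal receptor degradation |
| `f1`, `f2` | 0.5, 0.5 | – | degradation sorting fractions |
| `lambda_lu177` | 7.15e-5 | 1/min | physical decay (half-life ~6.7 d) |
| `alpha` | 0.0521 | 1/h | plasma clearance |
| `P` | 3.3e-4 | cm/s | vessel wall permeability |
| `sigma_f` | 0.9 | – | filtration reflection coefficient |
| receptor density | 50 / 500 / 200 | nmol/L | tumor scenarios 1/2/3; normal = 0.1x |

The flow block is per tissue (hydraulic conductivity `K`, `Lp`, `S/V`,
lymphatic `LpL SL/V`, vascular/osmotic pressures, `sigma_s`). Three
choices deserve comment:

* **Plasma volume `V`** is not part of the tabulated set; the package
  defaults to 3.0 L (a typical adult plasma volume) and exposes it as
  `plasma_volume`. Ratio-type outputs are insensitive to `V` only where
  the kinetics are linear; through receptor occupancy it does shift
  absolute numbers, which is one more reason the package reports ratios.
* **`V_r`** is kept at its printed value, 1.2e-22 mol m^-3 s^-1, which is
  numerically negligible (1.2e-16 nmol/L/s) against every other term. The
  magnitude suggests a per-cell count in the original trafficking
  literature rather than a volumetric rate; it is configurable for users
  who want to explore a rescaled constitutive synthesis.
* **`k_rec`** defaults to the tabulated 0.15 1/min; the studied sweep range
  1e-4..1e-1 1/min is exposed through `run_sweep("k_rec", ...)`.

## Numerical scheme

**Flow.** Cell-centered finite volumes with harmonic face conductivities,
which enforce pressure and normal-flux continuity at the tumor–normal
interface without explicit interface equations. The outer boundary carries
`p_i = 0` via half-cell Dirichlet transmissibilities. Because every
Starling term is linear in `p_i`, the discrete system is symmetric
positive definite and one linear solve suffices; the Starling terms
dominate the diagonal, so diagonally preconditioned conjugate gradients
(relative residual 1e-10) converge in tens of iterations at any of the
grid sizes used. The discrete divergence theorem then holds to solver
precision: the summed Starling production equals the boundary outflow
(`fluid_balance` diagnostic, tested at 0.5%).

**Transport and reactions.** The paper-style segregated step (default
`dt` = 0.1 min over 50 h) splits each step into

1. an explicit finite-volume convection–diffusion update of the two free
   fields — first-order upwind advection on the staggered face velocities,
   central diffusion, zero diffusive flux at the outer boundary with
   advective outflow permitted. At the defaults the diffusion number
   (~5e-4) and CFL (~6e-4) are tiny, so the explicit update is both stable
   and essentially exact; upwind numerical diffusion is negligible because
   interstitial transport is diffusion-dominated (tissue Peclet << 1).
2. a per-voxel reaction update. Given the (slowly varying) free-receptor
   level, the binding/exchange subsystem for (free, bound) is linear; the
   hot pair and the hot+cold sum pair are advanced with TR-BDF2, an
   L-stable second-order implicit scheme whose two stages share a single
   2x2 matrix — the cold pair follows by subtraction, which preserves the
   exact pairwise cancellation of decay terms. Internalized pools use
   exact scalar integrating factors. The four receptor pools use explicit
   midpoint with adaptive sub-stepping keyed to `k_on * C` (the only rate
   that can grow large); the sub-step count is recorded in the run
   diagnostics.

Negative values can only arise at round-off level; anything below
-1e-12 nmol/L is counted in a `clip_count` diagnostic before being floored
at zero (the count is zero in all shipped experiments). Degenerate inputs
are handled explicitly: a zero-amount protocol yields identically zero
fields, the `Pe -> 0` wall-exchange limit uses the series form of
`Pe/(e^Pe - 1)`, and near-degenerate TR-BDF2 systems are protected by the
closed-form 2x2 inverse.

**Verification.** The suite cross-checks every layer against an
independent route: the flow solver against the closed-form two-region
radial solution and a manufactured-solution refinement study (observed
order ~2); the transport stencil against the analytic heat kernel for a
diffusing-decaying Gaussian (1%); the coupled reaction stepping against
tight-tolerance `deSolve::lsoda` trajectories that share no code with the
compiled kernel (0.5% over 50 h; halving `dt` moves tumor TIA by <0.5%,
mirroring a time-step sensitivity test).

## Behavior of the model as written — and a structural caveat

The receptor equations include ligand-induced synthesis `k_syn * RP_s`
feeding the free-surface pool while occupied receptors internalize only
slowly (`k_int` = 0.001 1/min, slower than the constitutive `k_ec`). Under
the saturating ligand exposures of a therapy-scale injection (plasma
concentrations far above K_d = 1 nmol/L for tens of hours), synthesis then
outruns every degradation pathway and the surface receptor pool grows
throughout the 50 h window — in the shipped experiments `F_s` ends orders
of magnitude above its initial density. The package integrates this
faithfully (the stepping scheme is unconditionally stable in that regime),
but two consequences are worth understanding before interpreting sweeps:

* Given the receptor trajectory, the labeled subsystem is *linear* in the
  injected amount at a fixed labeled fraction, and a larger total amount
  only raises receptor availability. Tumor TIA is therefore monotonically
  increasing over the 100–1000 nmol amount sweep (the shipped sweep finds
  its maximum at the upper end of the grid) — receptor saturation can
  lower uptake *per nanomole*, but in this model it cannot produce an
  interior optimum of absolute TIA.
* Recycling-rate effects are damped: once the pool has grown, capture is
  limited by transvascular supply rather than receptor availability, so
  the TIA fold-change between `k_rec` = 1e-4 and 1e-1 1/min computes to
  ~1.10 at receptor density 50 nmol/L and ~1.07 at 500 nmol/L. The
  *ordering* — denser tumors benefit less from faster recycling — and the
  argmax at 0.1 1/min are robust, as are the ~10x TIA scaling with the
  labeled fraction, the saturating (concave) TIA-vs-density curve, and
  the infusion >= bolus TIA comparison.

Users who want a receptor pool bounded on therapy time scales can set
`k_syn` near zero (or raise `k_int`) through the parameter registry; the
defaults keep the tabulated values.

A related bookkeeping subtlety: bound ligand is tracked twice, once in
the ligand ledger (`C_B`, `C_BU`) and once in the receptor ledger
(`RP_s`). The two equations are not mutually conservative as formulated
(occupied-receptor recycling returns receptors without a matching ligand
source, and the ledgers see different effective sinks), so the package
evolves both as written and logs the divergence
(`diagnostics$rp_discrepancy`) rather than forcing a reconciliation.

## Scale diagnostics

`characteristic_scales()` evaluates the near-vessel penetration analysis:
the free ligand decays away from a vessel wall with characteristic length
`L_F = 2D / (sqrt(v^2 + 4 K_F D) - v)`, `K_F = D_R * k_on`; with the flow
suppressed in a pressurized tumor core this is `sqrt(D/K_F)` (~48 um at
density 50 nmol/L), with diffusion time `T_d = L_F^2/D = 1/K_F` (~26 s)
and advection time `T_a = T_d/Pe`. `transcapillary_peclet_report()`
evaluates the vessel-wall Peclet number both as the full filtration-flux
expression and as the pressure-difference-only form; with the tumor
parameter set and the averaged pressures (2079.8 and 1500 Pa) the two give
2.1e-5 and 3.69e-3 respectively, and the report labels the
pressure-difference variant as the one matching the commonly quoted
~3e-3 order. Either way the physical conclusion is the same: wall
exchange is strongly diffusion-dominated.

## A worked example

```{r example}
library(psmatrans)

params  <- load_parameters(scenario = "tumor1")
phantom <- surrogate_phantom()
flow    <- solve_ifp(phantom, params)
glance(flow)              # central IFP ~1533 Pa, balance error ~1e-10

sim <- run_scenario(scenario = "tumor1", amount_total = 100)
glance(sim)               # tumor/normal TIA, peak times
autoplot(sim)             # free/bound/internalized time courses

sweep <- run_sweep("k_rec", c(1e-4, 1e-3, 1e-2, 1e-1))
sweep_summary(sweep)      # argmax at 0.1 /min
autoplot(sweep)
```

## Known limitations

* No microvascular geometry: vessels enter only as distributed
  source/sink densities (`S/V`), uniform within each tissue.
* No dosimetry: TIA is the endpoint; absorbed dose, beta-particle range
  and cell-survival modeling are out of scope, as are tumor growth,
  angiogenesis and organ-at-risk kinetics.
* Prescribed plasma: tissue extraction does not deplete the plasma curve,
  so whole-body mass balance is not enforced (consistent with using a
  fitted clearance).
* The receptor-ledger growth and the dual bound-ligand bookkeeping
  discussed above are properties of the model equations as formulated;
  conclusions that depend on a bounded receptor pool at high occupancy
  should be drawn with care.
* Absolute TIA values depend on the phantom volume; only ratios, argmax
  locations and orderings are comparable across geometries.
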