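---
title: "Methods: flow and nutrient transport around trapped cell aggregates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flow and nutrient transport around trapped cell aggregates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Three-dimensional multicellular aggregates — spheroids, and toroids whose
central lumen shortens diffusion distances — are cultured in perfused
microfluidic devices, held in place either by a U-shaped barrier on the
channel floor or inside a recessed microwell.  Whether the cells thrive
depends on three fields that are hard to measure and cheap to compute: the
dissolved-oxygen and glucose concentrations inside the aggregate, and the
shear stress the medium exerts on its surface.  `aggtrap` computes all three
at steady state for a parametric device: a rectangular channel (width
W = 1 mm) with an oxygen-permeable PDMS lid, a single trap of length 600 µm
and outer footprint ≈0.321 mm² centred on the floor, and a toroidal
(minor radius r, aspect ratio R/r) or volume-matched spheroidal aggregate
resting inside it with a ~1 µm clearance margin.

## Model

**Flow.** The culture medium (water at 37 °C: ρ = 993.3 kg/m³,
µ = 6.92·10⁻⁴ Pa·s) enters at a constant rate Q = 5 µL/min with a fully
developed duct profile, leaves through a zero-pressure outlet, and obeys
no-slip on every wetted surface including the aggregate, which is treated as
a rigid body with zero interior velocity.  The spanwise sides are symmetry
planes (the device is one trap of a periodic row).  At these scales
Re = ρUL/µ ≈ 0.1 and Kn = λ/L ≈ 3·10⁻⁶, so the package solves the Stokes
limit of the incompressible momentum balance by default;
`solver_settings(include_inertia = TRUE)` restores the convective term via
deferred-correction Picard iterations, and a test verifies it changes the
solution by well under 1% here.

**Species transport.** Oxygen is carried by the medium
(advection–diffusion), diffuses through the PDMS lid and barrier walls
(pure diffusion, ambient supply at the lid top), and is consumed in the
tissue by Michaelis–Menten kinetics R = V~max~·c/(c + K~m~).  Glucose sees
only medium and tissue (PDMS is glucose-impermeable) and is otherwise
treated identically.  At material interfaces the flux is continuous and the
concentration jumps by the solubility (partition) ratio,
c~region~ = S·c~medium~ (S = 6 for O₂ in PDMS, 4.81 in tissue; 1 for
glucose).

**The partition-scaled variable.** The single most important discretization
decision: the solver works in φ = c/S~region~.  Writing the diffusive flux
as D·S·∇φ makes φ continuous across interfaces while reproducing both jump
conditions exactly, so the two-medium problem becomes an ordinary
heterogeneous-coefficient diffusion problem with cell coefficient β = D·S
and harmonic-mean face conductances.  A two-layer slab then matches the
series-resistance closed form to solver precision (this is a test), and the
ambient lid condition c~PDMS,top~ = S·c₀ becomes simply φ = c₀.

## Discretization and solvers

The device is voxelized on a uniform Cartesian grid by signed-distance
sampling at cell centres (stair-step boundaries, no cut cells); the
aggregate SDF is kept on the grid for surface normals and sub-cell Dirichlet
positioning.  Flow uses a staggered (MAC) finite-volume scheme; the discrete
Stokes system is solved by conjugate gradients on the pressure Schur
complement (Uzawa), with each momentum Laplacian solved by MILU(0)-
preconditioned CG in compiled code.  The outlet layer holds the pressure
reference, and outlet face velocities are recovered so that every medium
cell is discretely divergence-free; global mass balance closes to ~10⁻¹¹.
Transport uses the same grid with Patankar's power-law face scheme
(see below) and Picard iterations on the Michaelis–Menten sink, linearized
as V~max~/(c~old~ + K~m~)·c~new~ — an M-matrix form that keeps iterates
nonnegative.  Nonlinear convergence is the relative ℓ₂ residual, default
10⁻³ (the conventional criterion for this class of problem); acceptance
runs use 10⁻⁶.

**Advection scheme.** The cell Peclet number in the channel is
U·h/D ≈ 0.5–2 at 8–16 µm spacing, small enough that pure first-order upwind
would add noticeable numerical diffusion while pure central differencing is
only conditionally bounded.  The default is the power-law scheme
(upwind-limited, second order at low Pe); `upwind` and `central` are
selectable.  Manufactured-solution tests show order ≈2 on the diffusion
path and ≈1.3–1.5 on the advection–diffusion path at these Peclet numbers.

**Wall shear.** The reported τ_max is the maximum tangential traction on
the aggregate surface.  Voxel normals are useless for traction, so the
normal comes from the analytic SDF; the wall-tangential velocity is sampled
at 1.5h and 3h along the normal (trilinear interpolation) and differentiated
by a one-sided quadratic fit through the no-slip point.  The offsets were
fixed once by a probe study on a resolved Stokes sphere: 1.0h probes are
contaminated by the stair-step layer (+13% on the max), 2h over-smooths
(−4%); 1.5h/3h keeps the worst case within a few percent, and the estimator
remains exact for plane Couette and plane Poiseuille profiles.

## Verification

* Constant-rate sphere (Rs = 500 µm, A = 0.005 mol·m⁻³·s⁻¹): the 3D solver
  matches the closed form c(b) = A/(6D)(b² − Rs²) + c~s~ to ≈0.1% of the
  surface value at 10 µm spacing (the sub-cell Dirichlet positioning from
  the SDF is what makes this comfortably first-percent).
* The 3D Michaelis–Menten solution matches an independent 1D radial
  Newton/finite-difference oracle (≥200 nodes, separate code path) to ≈0.2%.
* A Stokes sphere with the exact low-Re solution as box boundary data
  reproduces the 1.5µU/a maximum shear within a few percent.
* Manufactured solutions verify the design order of both solvers; mirror
  symmetry, Q-linearity, maximum principles, conservation balances and
  monotone parameter responses are property tests.

## Synthetic fixtures and what a green test establishes

There are no external data; every fixture is generated by code.  Reduced
fixtures preserve the governing dimensionless groups rather than raw sizes:
the mini chip scales lengths by s = 1/4, the flow rate by s (preserving
Pe = UL/D) and V~max~ by 1/s² (preserving V~max~L²/(D·c)), so the solution
structure — and the qualitative orderings between trap types, aggregate
shapes and orientations — carries over at a fraction of the cost.  A green
ordering test at mini scale therefore establishes the mechanism (convective
access + diffusion distance), not the full-scale numbers; those are checked
separately on the full-size chip.  The fixtures do not emulate aggregate
deformation, cell-density heterogeneity, or metabolic coupling between
species, all of which are outside the model.

## Geometry choices where the source is silent

The trap's outer footprint (0.321 mm² over a 600 µm length → 535 µm width)
is interpreted as the outer envelope.  The barrier wall thickness defaults
to 25 µm: with 50 µm walls the interior span (435 µm) could not hold a
vertical toroid of r = 80 µm, R/r = 2 (482 µm needed), which the source's
own vertical-orientation cases require; the value is configurable.
Unstated channel dimensions default to Hc = 800 µm, Lx = 2.6 mm (1 mm
clearance on each side of the trap) and a 200 µm lid, all configurable.
The toroid axis convention follows the physics: horizontal = axis vertical
(ring flat on the floor), vertical = axis streamwise so the lumen faces the
flow.  The equal-volume spheroid radius defaults to the geometric identity
Rs = ((3π/2)r²R)^(1/3) (the widely quoted shorthand without π is available
as `as_printed`).  A 1 µm margin below the voxel size is collapsed with a
warning — the recorded effect of margin 0 vs 1 µm on the reported metrics
is ≤0.1%.

## Numerical parameters that matter

| parameter | default | meaning |
|---|---|---|
| `spacing` | scenario-dependent (20 µm for the full chip at acceptance scale) | voxel edge; must resolve r with ≥4 cells unless `coarse_ok` |
| `flow_residual_tol` | 10⁻⁶ | momentum/continuity convergence |
| `transport_residual_tol` | 10⁻³ (10⁻⁶ in acceptance runs) | nonlinear transport residual |
| `picard_relaxation` | 0.7 | under-relaxation of the Picard update |
| `schur_tol` | 10⁻⁹ | pressure CG tolerance; keeps mass balance ≲10⁻⁹ |
| `advection_scheme` | `powerlaw` | face flux scheme |

## Known limitations

Stair-step surfaces limit shear accuracy to a few percent at practical
resolutions and make the *maximum*-type metrics noisier than averages.
Grid extents are snapped to whole cells, so a spacing that does not divide
the device dimensions perturbs the channel cross-section by up to half a
cell and adds 1–2% wobble to average-concentration comparisons across
resolutions; acceptance runs therefore use commensurate spacings (20 µm for
the full chip; the 50/25/20 µm refinement study bounds the remaining
resolution error at well under 0.1% on the tissue averages).  The full-size
chip runs at 20 µm rather than the ~8 µm a lower-level implementation would
afford, to stay inside a 20-minute single-core budget.  Transient
behaviour, aggregate deformation and oxygen–glucose metabolic coupling are
out of scope.
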