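---
title: "The cross-bridge migration model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cross-bridge migration model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`rbcbridge` simulates a two-cell red blood cell (RBC) doublet in blood
plasma. Each cell is a closed triangulated membrane; adhesion between the
two membranes represents fibrinogen (Fg) cross-bridges through a Morse-type
interaction evaluated per adhesion vertex,

$$U_i = \Gamma_{\rm affin}\left[e^{2\beta(r_0-r)} - 2e^{\beta(r_0-r)}\right]A_i
\quad (r \le r_{\rm cutoff}),$$

where $A_i$ is the median-dual control-volume area around vertex $i$, $r$
the separation from the pairing surface, $r_0$ the zero-force separation
(electrostatic double-layer balance) and $\beta$ the spatial decay. The
force applied at a vertex is the exact negative radial derivative,
$\Gamma A_i\,[2\beta e^{\beta(r_0-r)} - 2\beta e^{2\beta(r_0-r)}]$, along
the vertex-to-vertex (VTV) direction for specific receptor-bound bridges
and along the vertex-to-nearest-surface-point (VTS) direction for
non-specific bridges.

The total affinity composes three bridge populations,

$$\Gamma_{\rm affin} = \Gamma_{\rm iFgR} + \Gamma_{\rm iFg}
 + N_{\rm mFg}\,\Gamma_{\rm mFg},\qquad
N_{\rm mFg} = N_{\rm mFg}^{\rm RBC1} + N_{\rm mFg}^{\rm RBC2},$$

and the normalized mobile density $N$ on each cell surface obeys a
convection–diffusion equation in the membrane's material frame,

$$\frac{dN}{dt} = D_{\rm mFg}\nabla^2 N
 - \nabla\!\cdot\!(\vec V_{\rm drift} N) + \dot S_{\rm adsorp},$$

with a drift induced by intercellular Couette friction wherever the
surface gap $\delta_{\rm gap} = r_{\rm sep} - 2r_{\rm glyco}$ is narrower
than the hydrodynamic size $\delta_{\rm Fg}$ of the adsorbed mobile Fg:
$\vec V_{\rm drift} = \tfrac12(\vec V_{\rm nbr}-\vec V_{\rm RBC})
(\delta_{\rm Fg}-\delta_{\rm gap})/\delta_{\rm Fg}$ (tangential part).
With $\Gamma_{\rm mFg}=0$ the model reduces to the uniform affinity model
(UAM). Intercellular friction itself assumes a Couette profile in the gap:
stress $-\mu_{\rm gap}\vec v_t/(r_{\rm sep}-2r_{\rm glyco})$, converted to
a nodal force by $A_i$ (the friction law is stated as a stress;
the area factor makes it consistent with every other per-vertex quantity).

The membrane is the standard coarse-grained viscoelastic particle model:
worm-like-chain + power-law ($k_p/l^2$) edge springs calibrated per edge so
that the generated mesh is stress-free and the network shear modulus equals
$E_{s0}$ (with $x_0 = l_0/l_{\max} = 1/2.2$); dihedral bending with
$k_b = 2E_b/\sqrt3$; quadratic global-area, per-triangle local-area and
volume penalties; and pairwise dissipative edge forces
$-\eta_T\vec v_{ij} - \eta_C(\vec v_{ij}\cdot\hat e)\hat e$ with
$\eta_m = \sqrt3\,\eta_T + \sqrt3\,\eta_C/4$, $\eta_C = \eta_T/3$ (our
reading of the ambiguously typeset constant relation, standard in the
dissipative-membrane literature).

## Parameters that matter

| parameter | default | units | meaning |
|---|---|---|---|
| `es0` | 6.54e-6 | N/m | resting cytoskeleton shear modulus |
| `eb` | 2.4e-19 | J | bending modulus |
| `ka`, `kd` | 0.288, 0.144 | N/m | global / local area penalties; `k0 = 2 es0 + ka + kd` is enforced |
| `k_omega` | 220 | J/m^3 | volume penalty (the conventional unit for this constant is ambiguous; the pressure-like reading is the only dimensionally consistent one, and the closed area-constrained surface keeps volume drift far below the 2% bound under it) |
| `eta_m` | 0.7e-6 | N s/m | membrane viscosity |
| `beta` | 0.05 | 1/nm | Morse decay |
| `r0`, `r_cutoff` | 20, 100 | nm | zero-force and cutoff separations |
| `r_glyco` | 5 | nm | glycocalyx height |
| `mu_gap` | 3.6 | cP | gap plasma viscosity (friction-optimized) |
| `d_mfg` | 1e-15 | m^2/s | mobile-Fg surface diffusivity (CBMM baseline) |
| `delta_fg` | 45 | nm | hydrodynamic size of adsorbed mobile Fg |

Pathophysiological states scale the baseline mobile-bridge state:
$\Gamma_{\rm affin} = \Gamma_{\rm iFg} + N^* N_{\rm mFg,b}\Gamma^*
\Gamma_{\rm mFg,b}$. We initialize the simulated per-surface density field
at $N^*$ (so the measured starting gap density is $2N^*$: 2.5 for the
healthy median $N^*=1.25$, 3 for SLE $N^*=1.5$) and fold $\Gamma^*$ into
the effective mobile affinity; the composition above is then reproduced
exactly by the ordinary affinity sum at initialization.

## Numerical scheme

*Mechanics.* Semi-implicit (symplectic) Euler: velocities are updated from
the total force, positions from the updated velocities. The per-vertex mass
is fictitious (`mass_total/n_vertices`, default 1e-5 kg per cell), chosen
so the dynamics are overdamped and quasi-static at the protocols'
micrometre-per-second loading rates: the inertial force scale at these
accelerations (~1e-13 N) is three orders below the piconewton adhesion
forces, while the velocity relaxation time (~5 ms) stays far below the
seconds-scale loading. `stable_dt()` bounds the step from the stiffest
local coefficient (edge springs, area penalties, the Morse curvature at
full compression) and the per-vertex drag, with a 0.3 safety factor; a
10^4-step hold of a rest mesh verifies the bound in the test suite.

*Contact.* VTS queries find the exact nearest point on the pairing
triangulation (tie-break: lowest triangle index) through a uniform spatial
grid rebuilt every 50 steps with a 20 nm skin; between rebuilds distances
are re-evaluated against the cached nearest primitive (surface motion
between rebuilds is ~1e-11 m, five orders below the skin). VTV pairings
are nearest-vertex per query, not persistent bonds. VTS reaction forces
are distributed to the nearest element by barycentric weights, conserving
linear momentum exactly.

*Transport.* Finite volumes on the median-dual cells of the deforming
mesh, solved in the material frame so only the relative drift appears as
convection: cotangent-weighted Laplacian (weights clamped at zero to keep
positivity on obtuse pairs), first-order upwind drift fluxes through the
circumcentric dual edges, explicit source. The update operates on the
transported *amount* $N_iA_i$, so deformation of the control volumes
transports amount and the closed-surface total is conserved to machine
precision with the source off; sub-stepping engages automatically from the
diffusion/CFL bound. Transport is advanced every 8 mechanics steps
(operator splitting); at the baseline diffusivity the transport timescales
are many orders slower than that splitting interval.

*Adsorption.* The source composition $J_{\rm const}+J_{\rm diff}$
simplifies algebraically to $D(N_0-N)/(1.4\delta_{\rm Fg})^2$ — the
equilibrium-ratio parameter $\phi_0$ cancels exactly. We implement the two
terms separately (and test that they balance at $N=N_0$), noting that the
source is therefore insensitive to $\phi_0$.

## Protocols

*Formation.* Two stress-free discocytes are stacked face-over-face with a
lateral centre offset of 0.8 diameters and lowered until the minimum
surface separation equals $r_0$ — a point contact at the margin of the
face plateaus. This placement matters: contact initiated on the outer rim
shoulder cannot spread, because conforming to the doubly-curved rim crest
would require in-plane strain far beyond the ~0.3% that the adhesion
energy can pay for against the 0.43 N/m area compressibility. From the
plateau margin the contact line advances across near-parallel faces and
the doublet slides spontaneously, resisted by gap friction — the sliding
stage of rouleau formation. The formation-rate metric is the overlap
length at 80% of the run's final overlap divided by the time to reach it,
with overlap measured as the projected silhouette overlap along the
sliding axis.

*Disaggregation.* A doublet in 50% crescent overlap (uniform density, gap
$r_0$) is held for a 4 s settling phase (distal patches fixed) while the
adhesive contact seats, then the patches -- covering 2% of each cell's
area at the far poles -- are displaced in opposite directions at
0.15 um/s. The trap is kinematic: the patch vertices follow the prescribed
motion exactly and the recorded trap tension is the reaction force
required to enforce it (excluding the fictitious-mass impulse, which is
numerical, not trap load). The trap velocity ramps up over 0.25 s so the
overdamped membrane loads quasi-statically; an instantaneous jump excites
a millisecond-scale transient in the reaction force of tens of pN. Escape
is detected by tension crossing the configured threshold (default 32 pN,
the upper end of the reported 29 +/- 3 pN trap escape range).

*Interface counting.* The affinity $\Gamma_{\rm affin}$ and the gap
Couette stress are interfacial quantities -- the composition above already
sums both surfaces' density contributions ($N_1 + N_2$). The simulator
therefore samples the interface from both surfaces and averages: each
side's adhesion and friction assembly carries a factor 1/2. Evaluating
both sides at full weight would double the effective interface energy per
unit area; under that convention the uniform-affinity disaggregation run
escapes the trap outright instead of showing its characteristic two-stage
curve.

## Desk-scale (scaled-down) mode

Full resolution for this model is ~5000 adhesion vertices per cell, giving
the receptor-density-based ~200 nm vertex spacing; protocol runs at that
size take hours. The package's default protocol resolution is 750 vertices
per cell. Because the cross-bridge interaction lengths are defined
relative to the 200 nm spacing, a coarser mesh stretches them by
$s = \bar\ell/200\,\mathrm{nm}$ (applied to $1/\beta$, $r_0$,
$r_{\rm cutoff}$, $r_{\rm glyco}$, $\delta_{\rm Fg}$) and scales
$\mu_{\rm gap}$ by $s$, which preserves both the adhesion energy per unit
area and the Couette shear stress at the scaled zero-force gap. Without
this scaling the contact line is lattice-pinned: the interaction range
falls below the inter-vertex spacing and the doublet cannot slide at all.
Protocol durations in the tests and in the acceptance script are 12-20 s
(formation; the overlap growth plateaus well before that at desk
resolution) and 20-34 s (disaggregation, which runs to complete
separation), with rate metrics computed on the simulated window.

A caveat the tests make explicit: at desk resolution the sliding doublet
can arrest at intermediate overlap (the contact line meets the dimple
region, where conforming again requires in-plane strain), and the arrest
point moves with mesh resolution and affinity. The formation-rate metric
is therefore reproduced only to a few tens of percent at coarse
resolution, and the simulated formation-rate ladder, while strictly
increasing in affinity, sits ~10-35% below the full-resolution reference
values at its lower rungs.

## What the simulations do and do not show

The two cells are deterministic, athermal continuum membranes: no thermal
undulations, no explicit bulk fluid (all dissipation is membrane viscosity
plus intercellular Couette friction), no bridge formation/cleavage
kinetics (their net effect is folded into the effective mobile-Fg
diffusivity), and no plasma proteins other than fibrinogen. Passing tests
therefore demonstrate the internal consistency of the mechanistic model
and its ability to reproduce doublet-scale kinematics and forces — not a
validation against any individual patient's cells. Multi-cell aggregates,
vessel-lumen or pulsatile flows, and self-contact of a single cell are out
of scope; mesh connectivity never changes during a run.

## Degenerate inputs and tie-breaks

Degenerate triangles raise a geometry error naming the triangle; equidistant
contact candidates resolve to the lowest index (determinism); the WLC
extension is clamped at 0.98 of the maximum length; the Couette gap
denominator is clamped below at 1 nm; negative transported densities are
prevented by upwinding (a defensive clamp-and-renormalize remains). Two
runs with identical configuration and seed are bit-identical; the only
randomness is an optional initial vertex jitter, off by default.
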