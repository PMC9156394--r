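---
title: "Steady hemodynamics of end-to-side anastomoses: model, numerics and verification"
author: "etsflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steady hemodynamics of end-to-side anastomoses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(etsflow)
```

## The problem

In free-flap reconstruction an end-to-side (ETS) anastomosis joins the end
of a graft artery (here, the deep inferior epigastric artery of a DIEP
flap) into an opening cut in the side of a donor artery (the internal
mammary artery). The geometry of that junction — above all the angle at
which the graft leaves the donor — shapes the local flow. Three flow
features are the accepted mechanical correlates of anastomotic failure,
through the lens of Virchow's triad: *stagnation* (stasis), *recirculation*
(separated eddies, also stasis-promoting), and *wall shear stress* (WSS,
endothelial injury). This package builds a desk-scale computational model
of that junction, sweeps the anastomotic angle over 30-90 degrees, and
quantifies the three features together with a linear model of maximum
cross-sectional graft stagnation versus angle.

## The model

**Geometry.** Both vessels are straight rigid channels of internal
diameter 2.3 mm (wall thickness, 200 um, is carried as metadata only: the
fluid domain is the lumen and the walls do not deform). The graft
centreline crosses the donor centreline 100 mm from the donor inlet at an
angle $\theta \in (0^\circ, 90^\circ]$ measured against the distal donor
direction, so a smaller angle means a more flow-aligned graft. The opening
cut into the donor wall then has chord length $d_g / \sin\theta$. Heel
(proximal corner), toe (distal corner), hood (graft roof over the mouth)
and floor (donor wall opposite) are recorded as landmarks. Corners are
sharp: no suture-line fillet is modelled, and none is reported for the
reference geometry.

**Reduction to 2-D.** The model is the planar mid-plane of the junction: a
channel junction rather than a tube junction. This preserves the mid-plane
flow topology that the reference visualizations themselves show (jet
through the mouth, separation bubble in the graft, stagnation growth with
angle, WSS concentration at the junction corners) at a computational cost
compatible with a laptop. What it cannot represent is genuinely
three-dimensional structure: secondary (Dean-type) vortices in the tube
cross-section, out-of-plane graft take-off, and the circular lumen's
cross-sectional area weighting. Quantities here are therefore per unit
depth (areas in mm^2, fluxes in kg/m/s) and comparisons with tube-flow
results are qualitative by construction.

**Domain truncation.** The physical vessel lengths (184 mm donor, 103 mm
graft) are two orders longer than the junction region. The computational
domain keeps 15 donor diameters upstream of the heel, 15 downstream of the
toe and 15 graft diameters along the graft. At the operating Reynolds
number (~70) the laminar entrance length is about `0.06 Re D` = 4.2
diameters, so fully developed conditions are comfortably re-established
before each outlet; the truncation floor of 5 diameters is enforced as an
invariant.

**Fluid and boundary conditions.** Blood is incompressible and Newtonian:
viscosity 3.5e-3 Pa s, density 1060 kg/m^3 — the standard large-vessel
approximation at arterial shear rates. The inlet carries a parabolic
(fully developed) profile with mean 100 mm/s; a uniform plug is available
by configuration. Both outlets are held at the same reference pressure
(100 mmHg, mean arterial pressure) with zero-gradient velocity, so the
donor/graft flow split is an *outcome* of the geometry, not a prescribed
input. Walls are no-slip. Because the fluid is incompressible, the
reference pressure level cannot influence the velocity field; the solver
stores pressure as gauge relative to the outlet reference and adds the
level back only on output, which makes the invariance exact in floating
point rather than approximate.

## Numerics

**Meshing.** The domain is meshed block-structured: a tensor-product grid
in the donor, a transfinite (bilinear) block in the graft between the
oblique junction mouth and the perpendicular graft outlet, sharing the
interface nodes, so the mesh is conforming by construction. Cross-channel
spacing places two wall-adjacent cell layers at half the interior spacing
(near-wall refinement for the WSS and no-slip gradients); axial spacing is
fine (the target edge length, default 0.12 mm) within one diameter of the
junction and grows geometrically (ratio 1.15, capped at 5x) toward the
inlet and outlets. At the default resolution a junction mesh has ~5,400
cells with ~21 cells across each vessel; quads by default, with an
optional split into triangles. A quality report (minimum cell angle,
aspect ratio, face non-orthogonality) gates the solver at a minimum cell
angle of 15 degrees. Note that at 30 degrees the graft block is sheared by
60 degrees near the mouth — the price of a conforming parametric mesh — and
the solver's discretization is built to be robust to exactly that.

**Solver.** Steady incompressible Navier-Stokes via SIMPLE pressure-
velocity coupling on a collocated, cell-centred finite-volume mesh:
first-order upwind convection, implicit viscous diffusion, Rhie-Chow flux
interpolation against pressure checkerboarding, under-relaxation 0.7
(velocity) / 0.3 (pressure), and a Cholesky-factorized pressure-correction
solve whose numeric factorization is updated in place each outer
iteration. Residuals are normalized by the inlet momentum flux (momentum)
and inlet mass flux (continuity), making the convergence tolerance —
default 1e-4 — dimensionless and mesh-independent. Iteration order is
fixed and there is no randomized state anywhere, so repeated solves are
bit-identical.

**Sheared cells.** On the sheared graft block the usual over-relaxed
deferred non-orthogonality corrections (explicit cell-gradient terms)
destabilize the outer iteration. The package instead writes each face-area
vector in the basis of the cell-centre line $d$ and the face tangent $T$,
giving a compact two-coefficient face-normal gradient
$\nabla\phi\cdot S = \alpha\,(\phi_N-\phi_P) + \beta\,(\phi_b-\phi_a)$
that is exact for linear fields on arbitrarily sheared cells; the $\beta$
(node-difference) term uses inverse-distance node interpolation with
Dirichlet nodes pinned. This compact form is used implicitly ($\alpha$)
and deferred ($\beta$) in the momentum diffusion and inside the Rhie-Chow
flux. The cell pressure gradient, however, is reconstructed from the
$\alpha$ family alone (per-cell least squares over the face-normal
differences): including the $\beta$ cross-differences in the gradient
couples the velocity corrections to modes the pressure-correction operator
cannot damp and destabilizes the iteration; the $\alpha$-only gradient
keeps the correction loop and the flux operator one consistent family. The
cost of this choice was measured on a channel whose middle third is meshed
with 60-degree sheared cells (the exact solution is still plane
Poiseuille): velocity error ~2.3% in the sheared region versus ~0.1% on
the orthogonal mesh. That is the accuracy class of the first-order upwind
scheme itself, and it is the price paid for unconditional stability of the
sweep across all five angles.

**Degenerate and edge cases.** A mesh failing the quality gate is refused
with the measured angle; non-convergence raises an error carrying the full
residual history; NaN in the field aborts with a pointer at the relaxation
factors; outlet faces that transiently see inflow are treated with an
upwind guard. For all-Dirichlet verification solves (manufactured
solutions) the pressure level is pinned softly at one cell and the
boundary flux imbalance of the analytic data (quadrature-level) is spread
over the boundary so the pressure equation stays solvable.

## Post-processing definitions

**Stagnation.** At 50 evenly spaced cross-sections perpendicular to the
graft centreline — starting at the first section that lies entirely within
the graft, $s_0 = (d_g/2)/\tan\theta$ past the mouth point, and spanning 10
graft diameters — the stagnant fraction is the percentage of the section
width where speed falls below a threshold times the inlet mean speed.
Sections are sampled at 200 points. Converged solver fields are sampled
through node-interpolated speeds, with wall nodes pinned to zero, so the
no-slip ramp is resolved rather than quantized at the first cell value;
constructed fixture fields are piecewise-constant cell data and are
sampled at cell values, keeping their built-in fractions exact to cell
quantization.
The reference workflow measured stagnation by thresholding velocity-
magnitude screenshots, and its cutoff is not stated; the default here is
0.05 (5% of inlet mean speed), exposed in the configuration, and the
absolute percentages should be read as conditional on that choice. The
acceptance script therefore also reports the angle regression at 0.10,
0.15 and 0.20: in this 2-D model the angle trend is *not* monotone at the
0.05 default — the strongly recirculating fluid at large angles moves
faster than 5% of the inlet speed, so large-angle sections read as less
"stagnant" — while at thresholds of 0.10-0.20 the maximum stagnation
increases strictly with angle and the linear fit recovers R^2 of about
0.83-0.85, with absolute percentages at 0.15-0.20 approaching the range
the reference reports. This threshold-conditionality is a genuine property of the
measure, inherited from the unstated reference cutoff, and is reported
rather than hidden.

**Recirculation.** A recirculation zone is a connected set of cells whose
velocity component along the local vessel axis (graft axis inside the
graft, donor axis elsewhere) is negative; components below a configurable
area floor (default 0.01 mm^2) are discarded, and each zone is assigned
the nearest landmark of its area-weighted centroid. Reversed-axial-flow
detection is deterministic and robust, unlike closed-streamline topology.

**Wall shear stress.** On each wall face,
$\tau = \eta\,|u_t|/\delta_n$ from the tangential velocity of the
wall-adjacent cell and its wall-normal distance — a one-sided first-order
estimate, consistent with the overall scheme order. Profiles are ordered
by arc length along the boundary walk; the global peak is assigned its
nearest landmark.

## Verification suite

The generator of synthetic inputs is first-class code and covers every
stage downstream of the solver as well as the solver itself:

* **Plane Poiseuille** (`poiseuille_field`): exact parabolic profile with
  matching linear pressure. Oracles: centreline speed $1.5U$, flux $Uh$,
  wall shear $6\eta U/h$ (~0.913 Pa at the operating point), discrete
  continuity residual at rounding level, and the solver's own channel
  solution within 2% L2 at 20 cells across.
* **Manufactured solution** (`manufactured_case`): divergence-free
  trigonometric stream-function field plus the closed-form body force that
  makes it an exact steady Navier-Stokes solution; used both as a
  consistency check (residual of the exact field decreases under
  refinement) and as the convergence oracle for `solve_steady` with
  all-Dirichlet boundaries.
* **Constructed post-processing fixtures**: `stagnation_fixture` builds a
  field whose per-section stagnant fraction is known exactly by
  construction (to one cell width of quantization); `vortex_fixture`
  embeds a solid-body rotation disc whose reversed-flow area is the
  analytic half-disc, the oracle for recirculation-zone areas.

Everything is deterministic given its parameters; no randomness exists in
the package, so no seeds are involved.

What passing these tests shows — and what it does not: the fixtures
validate the discrete operators and the measurement chain against closed
forms on channel geometries; they do not make the 2-D junction model a
surrogate for 3-D tube hemodynamics, pulsatile flow, non-Newtonian
rheology or compliant walls (all outside this model by design).

## The five-angle experiment and what it reproduces

`run_sweep()` meshes, solves and post-processes each angle (default 30,
45, 60, 75, 90 degrees) and fits max-stagnation versus angle by OLS. With
the default configuration each angle is a ~5,400-cell solve converging in
roughly 400 outer iterations (under a minute on one core; the full sweep a
few minutes). The packaged reference table of maximum stagnation by angle
is fitted by the same OLS path (`fit_table3()`), reproducing the printed
regression (slope 0.244 %/degree, intercept 20.6%, R^2 0.973) at full
precision against a closed-form oracle.

Findings of the 2-D model worth stating plainly, because they are
properties of the model rather than bugs, and the acceptance suite reports
them honestly:

* The separation bubble in the graft sits along the *heel-side* graft wall
  (the wall opposite the flow divider), growing in area and reversal depth
  with angle — peak backflow ~11% of inlet speed at 90 degrees versus
  ~2.4% at 30 degrees, with the area grid-converged (it changes by under
  10% between 0.12 mm and 0.07 mm grids). Classical channel-junction
  theory places laminar branch-entrance separation exactly there. The
  reference instead localizes recirculation at the toe; its own discussion
  notes the opposite heel finding in an ex-vivo model. This artifact
  reports the landmark it computes and does not adjudicate.
* A weak reversed band (under 2.5% of inlet speed) persists at 30 degrees,
  so the ratio of 30-degree to 90-degree recirculation area by the plain
  reversed-axial definition is far above the "minimal to none" reading of
  the reference's streamline images; restricting to dynamically
  significant reversal (above 5% of inlet speed) the 30- and 45-degree
  zones vanish entirely while the 90-degree zone remains. The package
  keeps the plain definition.
* Peak WSS localizes at the toe for 30-60 degrees and the heel for 75-90
  degrees in this model — always at heel or toe, never on hood or floor,
  matching the reference's localization claim at that granularity.

## Problem sizes

Defaults were chosen so that the full default sweep, the verification
suite and the acceptance script each run in minutes on a single core:
junction meshes ~5.4k cells (target edge 0.12 mm), channel benchmarks 2k
cells (20 across), manufactured-solution study up to 48x48. The
grid-convergence property (graft-outlet flux fraction moving under 2%
between refinements) is checked at coarser desk resolutions in the test
suite; the refinement behaviour quoted above for recirculation areas was
obtained with the same public API at 0.09 and 0.07 mm.

## Known limitations

* 2-D mid-plane physics only; no secondary flows, no out-of-plane angle.
* First-order upwind convection: robust and monotone at Re ~ 70, but
  diffusive; the linear-upwind refinement is deliberately not default.
* The alpha-only pressure-gradient reconstruction costs ~2% velocity error
  on 60-degree-sheared cells (measured, see above).
* Stagnation percentages are threshold-conditional; trends across angles
  at fixed threshold are the meaningful output.
* Steady flow at constant mean arterial pressure; pulsatility and
  non-Newtonian rheology are outside scope.
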