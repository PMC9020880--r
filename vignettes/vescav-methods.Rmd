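---
title: "Modelling cavitation microbubbles in elastic microvessels with vescav"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cavitation microbubbles in elastic microvessels with vescav}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vescav)
```

# The physical problem

An air microbubble (equilibrium radius $R_0 = 2\,\mu$m) sits in blood inside
a cylindrical microvessel (lumen radius $r_i = 3$–$20\,\mu$m, wall thickness
$h = 1\,\mu$m) surrounded by soft tissue.  A 1 MHz ultrasound wave with
130 kPa peak pressure drives the bubble into large-amplitude, non-inertial
oscillation.  The oscillating bubble loads the vessel wall with pressure
(circumferential, "hoop" stress — implicated in vessel rupture) and with
viscous shear from the induced microstreaming flow (implicated in membrane
bio-effects).  The package computes these wall stresses, the bubble volume
and shape history, and how everything changes as the bubble approaches the
wall or the vessel narrows.

Two tiers are provided:

* **Radial tier** — the compressibility-corrected radial dynamics
  (Keller–Miksis) equation for a free spherical bubble,
  $$\Big(1-\tfrac{\dot R}{c}\Big) R \ddot R +
    \tfrac32\Big(1-\tfrac{\dot R}{3c}\Big)\dot R^2 =
    \frac{R}{\rho c}\frac{dP_b}{dt} +
    \frac{1}{\rho}\Big(1+\tfrac{\dot R}{c}\Big)\big(P_b - P_\infty - p(t)\big),$$
  with interface pressure
  $P_b = p_{g0}(R_0/R)^{3k} - 2\sigma/R - 4\mu \dot R/R$, drive
  $p(t) = -P_a\sin 2\pi f t$ (rarefaction first), and isothermal gas
  ($k = 1$, $p_{g0} = P_\infty + 2\sigma/R_0$).  This tier is the
  validation oracle for the coupled tier.
* **Coupled (finite-element) tier** — incompressible Navier–Stokes blood on
  a moving mesh, a lumped polytropic gas bubble, linear-elastic vessel and
  tissue, an absorbing outer layer, and full kinematic/dynamic coupling at
  the bubble surface and the vessel wall, on a half-symmetry tetrahedral
  mesh.

Material constants follow the microvessel setting: blood
$\rho = 1055$ kg/m$^3$, $\mu = 5$ mPa s, $c = 1500$ m/s,
$\sigma = 0.072$ N/m, $P_\infty = 104.6$ kPa; vessel $E = 1.5$ MPa,
$\rho = 1070$ kg/m$^3$; tissue $E = 0.5$ MPa, $\rho = 1055$ kg/m$^3$; both
solids $\nu = 0.49$.

# Discretization choices

**Mesh.**  `generate_mesh()` builds a structured, mapped tetrahedral mesh:
a polar grid of ray directions around the bubble center (aligned per
azimuth column with the corner circle of the cylindrical lumen, so rays
exit purely through the lateral wall or purely through an end plane),
radial shells of prisms split into conforming tetrahedra for the blood and
the gas ball, and radial extrusion of the lateral wall triangulation
through vessel, tissue and absorbing layer.  The radial shell grading uses
an *absolute* near-bubble spacing ($0.35\,R_0$ by default): the kinetic
energy of the near-field flow decays like $1/r^4$, so the added mass — and
with it the oscillation period — is controlled by the first few cells at
the interface regardless of how far each ray travels.  A wall-side
boundary layer refines the shear region.  Azimuth counts are multiples of
8 so the nine stress stations at $0°,22.5°,\dots,180°$ coincide with node
columns.  The thin wall and boundary layers are meshed with intentionally
flat (anisotropic) tetrahedra; the quality floor therefore guards only
against degeneracy (fractions of a degree), not against anisotropy.

**Fluid.**  P1/P1 velocity–pressure with Brezzi–Pitkäranta pressure
stabilization.  The stabilization length is the element *minimum height*
($1/\max_a|\nabla N_a|$): a volume-based length over-stabilizes the flat
boundary-layer elements and visibly leaks mass there.  The constant
$\alpha = 0.02$ was chosen as the smallest value that suppresses pressure
checkerboarding on the structured grid (smaller values re-introduce
node-scale pressure noise, larger values inflate the interface compliance).
Convection uses the ALE relative velocity with the mesh velocity of the
previous step.

**Solid.**  Mixed displacement–pressure (Herrmann) P1/P1 elements with the
same stabilization: at $\nu = 0.49$ pure displacement P1 locks.  This
replaces the quadratic-displacement discretization a commercial desktop
solver would typically use; the static thick-cylinder test in the suite quantifies the
accuracy of this choice at the default resolutions.  The solid is
geometrically linear and assembled once on the reference configuration.

**Gas.**  The bubble interior is a single lumped state
$p_g = p_{g0}(V_0/V)^k$ closed by the interface flux.  The
`ideal_gas_compressible` tier keeps the same isothermal dynamics
($k = 1$) while tracking gas mass and density through the ideal-gas
equation of state; the interior flow field of the gas is not resolved —
at micron scales gas inertia and viscosity are negligible against the
blood, and the isothermal uniform state is exactly the $k=1$ polytropic
closure.  The volume state is initialized to the *polyhedral* bubble
volume so the gas stiffness and the faceted interface flux are mutually
consistent; reported volumes are rescaled by the constant faceting factor,
making `bubble_volume()` start at the continuum $\tfrac43\pi R_0^3$
(33.51 $\mu$m$^3$ for $R_0 = 2\,\mu$m) exactly.

**Surface tension.**  The Laplace–Beltrami (cotan) form: the nodal force
is the exact gradient of the triangulated surface area, treated
semi-implicitly.  Pressure-type interface loads (gas pressure, drive) use
the exact discrete *volume gradient* rather than facet-area normals: with
both forces derived from one energy ($\sigma A - \int p\,dV$), the
interface force field is variational and cannot pump energy through the
node-level quadrature mismatch that mixed pairings exhibit on irregular
triangulations.  The small residual imbalance between the discrete
curvature of the faceted sphere and the Laplace pressure is removed by
subtracting the $t=0$ interface residual (rescaled with the bubble radius),
so the rest state is an exact discrete equilibrium.

**Time stepping.**  BDF2 (BDF1 startup) at a fixed $\Delta t = 3$ ns for
all unknowns, monolithic: one sparse linear solve per step couples blood
velocity/pressure, solid displacement/pressure, bubble volume and gas
pressure.  Kinematic wall coupling is exact by construction (the wall
fluid velocity is eliminated in favour of the solid displacement rate);
dynamic continuity follows from summing fluid and solid weak forms over
the shared interface test functions.  Interface nodes move along fixed
rays from the bubble center by the distance that reproduces the
mass-consistent normal displacement (with one smoothing pass over the
surface graph: pointwise nodal speeds at the structured grid's poles and
symmetry ring carry stencil noise that would otherwise feed back into the
shape during collapse).  Blood interior nodes follow an algebraic
transfinite blend between the interface and the wall with frozen grading
weights — exact for the layered topology and immune to inversion for the
amplitudes simulated; the general-purpose stiffened harmonic smoother
`smooth_mesh()` backs arbitrary boundary motion.  The linear systems are
Ruiz-equilibrated (the raw SI system spans $\sim$45 orders of magnitude)
and solved with a frozen sparse LU reused across steps as a
preconditioner for iterative refinement; the factorization is refreshed
only when refinement stalls.

**Drive injection.**  The domain ($\sim$60 $\mu$m) is far below the 1.5 mm
acoustic wavelength, so the incident wave is a spatially uniform,
time-varying far-field pressure $p_d(t)$.  It is absorbed into the gauge
stress of *both* phases (fluid and solid): the only weak-form trace is
$+p_d\int\nabla\cdot\varphi$ on each phase, which loads the bubble
interface and the outer tissue boundary consistently.  Gauging only the
fluid would be screened entirely by a uniform pressure shift in this
nearly-sealed incompressible domain.

**Boundary conditions.**  Symmetry plane $x=0$: zero normal
velocity/displacement, tangentially free.  Solid axial ends: zero normal
displacement.  Outer boundary of the absorbing layer: traction-free — in
the drive gauge this *is* the incident-pressure load, and a free surface
lets the nearly incompressible surroundings accommodate bubble volume the
way an unbounded medium would.  The absorbing layer itself is a
mass-proportional sponge ramped quadratically over the layer with peak
rate $8\,c_p/\text{thickness}$, a value set by the one-dimensional pulse
test (`absorbing_layer_reflection()`: $\lesssim 1\%$ energy reflection,
against $\sim 100\%$ for the bare truncation).

**Axial ends of the blood.**  The modelled segment is a window onto an
axially unbounded vessel.  Sealing the lumen (zero normal velocity, the
literal "symmetric" reading) makes bubble growth nearly impossible: an
incompressible column behind a 1.5 MPa wall would need MPa-scale pressures
to accommodate the observed volume amplitudes, and reference amplitudes
for these conditions (peak volumes above 100 $\mu$m$^3$ even in narrow
vessels) rule that out.  The default therefore loads the end planes with
the characteristic impedance of the compliant tube,
$\rho\,c_{MK} v_n$ with the Moens–Korteweg pulse-wave speed
$c_{MK} = \sqrt{E h / (2\rho r_i)}$ ($\approx 6$ m/s here), so pressure
pulses leave the window as they would continue along the vessel; `"open"`
(zero impedance) and `"symmetric"` (sealed, a periodic bubble array) are
available for comparison.  At these parameters the tube impedance is small
and the behaviour is close to open.

# Wall stress extraction

The hoop stress uses the thick-cylinder (Lame) formula evaluated at the
inner surface from the wall pressure at the nine azimuth stations in the
bubble-center plane.  The default wall pressure is the *bubble-scattered*
part (the perturbation beyond the instantaneous ambient): the incident
ultrasound pressurizes the vessel from inside and outside alike and hence
carries no net circumferential load; including it would add a
$\sim$10$\times$130 kPa artificial swing to every trace
(`gauge = "total"` is available for comparison).  Wall shear is the
signed axial component of the viscous traction from the blood-side
velocity gradient, which reduces exactly to
$\mu(\partial v_y/\partial z + \partial v_z/\partial y)$ at the 0° and
180° stations where the wall normal is along $y$; the unsigned tangential
magnitude is available as an option.

# What the tests do and do not show

The test suite builds all fixtures in code.  The radial tier is checked
against closed forms (equilibrium, Minnaert/linearized resonance with the
viscous damping shift removed, linear driven response) and against an
independent fixed-step RK4 integration.  The coupled tier is checked
against *constructed* truths: an exact discrete rest state, a manufactured
Stokes solution under refinement, the plane-strain Lamé thick-cylinder
solution, the 1D absorbing-layer pulse, and conservation/constraint
residuals (incompressibility, gas mass, symmetry).  Trend-level
comparisons against the reference microvessel study are run at reduced
resolution and horizon (see below); they probe orderings and symmetries
(stress amplification with offset, volume suppression with vessel size,
asymmetry growth), not point values — absolute FEM stress magnitudes are
discretization-sensitive and are only checked for order of magnitude.
None of this certifies behaviour of real vessels: the model is Newtonian,
isothermal, linear-elastic, and truncated at tens of microns.

# Problem sizes used by the shipped tests and drivers

The suite and the acceptance script are sized for a single desktop core:

* validation runs (2 µm bubble centered in a 20 µm vessel): coarse preset
  with 8 radial shells, 2.5 µs horizon at Δt = 3 ns; the refinement pair
  for the convergence check uses a 1.2 µs horizon;
* the two eight-case sweeps: the `reduced` preset, 1.5 µs horizon at Δt = 6 ns —
  long enough to cover the first two oscillation cycles where the
  reference extrema occur (reported extrema times are at or below
  1.3 µs);
* unit tests use runs of 20–50 steps.

These are the package's default trade-off between runtime and fidelity;
all knobs (`resolution_params()`, `solver_config()`) are exposed.

# Known limitations

* The coupled tier reproduces the radial-dynamics oracle to within
  10–20% RMS over multiple cycles at the shipped resolutions.  The
  deviation is insensitive to the time step, to mesh refinement and to
  the interface-motion filtering, i.e. it is the converged behaviour of
  this model (truncated compliant-tube physics, which lets the driven
  oscillation gain some amplitude cycle over cycle), not a discretization
  artifact; the first oscillation cycle agrees to better than 10%.
* The mixed-P1 solid is ~8% stiff on the static thick-cylinder benchmark
  at the medium mesh (a consequence of linear elements at ν = 0.49 on
  anisotropic extrusions; a quadratic-displacement discretization would
  be tighter).
* Azimuthal symmetry of the discrete solution for a centered bubble holds
  to a few percent only: the per-angle spread of the peak scattered-
  pressure hoop stress is ~5–10% at the shipped resolutions (node-scale
  pressure noise around the ring), and the peak asymmetric ratio across
  an offset sweep carries comparable noise, so its growth with offset is
  a trend, not a strictly monotone sequence, at these sizes.
* No thermal effects (isothermal gas), no shelled bubbles, no
  non-Newtonian rheology, no background flow, no vessel rupture criteria.
* The structured mesh cannot remesh topologically; runs abort with a
  diagnostic if element quality collapses (extremely violent collapse or
  near-contact cases).
* Stress extraction uses the thick-cylinder surrogate at the wall
  stations; it is a wall-pressure functional, not an intramural stress
  tensor analysis.
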