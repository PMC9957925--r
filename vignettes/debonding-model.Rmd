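---
title: "An adhesive-frictional contact model for bone-implant debonding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An adhesive-frictional contact model for bone-implant debonding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The mechanical problem

Cementless implants are held in bone first by press-fit and friction
(primary stability) and later by osseointegration, the direct structural
bonding of bone to the implant surface (secondary stability). When such an
implant is overloaded, the bone-implant interface *debonds*: the bonded
fraction of the interface is progressively destroyed and the contact
behaviour degrades from that of a bonded, adhesive interface to bare
Coulomb friction. `osseodebond` implements a phenomenological contact law
for this process inside a quasi-static, finite-strain finite-element
simulator, together with two ready-made removal scenarios: the planar
coin-shaped implant (CSI) used in animal debonding experiments, and a
press-fit acetabular cup implant (ACI) removed by pull-out, lever-out, or
torsion.

## The interface law

Every contact quadrature point on the bone side of the interface carries a
bonding state $\phi \in [0, \phi_0]$, where $\phi_0$ is the initial degree
of osseointegration. The state is a smooth, non-increasing function of the
accumulated interface deformation $g_d$,

$$\phi = \phi_0 \cdot
\begin{cases}
1 & c_1 < 1\\[2pt]
\tfrac12 - \tfrac12\sin\!\big(\tfrac{\pi}{2 b_s}(c_1 - b_s - 1)\big) &
  1 \le c_1 \le 1 + 2 b_s\\[2pt]
0 & c_1 > 1 + 2 b_s
\end{cases}
\qquad c_1 = g_d / a_s,$$

with a displacement threshold $a_s$ and a transition-zone width $b_s$
(`state_function()`). The damage $g_d = g_s + g_{sn}$ adds the accumulated
tangential slip of the interacting point and the accumulated change of the
normal gap; both are sums of increment magnitudes, so they grow
monotonically even under load reversal (`update_damage()`). During pure
sticking with an unchanged normal gap the state does not evolve.

The friction coefficient interpolates between the bonded and broken values,
$\mu(\phi) = \phi\,\mu_{ub} + (1 - \phi)\,\mu_b$
(`friction_coefficient()`). Three law variants are provided:

* **Coulomb** -- constant $\mu = \mu_b$, no adhesion (the classical
  press-fit baseline);
* **MC** (modified Coulomb) -- state-dependent $\mu(\phi)$, no tensile
  support: the sliding limit is $\mu(\phi)\,p$ with the contact pressure
  $p$;
* **EMC** (extended modified Coulomb) -- MC plus an exponential cohesive
  zone in the normal direction,
  $t_n = \phi_0 t_0 \,(g_n/g_0)\, e^{1 - g_n/g_0}$ for
  $0 \le g_n < g_b$, which peaks at $\phi_0 t_0$ for $g_n = g_0$ and drops
  sharply to zero at the cutoff $g_b$ or once $\phi = 0$
  (`normal_traction()`), and an adhesion-shifted sliding limit
  $t_t^{slide} = \mu(\phi)(t_0 - t_n)$ (`sliding_limit()`), so that
  frictional resistance persists under tension.

Penetration is penalised linearly with modulus $\varepsilon_n$. Three
details are implementation decisions where the published description is
silent:

* the sliding limit is clamped at zero from below ($t_n > t_0$ would
  otherwise give a negative, unphysical limit);
* a point whose gap exceeds $g_b$ (or that leaves the master surface)
  is *open*: its traction vanishes and its history is frozen, because no
  interacting point exists from which further damage could be measured;
  on re-contact a fully debonded point behaves as bare Coulomb friction
  while a partially bonded point resumes the cohesive branches;
* the $\varepsilon_n = \phi_0\,e\,t_0/g_0$ choice that makes the traction
  curve slope-continuous at $g_n = 0$ (`smooth_penalty()`) is available,
  but the scenario builders use the scenario-level penalty
  $\varepsilon_n = \varepsilon_t = E_b/L_0$ throughout, which is what the
  removal studies themselves use; for $\phi_0 = 0$ the smooth choice
  degenerates to zero and a floor penalty is required anyway.

The amplitude $t_0$ is calibrated from pull-out experiments on polished
coin-shaped implants: a uniformly separating circular interface of radius
$R$ peaks at $F = \phi_0 t_0 \pi R^2$, and the measured 9 N at
$\phi_0 = 0.26$ ($R = 2.5$ mm) gives $t_0 \approx 1.8$ MPa
(`calibrate_t0()`, `uniform_pullout_peak()`).

One known tension in the source material: the published discussion of the
cup torsion test states that the post-debonding EMC plateau depends on
$\phi_0$, which the printed sliding limit $\mu(\phi)(t_0 - t_n)$ cannot
produce at $\phi = 0$. The printed law is implemented literally.

## Finite-element treatment

All bodies are compressible Neo-Hookean
($\sigma = \tfrac{\Lambda}{J}\ln J\, I + \tfrac{G}{J}(b - I)$), discretised
with 8-node hexahedra and $2^3$ Gauss points; the consistent spatial
tangent is verified against finite differences to $10^{-6}$ relative
accuracy in the tests. Contact uses a master-slave scheme: the bone
surface is the slave and carries the interface states (osseointegration is
a property of the peri-implant bone; the published description does not fix
this choice), the implant surface is the master. Slave facets carry a
$5\times5$ Gauss rule; each point is projected onto the master surface by
clamped Newton iteration on the bilinear facets, with an axis-aligned
broad phase and a search radius of $3 g_b$. A projection that clamps onto
a free boundary edge of the master surface marks the point open.

Sticking is regularised by a tangential penalty spring $\varepsilon_t$
anchored at the *interacting point*, a material point of the master
surface: the anchor is fixed while the point sticks and trails the contact
point at distance $t_t^{slide}/\varepsilon_t$ while it slides. The slip
increment of the damage law is the travel of this anchor, so elastic
closest-point drift during sticking does not create spurious damage.
Interface history (slip, gap change, state, anchor) is committed once per
*converged* load step, never inside the Newton loop, so the accumulated
damage is independent of the iteration path. Whether gap changes on the
tensile cohesive branch should accumulate into $g_{sn}$ is not fully
explicit in the source; they do here (damage accrues wherever a projection
exists), and only open points are frozen.

Because the bilinear facets are chords of the nominal shapes, a discrete
disc or sphere is systematically undersized -- which would directly bias
the contact area of the coin face and the interference fit of the cup. The
mesh generators therefore inflate the vertex positions so that the facet
polygon of the coin face encloses exactly $\pi R^2$ and the area-weighted
mean radius of the spherical surfaces equals the nominal radius
(chord-sag compensation). The quadratic surface enrichment used in the
original study is *not* reproduced; the published acceptance tolerances
absorb the remaining surface-smoothness difference.

## Solver

Each load step solves quasi-static equilibrium by Newton iteration on the
reduced system (prescribed displacements and generalized constraint columns
are condensed through a sparse transformation). The tangent is factored by
supernodal sparse Cholesky -- it is symmetric by construction, as the slip
tangent is symmetrised -- with sparse LU as fallback for indefinite
tangents on the cohesive softening branch. The factorisation is reused
across iterations while the residual contracts and reassembled when
convergence stalls (typically after stick-slip status changes). Defaults:
relative residual tolerance $10^{-8}$, at most 40 iterations, recursive
step bisection up to depth 4. Penalty frictional contact can settle into a
tiny stick-slip limit cycle in which the residual stagnates instead of
contracting; a stagnated iterate is therefore accepted once its residual is
below $10^{-4}$ of the load scale (a fraction of a newton here, far tighter
than typical commercial contact-solver force tolerances). These are solver
choices; the published study does not state its tolerances.

Force-controlled stages (press to $-70$ N, pull to $+20$ N, insertion to
$-2500$ N) are displacement-driven with force monitoring: the driver ramps
until the resultant crosses the target and then lands on it with a secant
sub-step computed from the *pre-step* state, so the committed history never
contains the overshoot. Constant-force holds during sliding or rotation tie
the vertical translation of the driven surface to a single unknown carrying
the held load. A tensile hold becomes unsupportable the instant the
remaining bonded capacity falls below the held force; the stage then ends
with the abrupt loss of contact and zero reactions, which is exactly the
experimentally observed failure mode.

## Scenarios and study conditions

**Coin-shaped implant** (`csi_config()`, `build_csi()`, `run_csi_test()`):
titanium cylinder ($R_i = 2.5$ mm, $H_i = 3$ mm, $E_i = 113$ GPa) centred
on a bone block ($12.5 \times 12.5 \times 5$ mm, $E_b = 18$ GPa,
$\nu = 0.3$), meshed with 18 implant and 450 bone elements (the published
resolution; `refine` scales it). Law parameters: $a_s = 22\,\mu$m,
$b_s = 0.74$, $\mu_{ub} = 0.44$, $\mu_b = 0.3$, $t_0 = 1.8$ MPa,
$g_0 = g_b = 3 a_s$ (the published table lists $g_b = a_s$, but the
accompanying text states $g_b = g_0 = 3a_s$, which is used here),
$\varepsilon = E_b / 0.01\,$m. Steps: $0.65\,\mu$m displacement,
$0.1^\circ$ rotation. The test families are mode IIa/IIb (slide under
$-70$ N / $+20$ N hold), mode IIIa/IIIb (rotation under the same holds),
and mixed mode I+II at angle $\alpha$. Tension holds are meaningful for
the EMC only; the MC interface cannot equilibrate tension.

**Acetabular cup** (`aci_config()`, `build_aci()`, `run_aci_removal()`):
bone cylinder (radius 50 mm, height 40 mm, bottom clamped) with a
hemispherical cavity $R_b = R_i - IF/2$ for the cup of outer radius
$R_i = 25.5$ mm (inferred from the published $L_0 = R_I = 0.0255$ m);
reference case $E_b = 0.2$ GPa, $IF = 1$ mm, $\mu_b = 0.3$,
$\mu_{ub} = 1.5\mu_b$, $a_s = 128\,\mu$m, $b_s = 1.84$,
$\varepsilon = E_b/0.0255$ m. The cup is a 3 mm hemispherical shell (the
cup thickness is not published; only the outer surface governs the
interface). The surgical ancillary is modelled as a rigid driver attached
to the cup inner surface: a steel shaft shortens by only about a
micrometre under the staged loads, which is negligible against the
millimetre-scale protocol. The 2 mm rim fillet is modelled as a
tangent-arc surface profile blending the cavity sphere into the flat top,
and the surface grids of both the cavity and the cup are graded towards
the rim, where the press-fit contact forces vary most strongly.

The protocol has three stages: (1) insertion -- the cup starts with its
centre $\sqrt{R_i^2 - R_b^2}$ above the cavity centre (the first geometric
contact of the interfering shapes, at the cavity rim) and is pushed down
until the vertical reaction reaches $F_0 = -2500$ N, recording the
attained displacement $d_0$; (2) osseointegration -- $\phi_0$ is assigned
homogeneously and the accumulated damage is zeroed (insertion damage does
not pre-consume the new bond: the healing period regrows the interface,
and without the reset the centimetre-scale insertion slide would destroy
any bond before removal), while the mechanical state -- contact pressures
and frictional stick -- is kept exactly as inserted: the implant stays
wedged in its primary-stability state, which is the state the bond forms
around, and the removal stage starts from the full $F_0$ preload as in the
published load-displacement curves; (3) removal by mode I (pull up by
$d_0$), mode II
(lateral lever-out through a rigid lever), or mode III (rotation by
$10^\circ$ in 100 steps).

### Problem sizes

The CSI runs use the published mesh exactly. The ACI default is a
desk-scale resolution -- a $16\times16$ cavity surface grid with 7 graded
radial layers ($\approx 1800$ bone elements) and a $12\times12\times2$
cup shell -- roughly a tenth of the full-study element count; the full
resolution is reachable through `mesh_scale`. Insertion uses 50 um steps
(about 90 steps to reach $-2500$ N, matching the published stage-1 step
count), removal the published 100 steps. At this resolution the removal
quantities are mesh-converged at the few-percent level
(`csi_convergence()` provides the refinement ladder used for this check),
which is well inside the published acceptance bands.

## What the scenarios do and do not emulate

The simulated protocols reproduce the *idealised* published experiments:
homogeneous, isotropic bone; perfectly smooth, rigidly bonded-or-sliding
interfaces described by the point-wise law; homogeneous osseointegration
fields; quasi-static loading. Passing the acceptance checks therefore
shows that the implementation reproduces the published model under the
published conditions -- not that the model predicts any individual
patient's implant stability. Real interfaces add surface roughness,
heterogeneous and time-dependent bone properties, cortical shells,
anatomical geometry and dynamic loading, all explicitly outside scope, as
are bone in-growth/remodelling coupling and rate- or healing-time
dependent law variants. Per-point $\phi_0$ fields are supported by the
state storage (heterogeneous osseointegration), though the shipped
scenarios exercise homogeneous fields only.

## Known limitations

* Lagrange facets instead of the original smooth surface enrichment make
  sliding responses slightly faceted; at the CSI resolution this is within
  a few percent of the published peaks.
* The mode II cup removal drives a rigid lever; the elastic ancillary
  shaft of the original study would soften the load train marginally.
* Stick-slip oscillations after the force peak are under-resolved at
  large step sizes, as in the original (quasi-static) study.
* The cup-insertion end state carries its vertical load over a broader
  band of the cavity than the original rim-concentrated solution; the
  distribution is converged under refinement of the cup surface, the bone
  grid, the rim grading and the fillet model here, but quantities weighted
  by the torque arm (the torsional friction plateau in particular) come
  out correspondingly lower. The coin-shaped-implant responses, which have
  no such press-fit state, are unaffected.
* The tensile-hold stages end at the abrupt loss of equilibrium; the
  post-failure free flight of the implant is not simulated.
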