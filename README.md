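# osseodebond

Finite-element simulation of bone-implant interface debonding under
coupled adhesion and friction.

Cementless implants are fixed first by press-fit and friction (primary
stability) and later by osseointegration — direct structural bonding of
bone to the implant surface (secondary stability). Overloading destroys
this bond progressively. `osseodebond` implements a state-variable contact
law for that process and embeds it in a quasi-static, finite-strain
finite-element solver, for researchers in implant biomechanics who want to
predict removal forces and torques of partially osseointegrated implants
and study how they depend on bone quality, interference fit, friction and
the degree of osseointegration.

## The model

Each contact point of the bone-implant interface carries a bonding state
φ ∈ [0, φ₀] given by a smooth, non-increasing function of the accumulated
interface deformation g_d = g_s + g_sn (irreversible tangential slip plus
accumulated normal-gap change):

    φ = φ₀            for g_d < a_s,
    φ = φ₀ [½ − ½ sin(π/(2 b_s) (g_d/a_s − b_s − 1))]
                       for a_s ≤ g_d ≤ a_s (1 + 2 b_s),
    φ = 0             beyond.

The friction coefficient blends the unbroken and broken values,
μ(φ) = φ μ_ub + (1 − φ) μ_b (the **modified Coulomb law**, MC). The
**extended** law (EMC) adds an exponential cohesive zone in the normal
direction, t_n = φ₀ t₀ (g_n/g₀) exp(1 − g_n/g₀) up to a cutoff gap g_b,
and shifts the sliding limit to μ(φ)(t₀ − t_n) so that frictional
resistance persists under tension. Penetration is penalised linearly.
The cohesive amplitude comes from pull-out experiments on coin-shaped
implants through F = φ₀ t₀ π R² (9 N at φ₀ = 0.26, R = 2.5 mm gives
t₀ ≈ 1.8 MPa).

Two scenario families are built in:

* **CSI** — a coin-shaped titanium implant on a bone block, slid, rotated
  or pulled off under constant compression (−70 N) or tension (+20 N);
* **ACI** — an acetabular cup press-fit into a reamed cavity
  (R_b = R_i − IF/2), inserted to −2500 N, osseointegrated, and removed by
  pull-out, lever-out or torsion.

## Worked example

The standard mode II debonding test: press the coin-shaped implant to
−70 N, apply full osseointegration, then slide in x under the constant
compression, with the modified Coulomb law:

```r
library(osseodebond)

h <- run_csi_test(test = "IIa", cfg = csi_config(law = "mc"))
peak_metrics(h, stage = "slide")
#> # A tibble: 1 × 5
#>   F_x_max F_z_max  M_z_max M_z_plateau          d0
#>     <dbl>   <dbl>    <dbl>       <dbl>       <dbl>
#> 1    29.8   -70.0 3.04e-10   -1.51e-11 -0.00000244
```

The tangential force rises while the interface sticks, peaks at 29.8 N —
the sliding limit μ(φ₀)·70 N of the fully bonded interface — and then
decays toward the broken-state Coulomb level μ_b·70 ≈ 21 N as the
accumulated slip destroys the bond (the published peak for this test is
30 N).
`F_z_max` confirms the −70 N hold; `d0` is the 2.4 μm press depth.
`autoplot(h)` draws the force, torque and mean-bonding curves;
`tidy(h)`/`glance(h)` give long-format and one-row summaries. With
`csi_config(law = "emc")` the same test peaks near 45 N because the
cohesive tension t₀ also shifts the sliding limit.

Scenarios can also be described declaratively and run from a file or the
thin CLI wrapper:

```r
run_config(system.file("extdata", "csi_mode2a.yaml", package = "osseodebond"))
```

```sh
inst/cli/osseodebond calibrate-t0 --force 9 --phi0 0.26 --radius 2.5e-3
#> 1.76295e+06
```

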