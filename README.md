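# peristalsim

A discrete-multiphysics model of intestinal peristalsis with a
stretch-sensing neural controller.

## What it is for

High-amplitude propagating contractions (HAPCs) move luminal content
(chyme) through the colon: a ring of circular muscle contracts behind the
bolus and the contraction travels down the tube.  How fast the wave should
travel depends on the content — push a watery bolus too fast and fluid
leaks backwards past the incompletely closed lumen; push a viscous one too
slowly and transport stalls.  The enteric nervous system solves this with
a neuromechanical loop: stretch sensors in the distending *receiving*
segment drive the contraction of the *propulsive* segment behind it.

`peristalsim` is for computational physiologists and biomechanics
researchers who want a self-contained, particle-based sandbox of that
loop: the wall mechanics, the fluid, the controller and its training are
all in one package, so one can ask how transport depends on wave speed and
viscosity, what a stretch-only controller can and cannot learn, and what
happens when its perception is distorted (a minimal model of inflammatory
bowel disease).

## The model in brief

Everything is particles.  The membrane is a cylindrical lattice of point
masses joined by Hookean springs, `F = k (r - r0)`; the fluid is weakly
compressible SPH with the Tait equation of state

    P = (c0^2 rho0 / 7) [ (rho/rho0)^7 - 1 ]

and a pairwise artificial viscosity
`Pi_ij = -alpha h c0 (v_ij . r_ij) / [(rho_i + rho_j)(r_ij^2 + b h^2)]`;
membrane and fluid repel through `U = A [1 + cos(pi r / r0)]` for
`r < r0`.  A constant inward radial force `f` on a window of length
`dL` emulates the muscle contraction; the window travels at `v_WAVE`.
The two observables are the fluid centre-of-mass velocity `v_COM`
(transport) and the receiving segment's mean diameter strain `eps`.

The controller is a small softmax network (250 particle-strain inputs →
mean-pooling → 100 → 100 → 3) that every 0.1 s increases, maintains or
decreases `v_WAVE` by 0.1 cm/s.  It is trained with cross-entropy-method
reinforcement learning: batches of stochastic 5 s episodes at random
viscosity, keep the top 30% by reward (`v_COM`), fit the network to the
elite state-action pairs.  Digital inflammation of degree `phi` adds a
perceptual strain offset `eps_phi = phi eps / (100 - phi)` to the
controller's input and touches nothing else.

## Worked example

```r
library(peristalsim)

# a desk-scale tube (same physics constants as the full colon-scale model)
geom <- geometry_preset("micro")
tube <- build_tube(geom)
bonds <- build_springs(tube, geom$spring_cutoff, geom$L)
print(tube)

# constant 5 cm/s peristaltic wave at the three reference viscosities
for (mu in c(7.8e-3, 7.8e-2, 7.8e-1)) {
  params <- physics_params(mu = mu)
  run <- simulate_static(tube, bonds, params, geom,
                         wave_state(0, v_wave = 0.05), duration = 5)
  cat(sprintf("mu = %.3g Pa s:  time-averaged v_COM = %.2f cm/s, plateau strain = %+.3f\n",
              mu, 100 * mean(run$v_com[-1]), plateau(run$epsilon[-1])))
}

# digital inflammation: at 50% the controller perceives twice the strain
profile <- inflammation_profile(data.frame(x_start = 0, x_end = geom$L, phi = 50))
inflammation_degree(eps_phi = 0.06, eps = 0.06)
perceive(0.04, x = 0.05, t = 0, profile, geom$L)
```

which prints

```
particle_state: 265 particles (160 membrane, 105 fluid), m=0.00025 kg
mu = 0.0078 Pa s:  time-averaged v_COM = 2.13 cm/s, plateau strain = -0.574
mu = 0.078 Pa s:  time-averaged v_COM = 2.27 cm/s, plateau strain = -0.094
mu = 0.78 Pa s:  time-averaged v_COM = 2.05 cm/s, plateau strain = -0.010
[1] 50
[1] 0.08
```

A 5 cm/s wave drags the content at ~2 cm/s on this small tube; the
strongly negative strain plateau at low viscosity is the wall left
partially collapsed after the wave has lapped the short periodic tube —
see the methods vignette (`vignettes/peristalsim-methods.Rmd`) for what
the desk presets do and do not establish.  The degree-of-inflammation
identity `phi(eps_phi = eps) = 50%` and the doubled perceived strain are
exact.

Full-scale experiments (the 14 578-particle tube of the reference
configuration) run through the same functions with
`geometry_preset("full")`, or from the command line:

```sh
Rscript exec/peristalsim sweep --preset full --out results/full
Rscript exec/peristalsim train --preset micro --out results/micro
Rscript scripts/full_scale_sweep.R --quick   # slow-tier emergent checks
```

A single full-scale 10 s run takes ~4 minutes; the 10-point sweep tens of
minutes.

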