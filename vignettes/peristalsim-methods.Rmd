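---
title: "Methods: a discrete-multiphysics tube with a stretch-sensing controller"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a discrete-multiphysics tube with a stretch-sensing controller}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`peristalsim` simulates high-amplitude propagating contractions (HAPCs) in a
fluid-filled flexible tube, the motility pattern that moves luminal content
through the colon.  Everything is particles (discrete multiphysics): the
membrane is a lattice-spring solid, the luminal content (chyme) a weakly
compressible SPH fluid, and the two phases interact through a short-range
repulsive potential.  A travelling radial force window emulates the circular
muscle contraction; its speed $v_{\mathrm{WAVE}}$ is either fixed ("static"
waves) or chosen every 0.1 s by a small policy network whose input-output
structure mimics the enteric nervous system's neuromechanical loop: stretch
sensors in the *receiving* segment (just downstream of the bolus) drive the
contraction of the *propulsive* segment behind it.

The two observables are the axial centre-of-mass velocity of the fluid
$v_{\mathrm{COM}}$ (the transport measure and the training reward) and the
mean Cauchy diameter strain $\varepsilon = (d - d_0)/d_0$ of the receiving
segment (the controller's only input).

### Force laws

* membrane bonds: Hookean springs $F = k\,(r - r_0)$ with
  $k = 0.5\ \mathrm{N\,m^{-1}}$;
* fluid pressure: Tait equation
  $P = \tfrac{c_0^2 \rho_0}{7}\left[(\rho/\rho_0)^7 - 1\right]$ with
  $\rho_0 = 10^3\ \mathrm{kg\,m^{-3}}$;
* fluid viscosity: pairwise term
  $\Pi_{ij} = -\alpha h c_0 \,(v_{ij}\cdot r_{ij}) /
  \left[(\rho_i + \rho_j)(r_{ij}^2 + b h^2)\right]$ with $\alpha = 1$,
  $b = 0.01$, $h = 1.2\times 10^{-2}$ m, added to the pressure bracket of the
  SPH momentum equation;
* membrane-fluid coupling: $U = A\left[1 + \cos(\pi r / r_0)\right]$ for
  $r < r_0$, $A = 2\times10^{-6}$ J, $r_0 = 6\times10^{-3}$ m (purely
  repulsive, keeps the phases from interpenetrating);
* contraction: a constant inward radial force $f = 10^{-3}$ N on every
  membrane particle inside the window $[x_{\mathrm{wave}},
  x_{\mathrm{wave}} + \Delta L)$.

Integration is velocity Verlet at $\Delta t = 2\times10^{-3}$ s with periodic
axial boundaries (period $L$); there is no thermostat and no gravity.

### Viscosity map

The three modelled viscosities $\mu = 7.8\times10^{-3}$, $7.8\times10^{-2}$
and $7.8\times10^{-1}$ Pa s are realized through the artificial sound speed,
$c_0 = \mu / 1.56 \in \{0.005, 0.05, 0.5\}\ \mathrm{m\,s^{-1}}$: the
effective dynamic viscosity of the pairwise term scales like
$\alpha h c_0 \rho_0$, so one decade in $c_0$ is one decade in $\mu$.  A
consequence the user should be aware of: at the low end the flow is locally
*supersonic* ($v_{\mathrm{COM}} \sim 2c_0$), so order-one density excursions
are part of normal operation rather than a numerical failure.  The density
guard (`rho_guard`, default `c(0.05, 20)` in units of $\rho_0$) only catches
genuine blow-ups and aborts a run with a diagnostic naming the first
offending step.

### Density handling

The SPH density uses a *normalized summation* by default:
$\rho_i = \rho_0\, W_i / W_i^{(0)}$, where $W_i$ is the particle's current
fluid-fluid kernel sum (self term included) and $W_i^{(0)}$ the same sum in
the freshly built tube.  Each particle is its own reference, so the initial
state has $\rho = \rho_0$ exactly (hence zero initial pressure), the density
always tracks the actual particle configuration, and it can never go
negative.  A continuity-equation mode (`density = "continuity"`) is kept for
comparison; we found that in the supersonic low-$c_0$ regime the integrated
continuity density decouples from the configuration and drifts negative
within a fraction of a second — the pressure is simply too weak to couple
density errors back to particle motion — which is why it is not the default.

The SPH kernel is pluggable (`kernel = "lucy"` by default, `"wendland"`
available); emergent quantities shift by a few percent between kernels,
which is part of why the full-scale transport checks carry a ±20% band.

### Geometry

The reference ("full") tube is $L = 0.63$ m long with radius $R = 0.025$ m
and contraction window $\Delta L = L/10 = 0.063$ m.  The membrane is a
100 × 25 cylindrical lattice (2500 particles, ~6.3 mm spacing both ways;
exactly 250 particles in any ring-aligned window).  The interior fluid is
12 078 particles in 99 axial discs of 122, each disc a set of concentric
circles (counts 1, 6, 12, 18, 24, 30, 31) reaching to $R - 6.5$ mm.  Only
the totals 2500 and 12 078 are mandated; the 99 × 122 factorization and the
disc layout are reconstructions.  The clearance is chosen at or above the
coupling range $r_0$ so that the freshly built tube is an *exact* force
equilibrium — a property the test suite asserts to machine precision.

Spring bonds connect all membrane pairs within 1.5 lattice spacings (2
axial + 2 circumferential + 4 diagonal neighbours each); each bond's rest
length is its built length, so the lattice is stress-free at construction.
A uniform rest length would pre-stress the diagonals.

Two scaled-down presets keep every force constant and interaction range
unchanged and shrink only the tube: `mini` (25 × 12 membrane, 456 fluid,
$L = 0.1575$ m, $R = 0.0125$ m) for desk-scale physics tests and `micro`
(16 × 10 membrane, 105 fluid, $L = 0.1008$ m, $R = 0.010$ m) for desk-scale
training.  Because the interaction ranges stay fixed, the lattice *spacing*
is preserved and the presets are smaller tubes, not coarser ones.  What a
green mini/micro test establishes is therefore the mechanism (transport by
a travelling contraction, an interior transport optimum, learnability of
the speed policy), not the full-scale numbers: the small tubes are lapped
by the wave every few seconds, their lumen holds proportionally less fluid,
and their walls are floppier relative to the contraction force, all of
which shift magnitudes.

### Observables and estimators

$\varepsilon$ is measured ring-wise: a ring's diameter is twice the mean
radial distance of its particles, rings are assigned to the receiving
window by the circular mean of their axial positions, and $\varepsilon$
averages over rings.  $v_{\mathrm{COM}}$ is the finite difference of the
fluid's unwrapped mean axial coordinate over the 0.1 s reporting interval.
Steady-state values use the mean over the final second ("plateau").  For
the small presets, sweeps additionally report the net displacement divided
by the duration (`v_com_avg`), which averages out the sloshing that
dominates a short periodic tube after the wave has lapped it several
times; the desk-scale sweep-shape test asserts unimodality on that
statistic over an 8 s run.

## The controller

The policy network follows the enteric circuit: the receiving segment's
membrane particles are the input layer (one strain per particle — 250 in
the full tube), a pooling stage averages them to the scalar $\varepsilon$,
two ReLU hidden layers of 100 units follow, and a 3-unit softmax outputs
the probabilities of increasing, maintaining or decreasing
$v_{\mathrm{WAVE}}$ by $\Delta v = 0.1\ \mathrm{cm\,s^{-1}}$.  Decisions
are taken every 0.1 s; the network slides with the wave so its input is
always the receiving segment.  The strain is fed as a dimensionless
fraction without normalization.  The wave speed is clamped to
$[0, 0.15]\ \mathrm{m\,s^{-1}}$: the floor is physical (no retrograde wave
is modelled), the ceiling is 1.5× the largest swept speed and exists only
for numerical safety.  Training rollouts sample actions from the softmax;
evaluation runs are greedy with ties broken toward the lowest action index.

## Training

Cross-entropy-method reinforcement learning: run a batch of 10 stochastic
5 s episodes (each starting at rest with a log-uniform random viscosity in
$[7.8\times10^{-3}, 7.8\times10^{-1}]$ Pa s), keep the episodes at or above
the 70th reward percentile (the top 30%, ties included), and take one
full-batch Adam step minimizing the categorical cross-entropy between the
policy and the elite state-action pairs.  The reward is the net axial COM
displacement divided by the episode duration (a time-averaged
$v_{\mathrm{COM}}$).  The default budget is 20 000 episodes.  Episodes that
trip the density guard receive a $-\infty$ sentinel and can never be elite.

Two readings of the batching prose are supported: each episode drawing its
own viscosity (default) or one viscosity shared per batch
(`mu_sampling = "per_batch"`).

### The surrogate environment

Trainer correctness is tested against an analytic stand-in with the same
episode interface: the strain responds instantaneously as
$\varepsilon = 1.2\, v\, \mu/\mu_{\mathrm{ref}}$ and the reward is the
episode-time average of $g(v) = (v/v^\ast)\exp(1 - v/v^\ast)\,v^\ast$, a
smooth unimodal transport rate with a known optimum $v^\ast$ (1 cm/s by
default).  For a constant-speed rollout the reward reduces to
$g(\bar v)$, so a grid scan recovers $v^\ast$ exactly.  We use the
*integrand* form rather than a function of the final mean speed because it
mirrors the physics (excessive speed causes backflow while the wave runs,
not retroactively at the end of the episode) and because it is what makes
the back-off action learnable: with a purely terminal reward the elite set
contains no within-episode signal against overshooting, and the trainer
reliably collapses to an always-accelerate policy.

Two desk-scale choices are made once and documented here: training tests
run at a learning rate of $3\times10^{-3}$ (the reference setup's ~2000
Adam updates are compressed into a few hundred), and the known-optimum
recovery is asserted on the *settled* greedy speed (the mean over the
second half of the rollout), because a 5 s episode that must ramp from
rest at $\Delta v$ per decision spends its first second below any optimum
by construction.

## Digital inflammation

Inflammation changes perception, not physics: the degree of inflammation
$\varphi = 100\,\varepsilon_\varphi / (\varepsilon + \varepsilon_\varphi)$
defines the strain offset $\varepsilon_\varphi$ added to the controller's
pooled input, so $\varphi = 50\%$ doubles the perceived strain.  A profile
maps axial position to $\varphi$ (piecewise-constant regions, looked up at
the receiving segment's midpoint) with an optional onset time $t_0$ before
which the whole tube is healthy.  Because $\varepsilon_\varphi$ depends on
the instantaneous strain, the offset is recomputed at every controller
step, keeping $\varphi$ — the stated control variable — constant within a
region.  Negative true strains (a locally collapsed wall) pass through
unmodified, since the offset is only defined for distension.  The test
suite asserts bit-identical trajectories between healthy and inflamed runs
when the action sequence is pinned, which is the operational meaning of
"perception-only".

## Numerical choices and degenerate inputs

* Neighbour search: type-split Verlet lists (fluid-fluid within $h$ + skin,
  membrane-fluid within $r_0$ + skin, skin = $0.25\max(h, r_0)$), rebuilt
  when the accumulated maximum displacement reaches half the skin, on top
  of a cell grid that is periodic in x.  Pair forces are accumulated
  antisymmetrically, so momentum conservation holds to round-off by
  construction.
* The summation-density reference $W_i^{(0)}$ is attached to the freshly
  built state (automatically on first use); re-anchoring a deformed state
  would redefine its rest density.
* Window membership uses half-open intervals $[x_0, x_0 + w)$ on wrapped
  coordinates; tiling windows therefore partition the membrane exactly.
* Greedy argmax ties take the lowest action index; `quantile(type = 7)`
  defines the elite threshold, with all records at the threshold included.
* Empty receiving segments, non-positive densities, cutoffs below the
  lattice spacing, $\varphi \ge 100$ and invalid action distributions are
  rejected with errors rather than coerced.

## Known limitations

* The membrane has no bending stiffness, so strongly squeezed rings can
  buckle rather than re-expand, and there is no explicit membrane damping
  (dissipation reaches the wall only through the fluid); small presets
  show persistent negative strain after repeated laps.
* At the lowest sound speed the fluid is effectively pressureless dust on
  contraction time scales; transport is then dominated by the coupling
  potential (the wall "carrying" the fluid), which is faithful to the
  stated constants but far from incompressible hydrodynamics.
* The full-scale emergent numbers (plateau $v_{\mathrm{COM}}$,
  $v^\ast_{\mathrm{WAVE}}$) depend on kernel choice and run length at the
  ±20% level; the slow-tier script reports them but the desk suite asserts
  only qualitative shape.
* Inflammation is purely perceptual; aetiology, secretion and rheology
  changes are out of scope, as is any non-Newtonian behaviour of the chyme.
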