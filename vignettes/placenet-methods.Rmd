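---
title: "A normative place-cell network with center-of-mass decoding: models, parameters, and design choices"
author: "placenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{placenet methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(placenet)
```

## The model

`placenet` implements a normative model of hippocampal place cells. A
vanilla recurrent network with `N_g` rectified units (state `g`)
receives only a Cartesian velocity signal `v_t` and a constant one-hot
context signal `c` identifying the current arena, and projects linearly
onto `N_p` rectified output units (state `p`):

    g_{t+1} = relu(W_R g_t + W_I [v_t; c])
    p_t     = relu(W_p g_t)

The network's position estimate is *not* a trainable readout. Instead a
fixed, place-cell-inspired center-of-mass decoder is applied to the
output population. Each unit is assigned a center, its activity-weighted
average position over the trajectory,

    mu_i = sum_t p_i(t) x_t / max(eps, sum_t p_i(t)),

and the instantaneous position estimate is the activity-weighted
average of those centers,

    xhat_t = sum_i p_i(t) mu_i / max(eps, sum_i p_i(t)).

The training objective is the mean squared Euclidean error between true
and decoded positions plus an L1 penalty on recurrent activity with
coefficient `lambda = 10`. Because the initial state is zero (no
positional information), minimizing this objective forces the network
to path-integrate and to anchor its estimate by learning arena geometry
through boundary interactions. Trained at full scale, output units
develop unimodal place-like fields, recurrent units become
boundary-tuned, and moving the frozen network between contexts elicits
global remapping in the output layer and rate remapping upstream.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `N_g`, `N_p` | 500, 100 | recurrent / output units (full scale) |
| `lambda_l1` | 10 | L1 coefficient on `g` |
| `epsilon` | 1e-8 | decoder zero-division guard |
| `sigma_step` | 0.5 | Rayleigh scale of step speed (arena units / time) |
| `kappa` | 4 | von Mises heading concentration |
| `dt` | 0.1 | forward-Euler step |
| trajectories | 15000 × 500 steps | dataset, 80/20 split by chain |
| chain length | 10 | trajectories sharing recurrent state |
| optimizer | Adam, lr 1e-4, batch 64, 100 epochs | full-scale protocol |

Three choices deserve comment because the underlying quantities are
genuinely open:

**L1 normalization.** The penalty is implemented as
`lambda * mean_t(|g_t|_1 / N_g)`. An unnormalized 500-unit 1-norm at
`lambda = 10` would dwarf a squared position error of order one; the
per-unit mean keeps the two terms commensurate. `loss_config(normalize_l1
= FALSE)` switches to the raw 1-norm.

**Gradients flow through the centers.** The decoder is non-trainable in
the sense of having no learnable parameters, but `mu` is a function of
the network output and sits inside the computational graph; the
backward pass differentiates through both the per-time estimate and the
trajectory-wide centers. `loss_config(detach_centers = TRUE)` provides
the stop-gradient variant. Centers are computed per trajectory per
batch lane over all timesteps (the defining expectations carry no
causal qualifier, so decoding within a trajectory is acausal).

**Arena dimensions.** The stock arenas are a 2.2 × 2.2 square centered
at the origin, a 3.3 × 3.3 large square, a 2.2 × 1.1 rectangle, a
circle of radius 1.1, the square with a thin dividing wall from
(0, 1.1) to (0, 0), and the square with a centered 0.73 × 0.73 hole.
These sizes make a decoding error of ~0.15 a plausible scale for a
well-trained full-size model; all of them can be rescaled via
`make_environment(..., scale = )`. The thin wall is stored as two
superimposed segments so that the ray-casting parity test is unaffected
while collision tests still see it; the hole is an extended object
whose single boundary loop the parity test handles natively.

## Trajectory simulation

Foraging paths draw step speeds from Rayleigh(0.5) and headings from a
von Mises centered on the previous heading with concentration 4,
integrated with `dt = 0.1`. A proposed step that intersects a wall has
its *heading* (never its speed) redrawn, which produces smooth paths
that turn away from boundaries. After 100 failed redraws the heading is
reversed and the speed halved until the step fits — a corner-escape
rule that guarantees progress; it fires on a vanishing fraction of
steps. Velocities stored with a trajectory are the realized
displacements divided by `dt`, i.e. the self-motion actually executed,
not the pre-collision proposal. Start positions are drawn by rejection
sampling from the arena bounding box; initial headings are uniform on
the circle.

Within a chain of 10 trajectories the environment of each trajectory is
drawn independently, and per-environment counts are exactly balanced
within each split. Chains are assembled once at dataset build time;
epochs permute chain order only.

## Training protocol

Training is stateful: each minibatch lane carries its recurrent state
across the 10 trajectories of its chain (detached at trajectory
boundaries, so BPTT never crosses a trajectory), and resets to zero at
chain boundaries. One Adam step is taken per trajectory position.
Validation mirrors this statefulness. Gradient clipping is off; the
identity initialization of `W_R` is the mitigation for exploding
gradients over the 5000-step effective sequences. A non-finite loss
aborts with a diagnostic rather than continuing silently.

### The scaled preset

`scaled_preset()` is the desk-scale protocol used by the tests and the
acceptance script: 128 recurrent / 64 output units, two environments
(square and square-with-wall), 1200 trajectories of 250 steps, 25
epochs. The preset fixes batch size 16 and learning rate 5e-4: with 120
chains this yields about 2000 Adam steps, a standard budget for a
network of this size, whereas the full-scale rate of 1e-4 belongs to a
~19000-step run. At this scale the trained model roughly halves the
untrained-baseline validation error (~0.35 vs ~0.71) rather than
reaching the ~0.15 of the full protocol; the remapping and attractor
signatures below are nevertheless already measurable.

## Experiment protocols

All experiment runners operate on frozen weights. The remapping episode
(square → square-with-wall → square) carries state across transfers and
aggregates binned output activity over 500 distinct 800-step
trajectories per condition. Per-condition ratemaps use a 500-step
burn-in per segment: condition ratemaps are meant to capture
steady-state representations, and both the zero-state start and each
context transfer are followed by a transient during which the
population settles (visible as the delayed correlation recovery in the
transition analysis). The recurrent state still evolves through
burn-in steps; they are only excluded from the maps.

Noise injection evaluates 1000 trajectories of 800 steps, replacing `g`
at step 400 by `relu(g + sigma * chi)`, and stores per-timestep binned
activity so population-vector correlation matrices can be computed
without retaining full state tensors. The noise draw can be given its
own seed so realizations vary at fixed paths. Velocity ablation zeroes
the velocity input from the injection time onward, isolating autonomous
dynamics from boundary-driven error correction. Context mismatch runs
simulate one geometry while feeding another context's one-hot signal.
Geometric manipulations (axis elongation, joint elongation, circle
expansion, hole filling) transform wall coordinates about the arena
center and re-simulate trajectories — paths are never warped — while
retaining the familiar context.

## Analysis conventions

**Ratemaps** divide summed unit activity by per-bin visit counts on a
16 × 16 grid over the arena bounding box (15 × 15 for
experimental-style maps); unvisited bins are undefined (`NaN`), never
zero. Smoothing uses a Gaussian kernel of one pixel with
NaN-interpolating renormalization: the kernel is renormalized over
defined bins, so uniform maps pass through unchanged and single
undefined bins are filled from their neighbors.

**Spatial correlation** is Pearson over jointly defined bins, maximized
over relative rotations {0, 90, 180, 270}° for square grids ({0, 180}°
for rectangular ones, where quarter rotations do not map the grid onto
itself). Shuffled nulls pair every active unit with every other active
unit across conditions; rate-overlap (`min/max`) and rate-difference
(`(a-b)/(a+b)`) nulls use 1000 random pairings. An *active* unit is one
with any strictly positive activity sample in the condition. The 95th
percentile uses R's default (type-7) quantile.

**Spatial information** is the Skaggs measure
`sum_i p_i (f_i/fbar) log2(f_i/fbar)` with `fbar` the
occupancy-weighted mean rate; zero-rate bins contribute zero and a
silent map scores zero. This is the standard bits-per-activity form; a
printed variant that multiplies rather than divides by `fbar` is
dimensionally inconsistent and was not used. High-SI units are those
above the per-environment 2.5th percentile in *every* environment
(strict inequality; at percentile zero all defined units are kept).

**Ripley's K** uses the edge correction
`f(x, y) = (k(x, y) + k(y, x))/2` where `k` is the reciprocal of the
fraction of the circle about one point through the other that lies
inside the domain. That fraction is computed by dense angular sampling
(720 samples, < 0.5° resolution, floored at 1/720 to keep reciprocals
finite); fully interior circles skip the sampling. Radii are 50
log-spaced values from 1e-8 to a quarter of the domain diagonal.
`H(R) = sqrt(K/pi) - R` is zero under complete spatial randomness. The
uniform baseline resamples points on the centers of a 15 × 15 grid
without replacement (grid-decoded field centers are distinct bins) and
reports a two-standard-deviation envelope over 100 samplings; an
analytic CSR band from the binomial pair-count approximation is also
provided. Field centers are decoded as the argmax bin of smoothed maps,
with ties broken to the first bin in column-major scan order, and KDE
uses an isotropic Gaussian of bandwidth 0.2 in the units of the points
on a 64 × 64 grid.

## What the synthetic data does and does not cover

The trajectory generator emulates semi-smooth rodent foraging —
Rayleigh speeds, persistent headings, wall avoidance — but not
head-direction dynamics, speed modulation near walls, reward-directed
runs, or replay of real animal paths. Passing tests therefore show that
the model and analysis pipeline behave correctly under the idealized
foraging statistics the model was specified for; they do not certify
behavior on real positional data, whose occupancy is far less uniform.
The mouse CA1 clustering analysis can be reproduced on external field
centers through the generic CSV + domain interface of the Ripley/KDE
pipeline, but no experimental data ships with the package.

## Numerical choices

Everything is computed in double precision (R's native numeric).
The decoder guard is `eps = 1e-8`; when a denominator is clamped the
corresponding gradient path treats it as a constant, matching the
subgradient of `max`. ReLU subgradients at zero are taken as zero.
Ray casting jitters a point's y-coordinate by 1e-9 when a horizontal
ray would pass exactly through a wall vertex; boundary points count as
inside, and the collision test nudges the step origin by 1e-9 toward
the target so a wall-touching walker can still move. Problem sizes in
the test-suite protocols (10^5-step fidelity samples, 10^6-step
crossing audits, 500 × 800-step remapping aggregation, 1000-trajectory
noise runs) were chosen so each statistic is comfortably resolved at
desk scale.

## Known limitations

The scaled preset does not reach the full protocol's asymptotic error,
and its representations are noisier: a minority of weakly active output
units fail the per-unit remapping threshold that full-scale units pass.
The decoder extracts a single center per unit, so multi-field place
codes are out of reach by construction. Wall-insertion experiments and
visual/sensory input are out of scope, as are gating or feedback
architectures.
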