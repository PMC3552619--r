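---
title: "Models and metrics of vertical pattern formation in microbial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and metrics of vertical pattern formation in microbial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micromix)
```

## The scientific question

When two microbial populations grow together on a surface, the vertical
cross-section of the resulting community carries a signature of their
ecological relationship.  Populations that merely compete for shared
resources demix into single-colored columns; when one partner outgrows or
feeds off the other, one population layers over the other; and strongly
cooperating partners build finely intermixed patchworks in which patches of
the two cell types accumulate alternately on top of each other.  `micromix`
implements two individual-based simulators of this process, the statistics
used to quantify the resulting patterns, the mean-field theory of pairwise
community composition, and a calculator for the length scale over which an
exchanged metabolite acts.

## The cell lattice and rearrangement rules

Both simulators share one on-lattice representation of the community
(`cell_lattice()`): a grid of 5 µm sites, periodic in x and y, with z = 1 the
colonization surface.  A dividing cell buds toward the *nearest empty site in
its own plane* within a confinement radius of `n = 2` sites; the chain of
cells between mother and target shifts outward one step to make room, and any
shifted cell left hanging is lowered until it rests on another cell or the
surface.  If the confinement neighborhood is full, the cell buds *upward*,
pushing its column up by one.  These rules mirror how surface-attached yeast
microcolonies behave: cells spread sideways while free space remains and send
progeny into upper layers once confined.  Two consequences worth knowing:

* no cell ever floats (enforced and tested as an invariant), and
* confined growth is strictly vertical, which *underestimates* intermixing
  relative to real communities where confined divisions can stray sideways.

Design choices the rules leave open, and how this package resolves them: the
chain shift follows the Bresenham line from mother to target (deterministic,
one new cell, purely local); equidistant empty targets are chosen uniformly
at random; and a push-up that would exceed the lattice top raises an error
rather than silently truncating the column.

## The fitness model

The fitness model abstracts away all molecular detail.  A focal cell of
population $i$ divides in a time step $\Delta t$ with probability $r_i
\Delta t$, where

$$ r_i = \left[ r_{i0} + \sum_{j \neq i} r_{ij}\,\phi_j (1-\phi_i) \right]
        \left[ 1 - \chi \sum_k \phi_k \right], $$

with $\phi$ the occupancy fractions of each population in the cubic
interaction neighborhood of halfwidth $l = 3$ sites around the cell
(`occupancy_fractions()`).  $r_{i0}$ is the basal fitness; the interaction
term grows with partner abundance and shrinks with the recipient's own
crowding; the second bracket penalizes total occupancy ($\chi = 0.8$
throughout).  Negative bracketed rates clamp to zero — the model has no
death, so strong inhibition appears as growth arrest.  With more than two
populations the crowding sum runs over all populations.

Parameter conventions:

* Interaction magnitudes are usually stated *per partner cell*: a benefit of
  2–3% of the recipient's basal fitness per partner cell in the neighborhood.
  `per_cell_effect_to_rij()` converts to the matrix coefficient by
  multiplying with the neighborhood size $(2l+1)^3 = 343$.
* $\Delta t$ is auto-selected as $0.1 / r_\max$ (division probability at most
  0.1 per step), with $r_\max$ the maximum of the rate formula over the
  feasible occupancy simplex.
* Cells are visited in a fresh uniform permutation each step and divide using
  the neighborhood state at their own update (the usual individual-based
  convention); a `synchronous` switch computes all rates from the pre-step
  state instead.  The choice has no visible effect on the reported
  statistics, but the sequential default avoids any sweep-order bias.

A run stops after $G$ community generations (live count reaching $2^G$ times
the inoculum), at a height cap, or at a step cap (`run_fitness()`).

### Inoculation density and the intermixing threshold

Simulated pattern studies here inoculate at 2000 cells/mm² unless stated
otherwise.  The choice matters when quoting an intermixing index after a
fixed number of generations, because the index of a cooperative community
grows in proportion to community height and height after 10 generations is
set by the inoculum: 2000 cells/mm² brings a 10-generation community to the
~40–50 cell layers at which intermixing indexes of different communities are
compared, and at which an index of 6 separates strong cooperation from the
other interaction classes.  Sparser inoculation (e.g. the 500 cells/mm² used
for the engineered-community experiments) produces equally fine local
intermixing but shorter communities, and correspondingly smaller indexes.

## The diffusion model

The diffusion model replaces fitness coefficients with explicit metabolite
bookkeeping.  Each nutrient obeys

$$ \frac{\partial S}{\partial t} = \nabla \cdot (D \nabla S) - U + Q, \qquad
   U = v_m \frac{S}{S + K_{MM}} n_u, \qquad Q = \rho\, n_q, $$

solved with an explicit finite-difference scheme on a multi-grid domain: a
fine community zone above a coarse agarose reservoir, no-flux at top and
bottom, periodic sides, and mass-conserving harmonic-mean fluxes across the
community/agarose interface.  Cells take up their limiting nutrient with
Michaelis–Menten kinetics ($K_{MM} = K_M$), accumulate it as an internal
quota, and divide once the quota reaches the requirement $\alpha$ (mother
keeps the excess, daughter starts empty).  Cells die at a constant rate;
dead cells stay in place, keep their color, and stop all activity.  Release
is either a pulse upon death (the unspent quota is also returned to the
pool) or a constant rate from live cells, optionally delayed.

Two time scales are split: uptake/diffusion substeps of `dt_u = 0.5` s
inside cell-action steps of `dt_cell = 360` s.  `check_stability()` reports
the two governing bounds — the worst-case uptake bound $K_{MM} c^3 / v_m$
(≈ 0.5 s for the default kinetics) and the finite-difference bound
$(nc)^2 / 2D$.  The latter is the classical one-dimensional criterion; the
solver itself additionally enforces the stricter three-dimensional stencil
bound $(nc)^2/6D$, which all shipped presets satisfy.  Per-grid uptake is
capped at the available amount and shared pro rata, so concentrations never
go negative even at the uptake bound.  Mass balance (free nutrient + quotas
+ amounts consumed by divisions − amounts released) is exact to numerical
precision and asserted in the tests.

### Default kinetics

The per-strain defaults are documented reconstructions consistent with the
published kinetics of engineered adenine/lysine-exchanging yeast, not direct
measurements: $K_M = K_{MM} = 1$ µM, $v_m = 2.5\times10^{-4}$ fmole/s (so
the worst-case uptake bound is 0.5 s and saturated doubling takes
$\alpha/v_m \approx 2.2$ h), $\alpha = 2$ fmole per division, death rate
0.025/hr for obligate partners, a release pulse of $\beta = 8$ fmole per
death, and an initial quota of $2\alpha$ reflecting vacuolar stores that
support a couple of divisions after plating.  Note that quota-triggered
division reproduces Monod growth with maximum *exponential* rate $\ln 2
\cdot v_m/\alpha \approx 0.31$/hr, tested as an invariant.  All values are
overridable per strain (`strain_spec()`).

### Presets

`diffusion_config()` encodes four communities: `cooperative` (R requires
lysine and releases adenine upon death; G requires adenine and releases
lysine upon death after a 10 h delay — delayed death onset models its better
starvation tolerance), `commensal` (80 µM lysine in the agarose; the
supplier releases adenine constantly while alive), `competitive` (one shared
agarose nutrient; a `fitness_ratio` produces unequal fitness), and
`symmetric_cooperative` (both partners identical, constant release, no
delay).  The community grid width adapts to the community diffusion
constant: 40 µm grids at the agarose-like $D = 360\ \mu m^2/s$, 15 µm grids
at the in-community tracer value of ~20 µm²/s.

The two control variants de-localize cooperative benefits:
`instant_distribution` replaces community-internal diffusion of released
nutrients by uniform redistribution every substep, and `excessive_release`
multiplies release amounts by 200.  Both reduce intermixing at matched
height under paired seeds — localized, growth-limiting benefits are what
drives the patchwork.

### Desk-scale geometry

Simulations in the tests and examples run on a 240 µm × 240 µm base (48 × 48
cells) with a 400 µm community allowance over 1.2 mm of agarose, and to
horizons of 100–150 h or a target height of ~30 cell layers.  These sizes
were chosen as the smallest domains that leave several diffusion grids and
interaction lengths across the domain; the phenomenology (cooperative
intermixing growing linearly with height, commensal/competitive leveling
off, variant suppression) is insensitive to modest changes in domain size.

## Pattern statistics

A vertical section is digitized as $f(x,z) \in \{+1, -1, 0\}$
(`digitize()`): pixels with both channels within 15% of background (the
middle of the 10–20% range, configurable) are no-signal; the rest are
normalized per channel by the channel's 90th-percentile intensity over
signal pixels and labeled by the larger normalized value.  A pixel can only
take a color whose own channel is above threshold, and exact ties map to 0
for determinism.

With $h(x)$ the local height (topmost nonzero pixel — internal gaps count
toward height) and $c(x)$ the number of sign changes up the column (zeros
skipped: a gap is not itself a transition), the intermixing index and the
characteristic vertical patch size are

$$ IM = \frac{\sum_x c(x) h(x)}{\sum_x h(x)}, \qquad
   \lambda_z^* = \frac{\sum_x h(x)^2 / [1 + c(x)]}{\sum_x h(x)}. $$

Columnar sections give $IM = 0$, one layered interface gives 1, and periodic
stacks of layer thickness $\lambda$ give exactly $IM = h/\lambda - 1$ and
$\lambda_z^* = \lambda$ — the closed forms the synthetic fixtures
(`make_section()`) pin down in the tests.  Community height is the
90th percentile of $h(x)$ (linear-interpolation convention), which discards
isolated height spikes; wide sections are tiled into 0.7 mm analysis
windows; indexes measured at different heights are compared after linear
rescaling to a common reference height (`normalize_im()`).  In
multi-population sections, two focal colors are analyzed at a time with all
others treated as no-signal (`pairwise_view()`).

## Mean-field theory of pairwise composition

Writing $\phi_G + \phi_R = 1$ for a saturated neighborhood, the crowding
factor cancels from the comparison of the two populations and the reduced
fitnesses are $\hat r_i = r_{i0} + s_i\, r_{int}\, \phi_j (1 - \phi_i)$ with
$s_i \in \{+1, 0, -1\}$ by interaction class.  `analyze_steady_state()`
solves $\hat r_G = \hat r_R$ and classifies stability from the sign of the
difference around the root:

* cooperation `[++]`: $\phi_G^* = (r_{G0} - r_{R0} + r_{int})/2r_{int}$,
  exists iff $r_{int} > |r_{G0} - r_{R0}|$, globally stable;
* mutual antagonism `[--]`: the mirrored root, unstable;
* commensalism `[~+]` / amensalism `[~-]`: square-root fixed points under
  the full quadratic form; the simplified linear form $\hat r_i = r_{i0} +
  s_i r_{int} \phi_j$ gives the linear fixed points with the same existence
  conditions (both forms are exposed via `form =`; for cooperation the two
  coincide exactly through the identity $(1-\phi)^2 - \phi^2 = 1 - 2\phi$);
* exploitation `[-+]`: a locally stable upper root
  $1/2 + \sqrt{(r_{G0}-r_{R0})/2r_{int} - 1/4}$ with the unstable lower root
  as basin boundary, requiring $r_{int} > r_{G0}-r_{R0} > 0$ and $r_{int} <
  2(r_{G0}-r_{R0})$.  Under the linear form the fitness difference is
  constant and no interior fixed point exists — one reason the quadratic
  form is the default.

The bracket notation `G[s_G s_R]R` reads as the effect *received* by G and
by R respectively.  `ratio_dynamics()` integrates $d\phi/dt = \phi(1-\phi)
(\hat r_G - \hat r_R)$ (RK4) and is tested to converge to every stable fixed
point and flee every unstable one; "globally stable" refers to the open
interval, the boundaries being absorbing.

```{r steady-state}
analyze_steady_state(pair_params("coop", r_g0 = 0.3, r_r0 = 0.4,
                                 r_int = 0.5))
```

## The interaction length scale

How far does a released metabolite travel before being consumed?  A release
event of $\beta$ fmole defines a spherical diffusion domain of radius $l$
containing $N_u = (2l/c)^3$ consumers; the packet survives $t_c = l^2/2D_1$;
each consumer takes up at most $v = \alpha/T$ (the division requirement over
the minimum doubling time, taken at equality for the characteristic scale).
Solving $\beta = N_u v t_c$:

$$ l = \left[ \frac{\beta}{\alpha} D_1 T \frac{c^3}{4} \right]^{1/5}. $$

```{r length-scale}
interaction_length(length_scale_params(D1 = 360))
interaction_length(length_scale_params(D1 = 20))
diffusion_domain_stats(p = length_scale_params())
```

The 1/5 power makes $l$ remarkably insensitive to the diffusion constant —
an 18-fold change in $D_1$ moves $l$ only from ~50 to ~28 µm — which is why
intermixing survives order-of-magnitude uncertainty in $D$.  The expected
number of further release events inside one domain during $t_c$ is ~0.2, so
domains rarely overlap in time and $l$ is a genuine interaction length.

## Multi-species networks

`random_network()` draws one of the six interaction types uniformly for
each pair of (by default five) species, basal fitnesses from 0.03–0.05/hr,
per-cell effects of 2–3% of the recipient's basal fitness, and initial
fractions with every species at least 5%.  `run_network_experiment()`
simulates the network with the fitness model for 10 generations, extracts
cross-sections, scores every pair's intermixing index on its two-color
view, and flags indexes of at least 6 as intermixed.  Indirect interactions
through third species can occasionally suppress cooperative intermixing or
induce commensal intermixing; the index reflects the *net* interaction
between two partners.

## What the synthetic data do and do not establish

The synthetic fixtures (`make_section()`, `render_channels()`) emulate
digitized sections and noisy two-channel images with exactly known metrics;
they validate the measurement pipeline, not the biology.  The simulators
are validated against their own invariants (mass balance, gravity,
neutrality, Monod consistency, mean-field agreement) and against the
qualitative and threshold claims of the theory.  None of this substitutes
for real cryosections or FISH stacks: real images carry uneven illumination,
section-angle artifacts and segmentation noise that the digitizer's
background and percentile conventions only approximate.

## Numerical conventions worth knowing

* Percentiles use R's default linear interpolation (type 7).
* Intensity ties in digitization map to no-signal; target ties in budding
  are broken uniformly at random; the focal cell counts toward its own
  $\phi_i$.
* The interaction cube is clipped at the z boundaries and its denominator
  shrinks accordingly.
* All randomness flows through R's RNG: a single `set.seed()` makes every
  run, including the C++ cores, bit-reproducible.
* Diffusion-model cells are updated in cell-id order; the fitness model uses
  a fresh random permutation each step.
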