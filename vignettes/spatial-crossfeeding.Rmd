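---
title: "The diffusion model: simulating spatial self-organization in a cross-feeding yeast community"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The diffusion model: simulating spatial self-organization in a cross-feeding yeast community}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The scientific question

Cooperation between *different* populations — heterotypic cooperation, such
as two auxotrophic yeast strains exchanging lysine and adenine — faces a
puzzle that clustering with one's own kind cannot solve: a cooperator
cluster and a cheater cluster should, naively, enjoy equal access to the
shared partner. `crossfeedr` implements an individual-based "diffusion
model" of a three-strain community to study how growth itself reorganizes
space so that cooperators end up with more partner neighbors than cheaters,
reversing the cheater's intrinsic fitness advantage:

* **R** (cooperator): requires lysine, continuously releases adenine at
  rate $\gamma_A$ per live cell.
* **G** (partner): requires adenine, releases $\beta_L$ fmole of lysine
  when it dies.
* **C** (cheater): requires lysine, releases nothing, and carries an
  intrinsic fitness advantage (e.g. 2%).
* **Rd** (partial releaser): like R but releasing at a $d$-fold rate,
  $0 \le d \le 1$.

## The model

Cells of size 5 µm occupy a 3-D lattice above an agarose column. Each live
cell takes up its required metabolite by Michaelis–Menten kinetics,

$$ v_i(S_i) = v_{m,i} \frac{S_i}{S_i + K_i}, \qquad
   v_{m,i} = \frac{\alpha_i\, r_{m,i}}{\ln 2}, $$

where $\alpha_i$ is the quota of metabolite needed to produce one daughter
and $r_{m,i}$ the maximum growth rate; at saturation a cell gathers one
quota per minimum doubling time. A fitness advantage is a multiplier on
$v_m$ (equivalently on $r_m$), constant at all concentrations: a 2%
advantage means $v_{m,C} = 1.02\, v_{m,R}$ (`derive_vm()`, `default_panel()`).

Metabolite fields obey reaction–diffusion dynamics updated with an explicit
finite-difference scheme, e.g. for adenine

$$ S_A(t + t_u) = S_A + t_u \left[ \nabla\!\cdot\!(D \nabla S_A)
   - v_{m,G}\tfrac{S_A}{S_A + K_A} n_G + \gamma_A n_R \right], $$

and analogously for lysine with the uptake of R and C as sinks and a
$\beta_L n_G'$ source from the binomially dying partners
($n_G' \sim \mathrm{Binom}(n_G, p)$). A shared resource (glucose) is
consumed alongside: a cell divides only after acquiring both its required
metabolite quota and its glucose quota; once one store is full the cell
stops consuming that metabolite and continues with the other.

$D$ is a spatially varying coefficient: 360 µm²/s inside agarose, 0–20
µm²/s inside the community in proportion to local voxel occupancy (a 15 µm
voxel holds at most 3×3×3 = 27 cells), and 0 in the surrounding air — which
encodes the community–air no-flux boundary automatically. Fields live on
two grids (60 µm agarose, 15 µm community/air), coupled by
flux-conservative exchange at the interface; no-flow conditions apply at
the top and bottom, periodic conditions at the four vertical sides.

Cell state is examined every $\tau$ = 6 min (many diffusion steps of
$t_u$ = 3.5 s, but far below the ~2 hr minimum doubling time). Cells at
quota divide; daughters bud in the horizontal plane along the shortest ray
to empty space within a five-cell radius, pushing the intervening chain
outward; a fully enclosed mother buds straight up with probability 0.7,
otherwise it displaces a random lateral neighbor (and everything above it)
upward. Deaths are stochastic at fixed per-strain rates. The only sources
of randomness are initial conditions, initial metabolite stores, death,
bud direction, and rearrangement tie-breaks; uptake and diffusion are
deterministic. A single seeded RNG stream makes whole trajectories
bit-reproducible.

## Numerical choices

* **Stability sub-stepping.** The physical step $t_u$ = 3.5 s violates the
  explicit 3-D stability bound on the agarose grid
  ($D t_u / h^2 = 0.35 > 1/6$), so the solver sub-steps each $t_u$
  internally (`ceiling` of the bound; 3 sub-steps at the defaults) while
  sources, sinks, and reporting stay at $t_u$. Fluxes use harmonic-mean
  face diffusivities, which keeps the update conservative and non-negative
  under the bound.
* **Stop-consuming granularity.** The "stops consuming at quota" rule is
  evaluated per $t_u$: a cell below quota takes its full Michaelis–Menten
  draw for that step and may overshoot the quota by at most $v_m t_u$; the
  overshoot carries over after division. Clamping exactly to
  `quota - store` instead would make every division re-align to the $\tau$
  grid and silently erase sub-$\tau$ rate differences — a 2% uptake
  advantage would never express. The field update above subtracts the full
  MM sink for unsatisfied cells, which is what this reproduces.
* **Within-voxel competition.** When aggregate demand in a voxel exceeds
  its content in a step, the available mass is split among requesting
  cells in proportion to their unclamped demands.
* **Settling.** Lateral budding and lateral pushes settle displaced cells
  downward until supported. Without this, a cell at the top of a column
  whose lateral sites are empty air would bud daughters into mid-air,
  and spot inocula grow needle towers that violate the support invariant.
  Vertical displacements keep columns contiguous, so no cell ever floats.
* **Mass accounting.** Cumulative release and consumption ledgers satisfy
  $\Delta(\text{total field mass}) = \text{released} - \text{consumed}$ to
  1e-9 relative tolerance over entire runs (asserted in the tests).
* **Mixing averaging.** "Average over the entire community" is implemented
  over community voxels only, with `include_agarose = TRUE` as an option.
* **Delocalization variants.** `excess_release_factor = 200` scales all
  release rates; `instant_distribution = TRUE` replaces each field by its
  volume-weighted mean after every step. Both reproduce the
  benefit-delocalization controls (association index driven toward 1,
  cooperators disfavored).
* **Uniform-D variant.** `uniform_D = TRUE` applies the agarose coefficient
  in the community as well — the single-coefficient simplification with
  which "similar results" are expected; the dual-grid geometry is kept, so
  this is an approximation of the single 50 µm-grid variant, not a second
  mesh implementation.

## Parameters

Printed physical constants are package defaults: grids 60/15 µm, cell
pitch 5 µm, $t_u$ = 3.5 s, $\tau$ = 6 min, $D$ = 360/0–20/0 µm²/s, upward
budding probability 0.7, enclosure radius 5 cells, supplements 650 µM
lysine + 430 µM adenine, initial densities 3000 (lawn), 4400 (periodic
lattice), ~10⁵ cells/mm² (spot). Units package-wide: µm, hr, fmole,
fmole/µm³ (1 µM = 10⁻⁶ fmole/µm³).

The kinetic constants live in the source publication's data supplement,
not its text; the package's defaults are therefore ASSUMED values, chosen
once so that the minimum doubling time is ~2 hr and communities grow
visibly within ≤ 8 generations, and flagged as such in the config schema:

| symbol | meaning | default | note |
|---|---|---|---|
| $r_m$ | max growth rate | 0.35 /hr | ln2 / 2 hr |
| $\alpha_L$ | lysine quota | 4 fmole | sets lysine uptake scale |
| $\alpha_A$ | adenine quota | 1 fmole | adenine is the cheaper currency |
| $\alpha_G$ | glucose quota | 8 fmole | shared resource |
| $K_L$ | lysine Monod constant | 50 µM | see below |
| $K_A$ | adenine Monod constant | 0.5 µM | near-perfect sink |
| $K_G$ | glucose Monod constant | 50 µM | non-limiting |
| $\gamma_A$ | adenine release | 0.4 fmole/cell/hr | supports partner growth |
| $\beta_L$ | lysine released per partner death | 24 fmole | 6 divisions' worth |
| $d_R, d_C$ | death rates | 0.015 /hr | lysine-requirers |
| $d_G$ | partner death rate | 0.05 /hr | sets the lysine supply rate |
| glucose | initial concentration | 110 mM | ~2% w/v |
| agarose depth | desk-scale column | 1920 µm | reservoir for ≥ 7 generations |

Two of these choices deserve explanation. $K_A$ is small so that released
adenine is absorbed within about a cell diameter — benefits to the partner
stay localized to the cooperator's neighborhood, which is the engine of
self-organization. $K_L$ is comparable to (but below) the supplement
concentration so that supplemented growth sits *slightly below*
saturation: in a $\tau$-checked quota model, perfectly saturated cells all
divide on the same step count and a small rate advantage cannot change an
integer number of steps; sub-saturation plus the spatial variability of
lysine (partner-death bursts) restores the continuous-time behavior in
which a 2% uptake advantage costs the cooperator ~2% per division.

The fitness multiplier scales uptake of the required metabolite *and* of
glucose. The advantage is defined as a growth-rate multiplier at all
concentrations; if glucose uptake were left unscaled, the glucose quota
would cap the division time and silently nullify the advantage whenever
glucose co-limits.

## What the desk-scale world does and does not establish

All protocols run at desk scale: a 600×600 µm periodic domain stands in
for the 6 mm experimental column, a ~2 mm high-density spot becomes an
80 µm disc (matching the experiment's ~1% inoculum-to-pad area ratio), and
runs stop after 6–7 community generations. At this scale, with the
defaults above:

* Supplemented competition ends with R:C ≈ 0.87–0.95 < 1 and a partner
  association index within the label-permutation null of 1.
* Cooperation & cheating (no supplements, 2% cheater advantage) ends with
  R:C ≈ 1.15–1.2 > 1 while the 3-D association index climbs from ~1 to
  ~1.3 — the cheater's intrinsic advantage is reversed by spatial
  self-organization.
* The symmetric periodic initialization (association exactly 1 at start)
  still self-organizes (index > 1 at generation 6), though less than
  random initializations — initial spatial heterogeneity helps but is not
  required.
* Partial releasers are excluded in proportion to what they withhold:
  the steady R–G vs Rd–G association ratio decreases in $d$.
* Delocalizing benefits (200× release, or instant distribution) collapses
  the association index toward 1 and hands the advantage back to cheaters.

Two paper-scale results are *not* reproduced quantitatively at this scale,
and the acceptance tests assert them as stated rather than hiding the gap:

* With an **8%** cheater advantage the desk-scale self-organized benefit
  (~4–5% per generation) no longer covers the advantage; R:C ends below 1,
  whereas mm-scale communities with taller pods and longer growth still
  favored cooperators.
* In the **range expansion**, the front's R:C hovers around 1
  (≈0.95–1.05 across seeds) instead of clearly exceeding it. The expanding
  ring at this scale remains confluent and sits inside the lysine halo of
  the dense center, so front self-organization is weak (front association
  index ≈ 1.07–1.11, consistently above the center's, as observed
  experimentally).

The generator also idealizes real communities in ways worth keeping in
mind: no evolution or adaptation (the experimental adaptive-race dynamics
are out of scope), no starvation-tolerance differences between strains, no
cell-size variation or lag phases, costless release, and rearrangement by
straight-ray pushing rather than mechanics.

## Protocols, metrics, rendering

`run_spatial()` drives lawns (`init_random_lawn()`), symmetric periodic
lattices (`init_periodic_lattice()`; R–G–C triplets tiled at 1 cell per 9
sites ≈ 4444 cells/mm², every focal cell with exactly one partner
neighbor), stripes (`init_stripes()`), and high-density spots
(`init_spot()`), with optional periodic complete randomization
(`mix_community()`: positions repacked bottom-up over the occupied
footprint, adenine/lysine averaged). `run_liquid()` is the well-mixed
control, in stochastic agent and deterministic expectation modes.

The partner association index (`association_index()`) is the mean number
of live partner neighbors per qualifying cooperator divided by the mean
per qualifying cheater, a focal cell qualifying when it touches at least
one live cell of a different population. The neighborhood is 26-connected
in 3-D and 8-connected in 2-D sections by default (the source text leaves
the connectivity unspecified; 6/4-connectivity are options and the choice
is reported in the result). Dead cells are excluded by default.
`fitness_advantage()` estimates percent-per-generation advantage as the
exponentiated log-linear slope of a ratio series between generations 2
and 6. `region_split_metrics()` splits spot communities into center
(inside the inoculum footprint) and expanding front.

`classify_pixels()` reproduces the fluorescence pixel rule (no-signal
below 30% above background in all channels, else argmax of
90th-percentile-normalized intensities; ties break R > G > C), and
`synth_fluor_image()` generates synthetic three-channel images so the rule
is testable without microscopy data.

```{r example}
library(crossfeedr)
cfg <- sim_config(rng_seed = 1, target_generations = 6.5)
coop <- run_spatial(cfg, protocol(density = 3000), medium_spec(),
                    default_panel(cheater_advantage = 0.02))
glance(coop)
association_index_3d_timeseries(coop)
autoplot(coop, "ratio")
```

## Known limitations

* The desk-scale domain wraps at 600 µm; long-range structures (expansion
  fronts, mm-scale sectors) are truncated.
* The agarose column is a scaled reservoir (1.9 mm vs 11 mm); very long
  runs (> 8 generations) deplete supplements.
* Snapshot persistence is plain-text JSON/CSV rather than a binary
  hierarchical container; fine at desk scale, bulky beyond it.
* The single-grid 50 µm variant is approximated by `uniform_D` on the
  dual-grid geometry.
* Liquid agent mode applies cell updates at the $\tau$ cadence (no
  diffusion exists to resolve below it).
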