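---
title: "A vacancy-mediated competition model of synapse elimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A vacancy-mediated competition model of synapse elimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological question and the model's answer

Developing neuromuscular junctions start out polyinnervated: several
motor axons share one endplate, together with terminal Schwann cells
(tSCs) and patches of territory — vacancies — contacted by neither.
Within roughly two postnatal weeks a single axon remains, while tSCs
and vacancies persist.  Any model of the process must therefore explain
two things at once: the *winner-take-all* dynamics among axons, and the
*stable coexistence* of the three territory classes.

`nmjelim` models the endplate as a disc tiled by identical circular
contact sites.  Each site holds one occupant: a tSC (`S`), a vacancy
(`V`), or an axon identity (class `A`, identities `1..9`).  One site is
selected per iteration and its occupant transitions under a three-state
Markov chain in which direct axon/tSC exchange is structurally absent —
all exchange between the two cellular classes passes through vacancies:

* an axon site becomes vacant with probability `p_AV`, else stays;
* a tSC site becomes vacant with probability `p_SV`, else stays;
* a vacant site never stays vacant: it becomes a tSC with probability
  `p_VS` and is otherwise reclaimed by an axon.

The chain is *calibrated*, not fitted: given a target stationary
composition `(r_S, r_V, r_A)` and the free parameter `p_VS`, the
stationarity balance fixes the remaining probabilities in closed form,

```
p_SV = r_V * p_VS / r_S,       p_AV = r_V * (1 - p_VS) / r_A .
```

`solve_stationary_probs()` implements this and refuses compositions for
which either expression leaves `[0, 1]` — for a given `p_VS` not every
composition admits a stabilising chain.  `stationary_vector()` is the
independent check: it solves the balance equations linearly and
cross-validates with power iteration on the lazy chain `(M + I)/2`
(tolerance `1e-12`; the lazy form converges even for periodic chains
such as `p_SV = p_AV = 1`), and the two routes must agree to `1e-8`.

Axon identities enter only through the vacancy-reclaim step: the
reclaiming identity is drawn with probability proportional to the
number of adjacent sites each surviving axon holds.  This
neighbour-weighted takeover is the spatial rich-get-richer mechanism
that converts identity-blind class dynamics into single-axon fixation.
When a vacancy has no axon neighbour the draw falls back to global site
counts (takeover proportional to current relative area); extinct axons
have weight zero everywhere, so extinction is absorbing.  A run is
*complete* at the first iteration at which exactly one axon identity
holds at least one site; this "least number of iterations" is the
model's elimination-time readout.

## Geometry

| parameter | default | units | why |
|---|---|---|---|
| `region_diameter` | 300 | px | endplate disc diameter |
| `site_diameter` | 30 | px | all contact sites identical |
| `n_sites` | 100 | sites | the stage compositions (e.g. 31/17/52) are integral at 100 sites, and 9 equal axon shares of ~6% fit exactly |
| `min_separation_factor` | 0.8 | site diameters | mild overlap permitted; see below |
| `neighbor_distance` | 37.5 (=1.25 d) | px | adjacency threshold |
| `n_axons` | 9 | identities | maximum polyinnervation at birth |

One hundred non-overlapping 30 px sites cannot fit in a 300 px disc, so
sites are allowed to overlap mildly: centres must be at least
`0.8 * site_diameter = 24` px apart.  Even that constraint is too dense
for naive rejection sampling — random sequential insertion jams at
roughly 70 sites, although hexagonal packing shows 100 are feasible
with room to spare.  `place_sites()` therefore follows the sequential
random draws with a deterministic pairwise-repulsion relaxation:
violating pairs are pushed apart (against a target inflated by 0.2%,
which keeps deficit-proportional steps from stalling just below the
bound) and re-clamped to the disc until every separation holds,
typically in one to three hundred sweeps.  A density provably above the
hexagonal bound raises a geometry error immediately.  Occupants are
assigned to the placed positions in a uniformly random permutation, so
the classes are spatially interleaved at the start.

Two sites are *adjacent* when their centres lie within 1.25 site
diameters — close enough to capture touching and slightly separated
circles under the permitted overlap.  At the default density this gives
a mean degree near 5 and, at 100 sites, a connected adjacency graph;
much sparser layouts (a few dozen sites) fragment into components, which
matters for the neighbour-adoption variants below.

Integer site counts come from largest-remainder apportionment over the
three classes (ties broken in the order tSC, vacancy, axon), with the
axon pool split as evenly as possible and remainders assigned to the
lowest identities.  Identities are exchangeable and occupants are
shuffled over positions, so the remainder rule introduces no spatial
bias — but it does mean that when the axon pool does not divide by 9
(52 sites at the birth composition), seven axons start with 6 sites and
two with 5.  Neutral fixation probability equals initial share, so
per-axon win probabilities are `6/52` or `5/52`, not exactly `1/9`; the
test suite checks winner counts against this initial-share null.

## Activity

An "active" axon is protected rather than boosted: every site it
occupies has its chance of being *selected for transition* divided by
`selection_divisor` (default 2).  Active sites therefore vacate more
slowly while reclaiming vacancies at the normal rate, which both biases
the winner toward the active set and accelerates elimination of the
others.  The active set can be fixed (`active =`) or redrawn uniformly
per replicate (`n_active =`).

## The random- and equal-probability reference schemes

The package also implements the two identity-agnostic reference
schemes.  In both, a uniformly selected site transitions into *a site
adjacent to it*: a uniformly chosen neighbour is adopted — kind and,
for axons, identity — with the probability the transition row assigns
to the neighbour's kind.  The row is redrawn each step from the uniform
simplex (`variant = "random"`) or fixed at `(1/3, 1/3, 1/3)`
(`variant = "equal"`).  Because every class spreads only from sites
that already hold it, this is a lazy multitype voter model: class
counts are martingales and the three homogeneous endplates (all one
axon, all tSC, all vacant) are genuine absorbing states, typically
reached within 15,000-90,000 iterations at 100 sites.  The contrast
with the calibrated chain is the package's central negative control:
the reference schemes cannot hold tSC/vacancy coverage and end
homogeneous, never in the single-axon-with-tSCs-and-vacancies state the
vacancy-mediated chain maintains.

An alternative reading — outcome kind drawn directly from the row,
with a neighbouring donor required only for axon identities
(`donor_rule = "axon_only"`) — is kept selectable.  It is instructive
to see why it was not made the default: with the outcome kind redrawn
each step independently of the neighbourhood, class counts become an
Ehrenfest-style urn with a restoring drift toward equal shares, and the
homogeneous states, while formally absorbing, are unreachable in
practice (none in `2e7` iterations at 100 sites).

Iteration accounting is uniform across variants: every step call counts
as one iteration, including no-transition outcomes.  Reported
iteration counts scale accordingly.

## Synthetic per-endplate profiles

`generate_ratio_variants()` emulates endplate-to-endplate variability
of measured compositions: profiles are drawn from a Dirichlet
distribution with a stage-average mean and concentration 50 — enough
spread that composite areas `r_S r_V / r_A` range over roughly
three-fold, while keeping essentially every draw feasible at
`p_VS = 0.6` (infeasible draws are rejected and redrawn).  These
synthetic profiles stand in for measured per-endplate ratios, which are
not tabulated anywhere machine-readable; they reproduce the *spread* of
real endplates but not any correlation structure between the three
areas beyond the simplex constraint, nor measurement error.

## What the simulations do and do not show

The test suite and `scripts/acceptance.R` run the study conditions at
full scale: 100-replicate batches per stage (each replicate a fresh
100-site layout run to completion), 1000-replicate activity batches,
eight Dirichlet profiles at 50 replicates each, and a 900-replicate
winner-symmetry batch; the compiled inner loop keeps the whole suite in
minutes.  Passing them shows the implementation realises this model
faithfully — stationarity holds to Monte-Carlo error, extinction is
absorbing, the distinct-axon count relaxes exponentially toward the
single survivor (fitting `N(t) = 1 + A e^{-bt}`; the mean curve's
excess over the absorbing floor is log-linear with R² ≈ 0.98), and
composite area rank-predicts elimination speed.  It does not validate
the model against real endplates: sites are identical discs, areas are
site counts, there is no site birth/death, no 3-D geometry, and no
within-endplate correlation between class areas.

Two quantitative behaviours of this implementation deserve explicit
flagging.  First, elimination time is governed by neutral drift of the
axon pool through the vacancy pool, so its scale is roughly
`N_A^2 / (r_A p_AV)` selections; compositions with scarce vacancies
(the P7 and P16 averages, `r_V` of 5-6%) make `p_AV` small and stretch
completion times by an order of magnitude relative to the P3
composition, far beyond the relative slowdown one might expect from the
composite-area ordering alone.  Second, with two or more active axons
the endgame is a contest *among protected axons*, whose sites are all
selected at the reduced rate; the final neutral phase therefore slows
even though the inactive axons are eliminated faster, and mean
completion with two active axons exceeds the one-active mean.  Both are
consequences of the stated mechanism rather than implementation
artefacts; the acceptance suite reports them as measured.

## Numerical and design details

* Reproducibility: a root seed expands into per-replicate layout and
  run seeds (recorded in every result row); the compiled and pure-R
  engines consume R's RNG draw-for-draw identically and are
  equivalence-tested trajectory-by-trajectory.
* Default iteration caps: 50,000 (vacancy-mediated and random) and
  200,000 (equal); experiment drivers raise them when runs must
  complete.  Hitting the cap yields `completed = FALSE`, never an
  error, and incomplete runs are counted in completion rates.
* Degenerate inputs: empty layouts, compositions starving any axon of a
  site, reducible chains (`p_SV = 0`), and unpackable densities all
  raise typed errors before any computation.
* Summaries are pure functions of the persisted per-run records; the
  CSV written by the CLI recomputes to identical statistics.
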