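# nmjelim

Stochastic vacancy-mediated competition model of synapse elimination at
the developing neuromuscular junction (NMJ).

At birth, each muscle endplate is innervated by several motor axons;
over the first two postnatal weeks all but one are eliminated.
Throughout this period the endplate is shared by three kinds of
territory: nerve-terminal contacts of the competing axons, caps of
terminal Schwann cells (tSCs), and *vacancies* — patches contacted by
neither.  `nmjelim` is for computational neuroscientists and
developmental biologists who want to simulate the hypothesis that tSCs
and axons do not displace each other directly, but compete *through*
those vacancies, and that the measured relative areas of the three
classes set the tempo of elimination.

## The model

An endplate is a disc (default 300 px) tiled by `n` identical circular
contact sites (default 100 sites of 30 px), each occupied by a tSC
(`S`), a vacancy (`V`), or one of 9 axon identities (pooled class `A`).
Each iteration selects one site at random and applies a three-state
Markov kernel in which direct `A <-> S` exchange is forbidden:

    P(A -> V) = p_AV        P(A -> A) = 1 - p_AV
    P(S -> V) = p_SV        P(S -> S) = 1 - p_SV
    P(V -> S) = p_VS        P(V -> A) = 1 - p_VS

Given a target stationary composition `(r_S, r_V, r_A)` — e.g. the
measured stage-average area ratios — and the one free parameter `p_VS`,
the stationarity balance `r M = r` has the unique closed-form solution

    p_SV = r_V * p_VS / r_S
    p_AV = r_V * (1 - p_VS) / r_A

A vacated site is reclaimed by an axon with probability proportional to
the number of adjacent sites each surviving axon holds, so locally
dominant axons expand and whole-endplate occupancy drifts to a single
winner while tSC and vacancy coverage hold their stationary shares.
"More active" axons have their sites selected for transition with
half the probability of every other site, which protects them from
vacation and biases the outcome.  Elimination speed is summarised by the
*least number of iterations* until exactly one axon identity survives,
and compositions are compared through the composite area
`r_S * r_V / r_A`.

Two reference schemes — fully random per-step transition probabilities
and all-equal probabilities, both with takeover of adjacent sites — are
included; unlike the calibrated chain they cannot maintain tSC/vacancy
coverage and drift to homogeneous endplates.

## Worked example

```r
library(nmjelim)

m <- nmj_model("P3")        # probabilities calibrated to the P3 ratios
summary(m)
#> endplate competition model (vacancy_mediated variant)
#>   geometry: 100 sites of 30 px in a 300 px disc, 9 axon identities
#>   initial composition: tSC 0.31, vacancy 0.17, axon 0.52
#>   stationary target: tSC 0.57, vacancy 0.18, axon 0.25 (p_VS = 0.6)
#>   solved: p_AV = 0.2880, p_SV = 0.1895, p_VA = 0.4000
#>   stationary check: tSC 0.5700, vacancy 0.1800, axon 0.2500
#>   composite area r_S*r_V/r_A = 0.4104

lay <- endplate_layout(stage_ratios("P0"), seed = 1)
run_simulation(lay, m$probs, seed = 2, max_iter = 2e6)
#> competition complete at iteration 6493: single axon 2 remains

summary(batch_run(m, n_reps = 20, base_seed = 42, max_iter = 2e6))
#> 20 replicates, 100% complete
#>   least iterations to completion: 10560 +/- 5763 (SD)
```

The solved `p_AV = 0.288` and `p_SV = 0.1895` are the only transition
probabilities that hold the P3 composition stationary at `p_VS = 0.6`;
the batch mean (~10,000 iterations, with a broad SD) is the model's
elimination-time readout for the P3 stage.  Experiment drivers:
`stage_comparison()` (P3/P7/P16 with pairwise t-tests),
`activity_sweep()` (0-9 active axons, win probabilities),
`ratio_sweep()` + `generate_ratio_variants()` (Spearman correlation of
composite area with elimination time).

A command-line front end is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "nmjsim.R", package = "nmjelim"))')" \
    solve-probs --ratios 0.57,0.18,0.25 --pvs 0.6
```

with subcommands `solve-probs`, `simulate`, `sweep`
(`activity|stages|ratios`) and `export-layout`, driven by YAML/JSON
configs (see `inst/extdata/p3.yaml`); results are written as per-run
CSV plus a JSON summary embedding the resolved configuration.

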