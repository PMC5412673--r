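# signalurn

Agent-based simulations of how populations of learners converge on shared
signaling conventions — for researchers in language evolution, cultural
evolution, and game theory who want the classic model families
(reinforcement learning, the Naming Game, observational and obverter
learning) runnable, comparable, and instrumented on one common substrate.

## The model

Agents play pairwise Lewis signaling games over discrete meanings `M` and
signals `S`. An agent's memory is an urn model: a count matrix `N` of
*exemplar* tokens, `N[m, s]` = stored associations of meaning `m` with
signal `s` (equivalently, a Roth–Erev reinforcement learner). For a topic
`t` the production weight of signal `s` is

    P(s | t) = N[t, s] / Σ_s' N[t, s']

and the reception weight of a context meaning `m` for utterance `u` is

    R(m | u, C) = N[m, u] / Σ_{m' ∈ C} N[m', u],

used either stochastically or winner-take-all; *obverter* agents swap the
two weightings. Learning mechanisms are switches on this substrate: which
roles store exemplars and when (reinforcement, Yes/No feedback, referential
feedback, observational), punishment deletions, lateral inhibition of
homonyms/synonyms (minimal/broad/maximal), memory limits with random
forgetting, and closed vs. gradual-replacement population dynamics.
Convergence is measured by communicative accuracy (CA): the expected
probability, over contexts, topics, and ordered agent pairs, that a hearer
recovers the speaker's topic. A population has an optimal signaling system
when CA = 1.

The hot loop is compiled (Rcpp) and backed by a pure-R reference engine
with an identical random-draw discipline; a fixed seed produces
bit-identical trajectories under either engine, which the test suite
asserts.

## Worked example

```r
library(signalurn)

# Pure Roth-Erev reinforcement never reaches strict optimality...
run_batch("skyrms_pure", n_runs = 200, max_interactions = 20000, base_seed = 1)
#> <batch_result: skyrms_pure, 200 runs x <= 20000 interactions>
#>   converged: 0.0%

# ...but adding a 35-exemplar memory limit makes convergence near-certain:
run_batch("barrett_memory35", n_runs = 200, max_interactions = 20000, base_seed = 1)
#> <batch_result: barrett_memory35, 200 runs x <= 20000 interactions>
#>   converged: 99.5% (mean convergence iteration 5170)

# Zipf-distributed topic frequencies slow convergence by about half:
zipf_slowdown(n_meanings = 5, n_reps = 20, base_seed = 1)
#> <zipf_result: |M| = |S| = 5, 20 reps/condition>
#>   zipf/uniform convergence-time ratio: 1.527 (1384 / 906 iterations)
```

The first batch reports that none of 200 runs reached CA = 1 (the
one-per-pair initialization tokens are never deleted, so ambiguity can
never be fully eliminated); the second, that random forgetting lets 199 of
200 runs reach a shared unambiguous lexicon, typically within ~5,000
interactions; the third, that presenting topics by a 1/rank frequency law
multiplies mean convergence time by ~1.5.

`preset_names()` lists all built-in model configurations;
`preset("naminggame_full")`, `run_simulation()`, `pairwise_ca()`,
`scaling_study()` and friends expose the pieces. A thin command-line
wrapper lives at `inst/scripts/signalurn-cli.R`:

```sh
Rscript inst/scripts/signalurn-cli.R batch --preset biased_hom --runs 200 --seed 1 --out results/
Rscript inst/scripts/signalurn-cli.R presets
```

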