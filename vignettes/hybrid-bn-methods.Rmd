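---
title: "Hybrid Bayesian-network structure learning: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid Bayesian-network structure learning: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnhybrid)
```

## The model

A discrete Bayesian network `B = (G, θ)` couples a directed acyclic graph
`G` over categorical variables with one conditional probability table (CPT)
per node, so the joint distribution factorises as
`P(X₁,…,Xₚ) = Π_i P(X_i | pa(X_i))`. Everything in this package operates on
that factorisation: sampling walks a topological order, scores decompose
over node families, and exact inference sums the factor product.

Two conventions matter for reproducibility and are enforced throughout:
level order is *declaration order* (never lexicographic), and CPT parent
configurations enumerate the first declared parent fastest. Both survive
BIF/JSON round-trips bit-stably.

## Hybrid structure learning

Learning proceeds in two phases.

**Phase 1 (constraint-based).** Per node, a neighbourhood learner queries
the G² likelihood-ratio test of `Ind(X; Y | Z)`:

* `mmpc_neighborhood()` grows the candidate parents-and-children set with
  the max-min heuristic (admit the variable whose *weakest* association
  over all subsets of the current set is strongest) and then removes false
  positives against subsets of the final set.
* `iamb_neighborhood()` estimates the Markov blanket (parents, children,
  spouses). The `inter` variant interleaves a full shrinking pass after
  every admission, which prunes false positives while the conditioning sets
  are still small; the `fast` variant ranks all candidates per pass by test
  significance and admits them speculatively, trading tests for passes.

`skeleton_from_neighborhoods()` applies the symmetric AND-rule (`{X,Y}`
adjacent iff each is in the other's set). Markov blankets also contain
spouse links, which are not adjacencies, so for the IAMB family a screening
pass removes any pair separated by some subset of either endpoint's blanket
minus the partner; a collider's co-parents are separated by the empty set,
so the screen is cheap and sound at the sample sizes where blankets are
estimable.

Tests whose sample support is inadequate (`n/df < 5`, the classic
sample-adequacy rule from the IAMB literature) are treated as *independence
not established at this sample size*: their effective p-value is 1 inside
the learners, so growing stops instead of admitting members on evidence the
data cannot support. The default significance level is `alpha = 0.05`; the
conditioning-subset cap is 3 (`max_sx`), bounding the combinatorial subset
searches while leaving typical neighbourhood sizes unaffected.

**Phase 2 (score-based orientation).** The skeleton restricts edge
*additions*; deleting or reversing existing edges is always legal. The
default score is the decomposable BIC,
`Σ_i [Σ N·ln(p̂) − (r_i − 1) q_i · ln(n)/2]`, with family scores memoised per
(child, parent-set); BDeu with equivalent sample size 1 is available.
Two searches share one move set (add / delete / reverse, acyclicity
preserved):

* `hill_climb()` — greedy best-improvement, stops at the first local
  optimum;
* `tabu_search()` — applies the best *non-tabu* move even when it worsens
  the score, keeps a FIFO list of visited-structure fingerprints
  (canonical sorted edge lists; default capacity 10), pardons a tabu move
  when it would strictly beat the best score (aspiration), and stops after
  15 non-improving moves or 200 iterations.

These tabu defaults are deliberately small: on 4–20 node problems the
search typically reaches its best structure within a few dozen moves, and
the stagnation rule dominates termination. Determinism is part of the
contract: among equally scoring moves the lexicographically smallest
(operation, parent, child) triple wins, so a fixed dataset always yields a
byte-identical DAG.

The sprinkler network illustrates why the tabu phase earns its keep. Its
`WetGrass` CPT contains a deterministic row (never wet when neither cause
is active), which makes single-edge dependences so strong that greedy hill
climbing, starting from the empty graph, frequently commits to a
misoriented early edge and ends in a local optimum a few dozen BIC units
below the true equivalence class — we verified by exhaustively rescoring
every neighbour that no single move improves those optima. Tabu search,
with the identical move set and score, walks out of them and reaches the
true class's score in nearly every replicate. This mirrors the benchmark
ordering the package's acceptance tests assert on the 20-node network.

## The bundled networks and what the generator emulates

* `sprinkler4` — the canonical cloudy/sprinkler/rain/wet-grass network;
  small enough for closed-form checks (e.g. P(Rain=T | WetGrass=T) =
  0.7079 by enumeration over 16 states).
* `car20` — a 20-node, 22-edge car-diagnosis benchmark *structure*. The
  original tool's CPTs are proprietary, so the parameterisation is a
  declared synthetic surrogate: all variables binary `{ok, bad}`, roots
  `P(ok) = 0.8`, and every non-root `P(ok | parents) = max(0.05,
  0.95 − 0.60·b)` where `b` counts parents in state `bad`. This is
  deterministic, portable, and produces dependences strong enough that
  recovery improves sharply with sample size — the property the benchmark
  experiment measures. Numeric error counts from the original publication
  of the protocol are *not* comparable, because they depend on the
  proprietary parameters; the package asserts the qualitative ordering
  (error shrinks with n; the interleaved hybrid at least matches MMHC at
  large n) rather than any printed row.
* `lipid10` — the 10-node, 14-arc hyperlipidemia survey network. The
  outcome CPT (hyperlipidemia given physical activity, gender, BMI class)
  is transcribed at three decimals from the published table; the published
  NO column is internally inconsistent in two rows at the printed
  precision, so the fixture stores the YES column and `no = 100 − yes`.
  All other CPTs are unprinted and therefore synthetic surrogates, chosen
  once: gender P(male) = 0.49 as surveyed; activity, BMI, central-obesity
  and smoking tables set to epidemiologically plausible values; the
  hypertension and diabetes CPTs reuse the noisy-threshold rule above with
  the risky level of each parent playing the role of `bad`. With these
  choices the enumerated marginal P(hyperlipidemia = yes) is **0.4546**,
  inside the surveyed band (detection rate 46.3%, 95% CI 44.8–47.7%).

The generator reproduces the *structure* of the survey data — categorical
levels, conditional dependences, complete cases — but none of its sampling
design (multi-stage stratification, weights), measurement error, or
unmodelled confounders. Tests passing on synthetic data therefore validate
the algorithms, not any epidemiological claim about real populations: only
the outcome CPT row queried with all parents observed (75.273% for
physically inactive obese men) is anchored to the published analysis, and
posteriors under partial evidence (e.g. the risk chain central obesity →
diabetes → obesity → inactivity, which rises 0.455 → 0.507 → 0.601 → 0.734
→ 0.752 here) reproduce the published *pattern* of monotone risk
accumulation, not its numbers, which depend on the survey-fitted
parameters.

Seeds: `forward_sample()` uses R's Mersenne–Twister and restores the
caller's RNG state; `replicate_datasets()` derives each cell's seed as
`base_seed·10000 + size_index·100 + rep`, so any replicate can be
regenerated in isolation. The derivation rule is public contract.

## Structural error

`compare_structures()` classifies each unordered pair as reversed, missing,
or extra and totals them as `S(E) = A + M + 0.5·R`. The comparison is
deliberately DAG-vs-DAG, not equivalence-class aware: a reversed edge
counts 0.5 even when Markov-equivalent, matching the convention of the
benchmark protocol this package implements (where reversals persist at
n = 20,000). Means over replicates are real-valued and totalled with the
same formula, which is an exact identity the tests assert.

## Inference and parameter fitting

`fit_mle()` is closed-form maximum likelihood per CPT row, with optional
pseudo-count smoothing; parent configurations never observed get a uniform
row and are reported in the `backfilled_rows` attribute rather than
silently. `query()` runs variable elimination with a greedy
smallest-intermediate-factor order; correctness is order-independent (the
tests compare every fixture against brute-force joint enumeration at
1e-9), only speed depends on it. Evidence of probability zero is a typed
error, not a NaN. `risk_chain()` is sugar for cumulative-evidence queries
and is tested to agree with independent `query()` calls exactly.

## The epidemiology pipeline

The pipeline mirrors a conventional risk-factor analysis. Univariate
Pearson chi-square screening uses the deliberately liberal entry threshold
p < 0.5, so weakly associated variables still reach the multivariable
stage. Stepwise logistic regression follows the classic survey-software
convention — score (Rao) test for entry at α(in) = 0.05, Wald test for
removal at α(out) = 0.10, each covariate entered as a single ordinal code
so the fit reports one coefficient per variable — and the returned table
carries the exact identities OR = exp(β̂), CI = exp(β̂ ∓ 1.959964·SE),
Wald χ² = (β̂/SE)². The z multiplier is pinned to 1.959964 rather than
`qnorm(0.975)`'s full precision so printed intervals match the tabulated
convention. `comparison_report()` then contrasts those ORs with graph
roles: adjacent to the outcome (direct), connected but not adjacent
(indirect), or unconnected — the distinction a regression cannot make, and
the reason a coefficient's sign can contradict mechanism when covariates
are collinear (the classification tables in the tests show exactly this on
synthetic data).

## Numerical choices and degenerate inputs

* G² p-values are computed on the log scale (`pchisq(..., log.p = TRUE)`),
  so association strengths like `-log p` remain finite and ordered for
  arbitrarily strong dependence.
* Zero cells contribute 0 to G²; degrees of freedom are *not* reduced for
  empty conditioning strata by default (a documented flag drops them).
* A variable observed at a single level makes a test degenerate: the
  result is independence with `reliable = FALSE`, so learners degrade
  gracefully instead of erroring mid-search.
* CPT rows must normalise to 1 within 1e-9 on construction and after file
  round-trips; enumerated joints must sum to 1 within 1e-6.
* BIF probabilities are written with 12 significant digits; the tokenizer
  accepts any non-delimiter token, so level labels such as `<18.5` or
  `≥6g` survive round-trips.

## Problem sizes used by the test suite

The suite validates recovery at the design's own scales: the 20-node
benchmark at n = 100 and 20,000 with 10 replicates per cell, sprinkler
recovery at n = 50,000 over 10 seeds, CPT recovery from 200,000 draws, and
survey-fidelity checks from 500,000 draws. The whole suite runs in about
two minutes on one core; the benchmark experiment dominates.

## Known limitations

* Only complete-case categorical data; no continuous or hybrid networks,
  and no missing-data estimation beyond listwise deletion.
* DAG-vs-DAG error counting penalises Markov-equivalent reversals; users
  wanting CPDAG-aware comparison must convert externally.
* The constraint phase's subset cap (`max_sx = 3`) can in principle miss
  separations that need larger conditioning sets; it is configurable.
* Exact inference enumerates or eliminates; networks far beyond ~22
  binary-equivalent nodes need approximate methods that are out of scope.
* The synthetic survey is a surrogate: only its outcome CPT is anchored to
  published numbers, and conclusions drawn from it concern the algorithms,
  not hyperlipidemia epidemiology.
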