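---
title: "Methods: logical modeling for cell-line-specific drug synergy prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: logical modeling for cell-line-specific drug synergy prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synlogic)
```

## The modeling pipeline

`synlogic` turns a signed prior-knowledge network (PKN) into per-cell-line
synergy predictions in five stages: rule generation, calibration,
perturbation simulation, screen binarization, and scoring. A sixth,
analytic stage (influence sweep, mechanism subgraphs, network features)
asks *which* nodes the predictions hinge on. This vignette documents the
model, every tunable that matters, and the design decisions taken where
the method is genuinely underdetermined.

### From network to rules

Each node's next value is a Boolean function of its regulators. The
default rule joins all activators by OR, all inhibitors by OR, and the two
clauses by AND NOT, so inhibition dominates. The per-node *link operator*
can be set to OR NOT instead, meaning activation wins and the node is also
active when nothing inhibits it; the canonical example is a p38/MAPK14
node that must stay active despite an active phosphatase. Regulator-free
(input) nodes get identity rules: both values are self-consistent, and it
is baseline data, not topology, that decides them — `calibrate()`
therefore pins inputs to their non-NA profile values before searching.

The two phenotype outputs, `Prosurvival` and `Antisurvival`, are
multi-level (0–3). A deposited network file fixes their regulators but
not their exact multi-level rules, so the package adopts a counting rule
as its default:

```
level = clip(#active activating regulators − #active inhibiting regulators, 0, 3)
```

with `output_rule_mode = "pos_count"` (activators only) as the
alternative, and `apply_edits()` available to install any explicit
expression. A multi-level value counts as "active" in a Boolean context at
level ≥ 1 — the simplest threshold semantics.

### Exact stable states

Predictions are read off stable states (fixed points). The solver
condenses the regulatory dependency graph into strongly connected
components, processes them in topological order, propagates values through
acyclic nodes, and exhaustively enumerates each feedback component's own
state space against the already-fixed upstream values. This is exact and
complete; the test suite pins it against a brute-force enumeration of the
entire state space on 200 random models (7–12 nodes, up to two feedback
cycles — sizes chosen so the oracle itself stays exhaustive). Components
whose state space exceeds `scc_limit` (default 2^16) raise an error rather
than silently truncating.

Where no fixed point exists, `simulate_perturbation()` falls back to the
asynchronous semantics: the model is first reduced — nodes outside the
retained set (drug targets, outputs, irreducible self-loops) are
eliminated by substituting their rules downstream, a transformation that
preserves projected fixed points — and the attractors are the terminal
strongly connected components of the full asynchronous transition graph,
with multi-level nodes stepping one level at a time. State spaces larger
than `max_states` (default 4096) return an explicit *undecided* result,
which propagates to an NA synergy call and is excluded from scoring.
Complex-attractor Viability is summarized as the mean of the per-state
`Prosurvival − Antisurvival` (min/max available via `complex_value` for
sensitivity analysis); the choice is an assumption, the published
procedure does not state one.

### Calibration

`calibrate()` repairs the generic model toward a 0/1/NA baseline activity
profile using only link-operator flips, the one change type the method
exemplifies. Two alternating rounds mirror the published procedure:

1. nodes inactive in the stable state but baseline-active, whose
   inhibitors are active, are flipped AND NOT → OR NOT;
2. for nodes active in the stable state but baseline-inactive, their
   currently inactive negative regulators are flipped to push those
   regulators toward activity.

A candidate flip is kept only when it strictly increases the matched
fraction, so agreement is monotone and "few changes over many" holds by
construction; rounds stop at convergence, when no candidate helps, or at
`max_rounds` (default 10, reported as non-convergence, never silently
accepted). Since the procedure does not say how to resolve an oscillating
repair (a flip fixing one node while breaking another), strict greedy
acceptance is the adopted policy. When several stable states exist, the
one maximizing profile agreement is selected, ties broken
lexicographically; under perturbation the state nearest (Hamming) to the
calibrated wild-type state is taken, treating the perturbed condition as a
continuation of the calibrated one.

An inhibitor's "baseline-active" status is read from the profile when
known and from the current stable state when the profile is silent —
without this fallback round 1 could never fire on sparsely curated
profiles.

### Synergy calls and screen scoring

A drug clamps all of its target nodes to 0 (full inhibition; no partial
dosing, no off-target effects). A pair is predicted synergistic when its
Viability is strictly below both single-drug Viabilities. Observed calls
binarize the screen by mean Highest Single Agent excess,
`V_AB(a,b) − min(V_A(a), V_B(b))`, averaged over **all** combination
cells of the dose grid (the published grid shape is unstated; a diagonal
average can be emulated by passing a diagonal-only record), synergistic at
`cutoff = −0.11` inclusive. Alternative cutoffs are a plain argument.
Metrics (sensitivity, specificity, PPV, NPV, balanced accuracy, MCC)
return NA on empty denominators, except MCC which uses the standard
zero-marginal convention MCC = 0. The random baseline draws the predicted
number of positives uniformly without replacement (`stats::rhyper`, which
is exactly that draw), reporting mean counts and mean per-draw metrics
alongside the closed-form `E[TP] = n·K/N`.

### Influence analysis

`influence_sweep()` clamps every Boolean non-output node at its stable
value ("fix") and its inverse ("invert") and re-simulates every single and
pair condition — `2 · n_swept · (d + d(d−1)/2)` mutant-condition
combinations, 171 conditions per mutant for an 18-drug panel. Output and
multi-level nodes are excluded because inversion `1 − value` is only
well-defined for Boolean nodes. A node is high-influence when any
perturbation changes any synergy call or produces a complex/undecided
attractor (undecided counts conservatively toward high influence).
Ranking uses unweighted total change counts (per-class TP/FN/FP/TN gains
and losses are preserved in the records; the published ranking does not
state a weighting), ties broken by node name. Mechanism subgraphs follow
the published recipe: pair-specific influence nodes (complex-attractor
nodes excluded), their induced subgraph, knock-in/knock-out of its
furthest-downstream nodes under the double perturbation, addition of all
activity-altered nodes, then a single pass removing non-output sinks.

### Network features

Features are computed on the directed graph ignoring edge signs (no
sign-aware variant is defined in the source material): out-degree,
directed betweenness, closeness in the harmonic form (classic closeness is
undefined on disconnected digraphs; the classic variant is available via
`closeness = "classic"`), global efficiency
`E = mean of 1/d(i,j)` over ordered pairs with unreachable pairs
contributing 0, and the pathway cross-talk inhibition index
`PCI(v) = (E(G) − E(G∖v))/E(G)` by node removal with the residual
efficiency over N−1 nodes. `importance_ranking()` wraps a random forest
(Gini / mean decrease in impurity), averaged over `n_repeats` seeded fits,
normalized to sum to 1; balanced mode subsamples the majority class per
tree.

## What the synthetic data emulates — and what it does not

The generators exist so every stage is testable without any external
download; their defaults are the study conditions of the test suite.

* `gen_network()` emulates PKN *shape*: a connected signed digraph,
  two outputs wired from a terminal layer with up to three regulators
  each, drug targets upstream, optional feedback cycles. It can produce a
  144-node / 366-edge instance matching the scale of a curated cancer
  PKN, but its wiring is random, not biology.
* `gen_bundle()` plants a mechanistically expressible ground truth: three
  drug-target branches redundantly sustaining a majority hub feeding
  `Prosurvival` (the OR-convergence motif of published synergy
  mechanisms), so exactly the three branch-drug pairs are synergistic;
  two branch nodes carry planted OR NOT operators that calibration must
  recover. Default scale: 24 nodes, 6 drugs, 15 pairs — small enough for
  every brute-force oracle to run exhaustively.
* `gen_profiles()` emulates the two profile sources: near-complete
  omics-inferred profiles with a configurable flip (error) and NA
  (missingness) fraction, and sparse error-free literature profiles
  (default a quarter of the nodes; the published curations cover 9–41
  nodes per cell line).
* `gen_screen()` emulates a viability dose matrix: monotone single-agent
  curves, combination cells at the stronger single agent plus a planted
  excess of −0.2 for synergistic pairs and Gaussian noise (default 0).

Passing tests on these bundles show the *pipeline logic* is correct —
planted mechanisms are recovered end-to-end at zero noise, and screen
binarization tolerates realistic noise. They do not show that a real PKN
is correct or complete, that PARADIGM-style omics inference is accurate,
or that real dose-response surfaces look like min-plus-offset; predictions
on real networks inherit all three uncertainties.

## Numerical choices and degenerate inputs

* Determinism: nodes are processed in sorted identifier order everywhere a
  sequence matters; stable states are returned lexicographically; every
  random component takes a seed.
* Strictness: synergy uses strict inequality (a pair equal to its best
  single is not synergistic); binarization is inclusive at the cutoff.
* Degenerate inputs: empty networks parse to empty objects; profiles with
  zero non-NA entries, panels naming unknown nodes, clamps on unknown
  nodes, `n_predicted > N`, and sub-3-row correlation tables all raise
  informative errors; dual (both-sign) regulations are kept as two
  parallel edges and surfaced by `validate_network()`.
* Reduction reports, rather than hides, irreducibility: self-regulating
  nodes outside the retained set are kept, and substitutions that make a
  retained node self-regulated (collapsed 2-cycles) are flagged.

## Known limitations

* Calibration searches link-operator flips only; arbitrary rule rewrites
  are deliberately manual (`apply_edits()`), so a profile unreachable by
  flips reports non-convergence.
* The asynchronous fallback enumerates the reduced state space explicitly;
  models whose reduced core exceeds `max_states` yield NA calls rather
  than approximate ones.
* Drug action is binary clamping; dose-dependent or off-target modeling is
  out of scope, as are synergy reference models other than HSA (no Bliss,
  Loewe, ZIP).
* The greedy calibration is a heuristic: it guarantees monotone
  improvement and minimal accepted flips per step, not a globally minimal
  edit set.

## Test-suite problem sizes

The suite exercises: 200 random 7–12-node models against the exhaustive
fixed-point oracle (plus 40 more with drug-target clamps), 30 reduction
cases, asynchronous attractors against closure/reachability checks on
10 random models, the full planted bundle end-to-end (calibration,
prediction, HSA scoring, influence sweep, mechanism subgraph), 300 noisy
screen seeds for recovery-rate estimation, and brute-force graph-feature
oracles on 6–10-node graphs. These sizes keep every oracle exhaustive and
the whole suite in the minutes range on one CPU.
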