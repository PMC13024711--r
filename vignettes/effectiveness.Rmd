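---
title: "Distance-based effectiveness indicators for Balance Beam process data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-based effectiveness indicators for Balance Beam process data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(procfx)
```

## The problem

Process data from interactive problem-solving assessments arrive as
time-stamped action sequences. When a task has many intersecting solution
paths, a raw action carries no fixed value: removing a weight from the beam
can be a brilliant correction in one state and a step backwards in another.
`procfx` equips two standard data-driven methods — n-gram feature selection
and distance-based sequence clustering — with *effectiveness indicators*
that inject exactly the missing context: how far the current state is from
task completion, and how each move changes that distance.

## The finite state automaton

The Balance Beam task gives students A and B four weights (50, 100, 300,
500 g) and a beam with four lever positions per side. Each weight occupies
one of ten slots (`HELD_A`, `HELD_B`, `A1`–`A4`, `B1`–`B4`), so a problem
state is a function from weights to slots: exactly 10⁴ = 10,000 states,
encoded bijectively as integers 0–9999 by a mixed-radix code (weight order
50, 100, 300, 500; the all-held-by-A initial state is 0). Weights may
co-occupy a lever position; only this slot model reproduces the task's
published state and transition counts.

Moves follow the interface rules:

* a held weight can be **passed** to the partner or **hung** by its holder
  on the holder's own side (5 moves per held weight);
* a hung weight can be **removed** back into the side owner's hand or
  **shifted** to one of the other three positions on the same side (4 moves
  per hung weight), and only the side owner may do so.

Every state therefore has out-degree 16–20, the directed edge count over
all states is 168,000, and every move is reversible. The role-collapsed
action vocabulary — pass, hang@1–4, remove@1–4, and the 12 ordered shift
pairs, per weight — has exactly 84 codes; mirror-image moves by the two
students share a code, and the mirror map (swap hands and sides) is an
automorphism of the whole graph.

A state is a **target** when exactly one weight hangs per side and integer
torques agree, mass_A·p_A = mass_B·p_B (integer arithmetic throughout; no
floating point enters the predicate). Brute-force enumeration gives 24
targets: six balanced weight/position configurations — 50 g opposite 100 g
at (2,1) and (4,2), either way around, and 300 g opposite 100 g at (1,3)
either way around — times four hand assignments of the two idle weights.
The 500 g weight appears in none of them.

## Effectiveness by breadth-first search

`state_effectiveness()` runs a multi-source BFS from the target set (unit
edge costs, so BFS is exact shortest path). The initial state has d = 3.
Transition effectiveness is the per-edge difference Δd = d(s) − d(s′);
reversibility forces |Δd| ≤ 1, and from every non-target state at least one
move has Δd = +1.

```{r eff}
eff <- state_effectiveness()
print(eff)
```

One numerical finding deserves a flag. Published summaries of this task
state that intermediate distances span 1–5 and that transitions realize 16
ordered (d, d′) pair types (5 progressive, 6 neutral, 5 regressive). Full
enumeration over the 10,000-state graph shows 96 states — those with *all
four* weights hung, in any side split other than two-and-two — at distance
6, and correspondingly 19 realizable pair types (the 16 plus `5->6`,
`6->5`, `6->6`). The 16-pair alphabet is exact for the d ≤ 5 core, which is
where virtually all empirical behavior lives; the deepest 1% of states
require one extra repair move because three hung weights must come off
before a balanced two-weight configuration can be assembled and the
remaining hung weight still needs repositioning. The package reports what
the graph actually yields.

## Three sequence representations

`encode_sequences()` replays a validated log from the initial state and
attaches, per move, a role-tagged token for n-gram work and a numeric value
for DTW work:

| representation | token (n-grams) | value (DTW) |
|---|---|---|
| `raw` | `"B hangs 500 g at position 2"` | collapsed code 1–84, as an ordinal number |
| `delta` | `"A: 1"` | Δd ∈ {−1, 0, 1} |
| `state_pair` | `"A: 3->2"` | post-move d (an optimal solution reads 2, 1, 0) |

Treating the 1–84 raw codes as ordinal numbers for DTW is deliberately
naive — it reproduces the baseline whose weakness motivates the
effectiveness encodings, and the comparison is part of the test suite.

`summarize_sequences()` adds per-group length, mean Δd (which telescopes to
(d_initial − d_final)/length), the forward/still/backward proportions, mean
post-move d, and a success label. Success defaults to *the final state is a
target* (the absorbing convention); `success_rule = "ever"` is available
because groups in principle can leave a balanced state, and the scoring
convention for such logs is a genuine design choice rather than a task
fact.

## N-gram chi-square selection

For order n ∈ {1, 2}, each n-gram is weighted per sequence by
TF-ISF = (1 + log tf) · log(N/sf), natural log by default (`base` is
configurable; the choice cancels in the sign of effects but not in χ²
magnitudes). The zero branch applies at tf = 0, and an n-gram present in
every sequence gets weight 0 — saturated features carry no discriminative
mass. The 2×2 table for an n-gram opposes its summed TF-ISF mass to the
summed mass of all other n-grams *of the same order and representation*,
split by success vs failure; χ² uses the plain observed-vs-expected
formula, no continuity correction, df = 1, φ = √(χ²/T) with T the grand
table mass. Benjamini–Hochberg runs across the n-grams of one
representation (`stats::p.adjust`); survivors at α = 0.05 are the key
segments. Ties in the χ² ranking break lexicographically so output order is
reproducible. Degenerate inputs error early: all-success or all-failure
outcomes, and corpora where every n-gram is saturated.

## DTW K-medoids clustering

`dtw_distance()` implements the classic unnormalized dynamic-programming
recurrence D(i,j) = |x_i − y_j| + min(D(i−1,j), D(i,j−1), D(i−1,j−1))
(`symmetric1`; a `symmetric2` variant doubling the diagonal local cost,
including the entry cell, is selectable), with no warping window and no
endpoint relaxation. The inner loop is compiled (Rcpp); a 422-sequence
matrix at typical lengths computes in seconds. PAM K-medoids runs on the
precomputed distance matrix via `cluster::pam` (deterministic BUILD + SWAP;
the solution is 1-swap optimal, which on tiny instances almost always
coincides with the exhaustively enumerated global optimum — the tests check
both). Cluster quality uses the mean silhouette (`cluster::silhouette`,
singletons scored 0) and a Calinski–Harabasz generalization for distance
matrices that the package defines explicitly, since the classical CH index
needs coordinates: W sums squared distances to cluster medoids, B sums
sizes times squared medoid-to-global-medoid distances, CH =
(B/(k−1))/(W/(n−k)); a zero W reports `Inf` with a warning. `scan_k()`
tabulates both indices over k = 2–6 and flags the maximizers;
`compare_cluster_features()` interprets a two-cluster solution with
pooled-variance t-tests (df = n₁+n₂−2), BH correction across the feature
family, and pooled-SD Cohen's d.

## The synthetic cohort generator

`simulate_cohort()` draws a per-group ability θ ~ Normal(0.8, 0.5) and
walks the task graph with P(move) ∝ exp(θ · Δd): θ = 0 is a uniform random
walk, large θ is near-greedy and solves in the minimal 3 steps. Walks
absorb at the first target (optionally continuing with a configurable
probability) and cap at 120 actions. One root seed spawns per-group child
seeds, so cohorts reproduce exactly regardless of generation order.

The generator emulates the structure of real two-role Balance Beam logs —
legal walks from the initial state, variable lengths, an intermediate
completion rate, and ability-dependent move quality — and is the basis of
every pipeline test. What it does *not* emulate: with the absorbing rule,
unsuccessful groups always run to the length cap, so completion rate and
mean length cannot be dialed independently (empirical cohorts show ~40%
completion with mean length ~50, a combination that requires giving-up
behavior the policy deliberately omits); there is no memory, fatigue, role
negotiation, or chat. Passing tests therefore demonstrate correctness of
the algorithms and recoverability of planted ability structure, not
behavioral realism.

Test problem sizes are the package's own choices, scaled for a routine
desktop run: the planted two-ability cohort uses 80 groups at cap 60, the
false-discovery check 120 null corpora of 40 sequences (the observed
key-flag rate under label-independent generation is far below α), the
θ-monotonicity grid {−0.5, 0.5, 1.5} with 120–150 groups per point, and
the uniform-policy completion probability is verified against an exact
sparse transition-matrix absorption computation on all 10,000 states.

## Known limitations

* The 1–84 raw-code assignment is one fixed enumeration (weight-major,
  pass/hang/remove/shift-minor); any order-preserving bijection would do,
  and other published codings of the same task need a mapping table.
* Effectiveness assumes unit-cost, reversible transitions; tasks with
  irreversible or weighted moves need a different distance.
* The CH generalization to distance matrices is a documented convention,
  not a canonical definition; silhouette is the primary index.
* The empirical dataset's on-disk schema is not guessed: `read_action_log()`
  takes an `adapter` function to map foreign column layouts onto the
  standard one.
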