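---
title: "Designing RNA sequences by Monte Carlo tree search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing RNA sequences by Monte Carlo tree search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnadesign)
```

## The problem

RNA inverse folding asks for a nucleotide sequence whose predicted secondary
structure equals a user-specified target, given in dot-bracket notation.
Because function tracks structure, and because GC content affects stability
and synthesis, the practical problem usually comes with a second constraint:
the designed sequence's GC fraction $\alpha$ should lie near a target
$\alpha^*$. `rnadesign` treats both at once: structure identity is the
success criterion, and GC content enters the objective as a bonus.

## Sequence space as a tree of assignment events

The target fixes which positions pair. A *paired site* $(i, j)$ can hold one
of the six admissible pairs AU, UA, GU, UG, CG, GC; a *single site* one of
the four bases. With $p$ pairs and $s$ free bases the design problem has
$\ell = p + s$ sites, and a complete assignment is a path of $\ell$ events.
The search tree over these events is explored by Monte Carlo tree search:

1. **Selection.** From the root, descend into the child maximizing the
   upper confidence bound
   $u_i = w_i / v_i + C \sqrt{2 \ln v_{parent} / v_i}$, ties broken
   uniformly at random; unvisited nodes ($v_i = 0$) count as $u_i = \infty$.
2. **Expansion.** A leaf visited at least $\beta$ times grows all children
   of one randomly chosen remaining site (four or six, each initialized
   with $v = w = z = 0$); one random child is taken for simulation. The
   root is expanded in the very first round.
3. **Simulation.** A playout generates $k$ candidate sequences: one initial
   sequence plus $k-1$ local updates, each folded once and scored. The
   positions fixed by the path (*essential positions*) never change.
4. **Backpropagation.** The playout's best reward $z$ is added to $w$, and
   the visit count incremented, at every node on the path, the simulated
   node included (its own playouts contribute to its own mean).

The run stops the moment any candidate's predicted structure is identical
to the target, or when the iteration/time/fold budget is spent.

## Reward

For a candidate of length $N$ at structural Hamming distance $d$ from the
target (computed on canonicalized dot-bracket strings) the reward is

$$
r = \begin{cases}
R_{GC} + (N - d)/N & \text{if } |\alpha - \alpha^*| \le \delta\\
(N - d)/N & \text{otherwise,}
\end{cases}
$$

and simply $(N-d)/N$ when no GC target is set. The window is closed, and
$\alpha - \alpha^*$ is rounded to 12 decimal places before the comparison so
that floating-point representation noise cannot flip the branch at an exact
boundary. The discontinuity of size $R_{GC}$ is deliberate: it makes the
tree's value signal sensitive to whether a branch's essential assignments
leave the GC window reachable.

## Playouts: initial sequences and local updates

With a GC target, the initial sequence visits non-essential sites in random
order assigning G/C (singles) or GC/CG (pairs) until the running GC count
reaches $N\alpha^*$, then fills the rest with A/U or AU/UA. A paired
placement may overshoot by one base — the generator aims for
"approximately $N\alpha^*$" and the reward's $\delta$-window absorbs the
slack. Without a GC target every non-essential site is drawn uniformly
(four bases, or six pairs).

Each local update makes one exhaustive pass against the current predicted
structure:

* **rule (i)** — a target pair absent from the prediction, both positions
  non-essential, is rewritten to one of AU, UA, CG, GC;
* **rule (ii)** — a predicted pair that is not a target pair, both positions
  non-essential, is broken: AU/UA $\to$ AA or UU, GC/CG $\to$ CC or GG,
  GU/UG $\to$ one of AC, CA, AG, GA, CU, UC. The six wobble options are
  exactly those that change neither base into nor out of $\{G, C\}$, so
  rule (ii) conserves the GC count.

Within a pass, rule (i) runs over its sites in ascending order of the
opening position, then rule (ii) likewise, skipping positions rule (i)
already rewrote; the fixed order buys exact seeded reproducibility and is
otherwise unobservable because the two rules' site sets are disjoint within
a pass. Rules are *not* iterated to a fixpoint inside one update: rule
applicability is defined relative to one fixed predicted structure, so one
exhaustive pass exhausts it, and the candidate is re-folded on the next
update. A playout of length $k$ therefore consumes exactly $k$ structure
predictions, which keeps fold-budget accounting exact. Pairs with exactly
one essential position are skipped by both rules — the rules are defined
for two non-essential positions only. This has consequences discussed under
*Limitations*.

## Folding backends

Three interchangeable backends satisfy one contract (predict, canonicalize,
count the call):

* `reference` — a built-in Nussinov-style maximum-base-pair dynamic program
  (Rcpp) over the six admissible pairs, minimum hairpin loop of 3 unpaired
  bases, length cap 200. Ties are broken deterministically (pair the
  leftmost position if that attains the optimum, preferring the smallest
  partner index), so it is a pure function of the sequence. It scores pair
  count, not free energy: it exists so the entire design loop, test suite
  and examples run with no external software, and the design loop only ever
  compares candidates against this same backend's predictions, which is
  internally consistent.
* `vienna` — an RNAfold-compatible external program (nested structures).
* `pkiss` — a pKiss-compatible external program (pseudoknots).

Structures are always canonicalized before comparison: nested pairs render
as `()` and crossing pairs are assigned to the first of `[]`, `{}`, `<>`
that keeps each layer internally nested. Different engines may put the same
crossing pairs on different layers, and a raw string comparison would
inflate the Hamming distance spuriously. Four layers are supported; deeper
crossing nests are rejected with a clear error. User-supplied targets are
not subjected to a hairpin-loop check — only the reference folder enforces
its own loop constraint on structures it predicts.

## Defaults and what they mean

| parameter | default | meaning |
|---|---|---|
| `C` | 0.5 | exploration constant of the UCB score |
| `beta` | 1 | visits required before a leaf expands |
| `k` | 50 | candidates per playout (1 initial + 49 updates) |
| `r_gc` | 1 | reward bonus for landing in the GC window |
| `delta` | 0.01 / 0.02 | GC tolerance; the larger default applies to pseudoknotted targets, where prediction is harder and the window is loosened accordingly |
| `time_limit` | 600 s | applied only when no other budget is given |

`delta` switches on the parsed target's pseudoknot status only when the
user did not set it explicitly. The expansion gate compares the visit count
*before* the current round's increment, so under `beta = 1` a freshly
created leaf is simulated once as-is and expands on its next visit; the
root is the single exception, expanded in round 1. Success by default means
structure identity alone; `require_gc = TRUE` additionally demands
$|\alpha - \alpha^*| \le \delta$, for workflows where the GC constraint is
hard rather than soft.

A note on small targets: at $\delta = 0.01$ and $\alpha^* = 0.5$ the GC
window contains an attainable integer GC count only for even $N$ (or odd
$N \ge 50$). Strict-GC examples and tests in this package therefore use
even-length targets.

## The fixture generator

`generate_fixture()` produces random valid targets for tests and
benchmarks: pairs are placed one at a time, uniformly among the placements
that keep the structure nested and honour the minimum loop, with a 0.75
probability of preferring a placement that extends an existing helix
whenever one is available. The stacking preference reflects real secondary
structures (helices come in stacks, rarely as isolated pairs) and is also
what makes pair densities above ~0.35 reachable at all. An optional
crossing pair on a second bracket layer gives a minimal pseudoknot. The
generator emulates the combinatorics of real targets — nesting, loop
minima, stem/loop mix — but not their thermodynamic provenance: real
consensus structures are shaped by an energy model the reference folder
does not have. Passing the end-to-end tests therefore demonstrates that the
search solves the inverse problem *for its own folder*, not that the
designed sequences would fold correctly under a thermodynamic model; for
that, run the `vienna` backend.

## Problem sizes used in tests and the acceptance script

The shipped suites solve the 12-nt hairpin plus batches of random nested
fixtures of length 15–30 (20 seeds each, 500-round cap), check the folder
against exhaustive enumeration at lengths 4–12 (200 sequences), verify GC
conservation over 1000 random rewrites, and run the tree-vs-restart
comparison on five fixtures of length 54–94 at a 300-prediction budget —
sizes chosen so the whole suite completes in minutes while still exercising
every code path at realistic scale.

## Known limitations

* **Maximum-pairing degeneracy.** Under the reference folder many sequences
  have several co-optimal structures; the deterministic tie-break picks one.
  Targets containing isolated base pairs adjacent to long unpaired
  stretches are the worst case: almost any base placed in the loops can
  recruit a spurious partner, and success requires a sequence whose
  maximum-pairing structure is *uniquely* the target. A small fraction of
  random fixtures of this shape resist design within the 500-round test
  budget. A thermodynamic folder does not share this pathology (isolated
  pairs are energetically penalized there).
* **Essential positions can poison subtrees under this folder.** Because
  the rewriting rules skip pairs touching an essential position, an
  essential base sitting in a loop region can sustain a spurious pair that
  no local update may break. With the aggressive maximum-pairing folder
  this happens often enough that per-playout success decays measurably with
  the number of essential positions (on one 19-nt fixture: 0.32 with no
  essentials, 0.11 with four, 0.02 with eight). Two consequences we observe
  and report honestly: deep trees can *hurt* with this folder, and at small
  fold budgets the tree also correlates its playouts (all early rounds
  share the root's expansion site), so tree search does not reliably beat
  plain random-restart local search here — the comparison ships as part of
  the acceptance suite and its outcome depends on the folder, not on the
  tree machinery, which the unit suites verify in isolation. With a
  thermodynamic folder, where loop bases rarely form isolated pairs,
  essential positions are close to harmless and the tree's guidance can
  dominate.
* **No sequence constraints.** IUPAC masks, forbidden motifs and
  energy-gap objectives are out of scope.
* **Pseudoknot design requires an external engine.** The reference folder
  is nested-only; a pseudoknotted target with a nested backend is rejected
  before the search starts.
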