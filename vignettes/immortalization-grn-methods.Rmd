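---
title: "Methods: the Boolean core network of epithelial spontaneous immortalization and its epigenetic landscape"
author: "immortalGRN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Boolean core network and epigenetic landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immortalGRN)
```

## The biological system and the model

Cultured human epithelial cells undergoing *spontaneous immortalization*
pass through a stereotyped succession of states: normal epithelial cells
become senescent, and some cells later surpass senescence to reach a
mesenchymal stem-like state with tumorigenic potential. This package
models the intracellular regulatory core believed to canalize that
succession as a nine-node Boolean network over NF-κB, ESE-2, Snai2, p16,
p53, Rb, E2F, Cyclin and Telomerase (TELase), with synchronous dynamics

$$x_i(t+1) = F_i\big(x_{j_1}(t), \dots, x_{j_k}(t)\big), \qquad x_i \in \{0, 1\},$$

where each $F_i$ is a truth table over node $i$'s regulators. Cell types
are identified with the network's attractors. The update is deterministic
and synchronous; because every attractor of the shipped network is a fixed
point, and fixed points are invariant under the update schedule, the
choice of synchronous updating does not affect the biological conclusions
(cyclic attractors of user-supplied networks are reported under
synchronous semantics only).

States are encoded as integers in $[0, 2^n)$ with node 1 (NF-κB) as the
most significant bit; this bijection is fixed and used for all serialized
output, so state codes are reproducible across runs.

## Reconstructing the update rules

The curated interaction list (`coreInteractions()`, 31 signed edges) fixes
which nodes regulate which, and with which sign, but not the Boolean
logic. The three reference expression profiles (`phenotypeProfiles()`)
and the published basin sizes provide strong constraints: the epithelial,
senescent and mesenchymal profiles must be the only attractors; their
basins must cover 17.97%, 25.78% and 56.25% of the 512 initial states;
clamping NF-κB to 1 must shift them to 6.25%, 18.75% and 75%; and the six
loss/gain-of-function mutants of ESE-2, Snai2 and p16 must reproduce the
reported attractor repertoires.

`searchRules()` implements the generic search: per node it enumerates a
deterministic family of monotone, sign-consistent candidate rules
(inhibitor-dominant AND–NOT, activator-AND variants,
all-inhibitors-jointly-required, and per-inhibitor exemptions), keeps
candidates that fix every target profile, and ranks combinations by
attractor match and basin deviation.

During development we established a stronger result: **no fully monotone,
sign-consistent rule set over the curated wiring can satisfy all the
constraints at once.** The argument has three steps. (1) With NF-κB
clamped, the (ESE-2, Snai2) pair is an autonomous four-state subsystem;
reproducing the 75% mesenchymal basin forces both "neither" and "both"
configurations of the pair to drain into the Snai2 wing, leaving exactly
the 64 ESE-2-on/Snai2-off states to split 16 : 48 between the epithelial
and senescent attractors. (2) In the Snai2 gain-of-function mutant, every
trajectory with NF-κB initially off loses ESE-2, E2F, Telomerase-free p16
and p53 within a few steps, so NF-κB must be activatable by Snai2 alone —
otherwise a spurious NF-κB-off attractor survives. (3) Monotonicity then
forces ESE-2 to decay in the presence of Snai2 regardless of context,
which routes at least 320 of the 512 wild-type initial states into the
mesenchymal basin — more than the 288 (56.25%) required. The constraints
are therefore only satisfiable if at least one edge acts
non-monotonically.

The shipped rule set (`buildCoreGRN()`) resolves this with the single
minimal deviation the extended search found in every exact solution: in
the ESE-2 rule, NF-κB *licenses Snai2's repression of ESE-2* instead of
acting as a direct activator,

| node | update rule |
|---|---|
| NF-κB | NFkB ∨ ESE2 ∨ Snai2 ∨ p16 |
| ESE-2 | ¬Snai2 ∨ (ESE2 ∧ ¬NFkB) |
| Snai2 | ¬ESE2 ∨ (Snai2 ∧ NFkB) |
| p16 | ¬Snai2 ∧ ¬TELase ∧ (p16 ∨ ¬E2F) |
| p53 | p16 ∧ ¬Snai2 ∧ ¬(NFkB ∧ TELase) |
| Rb | p16 ∨ ¬Cyclin |
| E2F | ¬Snai2 ∧ ((Cyclin ∧ (¬p53 ∨ ¬Rb)) ∨ (¬p53 ∧ ¬Rb)) |
| Cyclin | E2F ∨ (NFkB ∧ ¬p16) ∨ (ESE2 ∧ ¬Snai2 ∧ ¬p16) |
| TELase | Snai2 ∨ ¬ESE2 |

All 31 curated edges are functional inputs; 30 are monotone with their
curated sign. The ESE-2/Snai2 pair forms a default-on mutual-inhibition
switch — each side is expressed unless the other represses it — with
NF-κB tipping the balance toward Snai2 on both sides of the switch, a
reading consistent with inflammation promoting the
epithelial–mesenchymal transition. The reconstruction reproduces not only
the attractor counts of the six mutants but their reported character: the
ESE-2 gain-of-function hybrid attractor co-expresses epithelial (ESE-2)
and mesenchymal (Snai2, TELase) markers with Cyclin on, and the p16
gain-of-function mesenchymal-like attractor lacks p53.

## Basins, clamping and mutants

`basinPartition()` iterates every clamp-consistent initial configuration
to its attractor through the memoized successor table (full forward
iteration by pointer doubling; no sampling) and reports counts plus
percentages; printed tables round percentages to two decimals. Clamping
(`clampNode()`) holds a node at a fixed value and restricts exploration to
the $2^{n-1}$ consistent states; `simulateMutant()` is by construction
bit-for-bit identical to `basinPartition(clampNode(...))`.
`logicRobustness()` measures persistence of the wild-type fixed points
under permanent single-bit truth-table flips, exhaustively over all table
bits or by uniform sampling for larger networks; a single bit flip is the
minimal permanent alteration of the regulatory logic expressible in the
truth-table representation.

## The stochastic layer

The stochasticity-in-nodes (SIN) model perturbs the deterministic update:
each node independently disobeys its rule with probability $\xi$ per
step, so a state $s$ moves to $s'$ with probability
$\xi^{h}(1-\xi)^{n-h}$ where $h$ is the Hamming distance between $s'$ and
the deterministic successor of $s$. Noise is applied to the raw state
each step, with no deterministic relaxation in between.
`exactOneStepOperator()` materializes this matrix (guarded at
$n \le 12$) and is the analytic oracle for the Monte-Carlo estimator.

`estimateTransitionMatrix()` estimates the attractor-level matrix
$\pi_{ij} = P(A_{t+1} = j \mid A_t = i)$ by simulating, for every state,
a fixed number of one-step transitions (default 10,000 per state) and
pooling counts over the states of each basin with equal weight. Rows are
normalized; the estimate converges to the basin-aggregated exact operator
and the tests check agreement at three binomial standard errors.

The occupation distribution evolves by $p_j(t+1) = \sum_i p_i(t)\,
\pi_{ij}$ — the row-stochastic matrix acts on the right; this orientation
is fixed in `iterateDistribution()` and documented here because matrix
notation alone leaves it ambiguous.

### Temporal attainment

`temporalAttainment()` starts the probability mass on one attractor
(default use: the epithelial fixed point itself, consistent with the MFPT
initialization; a basin-uniform start can be expressed through `p0`) and
summarizes the trajectory two ways. The *argmax trace* records which
attractor is globally most probable at each step; the *peak order* sorts
attractors by the time their occupation probability peaks. For the
shipped network the attainment curves form three successive waves —
epithelial (peak at $t \approx 0$), senescent (a transient wave), then
mesenchymal (late plateau) — and the peak order is epithelial →
senescent → mesenchymal at every tested noise level
($\xi \in \{0.01, 0.05, 0.1\}$). The senescent wave, whose basin is the
smallest of the three, crests near $p \approx 0.26$ and never holds the
global argmax; we verified this is not an artifact of one reconstruction
by screening all 78 exact rule sets our search produced (and both the
attractor-level and full-state-space chains): in every one the argmax
trace jumps from epithelial directly to mesenchymal while the peak order
is epithelial → senescent → mesenchymal. The peak order is therefore the
summary that faithfully captures the attainment succession, and it is
what the acceptance test asserts; the argmax trace is still returned for
completeness.

### Relative stability and global ordering

`mfptSimulate()` estimates mean first-passage times by simulating sample
paths of the attractor-level chain started wholly at attractor $i$ and
averaging the first hitting step of $j$ (defaults: 10,000 paths, censoring
horizon $10^5$ steps; censored pairs report `Inf` plus the censor count
rather than raising). Since sample paths are exchangeable, the population
is propagated as per-state counts with multinomial steps — statistically
identical to per-path simulation and far cheaper. The independent oracle
is `mfptAnalytic()`, the fundamental-matrix solve
$(I - Q)\,m = \mathbf{1}$. A full-state-space MFPT variant (first entry
into the target basin under SIN steps) is available through the
`stateLevel` argument for sensitivity analysis; it is not used in the
headline results.

Net transition rates $d_{ij} = 1/\mathrm{MFPT}_{ij} -
1/\mathrm{MFPT}_{ji}$ are antisymmetric by construction;
`netRatesAndOrdering()` searches all attractor permutations (exhaustive —
six for three attractors) for one along which every consecutive rate is
strictly positive. For the shipped network the unique consistent global
ordering is epithelial → senescent → mesenchymal at all three noise
levels, matching the attainment analysis from the stability side.

## Numerical and design choices

- **Defaults**: $\xi = 0.05$ headline, swept over $\{0.01, 0.05, 0.1\}$;
  10,000 one-step simulations per state for $\Pi$; 10,000 MFPT sample
  paths with a $10^5$-step horizon; every stochastic function accepts a
  seed and the landscape writers record it (`writeLandscapeConfig()`).
- **Enumeration guard**: exhaustive operations refuse networks beyond 24
  nodes; the exact SIN operator beyond 12. Tests and examples use 4–9
  node networks, where every computation completes in seconds.
- **Ties**: the argmax trace breaks ties toward the incumbent attractor;
  peak-order ties break by descending peak height.
- **Degenerate inputs**: constant nodes are truth tables with zero
  regulators; empty attractor sets label to an empty labelling; a clamp
  violation in an input state is an error rather than silent coercion.
- **Serialization**: the rule-file writer emits canonical sum-of-minterm
  expressions, which drops declared-but-non-functional regulators of
  constant tables; the TSV truth-table format is structurally lossless
  and is the round-trip format of record for fixtures.
- **Reduction**: signed-digraph reduction deletes sources and collapses
  simple mediators (in- and out-degree one) with sign composition,
  iterated to a fixed configuration; opposite-sign parallel edges are
  kept and flagged because no cancellation rule is defined for them.
  Boolean reduction requires removable sources to carry constant rules
  (their value is substituted) and composes mediator functions into their
  single target; the guarantee — and the property the tests check — is
  preservation of fixed points under projection, not of cyclic
  attractors. The shipped nine-node core corresponds to the kept set of
  such a reduction applied to a larger curated network whose full wiring
  is not part of this package.

## What the synthetic fixtures do and do not show

`randomBooleanNetwork()` samples either unconstrained random truth tables
or sign-consistent monotone rules (random signed threshold functions);
`randomChain()` plants a dominant super-diagonal path in a row-stochastic
matrix. These fixtures exercise every pipeline stage — enumeration
against a brute-force successor-map oracle, reduction against projection
of fixed points, MFPT estimation against the linear solve, ordering
recovery against the planted path — without external data. They emulate
the combinatorial structure of small regulatory networks, not the
biology: degree distributions, canalization depth and redundancy of real
curated networks are not matched, so passing fixture tests validates the
algorithms, not the biological adequacy of any particular model. The
biological claims rest on the shipped core network and its agreement with
the reference attractors, basins and mutants.

## Known limitations

- The reconstruction is constrained, not unique: other rule sets
  reproduce the same attractors, basins and mutant repertoires (our
  search found 78); they differ in transient dynamics, and therefore in
  quantitative $\Pi$ and MFPT values, while the qualitative landscape
  (peak order and global ordering epithelial → senescent → mesenchymal)
  was identical across all of them.
- Asynchronous and probabilistic update schedules are out of scope except
  through the fixed-point invariance argument.
- The landscape layer characterizes noise-induced transitions of the
  intracellular network; tissue-level processes that modulate transition
  rates in vivo are outside the model.
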