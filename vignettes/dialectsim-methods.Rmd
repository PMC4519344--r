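---
title: "Simulating cognate evolution on contact networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating cognate evolution on contact networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dialectsim)
```

## The question the package addresses

Phylogenetic methods organize lexical data into branching trees, yet
dialectology explains the same kind of data spatially: innovations arise in
centers and diffuse to neighbors, without any branching event.  `dialectsim`
simulates the second world — dialects as nodes of a contact network that
exchange cognates (words of common origin) for a list of basic-vocabulary
concepts — and then asks the first world's diagnostic question: *do the
resulting data look tree-like?*  Tree-likeness is measured by the quartet
delta score of the Hamming-ratio distance matrix, and the binary matrices can
be exported as NEXUS for split-network or Bayesian tools.

## The model

Each node $i$ has a population $p_i$; each undirected edge carries a distance
$d_{ij}$.  The influence of $j$ on $i$ is

$$w_{ij} = \begin{cases} p_j / d_{ij}^2 & j \in N_i\\ s\,p_i & j = i\\ 0 &
\text{otherwise,} \end{cases}$$

so big neighbors push harder and influence decays with the square of
distance; $s$ scales how conservative a node is about its own lexicon.

For one concept, node $i$'s state $V_i^t$ is a non-empty set of cognates.
All nodes start from one shared cognate at $t = 0$.  At each step, node $i$
considers the candidates $C_i^t = \{\text{new word}\} \cup
\bigcup_{j \in \{i\} \cup N_i} V_j^{t-1}$ — everything its neighborhood held
one step ago plus at most one fresh innovation.  Candidates are scored:

$$\mathrm{wscore}(c) = \sum_{j \,:\, c \in V_j^{t-1}} w_{ij}\,/\,|V_j^{t-1}|
\qquad\text{(existing cognate)}, \qquad \mathrm{wscore}(\text{new}) = b\,p_i,$$

a set $v$ scores $\mathrm{sscore}(v) = \sum_{c \in v} \mathrm{wscore}(c) -
d\,|v|^2$, and the next state is drawn from
$P(v) \propto \exp(\mathrm{sscore}(v))$ over all non-empty subsets of the
candidates.  The quadratic cost $d > 1$ penalizes synonym-rich states, so
states of size one or two dominate in practice.  All nodes update
synchronously from the $t-1$ snapshot (the chain is Markov in the network
state), which also makes the update order irrelevant — a property the test
suite checks in distribution.

Births and deaths follow naturally: a cognate is born when a node keeps its
fresh token (a rejected token was never born, so each cognate is born exactly
once), and dies the first step no node holds it.  Dead cognates can never
re-enter a candidate set.  One boundary choice the formulas leave open: at
$b = 0$ the literal new-word score would be $0$, which still leaves the
innovation a weight of $e^{-d}$; the package instead treats $b\,p_i = 0$ as
"innovation disabled" and does not offer the token at all.

Concepts are mutually independent; each gets its own RNG substream derived
from the master seed, so results cannot depend on evaluation order.  The
defaults $T = 1000$ steps and 100 concepts correspond to a Swadesh-style
survey horizon.

## Exact subset sampling

The state space of one update is the non-empty power set of the candidates,
which grows as $2^n$.  `subset_distribution()` enumerates it (up to a cap of
15 candidates) and serves as the oracle; the production sampler
`sample_subset()` instead factorizes

$$P(v) \;\propto\; e^{-d k^2} \prod_{c \in v} x_c, \qquad x_c =
e^{\mathrm{wscore}(c)},\; k = |v|,$$

drawing the size $k$ with weight $e_k(x_1,\dots,x_n)\,e^{-d k^2}$ (elementary
symmetric polynomials) and then a $k$-subset with probability proportional to
$\prod x_c$ by the standard sequential scheme on suffix polynomials.  Scores
are max-shifted before exponentiation, and size weights are combined in log
space, so only score *differences* matter numerically.  The draw is exact —
no approximation is involved — and the test suite holds the sampler to the
enumerated distribution within a total-variation distance of 0.01 at
$10^5$ draws.

## From snapshots to tree-likeness

The final snapshot becomes a binary matrix (`encode_binary()`): one column
per cognate alive at $T$, grouped by concept; extinct cognates are not
characters, mirroring how a field survey only sees the current distribution.
Distances are Hamming ratios over all columns jointly (`distance_matrix()`).

The delta score (`delta_score()`) examines every quartet $\{x, y, u, v\}$:
the three pairings of distance sums are sorted $s_1 \le s_2 \le s_3$ and the
quartet contributes $(s_3 - s_2)/(s_3 - s_1)$, zero when all three sums tie
(the four-point condition says $s_2 = s_3$ on a tree metric, so 0 means
perfectly additive).  Partial ties need no special casing — the formula
already returns 0 or 1 as appropriate — and the triple tie is detected with a
relative tolerance of $10^{-9}$, which matters because Hamming-ratio
distances are ratios of small integers and tie exactly rather often.  The
exhaustive mean over $\binom{n}{4}$ quartets is the default; a seeded uniform
subsample is available for matrices large enough that enumeration hurts.
Per-taxon means (the average over quartets containing each taxon) are
reported as standard practice.

## The built-in topologies

Five networks ship as YAML configs (editable copies live under
`system.file("extdata", "fixtures", package = "dialectsim")`).  The
hyperparameters $s$, $b$, $d$ per topology are fixed study conditions; the
node-level populations and edge distances are the package's own defaults,
chosen once to satisfy the qualitative constraints each scenario encodes —
centers larger than peripheries, shared nodes equidistant from both centers,
two clusters joined by a single long bridge, a colony copied late into the
opposite cluster — while producing the contrast the five scenarios are meant
to exhibit between spatially tree-like and non-tree-like structures:

* **grid** (`s=4, b=1, d=3`): a 3×3 rook-adjacency lattice, all populations
  equal — no spatial tree structure at all.  The lattice spacing (1.4) keeps
  neighbor coupling loose enough that local innovations survive and spread
  partially, which is where the conflicting, loop-borne signal comes from.
* **star** (`s=2, b=0.1, d=3`): one center of population 10 with eight
  peripheries of population 1.  The spoke length is the one knob that
  matters here: short spokes let the center overwhelm the peripheries (no
  variation survives anywhere, distances collapse to ties), long spokes
  decouple them entirely.  The default (2.45) sits in the regime where
  peripheries keep a modest private vocabulary.
* **two_stars** (`s=2, b=1, d=3`): two centers of population 8, four
  exclusive peripheries each, and two shared nodes (H, K) at equal distance
  from both centers — the shared nodes are where conflicting signal
  concentrates.  Center population is the sensitive knob under `b = 1`:
  centers drive innovation at rate `b * p`, and slightly larger centers
  churn the whole network.
* **bottleneck** (`s=4, b=0.1, d=3`): a western ring A–E with two chords
  and an eastern triangle F–G–H joined by a single bridge (length 3) three
  times longer than any internal edge; E is the western bridgehead.
  Internal wiring density is the knob: a full clique makes each cluster
  internally uniform (delta near 0), a bare ring leaves path structure
  inside the cluster; the chords sit between the two.
* **colony** (`s=4, b=0.1, d=3`): ten founding nodes in a bottleneck-style
  west/east layout of loose rings run for 750 steps; then node B —
  population 10, a copy of western node A — appears among the eastern nodes
  and the last 250 steps run with it.  B's links into the east are long
  (weak), so within 250 steps it converts the eastern lexicon only
  partially: the data end up carrying both 750 steps of shared eastern
  identity and a western enclave that is a near-duplicate of A, a
  combination no additive tree accommodates well.  (Short, strong links
  were examined and behave differently: B then simply overwrites its
  neighbors and the data *gain* tree-likeness, because the east becomes a
  clean extension of the west.)

```{r fixtures}
fx <- fixture_topology("bottleneck")
fx$topology
fx$params
```

## What the generator does and does not emulate

The generator produces exactly the kind of data a basic-vocabulary survey
yields — binary cognate-presence vectors over ~100 concepts — with births,
horizontal diffusion, and deaths, under a *time-invariant* spatial structure
(except for explicit copy events).  It does not model: speaker-level
variation within a dialect (a node is a whole speech community), semantic
shift or repeated borrowing of the same etymon (each cognate is born once),
complementary near-synonyms that do not compete, population dynamics, or
prestige asymmetries beyond the population weight.  Passing tests therefore
show that the *analysis layer* behaves correctly on contact-generated data
of this idealized kind; they do not validate the model against any real
dialect survey.

## Numerical and design choices

* Enumeration cap: 15 candidates ($2^{15}-1$ subsets) for
  `subset_distribution()`; the factorized sampler has no cap and is the only
  path used inside runs.
* Copy events fire at the *end* of their step: a run of $T = 1000$ with an
  event at 750 performs 750 steps without the colony, copies the source's
  freshly updated state, and performs 250 steps with it.  At the event step
  the colony's set equals the source's exactly.
* Survival times (`survival_times()`) exclude the initial cognate and
  anything still alive at $T$, so the reported distribution is of complete
  lifespans only.
* Column order in `encode_binary()` (concept, then birth time, then id) is
  part of the contract; NEXUS export writes one CHARSET per concept.
* Replicated experiments (`run_experiment()`) default to 20 replicates: a
  single run's delta score carries appreciable Monte-Carlo spread (standard
  deviations around 0.01–0.09 depending on the topology), and 20 replicates
  bring the standard error of the mean delta near or below 0.01.

## Problem sizes used in the shipped tests

The package's own test suite runs each topology at the full study conditions
($T = 1000$, 100 concepts) for the invariant checks and the survival-time
analysis, and uses 20 seeded replicates per topology for the delta-score
comparisons.  Unit tests for the samplers and the delta score run on small
synthetic cases where brute-force enumeration is exact.

## Known limitations

* The delta score is reported without a significance test; no accepted test
  exists for comparing delta scores, so differences should be read
  qualitatively.
* Simulated matrices from small networks (8–12 taxa) produce granular
  distances; many quartets tie exactly, and the tie convention (0) matters.
* The factorized sampler is exact but $O(n^2)$ per draw in the candidate
  count; candidate counts stay below ~20 at the default $d = 3$, so this has
  never been the bottleneck in practice.
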