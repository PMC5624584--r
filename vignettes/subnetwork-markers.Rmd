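---
title: "Game-theoretic discovery of discriminative subnetwork markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Game-theoretic discovery of discriminative subnetwork markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Differentially expressed genes rarely act alone: in case/control expression
studies, the genes that separate the two phenotypes tend to cluster in the
protein–protein interaction network (PPIN), and a *connected set* of genes
whose aggregated expression discriminates the phenotypes — a subnetwork
marker — is both a stronger and a more interpretable signature than a flat
gene list.  `gtamarkers` searches for such markers by treating each
candidate subnetwork as a cooperative game: every gene is a player that
chooses to **join** (1) or **leave** (0) the marker, and a marker is a
pure-strategy Nash equilibrium of a payoff that rewards expression
evidence, neighbourhood support and density, and penalizes size.

## Scoring model

For gene $i$ with expression $x_{ij}$ in sample $j$, the two phenotype
classes define conditional densities $f_{i1}$ and $f_{i2}$, and the
per-sample log-likelihood ratio is

$$\mathrm{LLR}_i(x_{ij}) = \log\frac{f_{i1}(x_{ij})}{f_{i2}(x_{ij})}.$$

We model $f_{i1}, f_{i2}$ as Gaussians with the per-class sample mean and
unbiased standard deviation.  The Gaussian choice matches the normalized
microarray-style input the method assumes; no kernel estimate is offered.
Two numerical conventions matter:

* the per-class standard deviation is floored at $10^{-6}$ so a constant
  gene still defines a proper density rather than an infinite LLR;
* the natural log is used.  The choice of base is observationally
  irrelevant downstream: rescaling an LLR vector by any positive constant
  leaves its t-statistic unchanged (asserted numerically in the tests), and
  everything after scoring consumes only t-statistics.

A gene's scalar evidence is the Welch (unequal-variance, unpaired)
two-sample t-statistic of its LLR vector between the classes, signed
class 1 (case) minus class 2 (control).  When both class variances of the
LLR vector vanish with equal means the statistic is defined as 0.

## Payoff and equilibrium

Within a candidate subnetwork $G_s$, a state assigns join/leave to every
player (the seed always joins).  Let $G_{join}$ be the induced subgraph on
the joiners.  Player $i$'s payoff is gain minus loss:

$$\mathrm{GF}(i) = \alpha\, t_i + \beta\, \mathrm{LS}_i +
  \gamma\, \mathrm{DE}(G_{join}), \qquad
  \mathrm{LF}(i) = \delta\,(|V_{join}| - 1),$$

where $\mathrm{LS}_i$ is the sum of t-statistics of $i$'s *joined*
neighbours (zero for a leaver — a gene that leaves has no neighbour in the
subnetwork), and $\mathrm{DE}$ is the weighted edge sum of $G_{join}$ over
$\binom{|V_{join}|}{2}$, shared by all players and defined as 0 below two
joiners.  The defaults $\alpha = 1.24$, $\beta = \gamma = 1$, $\delta = 2$
are the published calibration of the algorithm and are exposed in
`gta_params()`.  A state is a (weak) pure-strategy Nash equilibrium when no
single player can *strictly* raise its own payoff by flipping its strategy.

## The search

1. **Working universe.** Network nodes without expression cannot be
   scored, so the working graph is the intersection of network nodes and
   profile genes (counts of removed nodes are reported).
2. **Seeds.** Genes with at least the mean degree of the working graph,
   visited in decreasing $|t|$ (signed ranking is available via
   `rank_signed`; absolute ranking treats down-regulated discriminators
   symmetrically and matches the tie-break metric below).
3. **Candidate extraction.** All genes within two steps of the seed; the
   one-step tier is the seed's neighbours, the two-step tier the nodes at
   distance exactly two.
4. **Pruning.** One-step neighbours are visited once in increasing order
   of in-candidate degree and removed when removal *strictly* increases
   the seed's local clustering coefficient (LCC: realized fraction of
   edges among a node's neighbours, 0 below two neighbours).  Strictness
   keeps markers maximal; the `< 2 neighbours := 0` convention prevents
   pruning to a single neighbour from being trivially optimal; a removal
   that would empty the tier is rejected.  The two-step pass repeats the
   procedure with the same reference value — the seed's clustering
   coefficient — which a two-step removal cannot alter, so in its default
   form (`two_step_rule = "seed"`) the pass removes exactly the nodes
   orphaned by one-step pruning.  Two stricter, non-vacuous
   reinterpretations are available: `"anchor"` re-tests the clustering
   coefficient of the node's one-step anchor, and `"extended"` the density
   of the seed's whole one-plus-two-step neighbourhood.  The anchor
   variant is aggressive by construction — a two-step node is never
   adjacent to the seed, so it always depresses its anchor's clustering
   once the one-step tier is interconnected, and the tier then collapses
   on dense modules — which is why the literal seed reference is the
   default.
5. **Caps.** Tiers are limited to `max_one_step` one-step neighbours and
   `max_two_step` two-step neighbours *per anchor* (both in 1–19,
   defaults 4 and 3, the worked-example settings of the original tool),
   keeping the top nodes by $|t|$ (`filter_method = "tscore"`) or
   in-candidate degree (`"degree"`).
6. **Sub-games.** Enumerating all $2^{|V_s|}$ states of a candidate is
   infeasible (a seed with 4 one-step and 12 two-step neighbours already
   has $2^{16} = 65{,}536$ states), so the game is decomposed into one
   sub-game per retained one-step neighbour (the anchor): seed, anchor,
   and the anchor's adjacent two-step nodes.  A two-step node adjacent to
   several anchors plays in each of their sub-games.  Each sub-game is
   solved exhaustively ($2^{\mathrm{free}}$ states, refused above
   `max_subgame_players = 21` free players); payoffs during deviation
   checks use the sub-game's induced graph.
7. **Selection and merge.** Among a sub-game's equilibria the one with
   the highest mean $|t|$ over its joined genes wins; ties go to the
   larger joined set, then the lexicographically smallest gene tuple, so
   enumeration order never matters.  Pure equilibria need not exist in a
   finite game restricted to pure strategies; in that case the state with
   maximal total payoff is used and flagged (`fallback`) — never
   silently.  Sub-game solutions merge by union (a duplicated player joins
   the marker if it joins anywhere), which preserves every sub-game's
   positive evidence; the merged marker may not be a global equilibrium of
   the undecomposed game.
8. **Ranking.** Every eligible seed is processed, exact-duplicate joined
   sets collapse to the higher-ranked seed, markers are sorted globally by
   score (mean $|t|$ of joined genes) and the top `n_results` (default
   50) are returned.

All tie-breaks anywhere in the pipeline are lexicographic on gene name,
and the algorithm contains no randomness: identical inputs and options
give identical output.

## What the simulator emulates

`simulate_gta_data()` generates the structure the method assumes: an
Erdős–Rényi background graph (default 200 genes, edge probability 0.02,
i.e. mean degree ≈ 4, the sparse small-world regime of PPINs) with a
planted module (default 10 genes) rewired to edge probability 0.6 and
forced connected by a random spanning tree; expression is Gaussian noise
(sd 1) with the planted genes' case mean shifted by 2 — per-gene Welch t
around $2/\sqrt{2/20} \approx 6$ under 20 + 20 samples, a clearly
detectable but not trivial signal.  Defaults were chosen once as a
realistic desk-scale benchmark and are exercised by the acceptance tests:
over 20 replicates the top marker's Jaccard overlap with the planted set
must reach 0.6 in at least 80% of runs.

The simulator deliberately omits several features of real data — no
scale-free degree distribution, no batch effects, no correlated
background expression, no annotation errors between network and chip —
so a passing recovery test shows the pipeline finds a dense
differentially expressed module under its own model assumptions, not that
it will do so on any given cohort.  A `log_normal` switch exponentiates
the matrix to probe robustness to the Gaussian density assumption.

## Problem sizes and costs

The test-suite and acceptance runs use 200-gene networks with 40 samples,
200 random sub-games of up to 10 free players for the brute-force
equilibrium cross-check, and 20 recovery replicates; a full search on such
a network takes a few seconds on one core.  Cost is dominated by
$2^{\mathrm{free}}$ per sub-game: with the default caps a sub-game has at
most 1 anchor + 3 exclusive two-step nodes plus any shared ones, far below
the enumeration cap.

## Known limitations

* Mixed-strategy equilibria are out of scope; the fallback covers games
  with no pure equilibrium.
* The per-anchor decomposition is a heuristic: merged markers are good
  sub-game equilibria but carry no global-equilibrium guarantee.
* Overlapping (non-identical) markers are all reported; only exact
  duplicates are collapsed.
* Expression input is assumed normalized; no normalization is performed.
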