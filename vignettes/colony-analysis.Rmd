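---
title: "Dominance hierarchies and network communities in group-housed colonies: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominance hierarchies and network communities in group-housed colonies: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonynet)
```

colonynet analyses the social structure of a large group of co-housed
animals — the motivating system is a colony of ~30 male laboratory mice
living in four interconnected vivaria — from two raw records: an
*agonistic event log* (one row per interaction: day, winner, loser,
behavior label, location) and a *spatial census log* (one row per sighting
of an individual in a vivarium at a census time point). From these it
derives the dominance hierarchy, the directed dominance network, social
network communities, dyadic association indices, and the spatial
organization of aggression. This vignette describes the statistical
machinery, the conventions chosen where the methods literature leaves
options open, and what the synthetic-colony generator does and does not
emulate.

## Sociomatrices

All analyses start from the frequency win/loss sociomatrix `M` (winners in
rows, losers in columns, structural zero diagonal) built by
`frequency_matrix()`. Two derived matrices feed the downstream stages:

* the **binary dominance matrix** (`binarize()`): `B[i,j] = 1` exactly
  when `i` beat `j` more often than the reverse; following Appleby's rule,
  tied dyads — including dyads that never interacted — get 0 in both
  directions. Every dyad therefore carries at most one directed relation,
  so `B` is structurally antisymmetric; several null models below respect
  this constraint deliberately.
* the **symmetrized interaction matrix** (`symmetrize()`): `M + t(M)`, the
  total interactions per dyad, which is the substrate of community
  detection.

Tied and never-interacted ("unknown") dyads are both *undecided* for
linearity purposes but are counted separately (`dyad_summary()`), because
de Vries' h' accounts for them explicitly.

## Hierarchy statistics

**Directional consistency** is `sum(H - L) / sum(H + L)` over interacting
dyads, with `H`/`L` the larger/smaller directed count per dyad.

**Landau's modified h'** is `12/(N^3 - N) * sum_i (V_i - (N-1)/2)^2`
where `V_i` counts the individuals that `i` dominates. Undecided dyads
are imputed to one side or the other by a fair coin; `h'` is defined as
the expectation of `h` over all such imputations, which the package
evaluates in closed form (`h` with undecided dyads split 0.5/0.5 plus
`12/(N^3 - N) * sum_i u_i / 4`, with `u_i` the number of undecided dyads
involving `i`). The closed form equals the mean over all `2^u`
imputations exactly, so no Monte-Carlo error enters the reported value;
the unit tests verify it against explicit enumeration of the imputations.

**David's scores** use the dyadic win proportions `P[i,j]` (or the
chance-corrected `Dij` variant behind a flag; the raw `Pij` is the
default). **Steepness** is the absolute OLS slope of normalized David's
scores against descending rank.

**Triangle transitivity**: among *complete* triads (all three dyads carry
a relation), `Pt` is the transitive fraction; `t.tri = 4 (Pt - 0.75)`
rescales it so that the random-tournament expectation 0.75 maps to 0 and
full transitivity to 1 (`ttri_scale()`).

**I&SI ranking** seeks the order minimizing, lexicographically, the number
`I` of dyads whose dominance contradicts the order and the summed rank
distances `SI` of those dyads. The search starts from the descending
David's-score order and sweeps over all pairwise swaps *and* all
single-individual insertions, accepting any move that reduces `(I, SI)`;
random restarts guard against local minima. Swap moves alone demonstrably
stall in local minima on small matrices, which is why the insertion moves
are part of the sweep; the test suite requires exact agreement with
exhaustive search over all orderings for N up to 6.

### Randomization tests

Every test reports an add-one Monte-Carlo p-value,
`(1 + #(null >= observed)) / (1 + n_rand)`, which can never be exactly
zero. Seeds are explicit arguments; identical seeds give identical
results, and the RNG state of the caller is always restored.

The common null for DC, h', and steepness re-orients interactions within
dyads by fair coins while holding each dyad's interaction total fixed
("direction flipping"). For h' the randomized matrices keep the observed
tied/unknown structure and only the decided relationships are
re-oriented, with `h'` computed identically on both sides. This keeps the
observed statistic and the null draws exchangeable, which makes the test
calibrated; the alternative of re-imputing the observed matrix inside
every trial and comparing against fully random tournaments shrinks the
per-trial observed value toward its expectation and rejects far too
rarely (we measured a type-I rate of 1% at a nominal 5% on unstructured
colonies).

Triangle transitivity and degree assortativity compare the observed graph
with random *dominance* graphs: the observed number of related dyads is
resampled uniformly over dyads and each relation is oriented by a fair
coin. Unconstrained directed rewiring would produce mutual edges, which a
binarized win/loss matrix can never contain, so those graphs would lie
outside the sample space of the data. A degree-label permutation null is
available for assortativity via `null = "label"`.

The extreme-degree test draws Bernoulli digraphs with the observed size
and density. In such graphs the N out-degrees (and, separately, the N
in-degrees) are independent Binomial(N-1, density) variables, and the
package samples them directly — distributionally identical to generating
the graphs edge by edge and considerably faster. Because the maximum
out-degree and minimum in-degree are coarsely discrete, the attainable
size of any valid Monte-Carlo test jumps below the nominal level; the
test is conservative, never anticonservative, and the calibration suite
asserts exactly that.

## Communities

`girvan_newman()` removes, one at a time, the edge with the highest edge
betweenness (recomputed after every removal), evaluates the weighted
modularity `Q` of the component partition at every step, and returns the
partition with maximal `Q`. Modularity always uses the raw interaction
weights.

For the betweenness step the package treats interaction weights as edge
*lengths* by default. In a dense sociomatrix — where most dyads have
interacted at least once — shortest paths then run along weak ties, which
are exactly the between-community ties, so betweenness concentrates on
them and the removal sequence cuts the graph along community boundaries.
This is also the long-standing behavior of igraph's edge-betweenness
clustering, i.e., of the software this family of analyses has
historically used. The seemingly more intuitive `1/weight` convention
makes strong within-community ties short, disperses shortest paths away
from every candidate cut, and on dense weighted networks routinely
produces no modular partition at all (measured `Q_max = 0` on colonies
with strongly planted structure); it remains available via
`betweenness = "inverse"`, as does plain unweighted betweenness.

Community confidence follows the bootstrap comembership design: events
are resampled with replacement to the original count, detection is re-run
per replicate, and the proportion of replicates in which each pair shares
a community forms the comembership matrix. Individuals with no sampled
interactions in a replicate are isolated and co-assigned with no one.
`consensus_communities()` re-runs detection on the comembership matrix as
a weighted graph and labels an individual `"unassigned"` when its mean
comembership with every detected community's members falls below the
assignment threshold (default 0.5, configurable and reported). The
threshold is this package's operationalization of "could not be placed";
the bootstrap unit is the individual agonistic event.

## Association and space

`hwi_matrix()` computes the half-weight association index per dyad,
`HWI = x / (x + yAB + 0.5 (yA + yB))`, where `x` counts census periods
with both individuals identified in the same vivarium, `yAB` both
identified in different vivaria, and `yA`/`yB` only one identified.
Individuals not sighted in a period contribute to none of the counts; the
half-weight denominator is the standard correction for partial
observability. `mantel_test()` correlates two symmetric matrices over
their upper triangles (Pearson by default, Spearman behind a flag) with
joint row/column permutations of the second matrix and a two-sided
magnitude comparison. `within_between_test()` contrasts the median
within-community and between-community indices under community-label
permutation.

`location_usage()` tabulates aggression given and received per individual
per vivarium; `shannon_evenness()` is `H / ln K` over the `K = 4` vivaria.
The per-individual unevenness test draws uniform multinomials with the
same total and asks how often the null evenness is at most the observed
one; this uniform-multinomial null is this package's operationalization
(the underlying analyses report per-individual unevenness without stating
a method) and is labelled as such in outputs. `nmds()` wraps vegan's
monotone-regression engine (Kruskal stress-1, global model) with a
classical-scaling start plus seeded random restarts, returning the
centered best configuration; `usage_distance()` offers Bray-Curtis
(default, the standard choice for count compositions) and Euclidean
distances.

## The synthetic colony generator

No raw observation data are published for this kind of colony study, so
`simulate_colony()` plants the structure the analyses assume and the test
suite measures how reliably the pipeline recovers it:

* **Hierarchy**: each individual has a latent dominance score; scores are
  evenly spaced with total spread `sigma_d` (default 2 logit units) and
  contests follow a Bradley-Terry-style logistic model with steepness
  `beta` (default 3). These defaults produce steep, near-linear observed
  hierarchies with directional consistency and transitivity in the range
  reported for real colonies of this size, while leaving enough noise
  that recovery is non-trivial.
* **Communities and space**: individuals belong to community A (home
  vivaria 1-2), community B (home 3-4), or a small floater group with no
  home (default sizes 19/8/3 of N = 30). Location fidelity `phi`
  (default 0.9) is the probability a community member is found in its
  home territory. Because agonistic interactions require co-presence, a
  dyad's interaction opportunity is the product of the within-community
  social bias `w` (default 5) and its co-location probability implied by
  `phi`: `phi^2 + (1-phi)^2` within a community, `2 phi (1-phi)` across
  communities, and 1/2 for any dyad involving a floater. Event locations
  follow the conditional territory distribution given co-location. This
  coupling is what makes the planted communities as recoverable as the
  published regime (consensus modularity around 0.2, two communities of
  19 and 8 with the floaters unassigned); an uncoupled flat between-dyad
  rate spreads weak cross-ties over the whole network and defeats
  edge-betweenness detection outright.
* **Censuses**: three time points per day for 19 days; each individual is
  identified with probability `p_sight` (default 0.8, a realistic census
  visibility for mice moving among shelves and nest-boxes — partial
  observability is exactly what the half-weight index corrects for) and
  placed in its home territory with probability `phi`.

`null_colony()` removes all structure (uniform dyads, fair-coin winners,
uniform locations) and is the calibration input for every randomization
test.

What the generator does **not** emulate: temporal hierarchy formation
(ranks are static), behavioral heterogeneity beyond the ethogram labels,
wounding or huddling, within-vivarium zone structure (zones are sampled
uniformly and carried through but not analysed), and overdispersed
per-dyad interaction rates. Passing recovery tests therefore show that
the pipeline's inferences are faithful when the planted model holds, not
that the model captures every feature of real colonies.

## Problem sizes and numerical choices

Function defaults use publication-scale randomization counts (10,000 for
the matrix tests, 1,000 random graphs for transitivity, 1,000 bootstrap
replicates, 20 x 5,000 Bernoulli draws). The shipped test suite uses
deliberately smaller sizes chosen to exercise the same code paths with
tight runtimes: calibration runs 500 unstructured colonies of 12
individuals and 250 events at 99 randomizations per test; recovery runs
20 colonies at the full 30/1230 design with 25 bootstrap replicates. The
calibration check asserts simultaneous binomial bounds across the battery
of tests (Bonferroni-adjusted, so a perfectly calibrated suite does not
fail by multiplicity), two-sided for the continuous statistics and
upper-bounded for the discrete extreme-degree statistics.

Other numerical conventions: closeness assigns unreachable targets a
distance of N (so closeness centralization is normalized against a
directed star under the identical convention), while average path length
substitutes the maximum finite geodesic — the two conventions differ on
purpose, matching the definitions the corresponding network toolchains
document. Hub scores come from power iteration on `A %*% t(A)` scaled to
a maximum of 1 (cross-network comparability), with a relative tolerance
of 1e-12. Betweenness ties during edge removal break at the lowest
(row, column) roster index in the R removal loop, making results
deterministic for a fixed roster order. All matrices carry the roster in
their dimnames, and roster order is lexicographic unless supplied
explicitly, so permuting input rows never silently changes meaning.

## Limitations

* The Girvan-Newman removal sequence only visits partitions that arise as
  connected components, so the reported `Q_max` is a lower bound on the
  global modularity optimum in general; the test suite verifies equality
  on small fixtures by exhaustive partition enumeration.
* The h' significance procedure, the unevenness null, and the consensus
  assignment threshold are documented operationalizations of
  under-specified published procedures; all three are flagged in outputs
  and configurable where sensible.
* Spearman correlation tables use the asymptotic p approximation
  (`exact = FALSE`), appropriate for the tied, discrete metrics involved.
* The generator's parameter-recovery guarantees are median statements
  over seeds at the default design; single seeds can fall below the
  stated recovery levels.
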