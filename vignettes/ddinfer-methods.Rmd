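---
title: "Parsimony inference of domain-domain interactions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsimony inference of domain-domain interactions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The inference problem

A protein interaction is usually realized physically by the binding of
one structural domain from each partner. Domain recognition is far more
conserved than the interactions themselves, so a catalogue of
domain-domain interactions (DDIs) is more transferable knowledge than
any single interactome — and much harder to measure. `ddinfer` infers
DDIs computationally, from two inputs: an undirected PPI network
`I = (P, E)` and a table assigning each protein its set of domains.

The guiding assumption is parsimony: biological interaction capability
evolves by reusing a small repertoire of recognition patterns, so the
preferred explanation of an interactome is the smallest set of domain
pairs that accounts for every observed interaction. Candidate pairs for
an edge `(P_m, P_n)` are all unordered domain pairs with one member in
each endpoint's composition (both orientations; homodomain pairs
`(A, A)` are legal). The union over edges is the candidate set `D`,
tracked with full support maps by `buildCandidatePairs()`.

## Three cover models

All three models are binary covers over indicator variables `d_ij`
(pair selected) and, where slack is allowed, `e_mn` (edge left
unexplained):

* **PE** (pure parsimony explanation): minimize `sum(d_ij)` subject to
  `sum(d_ij over the edge) >= 1` for every edge. No slack.
* **ILP**: PE plus per-edge slack `e_mn` and the budget
  `sum(e_mn) <= (1 - sd)|E|`. The tuning parameter `sd` is the fraction
  of interactions that must be explained; the rest may be dropped,
  absorbing false-positive edges.
* **WILP**: ILP with objective `sum(w_ij d_ij)`, the weights described
  below.

In practice the integer programs are relaxed: `d_ij, e_mn` take values
in `[0, 1]` (`buildLP()`), and the relaxation is solved exactly
(`solveLP()`). Because the solver is a simplex method it returns vertex
solutions, and on realistic instances these are almost always integral;
the package never hides the exception — `nFractional()` reports the
number of variables strictly inside `(1e-6, 1 - 1e-6)` on every solve.
`roundPredictions()` thresholds at 0.5 by default (values equal to the
threshold are included); for an integral solution any threshold in
(0, 1) selects the same pairs.

### Numerical choices

* The LP engine is a dense bounded-variable two-phase primal simplex
  written for this package (`src/simplex.cpp`). A vertex-returning
  method is a requirement of the approach, not an optimization detail:
  interior-point solvers return interior optima, which would report
  heavily fractional solutions even when integral optima exist and
  would break the rounding step. The engine uses Dantzig pricing with a
  Bland-rule fallback after a run of degenerate pivots, pivot tolerance
  `1e-9`, optimality tolerance `1e-8`, and handles the `[0, 1]` bounds
  implicitly (no constraint inflation).
* Variable and constraint ordering is deterministic (candidate pairs
  sorted lexicographically, edges in canonical order), so repeated
  solves of one instance give identical vertices, including
  tie-breaking among alternative optima.
* The budget right-hand side `(1 - sd)|E|` is kept real-valued, per LP
  semantics; it is not floored. With fractional budgets the relaxation
  can spread slack across more edges than the integer model could drop
  whole — one reason relaxation optima can fall below integer optima on
  small instances (see *Testing strategy*).

### What the relaxation can and cannot promise

Set-cover relaxations have genuine integrality gaps: already three
edges with candidate sets `{x,y}, {y,z}, {x,z}` admit the fractional
cover `x = y = z = 1/2` of weight 1.5 while every integer cover costs
2. Such configurations need dense domain sharing and are rare in
realistic data, where the candidate-to-constraint ratio is close to 1.5
(about 1.5 candidate pairs per edge). The package treats integrality as
a diagnosed property, never an assumption.

## Weights from the global network conformation

Real PPI networks combine three global regularities: a large
Watts-Strogatz clustering coefficient, heavy-tailed degrees, and
disassortative mixing (hubs attach to low-degree proteins). The local
clustering of a vertex is triangles over centered triples, with the
degree < 2 case defined as 0 (`localClustering()`); the network value
is the plain average over all vertices (`globalClustering()`). Because
low-degree vertices have small denominators, the network's clustering
is dominated by triangles through low-degree ("poor") proteins —
biologically, small tight complexes. Interactions closing such
triangles are therefore the most trustworthy, and their candidate pairs
deserve priority in the cover.

`degreeBinning()` splits `[d_min, d_max]` into `K` equal-width
subintervals; a degree-`d` node gets bin
`min(K, floor((d - d_min)/width) + 1)`. Equal width is the simplest
partition that makes bin 1 the low-degree class and bin `K` the hubs;
when all degrees are equal every node goes to bin 1, the priority set
becomes triangle-driven only, and with `K = 1` all discounts vanish so
the weighted model coincides with the unweighted one — a safe
degenerate default.

The priority set `S` contains the candidate pairs of every observed
interaction `(P_m, P_n)` whose endpoints share a poor (bin 1) neighbor;
those pairs get weight `1/(1 + |s - t|)` with `s, t` the endpoint bins,
and a pair spanning several such interactions takes the smallest value
(`computeWeights()`). Three deliberate readings, flagged here because
the construction leaves them open:

* `S` requires the closing interaction `(P_m, P_n)` to be an observed
  edge — otherwise its pairs are not in `D` at all. Only
  neighbor-neighbor interactions are discounted, not the two wedge
  edges incident to the poor node itself.
* With `s = t` the weight is `1/(1+0) = 1`: the pair is recorded as a
  member of `S` but carries no discount. Assortative triangles
  contribute membership, not priority.
* The discount scale is set by `K`. At the scale of real interactomes
  (hub degrees in the hundreds) `K = 50` gives discounts down to 1/50
  on hub-poor triangles. On desk-scale networks (hundreds of proteins,
  maximum degree a few tens) large `K` makes bin 1 collapse to the
  degree-1 nodes, which have no wedges, leaving `S` empty; `K` between
  5 and 10 is the workable desk-scale analogue. Consequently the
  *magnitude* of desk-scale discounts (at best 1/2 to ~1/10, typically
  averaging near 0.5 over `S`) is structurally weaker than at full
  scale — a limitation discussed under *Known limitations*.

## The PE scoring machinery

For the pure cover model the package implements the reliability-based
scores. `lpScore()` keeps each cover constraint independently with
probability `r` and averages each pair's LP value over `nRuns`
constraint subsamples (deterministic at `r = 1`). `empiricalPValues()`
ranks the observed LP-score of each pair against the same score on an
ensemble of degree-preserving rewirings of the network with
compositions held fixed; the p-value is the fraction of reference
networks scoring at least as high, with pairs absent from a reference
candidate set contributing 0. The reference model is a choice — the
randomization is specified only as "random networks" in the tradition
this follows — and degree-preserving rewiring is the conservative
option, holding both the composition table and the degree sequence
fixed. `pwScore()` caps the p-value with the witness term
`(1 - r)^w(i,j)`, where a witness is an interacting pair of
single-domain proteins carrying exactly the two domains
(`countWitnesses()`): the probability that all direct single-domain
evidence is simultaneously false positive. `(1 - r)^0 = 1`, so
unwitnessed pairs keep their randomization p-value.

## Randomization tests

`parsimonyRandomizationTest()` asks whether the data are organized
parsimoniously at all. `T0` is the PE optimum on the observed data; `T`
is the same statistic after destroying the organization while keeping
the marginals: either permuting the global multiset of domain
assignments across protein slots (per-protein domain counts and the
global domain multiset conserved; permutations placing two copies of
one domain in a protein are redrawn), or rewiring the edges with the
degree sequence conserved (double-edge swaps, rejecting loops and
multi-edges, ten attempted swaps per edge by default). If the observed
interactome reuses few recognition patterns, `T0` falls far below the
null, so significance is the Gaussian lower tail of `T0` against the
`T` samples. Gaussian p-values everywhere use the sample mean and the
`n - 1` standard deviation, are one-sided with the direction stored
explicitly, and are flagged undefined (`NA`) when the null samples are
constant.

`randomWeightTest()` asks whether the triangle/binning weights carry
signal beyond their count: the weighted model is solved once with the
true weights and repeatedly with null weights — a uniformly chosen
subset of candidate pairs of size `|S|` receives i.i.d. `U(0, 0.5)`
weights, all others weight 1 ("the same number of weighted pairs as the
true model"; the subset is re-drawn each run). The statistic is TP, the
number of predictions confirmed by a gold-standard pair set, compared
by upper-tail Gaussian p-value.

## The synthetic-data generator

Real DDI inference can only be benchmarked against sparse structural
gold standards; the generator instead plants the truth.
`syntheticSpec()` fixes the study conditions; `generateSyntheticData()`
draws, in order: skewed domain usage (frequency proportional to
`rank^-0.8`, creating promiscuous domains and thereby hubs, without an
explicit preferential-attachment mechanism); per-protein domain counts
`1 + Geometric` with mean `domainsPerProtein`; a planted DDI set drawn
uniformly over all domain pairs (homodomain included) at density
`plantedDDIDensity`; base edges as all protein pairs sharing a planted
pair, subsampled to `meanDegree * nProteins / 2` edges; removal of
`fnRate` of them; addition of `fpRate` spurious edges explainable by no
planted pair; and finally triangle enrichment — each open wedge
centered on a poor (bin 1 of 5) protein is closed with probability
`triangleBoost`, and when no planted pair explains the closing edge,
one domain pair from its endpoints is planted. The last rule mirrors
complex biology (co-members of a complex both interact and carry
mutually recognizing domains) and is what makes enriched triangles
*true* triangles; without it a uniformly planted DDI set is essentially
triangle-free at the domain level and wedges almost never close
consistently.

Defaults — 200 proteins, 60 domains, mean degree 5 (about 500
interactions), 1.5 domains per protein, density 0.02, 10% edge noise
each way, boost 0.1 — are the desk-scale conditions used throughout the
test suite; every LP at this size solves in well under a second, and
the randomization tests at 50 shuffles run in seconds to a few tens of
seconds.

For studies of the weighted model the suite uses a triangle-enriched
condition: 150 domains, density 0.018, boost 0.3. These values were
calibrated against the structural anchors of real interactome data —
about 1.5 candidate pairs per constraint and a pure-cover optimum that
is a substantial fraction of the edge count — rather than to any test
outcome; at 60 domains a 200-protein instance is far *more*
parsimonious than real data (a handful of promiscuous pairs can cover
hundreds of edges), which makes prediction counts degenerate.

What the generator does **not** emulate: the exact degree distribution
of any real interactome, the frequency spectrum of real domain families,
correlated false positives (noise here is uniform), or domain
co-occurrence within proteins. Passing tests on this generator show the
machinery is correct and the directional claims hold under the stated
mechanisms; they do not certify performance numbers on real data.

## Testing strategy

* Exhaustive oracles: clustering coefficients are checked against
  brute-force triangle enumeration on all small random graphs; cover
  optima are checked against exhaustive search over every pair subset
  and dropped-edge budget on instances with at most 15 candidate pairs
  and 12 edges, generated in the sparse-sharing regime (about 1.5
  candidates per edge) of realistic data.
* For the cover oracle the assertions are: the relaxation never exceeds
  the exhaustive integer optimum, and whenever the simplex vertex is
  integral — the large majority of instances — the two agree exactly.
  Unconditional equality would be mathematically wrong: both odd-cycle
  candidate structures and fractional slack under a budget produce
  genuine gaps on small instances.
* Conservation properties (degree sequences under rewiring, domain
  multisets under shuffling, unit-weight WILP equal to ILP, fold change
  of the all-candidates predictor exactly 1) are asserted across seeds.
* Directional claims are tested at the desk scale stated above:
  planted-structure data must give `mean(T) > T0` at `p < 0.01` under
  both shuffles; pure-noise data must show no false parsimony signal
  (lower-tail p above 0.005); spurious edges must not increase
  sensitivity; triangle enrichment must raise the clustering
  coefficient.

## Known limitations

* The desk-scale weight regime is structurally weaker than the real
  one. True discounts `1/(1 + |s - t|)` average about 0.5 over `S` on
  200-protein networks, while the random-weight null draws from
  `U(0, 0.5)` (mean 0.25): at this scale the null weights are *cheaper*
  than the true ones, so null runs predict several-fold more pairs and
  can accumulate more gold hits on volume alone even when the
  true-weight predictions are far more precise. At full interactome
  scale the relation inverts (true discounts reach 1/50). The
  TP-versus-random-weights comparison is therefore meaningful at real
  scale but biased against the true weights on small synthetic
  networks; the suite runs it at the stated conditions and the
  weighted-versus-unweighted sensitivity comparison alongside it.
* Degree-preserving rewiring is a Markov chain, not an exact uniform
  sampler; at ten swaps per edge residual correlation with the seed
  network is possible. An observed network can also sit atypically
  within its own degree-sequence ensemble by chance, producing
  upper-tail deviations of `T0` that have nothing to do with parsimony.
* The composition shuffle redraws whole permutations until no protein
  holds a duplicate domain; for pathological compositions (one domain
  dominating the token pool) this rejection loop could in principle
  exhaust its retry budget, which is reported as an error rather than
  silently accepting a multiset.
* Equal-width degree binning is sensitive to a single extreme hub,
  which can empty the middle bins; quantile binning would be an
  alternative but would break the "bin 1 = smallest degrees" reading
  that the priority construction relies on.
* Identifiers are opaque case-sensitive strings; canonical pair order
  is byte-wise, so mixed-locale identifier sets sort by the session's
  collation.
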