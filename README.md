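# ddinfer

Parsimony inference of domain–domain interactions (DDIs) from
protein–protein interaction (PPI) networks.

## The problem

Most protein interactions are mediated by the physical recognition of a
pair of structural domains, but direct experimental evidence for
domain-level contacts is scarce. Given an observed PPI network
`I = (P, E)` and the domain composition of each protein, `ddinfer`
recovers a minimal set of domain pairs that explains the observed
interactions — the parsimony principle: every interaction must be
accounted for by at least one candidate domain pair, using as few (or as
little total weight of) domain pairs as possible.

With `D` the set of candidate pairs (all domain pairs `(D_i, D_j)` with
`D_i` in one endpoint and `D_j` in the other of some edge), the
weighted cover model is

```
min   Σ_{(i,j) ∈ D}  w_ij d_ij
s.t.  Σ_{(i,j) ∈ (P_m, P_n)}  d_ij  +  e_mn  ≥ 1     for every (P_m, P_n) ∈ E
      Σ_{(P_m, P_n) ∈ E}  e_mn  ≤  (1 − sd) |E|
      d_ij, e_mn ∈ [0, 1]
```

The slack variables `e_mn` let a fraction `1 − sd` of the interactions
go unexplained (experimental PPI data carry many false positives); with
unit weights this is the unweighted model (ILP), with `sd = 1` and no
slack it reduces to the pure parsimony-explanation cover (PE). The
programs are solved by LP relaxation with a built-in bounded-variable
primal simplex, so optima are vertex solutions — almost always integral
on realistic instances (the fractional count is always reported).

The weights carry global network information. Real PPI networks have a
far larger Watts–Strogatz clustering coefficient than matched random
graphs, and the excess triangles run through low-degree ("poor")
proteins. Interactions that close a triangle through a poor protein are
therefore prioritized: with degrees binned into `K` equal subintervals,
such an interaction's candidate pairs get weight `w_ij = 1 / (1 + |s − t|)`
where `s, t` are the degree bins of its endpoints — strongest discounts
for disassortative (hub–poor) interactions — and every other pair keeps
weight 1.

The package also provides the surrounding machinery: reliability-sampled
LP-scores, witness counts and pw-scores for the PE model; shuffle-based
randomization tests of the parsimony assumption and a random-weight test
of the weight signal (Gaussian-tail p-values); Erdős–Rényi `G(n,m)` and
degree-preserving null ensembles for the clustering coefficient;
sensitivity / fold-change evaluation against a gold standard with an
`sd` sweep; and a synthetic-data generator with planted DDIs so the
whole pipeline is testable offline.

## Worked example

```r
library(ddinfer)

ds  <- generateSyntheticData(syntheticSpec(seed = 1))   # planted DDIs
net <- harmonize(ds@network, ds@composition)
net
#> PPINetwork with 200 proteins and 506 edges

cand <- buildCandidatePairs(net, ds@composition)
cand
#> CandidateDDISet with 388 candidate pairs over 506 edges

w   <- computeWeights(net, ds@composition, cand, K = 5)
w
#> WeightMap over 388 candidate pairs; |S| = 52
sol <- solveLP(buildLP(cand, net, sd = 0.9, weights = w))
sol
#> ParsimonySolution (optimal): objective 24.95, 388 pair variables, 2 fractional

evaluatePredictions(roundPredictions(sol), ds@planted, cand)
#> EvaluationResult: 34 predictions, 27 true positives (gold in D: 40, |D|: 388)
#>   sensitivity 67.50%, fold change 7.70
```

34 domain pairs explain 90% of the 506 interactions; 27 of them are
planted ("gold") pairs, a 7.7-fold enrichment over the gold density of
the candidate set. The clustering signal that motivates the weights:

```r
clusteringNullDistribution("er", net, nSamples = 100, seed = 2)
#> NullDistribution: 100 samples, mean 0.02363, sd 0.00619639, median 0.0228561
#>   observed 0.0646867, upper-tail p-value 1.726e-11
```

The same operations are scriptable through the bundled CLI
(`inst/scripts/ddinfer`):

```sh
ddinfer simulate --out data --seed 1
ddinfer infer --ppi data/ppi.tsv --domains data/domains.tsv \
    --model wilp --sd 0.9 --K 5 --out predictions.tsv
ddinfer evaluate --pred predictions.tsv --gold data/gold.tsv
```

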