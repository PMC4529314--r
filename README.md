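# ccmspace

Exhaustive genotype–phenotype mapping of metabolic reaction-network spaces.

## The problem

A metabolic *genotype* is a presence/absence pattern over a fixed universe of
N candidate internal reactions — a binary vector, one point in a genotype
space of 2^N possible metabolisms. Its *phenotype* is the vector of
viabilities across a panel of minimal environments, each containing a single
sole carbon source plus shared nutrients. A metabolism is viable in an
environment when flux balance analysis (FBA),

```
v* = max { c'v : S v = 0,  a <= v <= b },
```

predicts a biomass synthesis rate exceeding 1% of the rate of the full
network (all N reactions present) in that environment. The structure of this
genotype–phenotype map — how many viable metabolisms exist per size n, whether
same-phenotype metabolisms form connected *genotype networks* under single
reaction swaps, how far those networks extend (diameter, bounded by
min(n, N−n)), which novel phenotypes are reachable within one reaction change,
and how close the networks of different phenotypes sit (minimal swap distance
D_min) — determines how readily metabolism can evolve new carbon-utilisation
abilities while conserving existing ones.

`ccmspace` is an R implementation of that entire analysis for people studying
genotype-space organisation in constraint-based metabolic models:

* **model_io** — a tabular model dialect (TSV) for reaction universes with an
  internal/transport partition, biomass precursors and co-factor pairs;
  environment panels as TSV.
* **fba_core** — viability by FBA (GLPK), phenotype vectors, essentiality,
  flux-variability blocked reactions, topologically disconnected reactions,
  and minimal viable networks (n_min) by mixed-integer programming with a
  direct-FBA-verified witness.
* **enumeration** — all viable genotypes per criterion (`at_least`,
  `exclusively`) by brute force or by essentiality pre-fixing plus
  divide-and-merge with monotone pruning (subsets of inviable metabolisms are
  inviable), provably identical to brute force.
* **genonet** — swap-neighbour graphs via an (n−1)-subset index, streaming
  BFS components, giant-component fraction r_G, exact and sampled diameters,
  co-factor and blocked-reaction controls for maximally distant pairs.
* **neighborhood** — novel phenotypes in 1-neighbourhoods and the uniqueness
  statistic u = 1 − |P1 ∩ P2| / |P1 ∪ P2| with randomisation nulls.
* **distances** — minimal inter-network distances, phenotypic-complexity
  aggregation, genotype-vs-phenotype distance distributions.
* **synthetic_data** — layered pathway universes with an exact reachability
  oracle, so every stage is testable against analytic ground truth.

The package ships a plain-text reconstruction of the *E. coli* central carbon
metabolism universe (51 variable internal reactions, 20 fixed transporters,
10 carbon sources, biomass over 13 precursors, 3 co-factor pairs), derived
from the published E. coli core model (`inst/extdata/`, see the file header
and the methods vignette).

## Worked example

```r
library(ccmspace)

fx <- ccm_fixture()                       # packaged CCM universe + 10 environments
u <- fx$universe; panel <- fx$panel

universe_N(u)                             # 51 variable internal reactions
ess <- essential_reactions(u, panel)
u$reaction_ids[u$internal_idx][ess]
#> [1] "ENO"  "GAPD" "GLNS" "PGK"  "PGM"  "RPI"

minimal_viable_size(u, list(panel$glucose))$n_min
#> [1] 23
minimal_viable_size(u, panel)$n_min       # viable on all ten carbon sources
#> [1] 34

phenotype(u, full_genotype(u), panel)     # the full network grows everywhere
#> [1] 1 1 1 1 1 1 1 1 1 1
```

Six reactions (enolase, GAPDH, glutamine synthetase, phosphoglycerate
kinase/mutase, Rpi) are essential on every carbon source, so every viable
metabolism contains them; the smallest viable metabolism has 23 reactions on
glucose and 34 when viability on all ten carbon sources is demanded at once.

On a generated toy universe the whole pipeline runs in seconds:

```r
toy <- make_layered_universe(n_sources = 1, layers = 2, alternatives = c(2, 1))
gs  <- enumerate_divide_merge(toy$universe, toy$panel, at_least("env_C1"))
size_histogram(gs)[3:5, ]
#>   n count  fraction
#> 3 2     1 0.1666667
#> 4 3     3 0.7500000
#> 5 4     1 1.0000000
connected_components(filter_size(gs, 3))$n_components
#> [1] 1
```

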