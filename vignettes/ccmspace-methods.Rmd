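---
title: "Methods: viability phenotyping and genotype-network analysis of reaction-network spaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: viability phenotyping and genotype-network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A reaction universe fixes N candidate internal reactions, a set of
always-present transport reactions, exchange reactions that interface with
the environment, and one biomass reaction. A genotype is a binary vector over
the internal reactions; a metabolism is the sub-network it selects. Viability
in an environment is decided by flux balance analysis: maximise the biomass
flux subject to steady-state mass balance `S v = 0` and flux bounds
`a <= v <= b`, with the fluxes of absent internal reactions fixed to zero and
exchange uptake opened only for the environment's nutrients. The assumptions
are the standard FBA ones — steady state, no kinetic or regulatory
constraints, a fixed biomass composition — and viability is deliberately
qualitative: a genotype is viable when its optimum exceeds a fixed fraction
(default 0.01) of the optimum of the all-ones genotype in the same
environment. Regulatory fine-tuning, thermodynamic constraints and
gene–protein–reaction mappings are out of scope.

Because widening bounds can only enlarge an LP's feasible region, the biomass
optimum is monotone under reaction addition. Two consequences carry the whole
enumeration design: supersets of viable genotypes are viable, and subsets of
inviable genotypes are inviable.

## Tunable parameters

* `threshold_fraction` (dimensionless, default 0.01): viability cut-off as a
  fraction of the all-ones reference rate, recomputed per (universe,
  environment) and cached.
* Uptake bounds (flux units, mmol/gDW/h by convention): 10 for the carbon
  source and for each open shared nutrient, secretion capped at 1000. The
  reference literature for this model family states that maximal uptake rates
  exist but not their values; 10 is the conventional carbon-limited setting
  for the core model, and because viability is measured relative to the full
  network in the *same* environment, the qualitative map is insensitive to
  the exact magnitude.
* `eps` (default 1e-6): flux-zero tolerance for the flux-variability scan
  behind `blocked_reactions()`.
* `blocks` (default 2 at toy scale; 5 blocks of 9 over 45 free bits is the
  full-scale configuration): divide-and-merge partition of the free bit
  positions, contiguous in bit order. The merge proceeds pairwise left to
  right; the result is provably order-independent because pruning is exact.

## The packaged central-carbon-metabolism universe

The fixture `inst/extdata/ccm_universe_reconstructed.tsv` is derived from the
published E. coli core model: the ethanol branch (alcohol dehydrogenase,
ethanol transport and exchange) is removed, aconitase A and B are merged into
a single citrate–isocitrate reaction, and the ATP maintenance reaction's
fixed lower bound is relaxed to zero so that it participates as an ordinary
variable reaction — the ATPase isoform of the ATPase/ATP-synthase co-factor
pair. This yields exactly 51 variable internal reactions and 20 fixed
transporters. The biomass reaction is the core model's, over the 13 classical
precursors (note one idiosyncrasy: the core biomass *nets* alpha-ketoglutarate
as a by-product because glutamate synthesis is folded into its
stoichiometry; the package therefore validates that precursors appear in the
biomass column rather than demanding a negative sign for every one of them).
The ten minimal environments are acetate, alpha-ketoglutarate, fumarate,
fructose, glucose, glutamate, lactate, malate, pyruvate and succinate, each
with oxygen, ammonium, phosphate, water and protons shared.

Reconstruction checks, all recomputed by the test suite and
`scripts/acceptance.R`: six reactions are essential on every carbon source;
the minimal viable network has 23 reactions on glucose and on fructose, 30 on
acetate, and 34 when viability on all ten sources is required at once; the
full network is viable everywhere and contains no disconnected reaction in
any environment.

## Enumeration

`enumerate_bruteforce()` phenotypes all 2^N genotypes (guarded to N <= 20)
and is the oracle. `enumerate_divide_merge()` implements the scalable path:

1. reactions whose single deletion from the all-ones genotype abolishes
   viability on a required source are pre-fixed to one (at full scale this
   removes 6 of 51 bits, reducing 2^51 tests to 2^45);
2. the remaining free positions are split into contiguous blocks; each block
   pattern is tested with every unresolved free bit set to one — if that
   most-permissive completion is inviable, monotonicity kills the entire
   sub-cube;
3. surviving patterns are merged block-pair-wise with the same permissive
   test until fully resolved. The last stage tests complete genotypes, so the
   member set equals brute force exactly; the suite asserts this identity
   over twenty seeded universes and block counts 2–5.

`exclusively(S)` criteria are enumerated as `at_least(S)` followed by an
inviability filter on the complement, because inviability is not monotone
under deletion and cannot prune.

## Genotype networks

Members are stored as bitmasks (32-bit words at desk scale, N <= 30; the
algorithms are word-size agnostic). Two same-size genotypes are neighbours
when one reaction swap converts them — Hamming distance two, i.e. they share
an (n−1)-subset. An index keyed by each member's (n−1)-subsets answers
neighbour queries in O(n) lookups, so connected components cost roughly mV
comparisons rather than V^2 and the adjacency list is never materialised.
BFS order is deterministic (sorted members, sorted frontiers), making
component labels reproducible. Diameters are exact all-pairs maxima up to
1e5 members and seeded without-replacement sampled lower bounds beyond; for
fragmented sets the giant component is used. The connectivity-inheritance
shortcut declares size n+1 connected when size n is connected and every
size-(n+1) member covers some size-n member; the precondition is checked and
a failed check falls back to BFS.

## Neighbourhood diversity and nulls

The neighbourhood of a metabolism is the set of genotypes differing in
exactly one reaction (one addition or one deletion). Whether swaps should
also count is genuinely open; the package defaults to Hamming-1 and records
the mode, since swap neighbours are reachable through two Hamming-1 steps and
the qualitative statistics agree. A neighbourhood phenotype is novel when it
gains at least one carbon source over the focal phenotype. For two
neighbourhoods, `u = 1 − |P1 ∩ P2| / (|P1| + |P2| − |P1 ∩ P2|)`; pairs with
both novel sets empty are 0/0, excluded from means and counted. The
randomisation null is not prescribed anywhere in detail, so the package makes
a size-matched choice and documents it in the output: surrogate neighbourhood
phenotypes are resampled uniformly from the empirical phenotype distribution
of all same-size viable genotypes, keeping the neighbourhood size fixed, and
the empirical p is the upper-tail frequency.

## Distances between genotype networks

`min_network_distance()` returns
`D_min = min { D(G1, G2) : G1 in GN1, G2 in GN2 }`; identity is checked
first, adjacency (D_min = 1) through the subset index, and only then the
exact cross-pair minimum. Small sets (< 1e4 members) use all components by
default — cheap and unambiguous — while larger fragmented sets restrict to
giant components, the reported convention at full scale.
`genotype_vs_phenotype()` strata pool unordered pairs; phenotype distance is
the Hamming distance of the panel-length viability vectors.

## The synthetic generator

`make_layered_universe()` emulates exactly the features the pipeline needs to
be checked against: per carbon source a chain of `layers` 1:1 irreversible
conversions into the precursor sink, optional two-step detours per segment
(alternative routes), optional nesting (source s feeds source s−1's chain,
creating a carbon-source implication), and a unit biomass over the
precursors. On such unit-stoichiometry irreversible DAGs, FBA viability at
any threshold fraction below one coincides with graph reachability of all
precursors from the supplied nutrients, so `reachability_oracle()` provides
exact ground truth independent of the LP stack; closed-form n_min values come
with the generator. What these toys do *not* emulate — and therefore what
passing tests do not establish for real data — are fractional and
many-to-many stoichiometry, co-factor cycling, reversibility, and internal
loops; those paths are exercised by `make_random_massbalanced()` (structural
stress tests with conserved integer pseudo-masses) and by the CCM fixture
itself. The test-suite problem sizes are N <= 14 for enumeration sweeps and
2^N <= 4096 full genotype–oracle comparisons, chosen so the whole suite runs
in well under a minute while covering all code paths; the fixture MILPs run
in seconds.

## Numerical choices

* All LP/MILP solves go through GLPK; the FBA batch solver keeps the
  factorised basis between genotypes, restarting from a standard basis on any
  non-optimal return. An infeasible LP reports biomass 0 (inviable), never an
  exception.
* Only the optimal *value* is used, so degeneracy and alternative optima are
  irrelevant; no tie-breaking is needed.
* The minimal-network MILP uses one flux copy per required environment,
  shared presence binaries with big-M coupling (M = the largest bound
  magnitude, 1000), a biomass floor of `threshold * reference + 1e-6` (the
  strict inequality margin), a greedy-deletion upper bound and pre-fixed
  essential reactions (both only prune), and zero MIP gap. GLPK's default
  integrality tolerance (1e-5) is unsafe under big-M coupling — a "zero"
  binary of order 1e-5 can leak 1000 × 1e-5 = 0.01 units of flux, enough to
  clear a 1% biomass floor — so the wrapper tightens it to 1e-9 and
  `minimal_viable_size()` additionally verifies its witness by direct FBA in
  every required environment, failing loudly rather than returning an
  unverified optimum.
* Degenerate inputs: empty genotype sets propagate as empty results with NA
  summaries; an all-ones genotype inviable under a criterion short-circuits
  enumeration to the empty set; D larger than a set's diameter yields an
  empty sample with a warning.

## Design choices on open questions

* **Disconnection test**: the two-clause definition — (i) products feed
  neither biomass nor any other present reaction, (ii) some substrate is
  neither produced nor environment-supplied — is applied in a single pass per
  reaction, exactly as worded; a fixed-point variant (a reaction can become
  disconnected after removing another) would be stricter and is deliberately
  not the default. Exchange pseudo-reactions count neither as producers nor
  consumers (otherwise an always-open secretion column would "connect" any
  dead-end product); metabolites importable through open exchanges are the
  environment nutrients. The focal reaction is read in its written direction;
  other reversible reactions count on both sides.
* **Blocked reactions** are scanned by feasibility-only flux variability (no
  biomass requirement), because blockedness is a purely stoichiometric
  notion; a biomass-floor variant is available by argument. A genuinely
  cyclic isolated pair of irreversible reactions (A→B, B→A) is *not* blocked
  under FVA — the cycle can carry circulating flux — so the suite's
  no-net-exchange example uses an isolated chain instead.
* **Sampling** (diameter, pair sampling, focal genotypes) is seeded and
  without replacement wherever the population permits; with-replacement
  kicks in only when more pairs are requested than exist.
* **Interface**: this is an analysis package; its interface is the exported
  API, `run_pipeline()` for the end-to-end flow with TSV/JSON artifacts and a
  config-hashed manifest, and `scripts/acceptance.R` for the headline
  numbers. No shell subcommand wrapper is shipped.

## Desk scale versus full scale

Everything in the test suite and the acceptance script runs at desk scale:
generated universes with N <= 14 plus fixture computations (essentiality
scans, MILPs) on the 51-reaction universe. The architecture supports the
full-scale run — 2^45 phenotype tests after essentiality pre-fixing, streamed
genotype sets, sampled diameters — but that computation is far outside a test
budget and is not performed here. For orientation, the reference figures for
the full-scale enumeration of this universe, which this package does **not**
recompute and the acceptance report does not contain, are on the order of
1.5 × 10^9 glucose-viable and 1.1 × 10^7 acetate-viable metabolisms, about
1.0 × 10^6 metabolisms viable on all ten sources, disconnected-reaction
fractions f_d around 0.3–0.5 depending on the source, and 84 of the 1024
possible phenotypes realized. Desk-scale acceptance instead pins the
machinery by exactness properties (enumeration identity, oracle equivalence,
monotonicity, graph-algorithm agreement) and by the fixture anchors (6
essential reactions; n_min 23/23/30/34; forbidden-phenotype count 256 per
implication on a 10-environment panel; genotype-space size 2^51; maximal
diameters min(n, N−n)).

## Known limitations

* Bitmask genotype sets cap enumeration at N <= 30 per word; the full 51-bit
  universe is handled for per-genotype operations (FBA, essentiality, MILP,
  distances on explicit pairs) but not for in-memory exhaustive enumeration.
* FBA viability inherits the usual blind spots: no regulation, no kinetics,
  no thermodynamic loop elimination (thermodynamically infeasible cycles can
  carry flux in variability scans).
* The disconnection and blocked-reaction diagnostics depend on the written
  reaction direction for the focal reaction; models with inconsistently
  oriented reversible reactions should be normalised first.
* The randomisation null is one defensible choice among several; conclusions
  that depend on the null's fine structure should vary it.
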