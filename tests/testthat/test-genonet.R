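# igraph (Suggests) provides the independent graph oracle
igraph_components <- function(masks) {
  d <- outer(masks, masks, function(a, b)
    ccmspace:::.popcount_cpp(bitwXor(a, b)))
  adj <- d == 2
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)
}

size3_set <- function() {
  toy <- toy_a()
  gs <- enumerate_bruteforce(toy$universe, toy$panel, at_least("env_C1"))
  list(toy = toy, gs3 = filter_size(gs, 3), gs = gs)
}

test_that("swap distance is half the Hamming distance", {
  expect_equal(genotype_distance(c(1, 1, 1, 0), c(1, 1, 0, 1)), 1)
  g <- rbinom(20, 1, 0.5)
  expect_equal(genotype_distance(g, g), 0)
  # size-30 pair sharing 24 reactions in a 51-universe: distance 6
  g1 <- c(rep(1, 30), rep(0, 21))
  g2 <- c(rep(1, 24), rep(0, 6), rep(1, 6), rep(0, 15))
  expect_equal(genotype_distance(g1, g2), 6)
  expect_error(genotype_distance(c(1, 0), c(1, 1)), "differ in size")
})

test_that("swap distance satisfies the metric axioms on random masks", {
  set.seed(33)
  N <- 12
  masks <- sample(0:(2^N - 1), 30)
  pc <- function(a, b) ccmspace:::.popcount_cpp(bitwXor(a, b))
  for (rep in 1:50) {
    abc <- sample(masks, 3)
    expect_equal(pc(abc[1], abc[2]), pc(abc[2], abc[1]))
    expect_gte(pc(abc[1], abc[2]) + pc(abc[2], abc[3]),
               pc(abc[1], abc[3]))
  }
  expect_true(all(pc(masks, masks) == 0))
})

test_that("the subset index finds exactly the swap neighbours", {
  s <- size3_set()
  u <- s$toy$universe
  g <- genotype_from_ids(u, c("S1L1", "S1L1A2a", "S1L2"))
  nb <- swap_neighbors(g, s$gs3)
  nb_ids <- lapply(nb, function(x) sort(genotype_ids(u, x)))
  expect_length(nb, 2)
  expect_true(list(sort(c("S1L1", "S1L1A2b", "S1L2"))) %in% nb_ids ||
              any(vapply(nb_ids, identical,
                         logical(1), sort(c("S1L1", "S1L1A2b", "S1L2")))))
  # index-based neighbour lists match the all-pairs scan on random sets
  set.seed(5)
  N <- 14
  pool <- sample(0:(2^N - 1), 600)
  n_target <- 7
  masks <- pool[ccmspace:::.popcount_cpp(pool) == n_target]
  idx <- ccmspace:::build_subset_index(masks)
  for (k in seq_along(masks)) {
    via_index <- setdiff(ccmspace:::neighbours_via_index(masks[k], idx), k)
    brute <- which(ccmspace:::.hamming_to_all_cpp(masks[k], masks) == 2)
    expect_identical(sort(via_index), sort(brute))
  }
})

test_that("a singleton set has no neighbours", {
  s <- size3_set()
  single <- s$gs3
  single$members <- single$members[1]
  expect_length(swap_neighbors(ccmspace:::mask_to_bits(single$members[1], 4),
                               single), 0)
})

test_that("streaming BFS equals adjacency-matrix components", {
  s <- size3_set()
  cc <- connected_components(s$gs3)
  expect_equal(cc$n_components, 1)
  expect_equal(cc$giant_fraction, 1)
  # two genotypes at swap distance 2: no edge, two components
  toy <- s$toy
  far <- s$gs3
  far$members <- c(ccmspace:::bits_to_mask(c(1L, 1L, 0L, 1L)),
                   ccmspace:::bits_to_mask(c(0L, 1L, 1L, 1L)))
  # distance between these two is 1 swap; build a genuine distance-2 pair
  far$members <- c(ccmspace:::bits_to_mask(c(1L, 0L, 0L, 1L)),
                   ccmspace:::bits_to_mask(c(0L, 1L, 1L, 0L)))
  far$size <- 2
  cc2 <- connected_components(far)
  expect_equal(cc2$n_components, 2)
  expect_equal(cc2$giant_fraction, 0.5)
  # randomized comparison against igraph on several universes
  for (seed in 1:3) {
    toyr <- make_from_cfg(list(n_sources = 2, layers = 2,
                               alternatives = c(2, 1), seed = seed))
    gsr <- enumerate_bruteforce(toyr$universe, toyr$panel, at_least("env_C1"))
    for (n in unique(ccmspace:::.popcount_cpp(gsr$members))) {
      gn <- filter_size(gsr, n)
      cc_pkg <- connected_components(gn)
      cc_ig <- igraph_components(gn$members)
      expect_equal(cc_pkg$n_components, cc_ig$no)
      expect_equal(sort(cc_pkg$sizes), sort(unname(cc_ig$csize)))
    }
  }
})

test_that("component labels are invariant under member ordering", {
  s <- size3_set()
  rev_set <- s$gs3
  rev_set$members <- rev(rev_set$members)
  cc1 <- connected_components(s$gs3)
  cc2 <- connected_components(rev_set)
  expect_equal(cc1$n_components, cc2$n_components)
  expect_equal(cc1$sizes, cc2$sizes)
})

test_that("connectivity inheritance is sound and guarded", {
  s <- size3_set()
  gs4 <- filter_size(s$gs, 4)
  inh <- connectivity_inheritance(s$gs3, gs4)
  expect_true(inh$connected)
  expect_equal(inh$method, "inferred")
  # direct BFS agrees
  expect_equal(connected_components(gs4)$n_components, 1)
  # a size-(n+1) member that covers no size-n member forces the fallback:
  # synthetic sets where the size-2 "network" is a singleton and one size-3
  # member shares only one bit with it
  syn_n <- s$gs3
  syn_n$members <- ccmspace:::bits_to_mask(c(1L, 1L, 0L, 0L))
  syn_n1 <- s$gs3
  syn_n1$members <- c(ccmspace:::bits_to_mask(c(1L, 1L, 1L, 0L)),
                      ccmspace:::bits_to_mask(c(1L, 0L, 1L, 1L)))
  inh2 <- connectivity_inheritance(syn_n, syn_n1)
  expect_equal(inh2$method, "bfs")
  expect_false(inh2$precondition_held)
  # sweep: whenever the precondition holds, inference matches direct BFS
  for (seed in 1:3) {
    toyr <- make_from_cfg(list(n_sources = 1, layers = 3,
                               alternatives = c(2, 2, 1), seed = seed))
    gsr <- enumerate_bruteforce(toyr$universe, toyr$panel, at_least("env_C1"))
    ns <- sort(unique(ccmspace:::.popcount_cpp(gsr$members)))
    for (n in head(ns, -1)) {
      gn <- filter_size(gsr, n); gn1 <- filter_size(gsr, n + 1)
      if (connected_components(gn)$n_components != 1) next
      inh <- connectivity_inheritance(gn, gn1)
      expect_equal(inh$connected,
                   connected_components(gn1)$n_components == 1)
    }
  }
})

test_that("diameter respects the genotype-space bound and sampling is a lower bound", {
  s <- size3_set()
  d <- diameter(s$gs3)
  expect_equal(d$value, 1)
  expect_equal(d$mode, "exact")
  expect_equal(d$max_possible, min(3, 4 - 3))
  expect_equal(max_diameter(51, 25), 25)
  expect_equal(max_diameter(51, 40), 11)
  for (seed in 1:3) {
    toyr <- make_from_cfg(list(n_sources = 2, layers = 3, alternatives = 1,
                               seed = seed))
    gsr <- enumerate_bruteforce(toyr$universe, toyr$panel, at_least("env_C1"))
    for (n in unique(ccmspace:::.popcount_cpp(gsr$members))) {
      gn <- filter_size(gsr, n)
      ex <- diameter(gn)
      expect_lte(ex$value, ex$max_possible)
      smp <- diameter(gn, sample_cap = 3, exact_cap = 0, seed = seed)
      expect_lte(smp$value, ex$value)
      expect_equal(smp$mode, "sampled_lower_bound")
    }
  }
})

test_that("co-factor filtering removes only opposite-isoform pairs", {
  # universe with one declared pair: two isoforms of the first segment
  u <- reaction_universe(
    reaction_ids = c("ISO_A", "ISO_B", "STEP", "ALT1", "ALT2", "EX", "BM"),
    equations = c("A -> B", "A -> B2", "B -> P", "A -> B3", "B3 -> P",
                  "A ->", "P ->"),
    reversible = rep(FALSE, 7), lb = rep(0, 7),
    ub = c(rep(1000, 5), 0, 1000),
    class = c(rep("internal", 5), "exchange", "biomass"),
    precursor_ids = "P", cofactor_pairs = list(c("ISO_A", "ISO_B")))
  # pair 1 differs by the isoforms, pair 2 does not
  m <- function(ids) ccmspace:::bits_to_mask(
    as.integer(u$reaction_ids[u$internal_idx] %in% ids))
  pairs <- rbind(c(m(c("ISO_A", "STEP")), m(c("ISO_B", "STEP"))),
                 c(m(c("ISO_A", "STEP")), m(c("ALT1", "ALT2"))))
  res <- cofactor_pair_filter(pairs, u)
  expect_equal(res$percent_remaining, 50)
  expect_identical(res$kept, c(FALSE, TRUE))
  # no declared pairs: everything remains
  u0 <- u; u0$cofactor_pairs <- list()
  expect_equal(cofactor_pair_filter(pairs, u0)$percent_remaining, 100)
  # all pairs differ by isoforms: nothing remains
  res0 <- cofactor_pair_filter(pairs[1, , drop = FALSE], u)
  expect_equal(res0$percent_remaining, 0)
})

test_that("blocked counts at maximal distance take the minimum over pairs", {
  toy <- toy_a()
  gs <- enumerate_bruteforce(toy$universe, toy$panel, at_least("env_C1"))
  gs3 <- filter_size(gs, 3)
  mp <- max_distance_pairs(gs3)
  expect_equal(mp$distance, 1)
  bl <- blocked_at_max_distance(mp$pairs, toy$universe, toy$panel[[1]])
  per_pair <- vapply(seq_len(nrow(mp$pairs)), function(r)
    length(blocked_reactions(toy$universe,
                             ccmspace:::mask_to_bits(mp$pairs[r, 1], 4),
                             toy$panel[[1]])) +
    length(blocked_reactions(toy$universe,
                             ccmspace:::mask_to_bits(mp$pairs[r, 2], 4),
                             toy$panel[[1]])), numeric(1))
  expect_equal(bl, min(per_pair))
  expect_true(all(bl <= per_pair))
})
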