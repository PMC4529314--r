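singleton_set <- function(u, ids) {
  gs <- ccmspace:::new_genotype_set(u, exclusively("x"), integer(0))
  gs$members <- ccmspace:::bits_to_mask(
    as.integer(u$reaction_ids[u$internal_idx] %in% ids))
  gs
}

test_that("minimal network distance handles the trivial cases", {
  toy <- toy_a()
  u <- toy$universe
  a <- singleton_set(u, c("S1L1", "S1L1A2a", "S1L2"))
  b <- singleton_set(u, c("S1L1", "S1L1A2b", "S1L2"))
  expect_equal(min_network_distance(a, b), 1)
  expect_equal(min_network_distance(a, a), 0)
  expect_equal(min_network_distance(a, b), min_network_distance(b, a))
})

test_that("the indexed search matches the brute-force cross minimum", {
  set.seed(77)
  N <- 14
  pc <- ccmspace:::.popcount_cpp
  toy <- make_layered_universe(n_sources = 2, layers = 3, alternatives = 1)
  u <- toy$universe
  for (rep in 1:10) {
    pool <- sample(0:(2^N - 1), 400)
    n_target <- 7
    m <- pool[pc(pool) == n_target]
    half <- seq_len(length(m) %/% 2)
    g1 <- ccmspace:::new_genotype_set(u, exclusively("a"), integer(0))
    g2 <- ccmspace:::new_genotype_set(u, exclusively("b"), integer(0))
    g1$members <- m[half]; g2$members <- m[-half]
    got <- min_network_distance(g1, g2, component = "all")
    brute <- min(outer(g1$members, g2$members,
                       function(x, y) pc(bitwXor(x, y)))) %/% 2
    expect_equal(got, brute)
  }
})

test_that("complexity aggregation is symmetric and excludes self-pairs", {
  toy <- toy_two_sources()
  u <- toy$universe; panel <- toy$panel
  excl <- list(
    env_C1 = enumerate_bruteforce(u, panel, exclusively("env_C1")),
    env_C2 = enumerate_bruteforce(u, panel, exclusively("env_C2")),
    both   = enumerate_bruteforce(u, panel, exclusively(c("env_C1", "env_C2"))))
  # exclusive sets are pairwise disjoint
  expect_length(intersect(excl$env_C1$members, excl$env_C2$members), 0)
  expect_length(intersect(excl$env_C1$members, excl$both$members), 0)
  common <- Reduce(intersect, lapply(excl, function(s)
    unique(ccmspace:::.popcount_cpp(s$members))))
  n_star <- common[1]
  cm <- complexity_matrix(lapply(excl, filter_size, n = n_star))
  expect_equal(nrow(cm$pairs), choose(3, 2))
  expect_true(all(cm$pairs$net1 != cm$pairs$net2))
  # aggregation key is unordered in (k, k')
  expect_true(all(cm$by_complexity$k1 <= cm$by_complexity$k2))
  # the two single-source networks abut: each route swaps into the other
  row11 <- cm$by_complexity[cm$by_complexity$k1 == 1 &
                            cm$by_complexity$k2 == 1, ]
  expect_equal(row11$n_pairs, 1)
})

test_that("genotype-phenotype distance strata behave as distances", {
  toy <- toy_two_sources()
  u <- toy$universe; panel <- toy$panel
  gs <- enumerate_bruteforce(u, panel, at_least(character(0)))
  viable_any <- union(
    enumerate_bruteforce(u, panel, at_least("env_C1"))$members,
    enumerate_bruteforce(u, panel, at_least("env_C2"))$members)
  sizes <- ccmspace:::.popcount_cpp(viable_any)
  n_star <- as.integer(names(which.max(table(sizes))))
  members <- viable_any[sizes == n_star]
  phen <- vapply(members, function(m)
    paste(phenotype(u, ccmspace:::mask_to_bits(m, universe_N(u)), panel),
          collapse = ""), character(1))
  gp <- genotype_vs_phenotype(members, phen, sample_size = length(members),
                              seed = 3)
  # focal-vs-self pairs are excluded: no (0, 0) inflation beyond duplicates
  expect_true(all(gp$table$count > 0))
  # same-phenotype pairs at D_G > 0 land in the D_P = 0 stratum
  expect_true(0 %in% gp$mean_D_G$D_P)
  # phenotype change needs at least as much genotype change on average
  if (any(gp$mean_D_G$D_P > 0)) {
    m0 <- gp$mean_D_G$mean_D_G[gp$mean_D_G$D_P == 0]
    mpos <- mean(gp$mean_D_G$mean_D_G[gp$mean_D_G$D_P > 0])
    expect_gte(mpos, m0 - 0.5)
  }
  # determinism under the seed
  gp2 <- genotype_vs_phenotype(members, phen, sample_size = length(members),
                               seed = 3)
  expect_identical(gp$table, gp2$table)
})
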