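test_that("viability on the toy universe matches the path structure", {
  toy <- toy_a()
  u <- toy$universe; env <- toy$panel[[1]]
  # direct route present: viable
  r <- solve_fba(u, genotype_from_ids(u, c("S1L1", "S1L2")), env)
  expect_true(r$viable)
  # no precursor production: inviable, biomass 0
  r0 <- solve_fba(u, genotype_from_ids(u, "S1L1"), env)
  expect_false(r0$viable)
  expect_equal(r0$biomass_rate, 0, tolerance = 1e-9)
  # all-ones genotype attains the reference rate by definition
  r1 <- solve_fba(u, full_genotype(u), env)
  expect_equal(r1$biomass_rate, r1$reference_rate)
  expect_true(r1$viable)
  # all-zero genotype: all-zero phenotype
  expect_equal(phenotype(u, rep(0L, 4), toy$panel), c(0L))
})

test_that("phenotype bits follow the panel order", {
  toy <- toy_two_sources()
  u <- toy$universe
  route1 <- grep("^S1", u$reaction_ids[u$internal_idx], value = TRUE)
  g <- genotype_from_ids(u, route1)
  expect_equal(phenotype(u, g, toy$panel), c(1L, 0L))
})

test_that("FBA viability equals reachability on a full exhaustive sweep", {
  toy <- make_layered_universe(n_sources = 2, layers = 2,
                               alternatives = c(2, 1))
  u <- toy$universe
  N <- universe_N(u)
  for (env_name in names(toy$panel)) {
    fba <- ccmspace:::viable_masks(u, 0:(2^N - 1), toy$panel[[env_name]])
    oracle <- (0:(2^N - 1)) %in% oracle_viable_masks(toy, env_name)
    expect_identical(fba, oracle)
  }
})

test_that("viability is monotone under reaction addition", {
  toy <- make_layered_universe(n_sources = 2, layers = 3,
                               alternatives = c(2, 1, 1))
  u <- toy$universe; N <- universe_N(u)
  set.seed(202)
  sup <- sample(0:(2^N - 1), 500, replace = TRUE)
  sub <- vapply(sup, function(m) bitwAnd(m, sample(0:(2^N - 1), 1)), integer(1))
  for (env in toy$panel) {
    v_sub <- ccmspace:::viable_masks(u, sub, env)
    v_sup <- ccmspace:::viable_masks(u, sup, env)
    expect_false(any(v_sub & !v_sup))
  }
})

test_that("essential reactions are the unavoidable steps", {
  toy <- toy_a()
  ess <- essential_reactions(toy$universe, toy$panel)
  expect_identical(
    toy$universe$reaction_ids[toy$universe$internal_idx][ess], "S1L2")
  # a universe where every step has a disjoint alternative has none
  toy2 <- make_layered_universe(n_sources = 1, layers = 1, alternatives = 2)
  # alternatives at layer 1: direct + detour; the detour shares no reaction
  # with the direct route, but the single direct step can still be bypassed
  ess2 <- essential_reactions(toy2$universe, toy2$panel)
  expect_length(ess2, 0)
})

test_that("blocked reactions are found by flux variability", {
  toy <- toy_a()
  u <- toy$universe; env <- toy$panel[[1]]
  # A->C present but C->B absent: the detour entry is blocked
  g <- genotype_from_ids(u, c("S1L1", "S1L2", "S1L1A2a"))
  blk <- blocked_reactions(u, g, env)
  expect_identical(u$reaction_ids[u$internal_idx][blk], "S1L1A2a")
  # full network: every reaction can carry flux
  expect_length(blocked_reactions(u, full_genotype(u), env), 0)
})

test_that("an isolated chain with no net exchange is entirely blocked", {
  u <- reaction_universe(
    reaction_ids = c("R1", "R2", "ISO1", "ISO2", "EX_A", "BM"),
    equations = c("A -> B", "B -> P", "X -> Y", "Y -> Z", "A ->", "P ->"),
    reversible = rep(FALSE, 6), lb = rep(0, 6),
    ub = c(1000, 1000, 1000, 1000, 0, 1000),
    class = c("internal", "internal", "internal", "internal",
              "exchange", "biomass"),
    precursor_ids = "P")
  env <- environment_def("A_in", "EX_A", c(EX_A = 10))
  blk <- blocked_reactions(u, full_genotype(u), env)
  expect_setequal(u$reaction_ids[u$internal_idx][blk], c("ISO1", "ISO2"))
})

test_that("disconnected reactions follow the two-clause topological test", {
  toy <- toy_a()
  u <- toy$universe; env <- toy$panel[[1]]
  ids <- function(idx) u$reaction_ids[u$internal_idx][idx]
  # detour entry A->C: product C feeds nothing present (clause i)
  expect_identical(
    ids(disconnected_reactions(u, genotype_from_ids(u, c("S1L1", "S1L2", "S1L1A2a")), env)),
    "S1L1A2a")
  # detour exit C->B: substrate C neither produced nor a nutrient (clause ii)
  expect_identical(
    ids(disconnected_reactions(u, genotype_from_ids(u, c("S1L1", "S1L2", "S1L1A2b")), env)),
    "S1L1A2b")
  # full network is fully connected
  expect_length(disconnected_reactions(u, full_genotype(u), env), 0)
})

test_that("minimal viable size matches brute force on the toy", {
  toy <- toy_a()
  u <- toy$universe
  mv <- minimal_viable_size(u, list(toy$panel[[1]]))
  expect_equal(mv$n_min, 2)
  expect_equal(mv$status, "optimal")
  expect_setequal(genotype_ids(u, mv$witness), c("S1L1", "S1L2"))
  # witness is viable and contains no disconnected reactions
  expect_true(solve_fba(u, mv$witness, toy$panel[[1]])$viable)
  expect_length(disconnected_reactions(u, mv$witness, toy$panel[[1]]), 0)
})

test_that("a multi-environment minimum dominates the single-source minima", {
  toy <- toy_two_sources(layers = 2)
  u <- toy$universe
  m_each <- vapply(toy$panel, function(e)
    minimal_viable_size(u, list(e))$n_min, integer(1))
  m_both <- minimal_viable_size(u, toy$panel)$n_min
  expect_true(m_both >= max(m_each))
  expect_equal(unname(m_each), unname(as.integer(toy$n_min)))
})
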