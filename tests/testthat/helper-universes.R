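# Shared fixtures, all built in code.

# The four-reaction toy used throughout: source A -> B -> precursor P, with a
# two-step detour A -> C -> B around the first step.  Bit order:
# S1L1 (A->B), S1L1A2a (A->C), S1L1A2b (C->B), S1L2 (B->P).
toy_a <- function() make_layered_universe(n_sources = 1, layers = 2,
                                          alternatives = c(2, 1))

# same topology plus a second, independent carbon source (C2 enters via its
# own chain); gives a 2-environment panel with no implications
toy_two_sources <- function(layers = 2, alternatives = 1)
  make_layered_universe(n_sources = 2, layers = layers,
                        alternatives = alternatives)

# enumerate the viable masks of a layered universe with the reachability
# oracle -- completely independent of the LP machinery
oracle_viable_masks <- function(toy, env_name) {
  u <- toy$universe
  N <- universe_N(u)
  masks <- 0:(2^N - 1)
  keep <- vapply(masks, function(m)
    reachability_oracle(u, ccmspace:::mask_to_bits(m, N),
                        toy$panel[[env_name]]),
    logical(1))
  sort(masks[keep])
}

# grid of layered-universe configurations (>= 20) used for the
# divide-and-merge equivalence sweep; all have N <= 14
layered_grid <- function() {
  cfg <- list()
  for (seed in 1:4) {
    cfg[[length(cfg) + 1]] <- list(n_sources = 1, layers = 2,
                                   alternatives = c(2, 1), seed = seed)
    cfg[[length(cfg) + 1]] <- list(n_sources = 1, layers = 3,
                                   alternatives = c(2, 2, 1), seed = seed)
    cfg[[length(cfg) + 1]] <- list(n_sources = 2, layers = 2,
                                   alternatives = c(2, 1), seed = seed)
    cfg[[length(cfg) + 1]] <- list(n_sources = 2, layers = 3,
                                   alternatives = 1, seed = seed)
    cfg[[length(cfg) + 1]] <- list(n_sources = 3, layers = 2,
                                   alternatives = 1, nested = TRUE,
                                   seed = seed)
  }
  cfg
}

make_from_cfg <- function(cfg) do.call(make_layered_universe, cfg)
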