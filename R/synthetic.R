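# Synthetic reaction universes with analytically known viable-set structure.
# Layered universes are DAGs of 1:1 irreversible conversions, so FBA
# viability coincides with graph reachability and every downstream stage can
# be checked against an exact combinatorial ground truth.

#' Generate a layered pathway universe
#'
#' Builds a universe in which each carbon source feeds a chain of
#' \code{layers} conversion segments ending in the precursor sink(s).  Each
#' segment has a direct one-reaction route, plus \code{alternatives[t] - 1}
#' two-reaction detours through a private intermediate, giving alternative
#' pathways of known structure.  All reactions are irreversible 1:1
#' conversions; the biomass reaction consumes one unit of each precursor;
#' exchanges are closed by default and opened (uptake only) by the
#' environments.  With \code{nested = TRUE} each source beyond the first is
#' attached by a single bridging reaction to the previous source's chain
#' entry, so viability on source s implies viability on source s-1 --
#' a constructed carbon-source implication.
#'
#' The minimal viable size on a single non-nested source is \code{layers}
#' (plus \code{n_precursors} shared sink steps when \code{n_precursors > 1});
#' each nesting level adds one bridging reaction.
#'
#' @param n_sources number of carbon sources (one environment each).
#' @param layers number of conversion segments per (non-nested) route.
#' @param alternatives scalar or per-segment vector: total alternative routes
#'   per segment (1 = direct route only).
#' @param n_precursors number of biomass precursors (1 = the chain target is
#'   the single precursor).
#' @param nested attach sources in a chain of implications (see above).
#' @param seed if non-NULL, the internal-reaction bit order is randomly
#'   permuted under this seed (exercises order independence downstream).
#' @param uptake maximal uptake rate of the carbon source (flux units).
#' @return list with \code{universe}, \code{panel}, \code{n_min} (named per
#'   source), and \code{mode = "layered_dag"}.
#' @export
make_layered_universe <- function(n_sources = 1, layers = 2, alternatives = 1,
                                  n_precursors = 1, nested = FALSE,
                                  seed = NULL, uptake = 10) {
  stopifnot(n_sources >= 1, layers >= 1, n_precursors >= 1)
  alt <- rep_len(as.integer(alternatives), layers)
  stopifnot(all(alt >= 1))

  rid <- character(0); req <- character(0); rcls <- character(0)
  add <- function(id, eq, cls) {
    rid <<- c(rid, id); req <<- c(req, eq); rcls <<- c(rcls, cls)
  }
  hub <- if (n_precursors == 1) "P1" else "HUB"
  src_met <- function(s) paste0("C", s)

  for (s in seq_len(n_sources)) {
    if (nested && s > 1) {
      add(paste0("BR", s), paste0(src_met(s), " -> ", src_met(s - 1)),
          "internal")
      next
    }
    nodes <- c(src_met(s),
               if (layers > 1) paste0("S", s, "X", seq_len(layers - 1)),
               hub)
    for (t in seq_len(layers)) {
      from <- nodes[t]; to <- nodes[t + 1]
      add(paste0("S", s, "L", t), paste0(from, " -> ", to), "internal")
      if (alt[t] > 1) for (a in 2:alt[t]) {
        mid <- paste0("S", s, "L", t, "D", a)
        add(paste0("S", s, "L", t, "A", a, "a"), paste0(from, " -> ", mid),
            "internal")
        add(paste0("S", s, "L", t, "A", a, "b"), paste0(mid, " -> ", to),
            "internal")
      }
    }
  }
  precursors <- if (n_precursors == 1) "P1" else paste0("P", seq_len(n_precursors))
  if (n_precursors > 1)
    for (j in seq_len(n_precursors))
      add(paste0("PRD", j), paste0(hub, " -> P", j), "internal")

  if (!is.null(seed)) {
    o <- withr_seed_sample(seed, length(rid))
    rid <- rid[o]; req <- req[o]; rcls <- rcls[o]
  }

  for (s in seq_len(n_sources))
    add(paste0("EX_C", s), paste0(src_met(s), " ->"), "exchange")
  add("BIOMASS", paste0(paste(precursors, collapse = " + "), " ->"), "biomass")

  n <- length(rid)
  is_ex <- rcls == "exchange"
  u <- reaction_universe(
    reaction_ids = rid, equations = req,
    reversible = rep(FALSE, n),
    lb = rep(0, n),
    ub = ifelse(is_ex, 0, 1000),
    class = rcls, precursor_ids = precursors)

  envs <- lapply(seq_len(n_sources), function(s)
    environment_def(paste0("env_C", s), paste0("EX_C", s),
                    setNames(uptake, paste0("EX_C", s))))
  panel <- environment_panel(envs)

  n_min <- vapply(seq_len(n_sources), function(s) {
    depth <- 0
    while (nested && s > 1) { depth <- depth + 1; s <- s - 1 }
    layers + depth + if (n_precursors > 1) n_precursors else 0
  }, numeric(1))
  names(n_min) <- names(panel)

  list(universe = u, panel = panel, n_min = n_min, mode = "layered_dag")
}

# order permutation under a local seed, leaving the caller's RNG untouched
withr_seed_sample <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(n)
}

#' Reachability ground-truth oracle for layered universes
#'
#' On an irreversible unit-stoichiometry DAG, a genotype is viable in an
#' environment exactly when every biomass precursor is reachable from the
#' environment-supplied metabolites through the present reactions, at any
#' viability threshold fraction below one.  Computed by graph closure,
#' independently of the LP machinery, so it serves as an exact oracle for
#' [solve_fba()] and everything built on it.
#'
#' @param u a layered [reaction_universe()] (see [make_layered_universe()]).
#' @param g genotype bit vector.
#' @param env a [environment_def()].
#' @return TRUE iff all precursors are reachable.
#' @export
reachability_oracle <- function(u, g, env) {
  stopifnot(length(g) == universe_N(u))
  b <- env_bounds(u, env)
  open_ex <- u$exchange_idx[b$lb[u$exchange_idx] < 0]
  avail <- unique(unlist(lapply(open_ex, function(j)
    rownames(u$S)[u$S[, j] != 0])))
  active <- c(u$internal_idx[g == 1L], u$transport_idx)
  repeat {
    fired <- FALSE
    for (j in active) {
      subs <- rownames(u$S)[u$S[, j] < 0]
      prods <- rownames(u$S)[u$S[, j] > 0]
      if (length(prods) && all(subs %in% avail) && !all(prods %in% avail)) {
        avail <- union(avail, prods)
        fired <- TRUE
      }
    }
    if (!fired) break
  }
  all(u$precursor_ids %in% avail)
}

#' Generate a random mass-balanced universe
#'
#' Stress-test generator with non-trivial stoichiometry: every metabolite
#' carries an integer pseudo-mass and every generated reaction conserves
#' total pseudo-mass exactly.  Optionally injects co-factor reaction pairs
#' (the same core conversion driven by either member of a co-factor couple)
#' to exercise the co-factor pair bookkeeping.  Deterministic under
#' \code{seed}.
#'
#' @param n_mets number of core metabolites.
#' @param n_rxns number of random internal reactions.
#' @param n_cofactor_pairs number of injected co-factor reaction pairs.
#' @param seed RNG seed (required; generation is seeded and reproducible).
#' @return list with \code{universe} and \code{masses} (named pseudo-masses).
#' @export
make_random_massbalanced <- function(n_mets = 8, n_rxns = 10,
                                     n_cofactor_pairs = 0, seed) {
  stopifnot(!missing(seed), n_mets >= 3, n_rxns >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  mets <- paste0("M", seq_len(n_mets))
  mass <- setNames(sample(1:4, n_mets, replace = TRUE), mets)

  rid <- character(0); req <- character(0); rcls <- character(0)
  add <- function(id, eq, cls) {
    rid <<- c(rid, id); req <<- c(req, eq); rcls <<- c(rcls, cls)
  }
  made <- 0
  while (made < n_rxns) {
    subs <- sample(mets, sample(1:2, 1))
    prods <- sample(setdiff(mets, subs), sample(1:2, 1))
    ok <- FALSE
    for (tries in 1:50) {
      cs <- sample(1:3, length(subs), replace = TRUE)
      cp <- sample(1:3, length(prods), replace = TRUE)
      if (sum(cs * mass[subs]) == sum(cp * mass[prods])) { ok <- TRUE; break }
    }
    if (!ok) next
    made <- made + 1
    term <- function(co, m) if (co == 1) m else paste(co, m)
    add(paste0("R", made),
        paste(paste(mapply(term, cs, subs), collapse = " + "), "->",
              paste(mapply(term, cp, prods), collapse = " + ")),
        "internal")
  }

  cof_pairs <- list()
  if (n_cofactor_pairs > 0) for (k in seq_len(n_cofactor_pairs)) {
    a <- sample(mets, 1); b <- sample(setdiff(mets, a), 1)
    # balance the core conversion with a filler of the mass difference if any
    d <- mass[a] - mass[b]
    core <- if (d == 0) paste(a, "->", b) else if (d > 0)
      paste(a, "->", b, "+", paste(d, paste0("F", k))) else
      paste(a, "+", paste(-d, paste0("F", k)), "->", b)
    for (iso in 1:2) {
      cid <- paste0("CF", k, "_", iso)
      cofa <- paste0("X", k, iso); cofb <- paste0("Y", k, iso)
      # co-factor couple X -> Y carried along, equal masses by construction
      eq <- sub("->", paste("+", cofa, "->"), core, fixed = TRUE)
      eq <- paste(eq, "+", cofb)
      add(cid, eq, "internal")
    }
    cof_pairs[[k]] <- paste0("CF", k, "_", 1:2)
  }

  add("EX_M1", paste0(mets[1], " ->"), "exchange")
  add("BIOMASS", paste0(mets[n_mets], " ->"), "biomass")
  n <- length(rid)
  u <- reaction_universe(
    reaction_ids = rid, equations = req, reversible = rep(FALSE, n),
    lb = rep(0, n), ub = ifelse(rcls == "exchange", 0, 1000),
    class = rcls, precursor_ids = mets[n_mets], cofactor_pairs = cof_pairs)
  # co-factor couple metabolites get equal pseudo-mass, fillers mass 1
  extra <- setdiff(u$metabolite_ids, mets)
  mass_all <- c(mass, setNames(rep(1L, length(extra)), extra))
  list(universe = u, masses = mass_all[u$metabolite_ids])
}
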