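# FBA viability core: one LP per (genotype, environment), plus the structural
# diagnostics built on the same machinery (essentiality, flux-variability
# blocked reactions, topological disconnection, minimal viable networks).

# sparse triplets of the stoichiometric matrix, 1-based
stoich_triplets <- function(u) {
  nz <- which(u$S != 0, arr.ind = TRUE)
  list(i = as.integer(nz[, 1]), j = as.integer(nz[, 2]),
       x = u$S[nz], m = nrow(u$S), n = ncol(u$S))
}

# optimal biomass rates for a batch of genotypes (matrix: one row per
# genotype, one column per internal reaction) in one environment
biomass_batch <- function(u, gmat, env) {
  tb <- stoich_triplets(u)
  b <- env_bounds(u, env)
  .fba_batch_cpp(tb$m, tb$n, tb$i, tb$j, tb$x, b$lb, b$ub,
                 as.integer(u$biomass_idx), as.integer(u$internal_idx),
                 matrix(as.integer(gmat), nrow(gmat), ncol(gmat)))
}

#' Reference biomass rate of the full universe in an environment
#'
#' The viability threshold is relative: a genotype is viable when its optimal
#' biomass rate exceeds \code{threshold_fraction} times the rate of the
#' all-ones genotype (every internal reaction present) in the same
#' environment.  The reference is computed once per (universe, environment)
#' and cached.
#'
#' @param u a [reaction_universe()].
#' @param env a [environment_def()].
#' @return the reference biomass rate (flux units).
#' @export
reference_rate <- function(u, env) {
  key <- paste(attr(u, "uid"), env$name, sep = "::")
  hit <- get0(key, envir = .ccm_cache, ifnotfound = NULL)
  if (!is.null(hit)) return(hit)
  r <- biomass_batch(u, matrix(1L, 1, universe_N(u)), env)[1]
  assign(key, r, envir = .ccm_cache)
  r
}

#' Decide viability of a genotype by flux balance analysis
#'
#' Solves \eqn{\max c^T v} subject to \eqn{S v = 0} and \eqn{a \le v \le b},
#' with fluxes of absent internal reactions fixed to zero and exchange bounds
#' set by the environment.  An infeasible LP is reported as biomass rate 0.
#'
#' @param u a [reaction_universe()].
#' @param g genotype bit vector of length \code{universe_N(u)}.
#' @param env a [environment_def()].
#' @param threshold_fraction viability threshold as a fraction of the
#'   all-ones reference rate (default 0.01).
#' @return list with \code{biomass_rate}, \code{viable}, \code{reference_rate},
#'   \code{threshold_fraction}.
#' @export
solve_fba <- function(u, g, env, threshold_fraction = 0.01) {
  stopifnot(length(g) == universe_N(u))
  ref <- reference_rate(u, env)
  z <- biomass_batch(u, matrix(as.integer(g), 1), env)[1]
  list(biomass_rate = z, viable = z > threshold_fraction * ref,
       reference_rate = ref, threshold_fraction = threshold_fraction)
}

# vectorised viability over bitmask genotypes
viable_masks <- function(u, masks, env, threshold_fraction = 0.01) {
  if (!length(masks)) return(logical(0))
  ref <- reference_rate(u, env)
  gmat <- masks_to_matrix(masks, universe_N(u))
  biomass_batch(u, gmat, env) > threshold_fraction * ref
}

#' Phenotype vector of a genotype over an environment panel
#'
#' One viability bit per panel environment, in panel order.  The popcount of
#' the phenotype vector is the phenotypic complexity k.
#'
#' @inheritParams solve_fba
#' @param panel an [environment_panel()].
#' @return integer 0/1 vector of length \code{length(panel)}.
#' @export
phenotype <- function(u, g, panel, threshold_fraction = 0.01) {
  unname(vapply(panel, function(env)
    as.integer(solve_fba(u, g, env, threshold_fraction)$viable), integer(1)))
}

#' Reactions essential in every environment of a panel
#'
#' A reaction is always-essential if deleting it alone from the all-ones
#' genotype abolishes viability in every environment of the panel.  By
#' monotonicity, such reactions must be present in every viable genotype.
#'
#' @inheritParams phenotype
#' @return integer vector of internal reaction positions (genotype bit
#'   indices).
#' @export
essential_reactions <- function(u, panel, threshold_fraction = 0.01) {
  N <- universe_N(u)
  gmat <- matrix(1L, N, N)
  diag(gmat) <- 0L
  ess <- rep(TRUE, N)
  for (env in panel) {
    ref <- reference_rate(u, env)
    if (ref <= 0)
      stop("all-ones genotype is inviable in environment ", env$name)
    z <- biomass_batch(u, gmat, env)
    ess <- ess & (z <= threshold_fraction * ref)
  }
  which(ess)
}

# reactions whose deletion breaks viability on >= 1 environment of `envs`
# (these are forced present in any genotype viable on all of `envs`)
criterion_essential <- function(u, envs, threshold_fraction = 0.01) {
  N <- universe_N(u)
  gmat <- matrix(1L, N, N)
  diag(gmat) <- 0L
  ess <- rep(FALSE, N)
  for (env in envs) {
    ref <- reference_rate(u, env)
    z <- biomass_batch(u, gmat, env)
    ess <- ess | (z <= threshold_fraction * ref)
  }
  which(ess)
}

#' Blocked reactions of a genotype
#'
#' A present reaction is blocked when its flux is forced to zero by
#' stoichiometry: both its minimal and maximal feasible flux under
#' \eqn{S v = 0} and the genotype/environment bounds lie within \code{eps} of
#' zero.  By default the scan is pure feasibility (no biomass requirement);
#' set \code{min_biomass_fraction} to scan under a biomass floor instead.
#'
#' @inheritParams solve_fba
#' @param eps flux-zero tolerance.
#' @param min_biomass_fraction if non-NULL, impose biomass >= this fraction
#'   of the reference rate during the scan.
#' @return integer vector of blocked internal reaction positions (subset of
#'   the present positions of \code{g}).
#' @export
blocked_reactions <- function(u, g, env, eps = 1e-6,
                              min_biomass_fraction = NULL) {
  stopifnot(length(g) == universe_N(u))
  tb <- stoich_triplets(u)
  b <- env_bounds(u, env)
  absent <- u$internal_idx[g == 0L]
  b$lb[absent] <- 0; b$ub[absent] <- 0
  present <- which(g == 1L)
  scan_cols <- u$internal_idx[present]
  floor_col <- 0L; floor_val <- 0
  if (!is.null(min_biomass_fraction)) {
    floor_col <- as.integer(u$biomass_idx)
    floor_val <- min_biomass_fraction * reference_rate(u, env)
  }
  fv <- .fva_cpp(tb$m, tb$n, tb$i, tb$j, tb$x, b$lb, b$ub,
                 as.integer(scan_cols), floor_col, floor_val)
  present[abs(fv[, 1]) <= eps & abs(fv[, 2]) <= eps]
}

#' Topologically disconnected reactions of a genotype
#'
#' A present internal reaction is disconnected from the resident metabolism
#' when (i) none of its products is a biomass precursor or a substrate of any
#' other present reaction, or (ii) at least one of its substrates is neither
#' a product of another present reaction nor a nutrient taken up from the
#' environment.  The test is a single pass per reaction against the other
#' present reactions (internal present, transporters, biomass); exchange
#' pseudo-reactions count neither as producers nor consumers, but metabolites
#' importable through an open exchange count as environment nutrients.
#' Substrates and products of the focal reaction follow its written
#' direction, while other reversible reactions count on both sides.
#'
#' @inheritParams solve_fba
#' @return integer vector of disconnected internal reaction positions.
#' @export
disconnected_reactions <- function(u, g, env) {
  stopifnot(length(g) == universe_N(u))
  b <- env_bounds(u, env)
  present_cols <- c(u$internal_idx[g == 1L], u$transport_idx, u$biomass_idx)
  can_reverse <- b$lb < 0
  producible_by <- function(j) {
    col <- u$S[, j]
    out <- rownames(u$S)[col > 0]
    if (can_reverse[j]) out <- c(out, rownames(u$S)[col < 0])
    out
  }
  consumable_by <- function(j) {
    col <- u$S[, j]
    out <- rownames(u$S)[col < 0]
    if (can_reverse[j]) out <- c(out, rownames(u$S)[col > 0])
    out
  }
  # metabolites importable from the environment (open uptake exchanges)
  open_ex <- u$exchange_idx[b$lb[u$exchange_idx] < 0]
  nutrients <- unique(unlist(lapply(open_ex, function(j)
    rownames(u$S)[u$S[, j] != 0])))
  focal_positions <- which(g == 1L)
  out <- integer(0)
  for (p in focal_positions) {
    j <- u$internal_idx[p]
    others <- setdiff(present_cols, j)
    other_subs <- unique(unlist(lapply(others, consumable_by)))
    other_prods <- unique(unlist(lapply(others, producible_by)))
    prods <- rownames(u$S)[u$S[, j] > 0]
    subs <- rownames(u$S)[u$S[, j] < 0]
    dead_products <- length(prods) > 0 &&
      !any(prods %in% u$precursor_ids | prods %in% other_subs)
    orphan_substrate <- any(!(subs %in% other_prods | subs %in% nutrients))
    if (dead_products || orphan_substrate) out <- c(out, p)
  }
  out
}

#' Minimal viable network size
#'
#' Finds the smallest number of internal reactions whose presence supports
#' viability in every required environment simultaneously, by mixed-integer
#' programming: one binary presence variable per internal reaction, one flux
#' vector copy per environment, big-M coupling of fluxes to the shared
#' binaries, and a biomass floor of \code{threshold_fraction} times each
#' environment's reference rate.  A greedy-deletion witness supplies a valid
#' upper bound, and reactions essential for the required environments are
#' pre-fixed; both only prune the search.
#'
#' @param u a [reaction_universe()].
#' @param required list of [environment_def()] objects (or an
#'   [environment_panel()]) that the network must be viable on.
#' @param threshold_fraction viability threshold fraction (default 0.01).
#' @param time_limit_s MILP time limit in seconds; on timeout the best
#'   feasible size found is returned with status \code{"time_limit"}.
#' @return list with \code{n_min}, \code{witness} (genotype bit vector),
#'   \code{status} (\code{"optimal"} unless the time limit was hit) and
#'   \code{greedy_size} (the warm-start upper bound).
#' @export
minimal_viable_size <- function(u, required, threshold_fraction = 0.01,
                                time_limit_s = 870) {
  if (inherits(required, "ccm_environment")) required <- list(required)
  N <- universe_N(u)
  for (env in required)
    if (reference_rate(u, env) <= 0)
      stop("all-ones genotype is inviable in environment ", env$name)

  greedy <- greedy_minimal_network(u, required, threshold_fraction)
  forced <- criterion_essential(u, required, threshold_fraction)

  tb <- stoich_triplets(u)
  env_lb <- vapply(required, function(e) env_bounds(u, e)$lb, numeric(tb$n))
  env_ub <- vapply(required, function(e) env_bounds(u, e)$ub, numeric(tb$n))
  floor <- vapply(required, function(e)
    threshold_fraction * reference_rate(u, e) + 1e-6, numeric(1))

  res <- .milp_min_reactions_cpp(
    tb$m, tb$n, tb$i, tb$j, tb$x, env_lb, env_ub,
    as.integer(u$biomass_idx), floor, as.integer(u$internal_idx),
    as.integer(forced), as.integer(sum(greedy)), time_limit_s)

  if (res$status %in% c("failed", "infeasible"))
    stop("minimal-network MILP ended with status ", res$status)
  witness <- as.integer(res$witness)
  n_min <- as.integer(round(res$size))
  if (res$status == "time_limit" && (is.na(n_min) || sum(greedy) < n_min)) {
    witness <- greedy
    n_min <- sum(greedy)
  }
  # the witness must stand up to a direct FBA check in every environment
  for (env in required) {
    ref <- reference_rate(u, env)
    z <- biomass_batch(u, matrix(witness, 1), env)[1]
    if (z <= threshold_fraction * ref)
      stop("MILP witness fails direct FBA verification in environment ",
           env$name, "; solver tolerances are not trustworthy here")
  }
  list(n_min = n_min, witness = witness, status = res$status,
       greedy_size = sum(greedy))
}

# greedy deletion from the all-ones genotype: drop any reaction whose removal
# preserves viability on all required environments, until stuck
greedy_minimal_network <- function(u, required, threshold_fraction = 0.01) {
  N <- universe_N(u)
  g <- rep(1L, N)
  viable_all <- function(gg) {
    for (env in required) {
      ref <- reference_rate(u, env)
      if (biomass_batch(u, matrix(gg, 1), env)[1] <= threshold_fraction * ref)
        return(FALSE)
    }
    TRUE
  }
  repeat {
    dropped <- FALSE
    for (i in which(g == 1L)) {
      g2 <- g; g2[i] <- 0L
      if (viable_all(g2)) { g <- g2; dropped <- TRUE }
    }
    if (!dropped) break
  }
  g
}
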