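# Genotype networks: graphs over same-size viable genotypes whose edges are
# single reaction swaps (Hamming distance 2 between presence masks).

#' Swap distance between two genotypes
#'
#' The minimal number of reaction swaps converting one same-size genotype
#' into the other; equal to half the Hamming distance of the bit vectors.
#'
#' @param g1,g2 genotype bit vectors of equal length and equal size.
#' @return integer swap distance.
#' @export
genotype_distance <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  h <- sum(g1 != g2)
  if (h %% 2 != 0)
    stop("genotypes differ in size; swap distance is defined for equal sizes")
  h %/% 2
}

# (n-1)-subset index: hash from "member minus one bit" masks to member ids.
# Two same-size members are swap neighbours iff they share an (n-1)-subset,
# so neighbour queries cost O(n) lookups instead of a scan over the set.
build_subset_index <- function(masks) {
  idx <- new.env(hash = TRUE, parent = emptyenv())
  for (k in seq_along(masks)) {
    m <- masks[k]
    bits <- which(bitwAnd(m, bitwShiftL(1L, 0:29)) != 0L)
    for (b in bits) {
      key <- as.character(m - bitwShiftL(1L, b - 1L))
      assign(key, c(get0(key, envir = idx, ifnotfound = integer(0)), k),
             envir = idx)
    }
  }
  idx
}

neighbours_via_index <- function(mask, idx) {
  bits <- which(bitwAnd(mask, bitwShiftL(1L, 0:29)) != 0L)
  out <- integer(0)
  for (b in bits) {
    key <- as.character(mask - bitwShiftL(1L, b - 1L))
    out <- c(out, get0(key, envir = idx, ifnotfound = integer(0)))
  }
  sort(unique(out))
}

#' Swap neighbours of a genotype within a set
#'
#' Returns the members of \code{gs} at swap distance exactly one from
#' \code{g}, found through an index keyed by each member's (n-1)-subsets
#' rather than an all-pairs scan.
#'
#' @param g genotype bit vector (same length as the set's N).
#' @param gs a \code{genotype_set} whose members all have the same size as
#'   \code{g}.
#' @return list of genotype bit vectors.
#' @export
swap_neighbors <- function(g, gs) {
  stopifnot(length(g) == gs$N)
  mask <- bits_to_mask(g)
  idx <- attr(gs, "subset_index")
  if (is.null(idx)) idx <- build_subset_index(gs$members)
  hits <- neighbours_via_index(mask, idx)
  hits <- hits[gs$members[hits] != mask]
  lapply(gs$members[hits], mask_to_bits, n = gs$N)
}

#' Connected components of a genotype network
#'
#' Streaming breadth-first search over the swap-neighbour graph of a
#' fixed-size genotype set: the adjacency list is never materialised;
#' neighbours are generated on demand from the (n-1)-subset index.
#' Traversal order is deterministic (members sorted, frontier processed in
#' order), so component labels are reproducible.
#'
#' @param gs a \code{genotype_set} with all members of one size.
#' @return list with \code{n_components}, \code{sizes} (decreasing),
#'   \code{giant_fraction} (r_G), and \code{membership} (component id per
#'   member, in member order).
#' @export
connected_components <- function(gs) {
  masks <- gs$members
  sz <- unique(.popcount_cpp(masks))
  if (length(sz) > 1)
    stop("connected_components expects a fixed-size genotype set; use filter_size()")
  V <- length(masks)
  if (!V) return(list(n_components = 0L, sizes = integer(0),
                      giant_fraction = NA_real_, membership = integer(0)))
  idx <- build_subset_index(masks)
  comp <- integer(V)
  cid <- 0L
  for (s in seq_len(V)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    frontier <- s
    comp[s] <- cid
    while (length(frontier)) {
      nxt <- integer(0)
      for (k in frontier) {
        nb <- neighbours_via_index(masks[k], idx)
        nb <- nb[comp[nb] == 0L & masks[nb] != masks[k]]
        comp[nb] <- cid
        nxt <- c(nxt, nb)
      }
      frontier <- sort(unique(nxt))
    }
  }
  sizes <- sort(tabulate(comp, cid), decreasing = TRUE)
  list(n_components = cid, sizes = sizes,
       giant_fraction = sizes[1] / V, membership = comp)
}

# members of the largest component (ties broken by smallest component id)
giant_component_masks <- function(gs) {
  cc <- connected_components(gs)
  if (cc$n_components <= 1L) return(gs$members)
  counts <- tabulate(cc$membership)
  gs$members[cc$membership == which.max(counts)]
}

#' Infer connectivity of the size-(n+1) network from size n
#'
#' If the size-n genotype network is connected and every size-(n+1) member
#' is a superset of some size-n member, the size-(n+1) network is connected
#' as well (supersets of viable genotypes are viable, and the added reaction
#' can be swapped stepwise along any size-n path).  The precondition is
#' checked; when it fails the inference is refused and a direct BFS is run
#' instead.
#'
#' @param gs_n fixed-size \code{genotype_set} at size n (must be connected).
#' @param gs_n1 fixed-size \code{genotype_set} at size n+1 over the same
#'   universe.
#' @return list with \code{connected} (logical), \code{method}
#'   (\code{"inferred"} or \code{"bfs"}), and \code{precondition_held}.
#' @export
connectivity_inheritance <- function(gs_n, gs_n1) {
  if (!length(gs_n1$members)) stop("the size-(n+1) genotype set is empty")
  cc_n <- connected_components(gs_n)
  if (cc_n$n_components != 1L)
    stop("size-n network is not connected; inheritance does not apply")
  member_set <- new.env(hash = TRUE, parent = emptyenv())
  for (m in gs_n$members) assign(as.character(m), TRUE, envir = member_set)
  covered <- vapply(gs_n1$members, function(m) {
    bits <- which(bitwAnd(m, bitwShiftL(1L, 0:29)) != 0L)
    for (b in bits)
      if (!is.null(get0(as.character(m - bitwShiftL(1L, b - 1L)),
                        envir = member_set, ifnotfound = NULL)))
        return(TRUE)
    FALSE
  }, logical(1))
  if (all(covered)) {
    list(connected = TRUE, method = "inferred", precondition_held = TRUE)
  } else {
    cc <- connected_components(gs_n1)
    list(connected = cc$n_components == 1L, method = "bfs",
         precondition_held = FALSE)
  }
}

#' Diameter of a genotype network
#'
#' Maximum swap distance between members of one connected component (the
#' giant component when the set fragments, which is the reported convention).
#' Exhaustive all-pairs scan up to \code{exact_cap} members; above that a
#' seeded without-replacement sample of \code{sample_cap} members yields a
#' lower bound.  The maximum possible value at size n in an N-universe is
#' \code{min(n, N - n)}.
#'
#' @param gs fixed-size \code{genotype_set}.
#' @param sample_cap sample size for the lower-bound estimate.
#' @param exact_cap largest component size for which the exact all-pairs
#'   scan is used.
#' @param seed RNG seed for the sampled mode.
#' @return list with \code{value} (swaps), \code{mode} (\code{"exact"} or
#'   \code{"sampled_lower_bound"}), \code{sample_size}, \code{max_possible}.
#' @export
diameter <- function(gs, sample_cap = 1e5, exact_cap = 1e5, seed = 42) {
  masks <- giant_component_masks(gs)
  n <- unique(.popcount_cpp(masks))
  stopifnot(length(n) == 1)
  maxpos <- min(n, gs$N - n)
  if (length(masks) <= exact_cap) {
    val <- if (length(masks) > 1) .max_pair_distance_cpp(masks) %/% 2L else 0L
    return(list(value = val, mode = "exact", sample_size = NA_integer_,
                max_possible = maxpos))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  smp <- sample(masks, min(sample_cap, length(masks)))
  list(value = .max_pair_distance_cpp(smp) %/% 2L,
       mode = "sampled_lower_bound", sample_size = length(smp),
       max_possible = maxpos)
}

#' Maximum possible genotype-network diameter
#'
#' The diameter of genotype space itself at metabolism size n in a universe
#' of N reactions: \code{min(n, N - n)} reaction swaps.
#'
#' @param N universe size.
#' @param n metabolism size.
#' @return integer.
#' @export
max_diameter <- function(N, n) pmin(n, N - n)

#' All member pairs at maximal distance
#'
#' @param gs fixed-size \code{genotype_set} (giant component used when
#'   fragmented).
#' @return list with \code{distance} (the diameter, swaps) and \code{pairs}
#'   (two-column matrix of member masks).
#' @export
max_distance_pairs <- function(gs) {
  masks <- giant_component_masks(gs)
  if (length(masks) < 2)
    return(list(distance = 0L, pairs = matrix(integer(0), 0, 2)))
  h <- .max_pair_distance_cpp(masks)
  pr <- .pairs_at_distance_cpp(masks, h)
  list(distance = h %/% 2L,
       pairs = cbind(masks[pr[, 1]], masks[pr[, 2]]))
}

#' Filter maximal-distance pairs by co-factor isoform usage
#'
#' A pair of genotypes at maximal distance is eliminated when, for any
#' declared co-factor reaction pair, one genotype uses one isoform (and not
#' the other) while the second genotype uses the opposite isoform: such
#' pairs owe part of their distance to a chemically trivial co-factor swap.
#' Returns the percentage of pairs that remain.
#'
#' @param pairs two-column matrix of genotype masks (as from
#'   [max_distance_pairs()]).
#' @param u the \code{reaction_universe} declaring \code{cofactor_pairs}.
#' @return list with \code{percent_remaining} and \code{kept} (logical per
#'   pair).
#' @export
cofactor_pair_filter <- function(pairs, u) {
  if (!nrow(pairs))
    return(list(percent_remaining = NA_real_, kept = logical(0)))
  internal_ids <- u$reaction_ids[u$internal_idx]
  bit_of <- function(id) bitwShiftL(1L, match(id, internal_ids) - 1L)
  kept <- rep(TRUE, nrow(pairs))
  for (cp in u$cofactor_pairs) {
    b1 <- bit_of(cp[1]); b2 <- bit_of(cp[2])
    has <- function(m, b) bitwAnd(m, b) != 0L
    for (r in seq_len(nrow(pairs))) {
      g1 <- pairs[r, 1]; g2 <- pairs[r, 2]
      opp <- (has(g1, b1) && !has(g1, b2) && has(g2, b2) && !has(g2, b1)) ||
             (has(g1, b2) && !has(g1, b1) && has(g2, b1) && !has(g2, b2))
      if (opp) kept[r] <- FALSE
    }
  }
  list(percent_remaining = 100 * mean(kept), kept = kept)
}

#' Minimum total blocked-reaction count over maximal-distance pairs
#'
#' For each genotype pair at maximal distance, sums the blocked-reaction
#' counts of both members and returns the minimum over pairs; zero means at
#' least one maximally distant pair owes nothing to blocked reactions.
#'
#' @param pairs two-column matrix of genotype masks.
#' @param u the universe.
#' @param env the environment.
#' @return integer minimum, or NA for an empty pair list.
#' @export
blocked_at_max_distance <- function(pairs, u, env) {
  if (!nrow(pairs)) return(NA_integer_)
  N <- universe_N(u)
  counts <- new.env(hash = TRUE, parent = emptyenv())
  blocked_count <- function(m) {
    key <- as.character(m)
    hit <- get0(key, envir = counts, ifnotfound = NULL)
    if (!is.null(hit)) return(hit)
    v <- length(blocked_reactions(u, mask_to_bits(m, N), env))
    assign(key, v, envir = counts)
    v
  }
  min(vapply(seq_len(nrow(pairs)), function(r)
    blocked_count(pairs[r, 1]) + blocked_count(pairs[r, 2]), numeric(1)))
}
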