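# Distances between genotype networks of different phenotypes, complexity
# aggregation, and genotype-versus-phenotype distance distributions.

#' Minimal distance between two genotype networks
#'
#' \eqn{D_{min} = \min \{ D(G_1, G_2) : G_1 \in GN_1, G_2 \in GN_2 \}}, the
#' minimal number of reaction changes converting a metabolism with one
#' phenotype into one with the other.  Identity (shared member) gives 0; an
#' adjacency test through the (n-1)-subset index detects \eqn{D_{min} = 1}
#' in near-linear time; otherwise the exact minimum is taken over all cross
#' pairs.  For fragmented sets the scan is restricted to the giant
#' components when \code{component = "giant"} (the convention for large
#' fragmented sets); small sets default to all components.
#'
#' @param gn1,gn2 fixed-size \code{genotype_set}s over the same universe.
#' @param component \code{"auto"} (giant only when a set exceeds
#'   \code{auto_cap} members), \code{"all"}, or \code{"giant"}.
#' @param auto_cap member-count threshold for \code{"auto"}.
#' @return integer \eqn{D_{min}} in reaction swaps.
#' @export
min_network_distance <- function(gn1, gn2, component = c("auto", "all", "giant"),
                                 auto_cap = 1e4) {
  component <- match.arg(component)
  m1 <- gn1$members; m2 <- gn2$members
  use_giant <- component == "giant" ||
    (component == "auto" && (length(m1) > auto_cap || length(m2) > auto_cap))
  if (use_giant) {
    m1 <- giant_component_masks(gn1)
    m2 <- giant_component_masks(gn2)
  }
  if (!length(m1) || !length(m2)) return(NA_integer_)
  if (any(m1 %in% m2)) return(0L)
  # adjacency shortcut: some cross pair shares an (n-1)-subset <=> D_min = 1
  idx <- build_subset_index(m1)
  for (m in m2) {
    bits <- which(bitwAnd(m, bitwShiftL(1L, 0:29)) != 0L)
    for (b in bits)
      if (length(get0(as.character(m - bitwShiftL(1L, b - 1L)),
                      envir = idx, ifnotfound = integer(0))))
        return(1L)
  }
  .cross_min_distance_cpp(m1, m2) %/% 2L
}

#' Average minimal distances by phenotypic complexity
#'
#' Given genotype networks of exclusive phenotypes at one size, computes the
#' minimal distance for every pair of distinct networks and aggregates by
#' the phenotypic complexities (k, k') of the pair: mean \eqn{D_{min}} and
#' the fraction of pairs that are neighbours (\eqn{D_{min} = 1}).
#'
#' @param sets named list of fixed-size \code{genotype_set}s with exclusive
#'   criteria; complexity k of each is \code{length(criterion$sources)}.
#' @param component passed to [min_network_distance()].
#' @return list with \code{pairs} (data frame: net1, net2, k1, k2, D_min),
#'   \code{by_complexity} (data frame: k1, k2, mean_D_min,
#'   neighbor_fraction, n_pairs).
#' @export
complexity_matrix <- function(sets, component = "auto") {
  sets <- sets[vapply(sets, function(s) length(s$members) > 0, logical(1))]
  nm <- names(sets)
  stopifnot(length(nm) >= 2)
  ks <- vapply(sets, function(s) length(s$criterion$sources), integer(1))
  pr <- utils::combn(length(sets), 2)
  pairs <- data.frame(
    net1 = nm[pr[1, ]], net2 = nm[pr[2, ]],
    k1 = ks[pr[1, ]], k2 = ks[pr[2, ]],
    D_min = vapply(seq_len(ncol(pr)), function(c)
      as.integer(min_network_distance(sets[[pr[1, c]]], sets[[pr[2, c]]],
                                      component = component)),
      integer(1)),
    stringsAsFactors = FALSE)
  key <- paste(pmin(pairs$k1, pairs$k2), pmax(pairs$k1, pairs$k2))
  agg <- do.call(rbind, lapply(unique(key), function(kk) {
    sel <- key == kk
    data.frame(k1 = as.integer(strsplit(kk, " ")[[1]][1]),
               k2 = as.integer(strsplit(kk, " ")[[1]][2]),
               mean_D_min = mean(pairs$D_min[sel]),
               neighbor_fraction = mean(pairs$D_min[sel] == 1L),
               n_pairs = sum(sel))
  }))
  list(pairs = pairs, by_complexity = agg)
}

#' Genotype distance versus phenotype distance
#'
#' For a seeded sample of focal genotypes at one size, computes the swap
#' distance \eqn{D_G} and the phenotype Hamming distance \eqn{D_P} against
#' every same-size viable genotype, and histograms \eqn{D_G} within each
#' \eqn{D_P} stratum (\eqn{D_P = 0} collects same-phenotype pairs).
#'
#' @param members integer mask vector of all same-size viable genotypes.
#' @param phenotypes character vector of phenotype keys (e.g. "1010"),
#'   parallel to \code{members}.
#' @param sample_size number of focal genotypes (without replacement).
#' @param seed RNG seed.
#' @return list with \code{table} (data frame: D_P, D_G, count) and
#'   \code{mean_D_G} (data frame: D_P, mean D_G).
#' @export
genotype_vs_phenotype <- function(members, phenotypes, sample_size = 100,
                                  seed = 42) {
  stopifnot(length(members) == length(phenotypes), length(members) >= 2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  foc <- sample(seq_along(members), min(sample_size, length(members)))
  pbits <- lapply(strsplit(phenotypes, ""), as.integer)
  acc <- list()
  for (i in foc) {
    dg <- .hamming_to_all_cpp(members[i], members) %/% 2L
    dp <- vapply(pbits, function(p) sum(p != pbits[[i]]), integer(1))
    keep <- seq_along(members) != i
    acc[[length(acc) + 1L]] <- data.frame(D_P = dp[keep], D_G = dg[keep])
  }
  all_d <- do.call(rbind, acc)
  tab <- stats::aggregate(list(count = all_d$D_P),
                          by = list(D_P = all_d$D_P, D_G = all_d$D_G), length)
  mn <- stats::aggregate(list(mean_D_G = all_d$D_G),
                         by = list(D_P = all_d$D_P), mean)
  list(table = tab[order(tab$D_P, tab$D_G), ], mean_D_G = mn)
}
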