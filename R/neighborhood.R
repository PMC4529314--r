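# Innovation potential of 1-neighbourhoods: novel phenotypes reachable by a
# single reaction change, the uniqueness statistic u of neighbourhood pairs,
# and randomisation nulls.

#' Novel phenotypes in the 1-neighbourhood of a genotype
#'
#' The neighbourhood of a metabolism is the set of genotypes differing in
#' exactly one reaction (one addition or one deletion).  A neighbourhood
#' phenotype is novel when it confers viability on at least one carbon
#' source the focal metabolism lacks.  Returns the set of distinct novel
#' phenotypes.
#'
#' @param u a [reaction_universe()].
#' @param g focal genotype bit vector.
#' @param panel an [environment_panel()].
#' @param threshold_fraction viability threshold fraction.
#' @return list with \code{focal_phenotype}, \code{novel} (list of phenotype
#'   bit vectors), \code{n_novel}.
#' @export
novel_phenotypes <- function(u, g, panel, threshold_fraction = 0.01) {
  N <- universe_N(u)
  stopifnot(length(g) == N)
  focal <- phenotype(u, g, panel, threshold_fraction)
  nb <- matrix(rep(as.integer(g), each = N), N, N)
  diag(nb) <- 1L - diag(nb)
  phen <- matrix(0L, N, length(panel))
  for (e in seq_along(panel)) {
    ref <- reference_rate(u, panel[[e]])
    phen[, e] <- as.integer(
      biomass_batch(u, nb, panel[[e]]) > threshold_fraction * ref)
  }
  keys <- apply(phen, 1, paste, collapse = "")
  gains <- apply(phen, 1, function(p) any(p == 1L & focal == 0L))
  uniq <- !duplicated(keys) & gains
  list(focal_phenotype = focal,
       novel = lapply(which(uniq), function(r) phen[r, ]),
       n_novel = sum(uniq))
}

phenotype_key <- function(p) paste(p, collapse = "")

#' Neighbourhood diversity of a genotype pair
#'
#' The fraction of novel phenotypes unique to either neighbourhood:
#' \eqn{u = 1 - |P_1 \cap P_2| / (|P_1| + |P_2| - |P_1 \cap P_2|)}, the
#' complement of the Jaccard index of the two novel-phenotype sets.  When
#' both sets are empty the statistic is 0/0 and reported as NA with
#' \code{defined = FALSE}.
#'
#' @param ns1,ns2 results of [novel_phenotypes()] for the two genotypes.
#' @return list with \code{u}, \code{defined}.
#' @export
pair_diversity <- function(ns1, ns2) {
  p1 <- unique(vapply(ns1$novel, phenotype_key, character(1)))
  p2 <- unique(vapply(ns2$novel, phenotype_key, character(1)))
  un <- length(union(p1, p2))
  if (un == 0) return(list(u = NA_real_, defined = FALSE))
  list(u = 1 - length(intersect(p1, p2)) / un, defined = TRUE)
}

#' Sample genotype pairs at an exact swap distance
#'
#' Seeded uniform sampling of unordered member pairs of a fixed-size set at
#' swap distance exactly D.  At desk scale the pair list is enumerated and
#' sampled without replacement (with replacement once \code{count} exceeds
#' the number of distinct pairs).
#'
#' @param gs fixed-size \code{genotype_set}.
#' @param D swap distance.
#' @param count number of pairs requested.
#' @param seed RNG seed.
#' @return two-column matrix of member masks (possibly 0 rows, with a
#'   warning, when no pair attains D).
#' @export
sample_pairs_at_distance <- function(gs, D, count, seed = 42) {
  pr <- .pairs_at_distance_cpp(gs$members, 2L * D)
  if (!nrow(pr)) {
    warning("no member pairs at swap distance ", D)
    return(matrix(integer(0), 0, 2))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  take <- if (count <= nrow(pr)) sample(nrow(pr), count)
          else sample(nrow(pr), count, replace = TRUE)
  cbind(gs$members[pr[take, 1]], gs$members[pr[take, 2]])
}

#' Mean neighbourhood diversity as a function of distance
#'
#' Averages [pair_diversity()] over sampled member pairs for each swap
#' distance in \code{D_range}; pairs whose two novel-phenotype sets are both
#' empty are excluded from the mean and counted separately.
#'
#' @param gs fixed-size \code{genotype_set}.
#' @param u the universe.
#' @param panel the environment panel.
#' @param D_range integer vector of swap distances.
#' @param pairs pairs sampled per distance.
#' @param seed RNG seed.
#' @param threshold_fraction viability threshold fraction.
#' @return data frame with columns \code{D}, \code{mean_u}, \code{n_pairs},
#'   \code{n_undefined}.
#' @export
diversity_curve <- function(gs, u, panel, D_range, pairs = 30, seed = 42,
                            threshold_fraction = 0.01) {
  cache <- new.env(hash = TRUE, parent = emptyenv())
  ns_of <- function(mask) {
    key <- as.character(mask)
    hit <- get0(key, envir = cache, ifnotfound = NULL)
    if (!is.null(hit)) return(hit)
    v <- novel_phenotypes(u, mask_to_bits(mask, gs$N), panel,
                          threshold_fraction)
    assign(key, v, envir = cache)
    v
  }
  rows <- lapply(D_range, function(D) {
    if (D == 0) {
      # identical pair: P1 = P2, u = 0 whenever defined
      smp <- cbind(gs$members, gs$members)
      if (nrow(smp) > pairs) {
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        set.seed(seed)
        smp <- smp[sample(nrow(smp), pairs), , drop = FALSE]
        if (is.null(old)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old, envir = globalenv())
      }
    } else {
      smp <- suppressWarnings(
        sample_pairs_at_distance(gs, D, pairs, seed = seed + D))
    }
    if (!nrow(smp))
      return(data.frame(D = D, mean_u = NA_real_, n_pairs = 0L,
                        n_undefined = 0L))
    us <- vapply(seq_len(nrow(smp)), function(r) {
      pd <- pair_diversity(ns_of(smp[r, 1]), ns_of(smp[r, 2]))
      if (pd$defined) pd$u else NA_real_
    }, numeric(1))
    data.frame(D = D, mean_u = mean(us, na.rm = TRUE),
               n_pairs = sum(!is.na(us)), n_undefined = sum(is.na(us)))
  })
  do.call(rbind, rows)
}

#' Randomisation null for neighbourhood statistics
#'
#' Compares an observed neighbourhood statistic against a size-matched
#' phenotype-resampling null: for each focal metabolism the surrogate
#' neighbourhood phenotypes are drawn uniformly from the empirical phenotype
#' distribution of all genotypes of the same size, keeping the neighbourhood
#' size fixed.  For \code{stat = "novel_count"} the statistic is the mean
#' number of distinct novel phenotypes per focal; for \code{stat = "u"} it
#' is the mean diversity over sampled focal pairs at distance \code{D}.
#' The empirical p-value is the fraction of null replicates at least as
#' large as the observed statistic.
#'
#' @param gs fixed-size \code{genotype_set}.
#' @param u the universe.
#' @param panel the environment panel.
#' @param stat \code{"novel_count"} or \code{"u"}.
#' @param reps number of null replicates (> 0).
#' @param seed RNG seed.
#' @param focals number of focal genotypes (or pairs) used.
#' @param D swap distance of pairs for \code{stat = "u"}.
#' @param threshold_fraction viability threshold fraction.
#' @return list with \code{observed}, \code{null} (numeric vector),
#'   \code{p_upper}, \code{defined}.
#' @export
randomization_null <- function(gs, u, panel, stat = c("novel_count", "u"),
                               reps = 100, seed = 42, focals = 20, D = 1,
                               threshold_fraction = 0.01) {
  stat <- match.arg(stat)
  if (reps <= 0) stop("reps must be positive")
  N <- gs$N
  # empirical phenotype distribution of the size class
  class_phen <- vapply(gs$members, function(m)
    phenotype_key(phenotype(u, mask_to_bits(m, N), panel,
                            threshold_fraction)),
    character(1))
  if (length(unique(class_phen)) < 1 ||
      (length(class_phen) > 1 && length(unique(class_phen)) == 1 &&
       stat == "novel_count")) {
    # degenerate distribution: every draw identical, null has no spread
  }
  split_key <- function(k) as.integer(strsplit(k, "")[[1]])

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  novel_from_keys <- function(focal, keys) {
    ph <- lapply(unique(keys), split_key)
    sum(vapply(ph, function(p) any(p == 1L & focal == 0L), logical(1)))
  }

  if (stat == "novel_count") {
    foc <- sample(gs$members, min(focals, length(gs$members)))
    obs_list <- lapply(foc, function(m)
      novel_phenotypes(u, mask_to_bits(m, N), panel, threshold_fraction))
    observed <- mean(vapply(obs_list, `[[`, numeric(1), "n_novel"))
    nb_size <- N
    null <- vapply(seq_len(reps), function(r) {
      mean(vapply(seq_along(foc), function(i) {
        keys <- sample(class_phen, nb_size, replace = TRUE)
        novel_from_keys(obs_list[[i]]$focal_phenotype, keys)
      }, numeric(1)))
    }, numeric(1))
  } else {
    smp <- suppressWarnings(sample_pairs_at_distance(gs, D, focals, seed = seed))
    if (!nrow(smp))
      return(list(observed = NA_real_, null = numeric(0),
                  p_upper = NA_real_, defined = FALSE))
    obs_u <- vapply(seq_len(nrow(smp)), function(r) {
      pd <- pair_diversity(
        novel_phenotypes(u, mask_to_bits(smp[r, 1], N), panel,
                         threshold_fraction),
        novel_phenotypes(u, mask_to_bits(smp[r, 2], N), panel,
                         threshold_fraction))
      if (pd$defined) pd$u else NA_real_
    }, numeric(1))
    observed <- mean(obs_u, na.rm = TRUE)
    nb_size <- N
    null <- vapply(seq_len(reps), function(r) {
      us <- vapply(seq_len(nrow(smp)), function(i) {
        k1 <- unique(sample(class_phen, nb_size, replace = TRUE))
        k2 <- unique(sample(class_phen, nb_size, replace = TRUE))
        un <- length(union(k1, k2))
        if (!un) return(NA_real_)
        1 - length(intersect(k1, k2)) / un
      }, numeric(1))
      mean(us, na.rm = TRUE)
    }, numeric(1))
  }
  if (all(!is.finite(null)) || is.na(observed))
    return(list(observed = observed, null = null, p_upper = NA_real_,
                defined = FALSE))
  list(observed = observed, null = null,
       p_upper = mean(null >= observed), defined = TRUE)
}
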