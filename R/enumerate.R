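# Exhaustive enumeration of viable genotypes.  Genotype sets are stored as
# integer bitmasks over the internal-reaction positions (N <= 30 at desk
# scale; the full-scale engine would swap in wider words, the algorithms are
# unchanged).

#' Viability criteria for genotype sets
#'
#' \code{at_least(S)} selects genotypes viable on every carbon source in
#' \code{S} (they may be viable on others too); \code{exclusively(S)}
#' additionally requires inviability on every environment not in \code{S}.
#' \code{at_least(character(0))} is vacuous (all genotypes);
#' \code{exclusively(character(0))} selects the genotypes viable nowhere.
#'
#' @param sources character vector of environment names (subset of the
#'   panel's names).
#' @return a \code{viability_criterion} object.
#' @export
at_least <- function(sources = character(0)) {
  structure(list(type = "at_least", sources = sources),
            class = "viability_criterion")
}

#' @rdname at_least
#' @export
exclusively <- function(sources = character(0)) {
  structure(list(type = "exclusively", sources = sources),
            class = "viability_criterion")
}

criterion_label <- function(criterion) {
  paste0(criterion$type, ":",
         paste(criterion$sources, collapse = "+"))
}

check_criterion <- function(criterion, panel) {
  stopifnot(inherits(criterion, "viability_criterion"))
  bad <- setdiff(criterion$sources, names(panel))
  if (length(bad))
    stop("criterion names unknown environment(s): ", paste(bad, collapse = ", "))
  invisible(criterion)
}

new_genotype_set <- function(u, criterion, members, bit_order = NULL) {
  structure(list(
    N = universe_N(u),
    universe_uid = attr(u, "uid"),
    bit_order = if (is.null(bit_order)) u$reaction_ids[u$internal_idx] else bit_order,
    criterion = criterion,
    members = sort(unique(as.integer(members)))
  ), class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat(sprintf("genotype set: %d members, N = %d, criterion %s\n",
              length(x$members), x$N, criterion_label(x$criterion)))
  invisible(x)
}

#' Members of a genotype set at one size
#' @param gs a \code{genotype_set}.
#' @param n metabolism size (number of present reactions).
#' @return a \code{genotype_set} restricted to size-n members.
#' @export
filter_size <- function(gs, n) {
  keep <- .popcount_cpp(gs$members) == n
  out <- gs
  out$members <- gs$members[keep]
  out$size <- n
  out
}

# viability of masks under a criterion, with environment-by-environment
# short-circuiting for the required part
criterion_filter <- function(u, masks, panel, criterion,
                             threshold_fraction = 0.01) {
  keep <- masks
  for (nm in criterion$sources)
    keep <- keep[viable_masks(u, keep, panel[[nm]], threshold_fraction)]
  if (criterion$type == "exclusively") {
    for (nm in setdiff(names(panel), criterion$sources))
      keep <- keep[!viable_masks(u, keep, panel[[nm]], threshold_fraction)]
    if (!length(criterion$sources)) {
      # viable nowhere: the loop above already did the work
    }
  }
  keep
}

#' Enumerate viable genotypes by brute force
#'
#' Tests all \code{2^N} genotypes with one FBA call per (genotype,
#' required environment); exact but exponential, guarded to \code{N <= 20}.
#' Serves as the oracle for [enumerate_divide_merge()].
#'
#' @param u a [reaction_universe()].
#' @param panel an [environment_panel()].
#' @param criterion an [at_least()] or [exclusively()] criterion.
#' @param threshold_fraction viability threshold fraction.
#' @return a \code{genotype_set}.
#' @export
enumerate_bruteforce <- function(u, panel, criterion,
                                 threshold_fraction = 0.01) {
  check_criterion(criterion, panel)
  N <- universe_N(u)
  if (N > 20L) stop("brute force enumeration is guarded to N <= 20")
  masks <- if (N == 0L) integer(0) else 0:(2^N - 1)
  keep <- criterion_filter(u, masks, panel, criterion, threshold_fraction)
  new_genotype_set(u, criterion, keep)
}

#' Enumerate viable genotypes by divide-and-merge with monotone pruning
#'
#' Implements the scalable enumeration strategy: (1) reactions essential for
#' the required sources are pre-fixed to one (no genotype lacking them can
#' satisfy the criterion); (2) the remaining free bit positions are split
#' into \code{blocks} contiguous blocks; (3) each block pattern is tested
#' with all unresolved free bits set to one -- by monotonicity (deleting
#' reactions from an inviable metabolism cannot restore viability) a partial
#' pattern whose most-permissive completion is inviable has no viable
#' completion and the whole sub-cube is pruned; (4) surviving patterns are
#' merged block-pair-wise left to right, re-testing permissive completions,
#' until fully resolved.  The final stage tests complete genotypes, so the
#' result equals [enumerate_bruteforce()] exactly.
#'
#' For an \code{exclusively} criterion the required part is enumerated as
#' above and the exclusions are applied as a final filter (inviability is not
#' monotone under deletion, so it cannot prune).
#'
#' @inheritParams enumerate_bruteforce
#' @param blocks number of contiguous blocks the free positions are split
#'   into (the full-scale configuration used 5 blocks of 9 over 45 free
#'   bits).
#' @param counts if TRUE, attach the number of viability tests performed as
#'   attribute \code{n_tests} (observability of the pruning factor).
#' @return a \code{genotype_set}; equal to brute force on the same inputs.
#' @export
enumerate_divide_merge <- function(u, panel, criterion, blocks = 2,
                                   threshold_fraction = 0.01, counts = FALSE) {
  check_criterion(criterion, panel)
  if (!length(criterion$sources))
    stop("divide-and-merge requires a criterion with at least one source; ",
         "use enumerate_bruteforce() for vacuous criteria")
  N <- universe_N(u)
  required <- panel[criterion$sources]
  n_tests <- 0L
  test <- function(masks) {
    # viable on all required sources, with short-circuit
    keep <- rep(TRUE, length(masks))
    for (env in required) {
      idx <- which(keep)
      if (!length(idx)) break
      v <- viable_masks(u, masks[idx], env, threshold_fraction)
      n_tests <<- n_tests + length(idx)
      keep[idx] <- v
    }
    keep
  }

  full_mask <- bits_to_mask(rep(1L, N))
  if (!test(full_mask)) {
    out <- new_genotype_set(u, criterion, integer(0))
    if (counts) attr(out, "n_tests") <- n_tests
    return(out)
  }

  ess <- criterion_essential(u, required, threshold_fraction)
  ess_mask <- if (length(ess)) bits_to_mask(as.integer(seq_len(N) %in% ess)) else 0L
  free <- setdiff(seq_len(N), ess)

  if (!length(free)) {
    survivors <- ess_mask
  } else {
    blocks <- max(1L, min(as.integer(blocks), length(free)))
    block_of <- split(free, cut(seq_along(free), blocks, labels = FALSE))
    # all submasks over a set of bit positions
    submasks <- function(positions) {
      ms <- 0L
      for (p in positions) ms <- c(ms, bitwOr(ms, bitwShiftL(1L, p - 1L)))
      ms
    }
    rest_mask <- function(done_positions) {
      rest <- setdiff(free, done_positions)
      if (!length(rest)) 0L else
        Reduce(bitwOr, bitwShiftL(1L, rest - 1L), 0L)
    }
    done <- integer(0)
    survivors <- 0L
    for (b in seq_along(block_of)) {
      pats <- submasks(block_of[[b]])
      cand <- as.integer(outer(survivors, pats, bitwOr))
      done <- c(done, block_of[[b]])
      permissive <- bitwOr(bitwOr(cand, ess_mask), rest_mask(done))
      survivors <- cand[test(permissive)]
      if (!length(survivors)) break
    }
    survivors <- bitwOr(survivors, ess_mask)
  }

  if (criterion$type == "exclusively") {
    for (nm in setdiff(names(panel), criterion$sources)) {
      if (!length(survivors)) break
      v <- viable_masks(u, survivors, panel[[nm]], threshold_fraction)
      n_tests <- n_tests + length(survivors)
      survivors <- survivors[!v]
    }
  }
  out <- new_genotype_set(u, criterion, survivors)
  if (counts) attr(out, "n_tests") <- n_tests
  out
}

#' Per-size counts and fractions of a genotype set
#'
#' @param gs a \code{genotype_set}.
#' @return data frame with columns \code{n}, \code{count}, \code{fraction}
#'   (count / choose(N, n)); attribute \code{n_min} records the smallest
#'   size with a member (NA for an empty set).
#' @export
size_histogram <- function(gs) {
  N <- gs$N
  sizes <- .popcount_cpp(gs$members)
  count <- vapply(0:N, function(n) sum(sizes == n), integer(1))
  out <- data.frame(n = 0:N, count = count,
                    fraction = count / choose(N, 0:N))
  attr(out, "n_min") <- if (length(sizes)) min(sizes) else NA_integer_
  out
}

#' Binomial lower-bound predictor of viable counts
#'
#' Every superset of a viable minimal metabolism is viable, and there are
#' \code{choose(N - n_min, n - n_min)} ways of adding \code{n - n_min}
#' reactions to a fixed size-\code{n_min} witness; this predicts the
#' qualitative unimodal shape of the per-size counts and is a lower bound
#' whenever a minimal witness exists.
#'
#' @param N universe size.
#' @param n_min minimal viable size.
#' @param n metabolism size, \code{n >= n_min}.
#' @return \code{choose(N - n_min, n - n_min)}.
#' @export
binomial_prediction <- function(N, n_min, n) {
  stopifnot(n >= n_min, n_min >= 0, N >= n)
  choose(N - n_min, n - n_min)
}

#' Realized phenotype table and carbon-source implications
#'
#' Given the enumerated viable sets per single carbon source, assigns each
#' genotype in their union its phenotype vector (one membership bit per
#' source, in panel order), counts genotypes per realized phenotype, and
#' detects implications between sources: source \code{i} implies source
#' \code{j} when every genotype viable on \code{i} is viable on \code{j}.
#' Each ordered implication forbids \code{2^(panel size - 2)} phenotypes
#' (those viable on \code{i} but not \code{j}).
#'
#' @param viable_sets named list of \code{genotype_set}s, one per panel
#'   environment, in panel order (criteria \code{at_least(source)}).
#' @return list with \code{phenotypes} (data frame: phenotype string, count,
#'   complexity k), \code{implications} (data frame: from, to,
#'   forbidden_phenotypes), and \code{n_realized} counting distinct realized
#'   phenotypes among genotypes viable on at least one source.
#' @export
phenotype_table <- function(viable_sets) {
  p <- length(viable_sets)
  stopifnot(p >= 1)
  all_members <- sort(unique(unlist(lapply(viable_sets, `[[`, "members"))))
  member_of <- vapply(viable_sets, function(gs)
    all_members %in% gs$members, logical(max(1L, length(all_members))))
  if (length(all_members) == 1L) member_of <- matrix(member_of, nrow = 1)
  pheno <- apply(member_of, 1, function(b) paste(as.integer(b), collapse = ""))
  tab <- table(pheno)
  phenotypes <- data.frame(phenotype = names(tab),
                           count = as.integer(tab),
                           stringsAsFactors = FALSE)
  # the all-zero phenotype class (viable nowhere) is realized by every
  # genotype outside the union of the viable sets
  N <- viable_sets[[1]]$N
  zeros <- paste(rep("0", p), collapse = "")
  n_zero <- if (N <= 30) 2^N - length(all_members) else NA_real_
  if (!is.na(n_zero) && n_zero > 0 && !zeros %in% phenotypes$phenotype)
    phenotypes <- rbind(phenotypes,
                        data.frame(phenotype = zeros, count = n_zero,
                                   stringsAsFactors = FALSE))
  phenotypes$k <- vapply(strsplit(phenotypes$phenotype, ""),
                         function(x) sum(x == "1"), integer(1))
  phenotypes <- phenotypes[order(-phenotypes$count), ]
  rownames(phenotypes) <- NULL

  imp <- data.frame(from = character(0), to = character(0),
                    forbidden_phenotypes = numeric(0),
                    stringsAsFactors = FALSE)
  nms <- names(viable_sets)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    gi <- viable_sets[[i]]$members; gj <- viable_sets[[j]]$members
    if (length(gi) && all(gi %in% gj))
      imp <- rbind(imp, data.frame(
        from = nms[i], to = nms[j],
        forbidden_phenotypes = if (p >= 2) 2^(p - 2) else 0,
        stringsAsFactors = FALSE))
  }
  list(phenotypes = phenotypes, implications = imp,
       n_realized = nrow(phenotypes))
}

#' Fraction of viable metabolisms containing disconnected reactions
#'
#' For each member of a genotype set, tests whether it contains at least one
#' topologically disconnected reaction (see [disconnected_reactions()]), and
#' reports the fraction \code{f_d} per metabolism size and overall, together
#' with \code{1 - f_d} (the fraction of fully connected metabolisms).
#'
#' @param gs a \code{genotype_set}.
#' @param u the universe the set was enumerated on.
#' @param env the environment defining nutrient availability.
#' @return list with \code{per_size} (data frame: n, members, with_disconnected,
#'   f_d, connected_fraction) and \code{overall_f_d}.
#' @export
disconnected_fraction <- function(gs, u, env) {
  N <- gs$N
  sizes <- .popcount_cpp(gs$members)
  has_disc <- vapply(gs$members, function(m) {
    g <- mask_to_bits(m, N)
    length(disconnected_reactions(u, g, env)) > 0
  }, logical(1))
  per_size <- do.call(rbind, lapply(sort(unique(sizes)), function(n) {
    sel <- sizes == n
    data.frame(n = n, members = sum(sel),
               with_disconnected = sum(has_disc[sel]),
               f_d = mean(has_disc[sel]),
               connected_fraction = 1 - mean(has_disc[sel]))
  }))
  list(per_size = per_size,
       overall_f_d = if (length(has_disc)) mean(has_disc) else NA_real_)
}
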