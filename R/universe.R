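#' Construct a reaction universe
#'
#' A reaction universe is the fixed arena of a genotype space: a stoichiometric
#' matrix over all candidate reactions, a partition of its columns into
#' variable internal reactions (the genotype bits), always-present transport
#' reactions, exchange reactions (environment interface) and one biomass
#' objective reaction, together with flux bounds, the biomass precursor
#' metabolites and any declared co-factor reaction pairs.
#'
#' The column ordering of the internal reactions defines the genotype bit
#' positions and is serialised with every result the package writes.
#'
#' @param reaction_ids character vector of unique reaction identifiers.
#' @param equations character vector of reaction equations in the tabular
#'   dialect, e.g. \code{"2 A + B -> C"}; reversible reactions use
#'   \code{"<->"}; exchange reactions leave one side empty (\code{"A ->"}).
#' @param reversible logical vector; reversible reactions may carry negative
#'   flux, irreversible reactions must have a non-negative lower bound.
#' @param lb,ub numeric flux bounds (mmol/gDW/h by convention).
#' @param class character vector with entries in \code{internal},
#'   \code{transport}, \code{biomass}, \code{exchange}; exactly one biomass
#'   reaction is required.
#' @param precursor_ids metabolite identifiers that the biomass reaction must
#'   involve (the biomass precursors).
#' @param cofactor_pairs list of length-2 character vectors naming internal
#'   reaction pairs that differ only in the co-factor they use.
#' @param metabolite_ids optional explicit metabolite ordering; defaults to
#'   order of first appearance in the equations.
#'
#' @return an object of class \code{reaction_universe} with fields
#'   \code{metabolite_ids}, \code{reaction_ids}, \code{S} (dense metabolite x
#'   reaction matrix, consumption negative), \code{lb}, \code{ub},
#'   \code{reversible}, \code{class}, \code{internal_idx}, \code{transport_idx},
#'   \code{exchange_idx}, \code{biomass_idx}, \code{precursor_ids},
#'   \code{cofactor_pairs}.
#' @export
reaction_universe <- function(reaction_ids, equations, reversible, lb, ub,
                              class, precursor_ids,
                              cofactor_pairs = list(),
                              metabolite_ids = NULL) {
  n <- length(reaction_ids)
  stopifnot(length(equations) == n, length(reversible) == n,
            length(lb) == n, length(ub) == n, length(class) == n)
  if (anyDuplicated(reaction_ids))
    stop("duplicate reaction identifiers: ",
         paste(unique(reaction_ids[duplicated(reaction_ids)]), collapse = ", "))
  bad_class <- setdiff(unique(class),
                       c("internal", "transport", "biomass", "exchange"))
  if (length(bad_class))
    stop("unknown reaction class: ", paste(bad_class, collapse = ", "))

  parsed <- lapply(equations, parse_equation)
  mets_seen <- unique(unlist(lapply(parsed, function(p) names(p$coef))))
  if (is.null(metabolite_ids)) {
    metabolite_ids <- mets_seen
  } else {
    missing_met <- setdiff(mets_seen, metabolite_ids)
    if (length(missing_met))
      stop("reaction names undeclared metabolite(s): ",
           paste(missing_met, collapse = ", "))
  }

  S <- matrix(0, length(metabolite_ids), n,
              dimnames = list(metabolite_ids, reaction_ids))
  for (j in seq_len(n)) S[names(parsed[[j]]$coef), j] <- parsed[[j]]$coef

  u <- structure(list(
    metabolite_ids = metabolite_ids,
    reaction_ids   = reaction_ids,
    S              = S,
    lb             = as.numeric(lb),
    ub             = as.numeric(ub),
    reversible     = as.logical(reversible),
    class          = class,
    internal_idx   = which(class == "internal"),
    transport_idx  = which(class == "transport"),
    exchange_idx   = which(class == "exchange"),
    biomass_idx    = which(class == "biomass"),
    precursor_ids  = precursor_ids,
    cofactor_pairs = cofactor_pairs
  ), class = "reaction_universe")
  attr(u, "uid") <- .next_uid()
  validate_universe(u)
  u
}

.uid_counter <- new.env(parent = emptyenv())
.next_uid <- function() {
  k <- get0("k", envir = .uid_counter, ifnotfound = 0L) + 1L
  assign("k", k, envir = .uid_counter)
  sprintf("u%06d", k)
}

#' Validate a reaction universe
#'
#' Checks the structural invariants: non-empty reaction columns, consistent
#' bounds (\code{lb <= ub}, irreversible reactions non-negative), disjoint
#' internal/transport classes, exactly one biomass reaction, and every
#' declared precursor carried by the biomass reaction.  Failures name the
#' offending reaction or metabolite.
#'
#' @param u a \code{reaction_universe}.
#' @return \code{u}, invisibly.
#' @export
validate_universe <- function(u) {
  stopifnot(inherits(u, "reaction_universe"))
  if (length(u$biomass_idx) != 1L)
    stop("universe must declare exactly one biomass reaction")
  zero_col <- colSums(u$S != 0) == 0
  if (any(zero_col))
    stop("reaction(s) with empty stoichiometry: ",
         paste(u$reaction_ids[zero_col], collapse = ", "))
  bad_b <- u$lb > u$ub
  if (any(bad_b))
    stop("lb > ub for reaction(s): ",
         paste(u$reaction_ids[bad_b], collapse = ", "))
  # exchanges use negative lower bounds for uptake irrespective of the flag
  chk <- !u$reversible & u$lb < 0 & u$class != "exchange"
  if (any(chk))
    stop("irreversible reaction(s) with negative lower bound: ",
         paste(u$reaction_ids[chk], collapse = ", "))
  if (length(intersect(u$internal_idx, u$transport_idx)))
    stop("internal and transport classes overlap")
  bcol <- u$S[, u$biomass_idx]
  missing_prec <- setdiff(u$precursor_ids, rownames(u$S)[bcol != 0])
  if (length(missing_prec))
    stop("biomass reaction does not involve precursor(s): ",
         paste(missing_prec, collapse = ", "))
  if (!any(bcol[u$precursor_ids] < 0))
    stop("biomass reaction consumes none of the declared precursors")
  for (cp in u$cofactor_pairs) {
    if (length(cp) != 2L || !all(cp %in% u$reaction_ids[u$internal_idx]))
      stop("co-factor pair must name two internal reactions: ",
           paste(cp, collapse = "|"))
  }
  invisible(u)
}

#' @export
print.reaction_universe <- function(x, ...) {
  cat(sprintf(
    "reaction universe: %d metabolites, %d reactions (%d internal, %d transport, %d exchange)\n",
    length(x$metabolite_ids), length(x$reaction_ids),
    length(x$internal_idx), length(x$transport_idx), length(x$exchange_idx)))
  cat(sprintf("biomass: %s over %d precursors; %d co-factor pair(s)\n",
              x$reaction_ids[x$biomass_idx], length(x$precursor_ids),
              length(x$cofactor_pairs)))
  invisible(x)
}

#' Number of variable internal reactions (genotype length)
#' @param u a \code{reaction_universe}.
#' @return integer N.
#' @export
universe_N <- function(u) length(u$internal_idx)

# --- equation parsing ------------------------------------------------------

# "2 A + B -> C" / "A <-> B" / "A ->" (exchange).  Coefficients are optional
# and may be fractional; metabolite ids must not contain spaces or '+'.
parse_equation <- function(eq) {
  rev <- grepl("<->", eq, fixed = TRUE)
  sides <- strsplit(eq, if (rev) "<->" else "->", fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  if (length(sides) != 2L || !grepl("->", eq, fixed = TRUE))
    stop("malformed equation: '", eq, "'")
  term_coefs <- function(side, sign) {
    side <- trimws(side)
    if (side == "") return(numeric(0))
    terms <- trimws(strsplit(side, " + ", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (t in terms) {
      parts <- strsplit(t, "[[:space:]]+")[[1]]
      if (length(parts) == 1L) {
        coef <- 1; met <- parts
      } else if (length(parts) == 2L &&
                 !is.na(suppressWarnings(as.numeric(parts[1])))) {
        coef <- as.numeric(parts[1]); met <- parts[2]
      } else stop("malformed term '", t, "' in equation '", eq, "'")
      out[met] <- (if (is.na(out[met])) 0 else out[met]) + sign * coef
    }
    out
  }
  lhs <- term_coefs(sides[1], -1)
  rhs <- term_coefs(sides[2], +1)
  coef <- lhs
  for (m in names(rhs)) coef[m] <- (if (is.na(coef[m])) 0 else coef[m]) + rhs[m]
  coef <- coef[coef != 0]
  list(coef = coef, reversible = rev)
}

format_equation <- function(col, reversible) {
  fmt <- function(ids, coefs) {
    paste(vapply(seq_along(ids), function(k) {
      if (coefs[k] == 1) ids[k]
      else paste(format(coefs[k], digits = 17, scientific = FALSE), ids[k])
    }, character(1)), collapse = " + ")
  }
  subs <- which(col < 0); prods <- which(col > 0)
  arrow <- if (reversible) "<->" else "->"
  paste(fmt(names(col)[subs], -col[subs]), arrow,
        fmt(names(col)[prods], col[prods]))
}

# --- tabular I/O -----------------------------------------------------------

#' Read a reaction universe from the tabular dialect
#'
#' The tabular model format is a TSV with columns \code{id}, \code{equation},
#' \code{reversible}, \code{lb}, \code{ub}, \code{class}, preceded by optional
#' header directives: \code{# metabolites: a,b,c} (fixes metabolite order),
#' \code{# precursors: ...} and one \code{# cofactor_pair: A|B} line per pair.
#'
#' @param path file path.
#' @param format only \code{"tabular"} is supported natively; SBML input
#'   should be converted to the tabular dialect upstream.
#' @return a validated [reaction_universe()].
#' @export
load_universe <- function(path, format = c("tabular")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  directive <- function(key) {
    m <- grep(paste0("^#[[:space:]]*", key, ":"), hdr, value = TRUE)
    sub(paste0("^#[[:space:]]*", key, ":[[:space:]]*"), "", m)
  }
  mets <- directive("metabolites")
  mets <- if (length(mets)) strsplit(mets[1], ",", fixed = TRUE)[[1]] else NULL
  prec <- directive("precursors")
  prec <- if (length(prec)) strsplit(prec[1], ",", fixed = TRUE)[[1]] else character(0)
  cps <- lapply(directive("cofactor_pair"),
                function(x) strsplit(x, "|", fixed = TRUE)[[1]])
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)],
                           stringsAsFactors = FALSE)
  need <- c("id", "equation", "reversible", "lb", "ub", "class")
  if (!all(need %in% names(tab)))
    stop("model table must have columns: ", paste(need, collapse = ", "))
  reaction_universe(
    reaction_ids = tab$id, equations = tab$equation,
    reversible = as.logical(tab$reversible),
    lb = tab$lb, ub = tab$ub, class = tab$class,
    precursor_ids = prec, cofactor_pairs = cps, metabolite_ids = mets)
}

#' Write a reaction universe in the tabular dialect
#'
#' Round-trips exactly: \code{load_universe(save_universe(u))} reproduces all
#' fields, including metabolite order and bound values to full precision.
#'
#' @param u a \code{reaction_universe}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
save_universe <- function(u, path) {
  validate_universe(u)
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  hdr <- c("# ccmspace reaction universe v1",
           paste0("# metabolites: ", paste(u$metabolite_ids, collapse = ",")),
           paste0("# precursors: ", paste(u$precursor_ids, collapse = ",")),
           vapply(u$cofactor_pairs,
                  function(cp) paste0("# cofactor_pair: ", cp[1], "|", cp[2]),
                  character(1)))
  eqs <- vapply(seq_along(u$reaction_ids), function(j) {
    col <- u$S[, j]; col <- col[col != 0]
    format_equation(col, u$reversible[j])
  }, character(1))
  tab <- data.frame(id = u$reaction_ids, equation = eqs,
                    reversible = u$reversible,
                    lb = num(u$lb), ub = num(u$ub), class = u$class,
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- environments ----------------------------------------------------------

#' Define a minimal growth environment
#'
#' An environment is a sole carbon source plus a fixed complement of shared
#' nutrients, encoded as uptake bounds on exchange reactions: an exchange with
#' uptake bound \code{b} gets lower bound \code{-b} (uptake is negative flux);
#' all other exchanges are closed to uptake but remain open for secretion.
#'
#' @param name environment identifier.
#' @param carbon_source exchange reaction id of the sole carbon source.
#' @param uptake_bounds named numeric vector of maximal uptake rates, one
#'   entry per open exchange; must include \code{carbon_source}.
#' @return an object of class \code{ccm_environment}.
#' @export
environment_def <- function(name, carbon_source, uptake_bounds) {
  if (!carbon_source %in% names(uptake_bounds))
    stop("uptake_bounds must include the carbon source ", carbon_source)
  structure(list(name = name, carbon_source = carbon_source,
                 open_exchanges = names(uptake_bounds),
                 uptake_bounds = uptake_bounds),
            class = "ccm_environment")
}

#' Assemble an ordered panel of environments
#'
#' The ordering is fixed: phenotype bit \code{i} always refers to environment
#' \code{i}.  All environments must share the same non-carbon nutrient set.
#'
#' @param ... \code{ccm_environment} objects, or a single list of them.
#' @return an object of class \code{environment_panel}.
#' @export
environment_panel <- function(...) {
  envs <- list(...)
  if (length(envs) == 1L && !inherits(envs[[1]], "ccm_environment"))
    envs <- envs[[1]]
  stopifnot(all(vapply(envs, inherits, logical(1), "ccm_environment")))
  nm <- vapply(envs, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate environment names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  shared <- lapply(envs, function(e) sort(setdiff(e$open_exchanges, e$carbon_source)))
  if (length(unique(shared)) > 1L)
    stop("shared-nutrient exchanges differ between environments")
  structure(setNames(envs, nm), class = "environment_panel")
}

#' Read an environment panel from TSV
#'
#' Expected columns: \code{environment}, \code{exchange}, \code{bound},
#' \code{role} (\code{carbon} or \code{shared}); one row per open exchange.
#' Environment order follows first appearance in the file.
#'
#' @param path file path.
#' @param universe optional \code{reaction_universe} to validate exchange ids
#'   against.
#' @return an [environment_panel()].
#' @export
load_environments <- function(path, universe = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("environment", "exchange", "bound", "role")
  if (!all(need %in% names(tab)))
    stop("environment table must have columns: ", paste(need, collapse = ", "))
  if (!is.null(universe)) {
    ex_ids <- universe$reaction_ids[universe$exchange_idx]
    bad <- setdiff(unique(tab$exchange), ex_ids)
    if (length(bad))
      stop("environment references absent exchange(s): ",
           paste(bad, collapse = ", "))
  }
  envs <- lapply(unique(tab$environment), function(nm) {
    rows <- tab[tab$environment == nm, ]
    carbon <- rows$exchange[rows$role == "carbon"]
    if (length(carbon) != 1L)
      stop("environment ", nm, " must declare exactly one carbon source")
    environment_def(nm, carbon, setNames(as.numeric(rows$bound), rows$exchange))
  })
  environment_panel(envs)
}

#' Write an environment panel to TSV
#' @param panel an \code{environment_panel}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
save_environments <- function(panel, path) {
  rows <- do.call(rbind, lapply(panel, function(e) {
    data.frame(environment = e$name, exchange = e$open_exchanges,
               bound = e$uptake_bounds[e$open_exchanges],
               role = ifelse(e$open_exchanges == e$carbon_source,
                             "carbon", "shared"),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Flux bounds of the full universe under an environment: exchange uptake
# closed except for the environment's open exchanges.
env_bounds <- function(u, env) {
  lb <- u$lb; ub <- u$ub
  lb[u$exchange_idx] <- pmax(lb[u$exchange_idx], 0)
  open <- match(env$open_exchanges, u$reaction_ids)
  if (anyNA(open))
    stop("environment ", env$name, " references absent exchange(s): ",
         paste(env$open_exchanges[is.na(open)], collapse = ", "))
  lb[open] <- -abs(env$uptake_bounds[env$open_exchanges])
  list(lb = lb, ub = ub)
}

#' Packaged central-carbon-metabolism fixture
#'
#' Loads the reconstructed E. coli central carbon metabolism universe shipped
#' with the package (51 variable internal reactions, 20 fixed transporters,
#' 19 exchanges, biomass over 13 precursors, 3 co-factor pairs) and its
#' 10-carbon-source environment panel.  The universe is derived from the
#' published E. coli core model; see the fixture file header and the methods
#' vignette for the construction.
#'
#' @return list with elements \code{universe} and \code{panel}.
#' @export
ccm_fixture <- function() {
  mdl <- system.file("extdata", "ccm_universe_reconstructed.tsv",
                     package = "ccmspace", mustWork = TRUE)
  env <- system.file("extdata", "ccm_environments.tsv",
                     package = "ccmspace", mustWork = TRUE)
  u <- load_universe(mdl)
  list(universe = u, panel = load_environments(env, u))
}
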