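# End-to-end pipeline: enumerate -> histograms -> phenotype table ->
# genotype-network structure -> neighbourhood diversity -> network distances,
# with all artifacts written as TSV/JSON under an output directory and a
# manifest recording config, bit order and stage provenance.

#' Pipeline configuration
#'
#' @param model path to a tabular universe file (see [load_universe()]).
#' @param environments path to an environment TSV (see
#'   [load_environments()]).
#' @param blocks divide-and-merge block count.
#' @param seed seed for all sampled stages.
#' @param threshold_fraction viability threshold fraction.
#' @param diameter_sample_cap sample cap for diameter estimation.
#' @param diversity_pairs pairs per distance in the diversity curve.
#' @param out_dir output directory.
#' @return a \code{run_config} list.
#' @export
run_config <- function(model, environments, blocks = 2, seed = 42,
                       threshold_fraction = 0.01,
                       diameter_sample_cap = 1e5, diversity_pairs = 20,
                       out_dir = tempfile("ccmspace_run_")) {
  structure(list(model = model, environments = environments,
                 blocks = blocks, seed = seed,
                 threshold_fraction = threshold_fraction,
                 diameter_sample_cap = diameter_sample_cap,
                 diversity_pairs = diversity_pairs, out_dir = out_dir),
            class = "run_config")
}

config_hash <- function(config) {
  core <- config[setdiff(names(config), "out_dir")]
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(core, f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Executes enumeration (per carbon source, divide-and-merge), per-size
#' histograms, the realized-phenotype table with implication detection,
#' connected components and diameters per size, disconnected-reaction
#' fractions, the neighbourhood diversity curve at the most populated size,
#' and minimal inter-network distances for the exclusive single-source
#' phenotypes.  Each stage writes a TSV under \code{config$out_dir}; a
#' manifest (JSON) records the config hash, genotype bit order and the
#' stages run.  Stages whose output already exists under the same config
#' hash are reused.
#'
#' @param config a [run_config()].
#' @return the output directory, invisibly; the manifest is
#'   \code{file.path(out_dir, "manifest.json")}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  u <- load_universe(config$model)
  panel <- load_environments(config$environments, u)
  hash <- config_hash(config)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else
    list(config_hash = "", stages = character(0))
  fresh <- !identical(manifest$config_hash, hash)
  if (fresh) manifest <- list(config_hash = hash, stages = character(0),
                              reused = character(0))
  manifest$bit_order <- u$reaction_ids[u$internal_idx]
  manifest$threshold_fraction <- config$threshold_fraction
  manifest$seed <- config$seed

  out <- function(name) file.path(config$out_dir, name)
  stage_done <- function(name) !fresh && file.exists(out(name))
  note <- function(name, reused = FALSE) {
    manifest$stages <<- union(manifest$stages, name)
    if (reused) manifest$reused <<- union(manifest$reused, name)
  }
  write_tsv <- function(d, name) {
    utils::write.table(d, out(name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  # stage 1: enumeration per carbon source
  sets <- list()
  for (nm in names(panel)) {
    fn <- paste0("set_", nm, ".txt")
    if (stage_done(fn)) {
      members <- as.integer(strtoi(readLines(out(fn))[-1], 16L))
      sets[[nm]] <- new_genotype_set(u, at_least(nm), members)
      note(fn, reused = TRUE)
    } else {
      sets[[nm]] <- enumerate_divide_merge(u, panel, at_least(nm),
                                           blocks = config$blocks,
                                           config$threshold_fraction)
      writeLines(c(paste0("# N=", universe_N(u), " criterion=at_least:", nm),
                   sprintf("%x", sets[[nm]]$members)), out(fn))
      note(fn)
    }
  }

  # stage 2: per-size histograms
  hist_rows <- do.call(rbind, lapply(names(sets), function(nm) {
    h <- size_histogram(sets[[nm]])
    h$criterion <- paste0("at_least:", nm)
    h$n_min <- attr(h, "n_min")
    h[h$count > 0, c("criterion", "n", "count", "fraction", "n_min")]
  }))
  write_tsv(hist_rows, "size_histograms.tsv"); note("size_histograms.tsv")

  # stage 3: phenotype table and implications
  pt <- phenotype_table(sets)
  write_tsv(pt$phenotypes, "phenotypes.tsv")
  write_tsv(pt$implications, "implications.tsv")
  note("phenotypes.tsv"); note("implications.tsv")

  # stage 4: components and diameter per populated size (first source's set
  # spans the union reasonably at toy scale; report per criterion)
  net_rows <- do.call(rbind, lapply(names(sets), function(nm) {
    sizes <- sort(unique(.popcount_cpp(sets[[nm]]$members)))
    do.call(rbind, lapply(sizes, function(n) {
      gsn <- filter_size(sets[[nm]], n)
      cc <- connected_components(gsn)
      di <- diameter(gsn, sample_cap = config$diameter_sample_cap,
                     seed = config$seed)
      data.frame(criterion = paste0("at_least:", nm), n = n,
                 members = length(gsn$members),
                 n_components = cc$n_components,
                 giant_fraction = cc$giant_fraction,
                 diameter = di$value, diameter_mode = di$mode,
                 max_possible = di$max_possible)
    }))
  }))
  write_tsv(net_rows, "networks.tsv"); note("networks.tsv")

  # stage 5: disconnected-reaction fractions per source
  disc_rows <- do.call(rbind, lapply(names(sets), function(nm) {
    df <- disconnected_fraction(sets[[nm]], u, panel[[nm]])
    if (is.null(df$per_size)) return(NULL)
    df$per_size$criterion <- paste0("at_least:", nm)
    df$per_size
  }))
  if (!is.null(disc_rows)) {
    write_tsv(disc_rows, "disconnected.tsv"); note("disconnected.tsv")
  }

  # stage 6: diversity curve at the most populated size of the first source
  gs1 <- sets[[1]]
  if (length(gs1$members)) {
    sizes <- .popcount_cpp(gs1$members)
    n_star <- as.integer(names(which.max(table(sizes))))
    gsn <- filter_size(gs1, n_star)
    dmax <- max(1L, diameter(gsn, seed = config$seed)$value)
    dc <- diversity_curve(gsn, u, panel, D_range = 0:dmax,
                          pairs = config$diversity_pairs,
                          seed = config$seed,
                          threshold_fraction = config$threshold_fraction)
    dc$n <- n_star
    write_tsv(dc, "diversity_curve.tsv"); note("diversity_curve.tsv")
  }

  # stage 7: minimal distances between exclusive single-source networks
  excl <- lapply(names(panel), function(nm)
    enumerate_divide_merge(u, panel, exclusively(nm),
                           blocks = config$blocks,
                           config$threshold_fraction))
  names(excl) <- names(panel)
  excl <- excl[vapply(excl, function(s) length(s$members) > 0, logical(1))]
  if (length(excl) >= 2) {
    common_sizes <- Reduce(intersect,
                           lapply(excl, function(s)
                             unique(.popcount_cpp(s$members))))
    if (length(common_sizes)) {
      n_star <- common_sizes[which.max(vapply(common_sizes, function(n)
        sum(vapply(excl, function(s)
          sum(.popcount_cpp(s$members) == n), numeric(1))), numeric(1)))]
      cm <- complexity_matrix(lapply(excl, filter_size, n = n_star))
      cm$pairs$n <- n_star
      write_tsv(cm$pairs, "network_distances.tsv")
      note("network_distances.tsv")
    }
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(config$out_dir)
}
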