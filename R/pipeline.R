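#' Pipeline configuration
#'
#' Either `input` paths (species tree, gene trees, clade table, optional
#' plastome tree) or a `synthetic` [simulation_config()] must be supplied.
#'
#' @param out_dir Output directory for report files.
#' @param input Optional list with `species_tree`, `gene_trees`,
#'   `clade_table`, and optionally `plastome_tree` file paths.
#' @param synthetic Optional [simulation_config()] (or list of its
#'   arguments) for synthetic mode.
#' @param opts [analysis_options()].
#' @param n_sim Simulated null gene trees per adequacy test.
#' @param alpha Significance level.
#' @param seed Master seed for simulation and quartet sampling.
#' @param rooting Character vector of clade names, in priority order, used
#'   to root gene trees (default `"outgroup"`). Unrootable trees are
#'   excluded from rooted analyses and counted in the log.
#' @param n_quartets Sampled quartets for the quartet score.
#' @param plastome_collapse Bootstrap threshold applied to the plastome tree
#'   before scoring (default 0.75).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, input = NULL, synthetic = NULL,
                            opts = analysis_options(), n_sim = 1000,
                            alpha = 0.05, seed = 1, rooting = "outgroup",
                            n_quartets = 20000, plastome_collapse = 0.75) {
  if (is.null(input) && is.null(synthetic)) {
    stop_validation("either `input` paths or a `synthetic` config is required")
  }
  if (!is.null(synthetic) && !inherits(synthetic, "simulation_config")) {
    synthetic <- do.call(simulation_config, synthetic)
  }
  structure(list(out_dir = out_dir, input = input, synthetic = synthetic,
                 opts = opts, n_sim = n_sim, alpha = alpha,
                 seed = as.integer(seed), rooting = rooting,
                 n_quartets = n_quartets,
                 plastome_collapse = plastome_collapse),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  opts <- do.call(analysis_options, if (is.null(y$opts)) list() else y$opts)
  if (!is.null(y$synthetic) && !is.null(y$synthetic$clade_blocks)) {
    y$synthetic$clade_blocks <- unlist(y$synthetic$clade_blocks)
  }
  pipeline_config(
    out_dir = if (is.null(y$out_dir)) "discordia_out" else y$out_dir,
    input = y$input, synthetic = y$synthetic, opts = opts,
    n_sim = if (is.null(y$n_sim)) 1000 else y$n_sim,
    alpha = if (is.null(y$alpha)) 0.05 else y$alpha,
    seed = if (is.null(y$seed)) 1 else y$seed,
    rooting = if (is.null(y$rooting)) "outgroup" else y$rooting,
    n_quartets = if (is.null(y$n_quartets)) 20000 else y$n_quartets,
    plastome_collapse = if (is.null(y$plastome_collapse)) 0.75 else
      y$plastome_collapse)
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full discordance pipeline
#'
#' Loads (or synthesizes) a species tree, gene trees, clade table and
#' optionally a plastome tree, then writes to `config$out_dir`:
#' `distances.tsv` (per-locus distances per clade and metric),
#' `table1_analogue.tsv` (per-clade means with compact letters from the
#' among-clade ANOVA/Tukey), `table2_analogue.tsv` (observed vs
#' ILS-expected adequacy tests), `tally.tsv` (per-node concordance tallies,
#' conservation checked at write time), `quartet_score.txt`,
#' `plastome_distances.tsv` (plastome collapsed at the plastome threshold,
#' scored per clade), `tanglegram_pairs.tsv` (matched tip orderings for
#' external plotting), and `run.log` (seed, config hash, versions, skipped
#' counts — no timestamps, so reruns are byte-identical).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  logit <- function(...) log_lines <<- c(log_lines, sprintf(...))

  if (!is.null(config$input)) {
    inp <- config$input
    for (f in c("species_tree", "gene_trees", "clade_table")) {
      if (is.null(inp[[f]]) || !file.exists(inp[[f]])) {
        stop_validation(sprintf("missing input file for `%s`: %s", f,
                                if (is.null(inp[[f]])) "(unset)" else inp[[f]]))
      }
    }
    species_tree <- parse_newick(paste(readLines(inp$species_tree), collapse = ""))
    gene_trees <- read_gene_trees(inp$gene_trees)
    clade_map <- read_clade_table(inp$clade_table)
    plastome <- if (!is.null(inp$plastome_tree)) {
      parse_newick(paste(readLines(inp$plastome_tree), collapse = ""))
    }
    study <- NULL
  } else {
    study <- generate_study(config$synthetic)
    species_tree <- study$model$tree
    gene_trees <- study$gene_trees
    clade_map <- study$clade_map
    plastome <- study$plastome_tree
  }
  if (!ape::is.rooted(species_tree)) {
    species_tree <- root_with_outgroups(
      species_tree, priority_sets(config$rooting, clade_map))
  }
  logit("seed: %d", config$seed)
  logit("config_hash: %s",
        rlang::hash(unclass_deep(config[setdiff(names(config), "out_dir")])))
  logit("discordia_version: %s",
        as.character(utils::packageVersion("discordia")))
  logit("n_gene_trees: %d", length(gene_trees))

  # rooted gene trees for the tally
  prio <- priority_sets(config$rooting, clade_map)
  rooted <- list()
  n_unrootable <- 0L
  for (nm in names(gene_trees)) {
    r <- tryCatch(root_with_outgroups(gene_trees[[nm]], prio),
                  discordia_unrootable_error = function(e) NULL)
    if (is.null(r)) n_unrootable <- n_unrootable + 1L else rooted[[nm]] <- r
  }
  logit("rootable_gene_trees: %d of %d", length(rooted), length(gene_trees))

  clades <- setdiff(unique(clade_map$clade), "outgroup")
  clades <- clades[vapply(clades, function(cl)
    sum(clade_map$clade == cl) >= 4L, logical(1))]

  # per-locus distances, all clades + genus-wide
  profiles <- list()
  skipped <- 0L
  withCallingHandlers({
    profiles[["all"]] <- distance_profile(species_tree, gene_trees, "all",
                                          opts = config$opts)
    for (cl in clades) {
      taxa <- clade_map$tip[clade_map$clade == cl]
      profiles[[cl]] <- tryCatch(
        distance_profile(species_tree, gene_trees, taxa, opts = config$opts,
                         clade_name = cl),
        discordia_empty_profile_error = function(e) NULL)
    }
  }, warning = function(w) {
    skipped <<- skipped + 1L
    invokeRestart("muffleWarning")
  })
  profiles <- purrr::compact(profiles)
  distances <- dplyr::bind_rows(lapply(profiles, tibble::as_tibble))
  write_tsv_plain(fmt_num(distances), file.path(config$out_dir, "distances.tsv"))
  logit("profile_warnings: %d", skipped)

  # Table 1 analogue: per-clade means + Tukey letters per metric
  t1 <- list()
  for (m in config$opts$metrics) {
    cmp <- tryCatch(
      among_clade_comparison(species_tree, gene_trees, clade_map, m,
                             opts = config$opts, alpha = config$alpha),
      discordia_runtime_error = function(e) NULL)
    if (is.null(cmp)) next
    g <- glance.group_comparison(cmp)
    g$metric <- m
    t1[[m]] <- g
  }
  table1 <- if (length(t1)) {
    wide <- tidyr::pivot_wider(
      dplyr::bind_rows(t1)[, c("group", "n_tips", "n_loci", "metric", "mean",
                               "letters")],
      names_from = "metric", values_from = c("mean", "letters"))
    wide
  } else tibble::tibble()
  write_tsv_plain(fmt_num(table1), file.path(config$out_dir, "table1_analogue.tsv"))

  # Table 2 analogue: adequacy tests
  model <- species_tree_model(species_tree)
  t2 <- list()
  for (m in config$opts$metrics) {
    for (cl in c("all", clades)) {
      taxa <- if (cl == "all") "all" else clade_map$tip[clade_map$clade == cl]
      res <- tryCatch(
        ils_adequacy_test(model, gene_trees, taxa, m, n_sim = config$n_sim,
                          seed = gene_seed(config$seed, match(m, config$opts$metrics),
                                           10L),
                          opts = config$opts, clade_name = cl),
        discordia_runtime_error = function(e) NULL)
      if (!is.null(res)) t2[[paste(cl, m)]] <- tidy.ils_adequacy(res)
    }
  }
  table2 <- dplyr::bind_rows(t2)
  write_tsv_plain(fmt_num(table2), file.path(config$out_dir, "table2_analogue.tsv"))

  # concordance tally
  tally <- phyparts_tally(species_tree, rooted, config$opts$collapse_threshold)
  bad <- with(tally, n_concordant + n_main_conflict + n_other_conflict +
                n_uninformative != n_analyzed)
  if (any(bad)) stop_runtime("tally conservation violated at write time")
  write_tsv_plain(tally, file.path(config$out_dir, "tally.tsv"))

  # quartet score
  qs <- normalized_quartet_score(
    species_tree, gene_trees,
    mode = if (length(species_tree$tip.label) <= 25) "exact" else "sampled",
    n_quartets = config$n_quartets, seed = gene_seed(config$seed, 7L, 11L))
  writeLines(sprintf("normalized_quartet_score\t%.6f\nn_resolved\t%d\nn_matched\t%d",
                     qs$score, qs$n_resolved, qs$n_matched),
             file.path(config$out_dir, "quartet_score.txt"))

  # plastome comparison
  plastome_tab <- tibble::tibble()
  if (!is.null(plastome)) {
    pl <- collapse_low_support(plastome, config$plastome_collapse)
    rows <- list()
    for (cl in c("all", clades)) {
      taxa <- if (cl == "all") species_tree$tip.label else
        clade_map$tip[clade_map$clade == cl]
      shared <- intersect(intersect(taxa, pl$tip.label), species_tree$tip.label)
      if (length(shared) < 4L) next
      st <- prune_to_taxa(species_tree, shared)
      pt <- prune_to_taxa(pl, shared)
      for (m in config$opts$metrics) {
        rows[[paste(cl, m)]] <- tibble::tibble(
          clade = cl, metric = m, distance = tree_distance(st, pt, m),
          n_shared_tips = length(shared))
      }
    }
    plastome_tab <- dplyr::bind_rows(rows)
    write_tsv_plain(fmt_num(plastome_tab),
                    file.path(config$out_dir, "plastome_distances.tsv"))
    # tanglegram tip orderings
    lsp <- ape::ladderize(species_tree)
    lpl <- ape::ladderize(pl)
    ord_sp <- lsp$tip.label[lsp$edge[lsp$edge[, 2] <= length(lsp$tip.label), 2]]
    ord_pl <- lpl$tip.label[lpl$edge[lpl$edge[, 2] <= length(lpl$tip.label), 2]]
    common <- intersect(ord_sp, ord_pl)
    write_tsv_plain(tibble::tibble(
      tip = common,
      species_order = match(common, ord_sp),
      plastome_order = match(common, ord_pl)),
      file.path(config$out_dir, "tanglegram_pairs.tsv"))
  }

  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(list(distances = distances, table1 = table1, table2 = table2,
                 tally = tally, quartet_score = qs,
                 plastome = plastome_tab, study = study,
                 n_unrootable = n_unrootable))
}

priority_sets <- function(rooting, clade_map) {
  lapply(rooting, function(cl) clade_map$tip[clade_map$clade == cl])
}

# stable numeric formatting so reruns are byte-identical across platforms
fmt_num <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.8g", df[[j]])
  }
  df
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}
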