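# per-node clade tip sets of a rooted tree, as character-key list
rooted_clades <- function(tree) {
  pt <- as_ptree(tree)
  n_all <- length(pt$parent)
  root <- ptree_root(pt)
  below <- vector("list", n_all)
  for (v in ptree_postorder(pt)) {
    below[[v]] <- if (!is.na(pt$label[v])) pt$label[v] else
      sort(unlist(lapply(which(pt$parent == v), function(c) below[[c]])))
  }
  internal <- which(is.na(pt$label))
  list(clades = below[internal], nodes = internal, root = root,
       all_tips = sort(tree$tip.label), below = below)
}

#' Per-clade concordance/conflict tally of gene trees
#'
#' For every internal clade `C` of a rooted species tree, classifies each
#' rooted gene tree `g` (after collapsing branches with support below
#' `collapse_threshold`) by the status of `C' = C` intersected with `g`'s
#' tips:
#' * **concordant** — `C'` (with at least 2 members, and at least one tip of
#'   `g` outside `C`) is a clade of `g`;
#' * **conflict** — `C'` is non-monophyletic in `g` and some clade of `g`
#'   positively conflicts with it (intersects `C'` but neither contains nor
#'   is contained in it);
#' * **uninformative** — everything else (fewer than 2 shared members, no
#'   outside tip, or polytomy-only signal).
#'
#' The main conflict at a node is the most frequent conflicting alternative
#' clade, identified by its tip set on the gene tree's taxa; per gene tree
#' the representative conflict is the conflicting clade with the largest
#' overlap with `C'` (ties: smaller clade, then lexicographically smallest).
#'
#' @param species_tree Rooted `phylo`.
#' @param gene_trees List of *rooted* `phylo` objects (root unrootable trees
#'   upstream with [root_with_outgroups()] and exclude failures).
#' @param collapse_threshold Support threshold for collapsing gene-tree
#'   branches (default 0.33).
#' @return A tibble of class `concordance_tally`: one row per internal
#'   species-tree node with columns `node`, `clade_tips`, `n_tips`,
#'   `n_concordant`, `n_main_conflict`, `n_other_conflict`,
#'   `n_uninformative`, `n_analyzed`, `main_conflict_tips`.
#' @export
phyparts_tally <- function(species_tree, gene_trees, collapse_threshold = 0.33) {
  validate_phylo(species_tree, "species_tree")
  if (!ape::is.rooted(species_tree)) {
    stop_validation("species tree must be rooted")
  }
  for (g in gene_trees) {
    if (!ape::is.rooted(g)) {
      stop_validation("all gene trees must be rooted (exclude unrootable trees upstream)")
    }
  }
  sp <- rooted_clades(species_tree)
  n_sp <- length(species_tree$tip.label)
  keep <- vapply(sp$clades, function(cl)
    length(cl) >= 2L && length(cl) < n_sp, logical(1))
  sp_nodes <- sp$nodes[keep]
  sp_clades <- sp$clades[keep]

  gclades <- lapply(gene_trees, function(g) {
    g2 <- collapse_low_support(g, collapse_threshold)
    rc <- rooted_clades(g2)
    ng <- length(g2$tip.label)
    cl <- rc$clades[vapply(rc$clades, function(x)
      length(x) >= 2L && length(x) < ng, logical(1))]
    list(tips = g2$tip.label, clades = cl)
  })

  rows <- purrr::map2(sp_nodes, sp_clades, function(nd, C) {
    n_con <- n_unin <- 0L
    conflicts <- character(0)
    for (gc in gclades) {
      Cp <- sort(intersect(C, gc$tips))
      outside <- setdiff(gc$tips, C)
      if (length(Cp) < 2L || !length(outside)) {
        n_unin <- n_unin + 1L
        next
      }
      keyCp <- paste(Cp, collapse = "|")
      is_clade <- any(vapply(gc$clades, function(D)
        identical(paste(D, collapse = "|"), keyCp), logical(1)))
      if (is_clade) {
        n_con <- n_con + 1L
        next
      }
      # positively conflicting clades
      best <- NULL
      best_ov <- -1L
      best_sz <- Inf
      for (D in gc$clades) {
        ov <- length(intersect(D, Cp))
        if (ov == 0L) next
        if (ov == length(Cp) || ov == length(D)) next  # contains / contained
        key <- paste(D, collapse = "|")
        if (ov > best_ov || (ov == best_ov && length(D) < best_sz) ||
            (ov == best_ov && length(D) == best_sz && !is.null(best) && key < best)) {
          best <- key
          best_ov <- ov
          best_sz <- length(D)
        }
      }
      if (is.null(best)) {
        n_unin <- n_unin + 1L   # non-monophyly from polytomies only
      } else {
        conflicts <- c(conflicts, best)
      }
    }
    n_conf <- length(conflicts)
    if (n_conf) {
      tab <- sort(table(conflicts), decreasing = TRUE)
      top <- max(tab)
      main_key <- min(names(tab)[tab == top])  # deterministic tie-break
      n_main <- as.integer(tab[[main_key]])
    } else {
      main_key <- NA_character_
      n_main <- 0L
    }
    tibble::tibble(
      node = nd,   # ape node number (as_ptree preserves ape indexing)
      clade_tips = paste(C, collapse = ","),
      n_tips = length(C),
      n_concordant = n_con,
      n_main_conflict = n_main,
      n_other_conflict = n_conf - n_main,
      n_uninformative = n_unin,
      n_analyzed = length(gclades),
      main_conflict_tips = if (is.na(main_key)) NA_character_ else
        gsub("\\|", ",", main_key))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("concordance_tally", class(out))
  out
}

#' Stacked bar chart of a concordance tally
#'
#' @param object A `concordance_tally`.
#' @param ... Unused.
#' @return A ggplot object (one bar per species-tree node, the analogue of
#'   per-node pie charts).
#' @export
autoplot.concordance_tally <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    c("n_concordant", "n_main_conflict", "n_other_conflict", "n_uninformative"),
    names_to = "status", values_to = "count")
  long$status <- factor(sub("^n_", "", long$status),
                        levels = c("concordant", "main_conflict",
                                   "other_conflict", "uninformative"))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$node), y = .data$count,
                                     fill = .data$status)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "species tree node", y = "gene trees", fill = NULL)
}

# quartet topology via the four-point condition on topological (unit branch
# length) path distances: returns 0 (unresolved) or the index 1/2/3 of the
# pairing ab|cd, ac|bd, ad|bc
quartet_topology <- function(D, q) {
  s1 <- D[q[1], q[2]] + D[q[3], q[4]]
  s2 <- D[q[1], q[3]] + D[q[2], q[4]]
  s3 <- D[q[1], q[4]] + D[q[2], q[3]]
  s <- c(s1, s2, s3)
  m <- which.min(s)
  if (sum(abs(s - s[m]) < 1e-9) > 1L) return(0L)
  m
}

unit_cophenetic <- function(tree) {
  tree$edge.length <- rep(1, nrow(tree$edge))
  ape::cophenetic.phylo(tree)
}

#' Normalized quartet score
#'
#' The proportion of resolved gene-tree quartets whose topology matches the
#' species tree, pooled over gene trees. In `exact` mode every 4-tip subset
#' shared by a gene tree and the species tree is scored (permitted up to
#' `exact_ceiling` shared tips); in `sampled` mode `n_quartets` quartets are
#' drawn uniformly (gene tree first, then four of its shared tips).
#'
#' @param species_tree `phylo`.
#' @param gene_trees List of `phylo` sharing >= 4 tips with the species tree.
#' @param mode `"exact"` or `"sampled"`.
#' @param n_quartets Number of sampled quartets (sampled mode).
#' @param seed Seed for sampled mode.
#' @param exact_ceiling Maximum shared-tip count for exact mode (quartet
#'   counts grow as n^4).
#' @return List with `score` (matches / resolved gene quartets; `NA` if no
#'   resolved shared quartets), `n_resolved`, `n_matched`.
#' @export
normalized_quartet_score <- function(species_tree, gene_trees,
                                     mode = c("exact", "sampled"),
                                     n_quartets = 10000, seed = 1,
                                     exact_ceiling = 25) {
  mode <- match.arg(mode)
  validate_phylo(species_tree, "species_tree")
  Dsp <- unit_cophenetic(species_tree)
  n_res <- n_match <- 0L
  if (mode == "exact") {
    for (gt in gene_trees) {
      shared <- intersect(gt$tip.label, species_tree$tip.label)
      if (length(shared) < 4L) next
      if (length(shared) > exact_ceiling) {
        stop_validation(sprintf(
          "exact mode limited to %d shared tips (got %d); use mode = 'sampled'",
          exact_ceiling, length(shared)))
      }
      Dg <- unit_cophenetic(gt)
      qs <- utils::combn(shared, 4L, simplify = FALSE)
      for (q in qs) {
        tg <- quartet_topology(Dg, q)
        if (tg == 0L) next
        n_res <- n_res + 1L
        if (tg == quartet_topology(Dsp, q)) n_match <- n_match + 1L
      }
    }
  } else {
    set.seed(as.integer(seed))
    ok <- purrr::keep(gene_trees, function(g)
      length(intersect(g$tip.label, species_tree$tip.label)) >= 4L)
    if (!length(ok)) return(list(score = NA_real_, n_resolved = 0L, n_matched = 0L))
    Dg_list <- lapply(ok, unit_cophenetic)
    shared_list <- lapply(ok, function(g)
      intersect(g$tip.label, species_tree$tip.label))
    pick <- sample.int(length(ok), n_quartets, replace = TRUE)
    for (i in pick) {
      q <- sample(shared_list[[i]], 4L)
      tg <- quartet_topology(Dg_list[[i]], q)
      if (tg == 0L) next
      n_res <- n_res + 1L
      if (tg == quartet_topology(Dsp, q)) n_match <- n_match + 1L
    }
  }
  list(score = if (n_res) n_match / n_res else NA_real_,
       n_resolved = n_res, n_matched = n_match)
}
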