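#' Analysis options for distance profiling
#'
#' Bundles the filters used throughout the pipeline: the branch-support
#' collapse threshold applied to observed gene trees (default 0.33, i.e.
#' branches below 33% bootstrap are contracted), the minimum clade occupancy
#' a locus must *exceed* to be scored (default 0.75), and which distance
#' metrics to compute.
#'
#' @param collapse_threshold Support fraction in \[0, 1\].
#' @param occupancy_min Occupancy fraction in \[0, 1\]; loci with occupancy
#'   `<= occupancy_min` are dropped (strict "greater than" filter).
#' @param metrics Subset of `c("RF", "NYE", "CI")`.
#' @return An `analysis_options` list.
#' @export
analysis_options <- function(collapse_threshold = 0.33, occupancy_min = 0.75,
                             metrics = c("RF", "NYE", "CI")) {
  if (collapse_threshold < 0 || collapse_threshold > 1 ||
      occupancy_min < 0 || occupancy_min > 1) {
    stop_validation("thresholds must lie in [0, 1]")
  }
  metrics <- match.arg(metrics, c("RF", "NYE", "CI"), several.ok = TRUE)
  structure(list(collapse_threshold = collapse_threshold,
                 occupancy_min = occupancy_min, metrics = metrics),
            class = "analysis_options")
}

# prune both trees to their shared tips and return canonical split matrices
shared_splits <- function(t1, t2) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (length(shared) < 4L) {
    stop(errorCondition(sprintf("trees share %d tips; >= 4 required", length(shared)),
                        class = c("discordia_degenerate_tree_error",
                                  "discordia_validation_error")))
  }
  taxa <- sort(shared)
  p1 <- if (length(shared) < length(t1$tip.label)) prune_to_taxa(t1, shared) else t1
  p2 <- if (length(shared) < length(t2$tip.label)) prune_to_taxa(t2, shared) else t2
  list(s1 = nontrivial_splits(p1, taxa), s2 = nontrivial_splits(p2, taxa))
}

#' Normalized Robinson-Foulds distance
#'
#' Symmetric-difference distance on nontrivial split sets, normalized by the
#' total split count: `d = (|S1 \\ S2| + |S2 \\ S1|) / (|S1| + |S2|)`. Both
#' trees are first pruned to their shared tips; branch lengths are ignored;
#' polytomous trees are handled naturally (each tree contributes however many
#' splits it resolves).
#'
#' @param t1,t2 `phylo` objects sharing at least 4 tips.
#' @return Distance in \[0, 1\], or `NA` when both trees are stars (no
#'   splits on either side — the distance is undefined).
#' @export
rf_distance <- function(t1, t2) {
  sp <- shared_splits(t1, t2)
  k1 <- nrow(sp$s1); k2 <- nrow(sp$s2)
  if (k1 + k2 == 0L) return(NA_real_)
  shared_n <- length(intersect(split_keys(sp$s1), split_keys(sp$s2)))
  (k1 + k2 - 2 * shared_n) / (k1 + k2)
}

#' Normalized Nye generalized tree distance
#'
#' Scores a maximum-weight one-to-one matching `S` between the split sets
#' under the Nye split similarity ([nye_split_score()]); unmatched splits
#' score zero and the matching is solved exactly (optimal assignment), not
#' greedily. Normalized as `d = 1 - 2 S / (|S1| + |S2|)`, which is 0 for
#' identical split sets and 1 at total conflict.
#'
#' @inheritParams rf_distance
#' @return Distance in \[0, 1\], or `NA` when both trees are stars.
#' @export
nye_distance <- function(t1, t2) {
  sp <- shared_splits(t1, t2)
  k1 <- nrow(sp$s1); k2 <- nrow(sp$s2)
  if (k1 + k2 == 0L) return(NA_real_)
  S <- if (k1 == 0L || k2 == 0L) 0 else assignment_value(nye_matrix(sp$s1, sp$s2))
  d <- 1 - 2 * S / (k1 + k2)
  min(max(d, 0), 1)
}

#' Normalized clustering-information tree distance
#'
#' Matches splits one-to-one to maximize total mutual clustering information
#' `M` (exact assignment), then measures the information *not* captured by
#' the matching: `d = (H1 + H2 - 2 M) / (H1 + H2)` where `Hi` is the summed
#' split entropy of tree `i`. Zero for identical split sets; 1 when no split
#' pair shares any clustering information.
#'
#' @inheritParams rf_distance
#' @return Distance in \[0, 1\], or `NA` when both trees are stars.
#' @export
ci_distance <- function(t1, t2) {
  sp <- shared_splits(t1, t2)
  k1 <- nrow(sp$s1); k2 <- nrow(sp$s2)
  if (k1 + k2 == 0L) return(NA_real_)
  H1 <- sum(row_entropies(sp$s1))
  H2 <- sum(row_entropies(sp$s2))
  M <- if (k1 == 0L || k2 == 0L) 0 else assignment_value(mci_matrix(sp$s1, sp$s2))
  d <- (H1 + H2 - 2 * M) / (H1 + H2)
  min(max(d, 0), 1)
}

tree_distance <- function(t1, t2, metric) {
  switch(metric,
         RF = rf_distance(t1, t2),
         NYE = nye_distance(t1, t2),
         CI = ci_distance(t1, t2),
         stop_validation(sprintf("unknown metric '%s'", metric)))
}

#' Per-locus distance profile of gene trees against a species tree
#'
#' For each gene tree: (1) branches with support below
#' `opts$collapse_threshold` are collapsed; (2) occupancy with respect to
#' `clade_taxa` is computed and the locus is dropped unless occupancy is
#' strictly greater than `opts$occupancy_min`; (3) species tree and gene
#' tree are pruned to the intersection of `clade_taxa` with the gene tree's
#' tips; (4) one row per requested metric is emitted. Loci whose pruned
#' trees share fewer than 4 tips are skipped with a warning.
#'
#' @param species_tree Reference `phylo` containing `clade_taxa`.
#' @param gene_trees Named list of `phylo` objects (names are locus ids).
#' @param clade_taxa Character vector of taxa defining the clade of
#'   interest, or `"all"` for the full species-tree tip set.
#' @param opts An [analysis_options()] list.
#' @param clade_name Label recorded in the output (defaults to `"all"` or a
#'   deparse of the clade).
#' @return A tibble of class `distance_profile` with columns `locus_id`,
#'   `clade`, `metric`, `distance`, `n_shared_tips`, `occupancy`. Summary
#'   statistics via [glance.distance_profile()].
#' @export
distance_profile <- function(species_tree, gene_trees, clade_taxa = "all",
                             opts = analysis_options(), clade_name = NULL) {
  validate_phylo(species_tree, "species_tree")
  if (identical(clade_taxa, "all")) {
    clade_taxa <- species_tree$tip.label
    if (is.null(clade_name)) clade_name <- "all"
  }
  if (is.null(clade_name)) clade_name <- "clade"
  if (!all(clade_taxa %in% species_tree$tip.label)) {
    stop_validation("species tree does not contain all `clade_taxa`")
  }
  if (is.null(names(gene_trees))) {
    names(gene_trees) <- sprintf("locus_%03d", seq_along(gene_trees))
  }
  skipped <- character(0)
  rows <- purrr::imap(gene_trees, function(gt, id) {
    occ <- clade_occupancy(gt, clade_taxa)
    if (!(occ > opts$occupancy_min)) return(NULL)
    gt <- collapse_low_support(gt, opts$collapse_threshold)
    shared <- intersect(clade_taxa, gt$tip.label)
    if (length(shared) < 4L) {
      skipped <<- c(skipped, id)
      return(NULL)
    }
    st <- prune_to_taxa(species_tree, shared)
    gt <- prune_to_taxa(gt, shared)
    tibble::tibble(
      locus_id = id, clade = clade_name, metric = opts$metrics,
      distance = purrr::map_dbl(opts$metrics, ~ tree_distance(st, gt, .x)),
      n_shared_tips = length(shared), occupancy = occ)
  })
  out <- dplyr::bind_rows(rows)
  if (length(skipped)) {
    warning(sprintf("%d locus/loci skipped (fewer than 4 shared tips): %s",
                    length(skipped), paste(skipped, collapse = ", ")),
            call. = FALSE)
  }
  if (!nrow(out)) {
    stop(errorCondition(
      sprintf("no gene trees survive the occupancy filter (> %g) for clade '%s'",
              opts$occupancy_min, clade_name),
      class = c("discordia_empty_profile_error", "discordia_runtime_error")))
  }
  class(out) <- c("distance_profile", class(out))
  attr(out, "opts") <- opts
  out
}

#' Per-metric summary of a distance profile
#'
#' @param x A `distance_profile` tibble.
#' @param ... Unused.
#' @return Tibble with one row per metric: `n`, `mean`, `sd` (sample SD,
#'   n - 1 denominator).
#' @export
glance.distance_profile <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$clade, .data$metric),
    n = sum(!is.na(.data$distance)),
    mean = mean(.data$distance, na.rm = TRUE),
    sd = stats::sd(.data$distance, na.rm = TRUE),
    .groups = "drop")
}

#' @export
tidy.distance_profile <- function(x, ...) tibble::as_tibble(x)

#' Box plot of per-locus distances by metric
#'
#' @param object A `distance_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.distance_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$metric, y = .data$distance)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~clade) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "normalized distance to species tree")
}
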