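#' Parse a Newick string with branch supports
#'
#' Reads a single Newick statement into an [ape::phylo] object, interpreting
#' numeric internal node labels as branch supports. Both bootstrap-style
#' percentages (0--100) and posterior-style fractions (0--1) occur in
#' practice; with `support_scale = "auto"` the whole tree is treated as
#' percentages whenever any support value exceeds 1, and all supports are
#' stored normalized to fractions in \[0, 1\] (as internal node labels).
#'
#' @param text A Newick string ending in `";"`.
#' @param support_scale `"auto"`, `"fraction"`, or `"percent"`.
#' @return A `phylo` object. Supports, where present, are carried in
#'   `node.label` as fractions; [node_support()] extracts them numerically.
#' @examples
#' tr <- parse_newick("((a:1,b:1)90:0.5,c:1.5);")
#' node_support(tr)
#' @export
parse_newick <- function(text, support_scale = c("auto", "fraction", "percent")) {
  support_scale <- match.arg(support_scale)
  stopifnot(is.character(text), length(text) == 1L)
  check_balanced(text)
  if (!grepl(";\\s*$", text)) {
    stop_validation("Newick statement must end in ';'")
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop_validation(paste("Newick parse error:",
                                                            conditionMessage(e))))
  if (is.null(phy)) stop_validation("Newick parse error: no tree read")
  if (anyDuplicated(phy$tip.label)) {
    stop_validation(paste("duplicate tip labels:",
                          paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
                                collapse = ", ")))
  }
  if (!is.null(phy$node.label)) {
    val <- suppressWarnings(as.numeric(phy$node.label))
    if (any(!is.na(val))) {
      if (any(val < 0 | val > 100, na.rm = TRUE)) {
        stop_validation("support values outside [0, 100]")
      }
      scale <- switch(support_scale,
                      auto = if (any(val > 1, na.rm = TRUE)) 100 else 1,
                      fraction = 1,
                      percent = 100)
      if (scale == 1 && any(val > 1, na.rm = TRUE)) {
        stop_validation("support values > 1 under fraction scale")
      }
      val <- val / scale
      phy$node.label <- ifelse(is.na(val), "", sprintf("%.10g", val))
    }
  }
  validate_phylo(phy)
  phy
}

check_balanced <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop_validation(sprintf("unbalanced parentheses at character %d", i))
      }
    }
  }
  if (depth != 0L) {
    stop_validation(sprintf("unbalanced parentheses: %d '(' left open at end (character %d)",
                            depth, length(chars)))
  }
  invisible(TRUE)
}

#' Serialize a tree to Newick
#'
#' Inverse of [parse_newick()]: supports are written as internal node labels,
#' either as fractions or rescaled to percentages.
#'
#' @param tree A `phylo` object (supports, if any, as fraction node labels).
#' @param support_scale `"fraction"` or `"percent"`.
#' @return A Newick string.
#' @export
write_newick <- function(tree, support_scale = c("fraction", "percent")) {
  support_scale <- match.arg(support_scale)
  validate_phylo(tree)
  sup <- node_support(tree)
  if (support_scale == "percent" && any(!is.na(sup))) {
    tree$node.label <- ifelse(is.na(sup), "", sprintf("%.10g", sup * 100))
  }
  ape::write.tree(tree)
}

#' Extract branch supports from internal node labels
#'
#' @param tree A `phylo` object.
#' @return Numeric vector of length `tree$Nnode`, `NA` where no support is
#'   attached. Values are fractions in \[0, 1\].
#' @export
node_support <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Root a tree using an ordered list of outgroup sets
#'
#' Scans `priority` in order; the first taxon set with at least one member
#' present in the tree is used, and the tree is rooted on the edge subtending
#' the smallest clade (side of an unrooted split) containing all present
#' members. If no proper side contains them (the "clade" would be the whole
#' tree), that set is skipped and the scan continues. Trees for which no set
#' works raise an unrootable error, so callers can exclude them, mirroring
#' the usual practice of dropping gene trees that lack all outgroups.
#'
#' @param tree A `phylo` with at least 3 tips.
#' @param priority A list of character vectors of tip labels, in order of
#'   preference.
#' @return A rooted `phylo`. When branch lengths exist the root sits at the
#'   midpoint of the chosen edge; topology-only trees get a zero-length root.
#' @export
root_with_outgroups <- function(tree, priority) {
  validate_phylo(tree)
  if (!is.list(priority) || !length(priority)) {
    stop_validation("`priority` must be a non-empty list of taxon sets")
  }
  if (length(tree$tip.label) < 3L) stop_validation("tree must have >= 3 tips")
  for (og in priority) {
    present <- intersect(og, tree$tip.label)
    if (!length(present)) next
    side <- smallest_containing_side(tree, present)
    if (is.null(side)) next
    return(root_on_side(tree, side))
  }
  stop(errorCondition("no outgroup taxa present allow rooting (tree should be excluded)",
                      class = c("discordia_unrootable_error",
                                "discordia_runtime_error")))
}

# The smallest side over all (trivial and nontrivial) unrooted splits that
# contains all of `present`; NULL if only the full tip set qualifies.
smallest_containing_side <- function(tree, present) {
  labs <- tree$tip.label
  n <- length(labs)
  pres <- labs %in% present
  utree <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  pt <- as_ptree(utree)
  n_all <- length(pt$parent)
  below <- matrix(FALSE, n_all, n)
  tip_idx <- match(pt$label[!is.na(pt$label)], labs)
  below[cbind(which(!is.na(pt$label)), tip_idx)] <- TRUE
  for (v in ptree_postorder(pt)) {
    p <- pt$parent[v]
    if (p > 0L) below[p, ] <- below[p, ] | below[v, ]
  }
  best <- NULL
  best_size <- n + 1L
  root <- ptree_root(pt)
  for (v in seq_len(n_all)) {
    if (v == root) next
    for (side in list(below[v, ], !below[v, ])) {
      sz <- sum(side)
      if (sz < n && !any(pres & !side) && sz < best_size) {
        best <- side
        best_size <- sz
      }
    }
  }
  if (is.null(best)) NULL else labs[best]
}

root_on_side <- function(tree, side_tips) {
  utree <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  rooted <- ape::root(utree, outgroup = side_tips, resolve.root = TRUE,
                      edgelabel = TRUE)
  # split the chosen edge evenly between the two root children
  if (!is.null(rooted$edge.length)) {
    rootnode <- length(rooted$tip.label) + 1L
    ch <- which(rooted$edge[, 1] == rootnode)
    if (length(ch) == 2L) {
      tot <- sum(rooted$edge.length[ch])
      rooted$edge.length[ch] <- tot / 2
    }
  }
  rooted
}

#' Collapse poorly supported branches into polytomies
#'
#' Contracts every internal edge whose support is present and strictly below
#' `threshold` (so a branch at exactly the threshold is kept — the filter is
#' "support < threshold", matching the usual "< 33% BS" phrasing). Edges
#' without support and all pendant edges are retained.
#'
#' @param tree A `phylo` object.
#' @param threshold Support fraction in \[0, 1\].
#' @return A `phylo`, possibly with polytomies; the tip set is unchanged.
#' @export
collapse_low_support <- function(tree, threshold) {
  validate_phylo(tree)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    stop_validation("`threshold` must be a fraction in [0, 1]")
  }
  pt <- as_ptree(tree)
  root <- ptree_root(pt)
  drop <- which(is.na(pt$label) & !is.na(pt$support) &
                pt$support < threshold & seq_along(pt$parent) != root)
  if (!length(drop)) return(tree)
  as_phylo(ptree_contract(pt, drop))
}

#' Prune a tree to a taxon set
#'
#' Removes tips outside `keep`; degree-2 internal nodes left behind are
#' suppressed with their branch lengths summed. When two edges with supports
#' are merged, the merged edge takes the *minimum* of the supports (never
#' inflating confidence; a pruning convention, since annotated datasets do
#' not specify one).
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain.
#' @return A `phylo` on `intersect(tree$tip.label, keep)`.
#' @export
prune_to_taxa <- function(tree, keep) {
  validate_phylo(tree)
  surv <- intersect(tree$tip.label, keep)
  if (length(surv) < 2L) {
    stop(errorCondition(sprintf("pruning leaves %d tip(s); >= 2 required",
                                length(surv)),
                        class = c("discordia_degenerate_tree_error",
                                  "discordia_validation_error")))
  }
  if (length(surv) == length(tree$tip.label)) return(tree)
  pt <- as_ptree(tree)
  drop <- which(!is.na(pt$label) & !(pt$label %in% surv))
  as_phylo(ptree_prune(pt, drop))
}

#' Fraction of a clade's taxa present in a tree
#'
#' Occupancy is the basis of the locus filter "use only gene trees containing
#' more than a given fraction of the clade's terminals".
#'
#' @param tree A `phylo` object.
#' @param clade_taxa Non-empty character vector of taxon labels.
#' @return Fraction in \[0, 1\].
#' @export
clade_occupancy <- function(tree, clade_taxa) {
  if (!length(clade_taxa)) stop_validation("`clade_taxa` must be non-empty")
  length(intersect(tree$tip.label, clade_taxa)) / length(unique(clade_taxa))
}

#' Read a multi-tree Newick file
#'
#' One Newick statement per line; lines starting with `#` are comments. A
#' comment line immediately preceding a tree names that tree (locus id);
#' otherwise trees are named `locus_001`, `locus_002`, ...
#'
#' @param path File path.
#' @param support_scale Passed to [parse_newick()].
#' @return A named list of `phylo` objects.
#' @export
read_gene_trees <- function(path, support_scale = "auto") {
  lines <- readLines(path)
  trees <- list()
  pending_name <- NULL
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      pending_name <- trimws(sub("^#+", "", ln))
      next
    }
    tr <- parse_newick(ln, support_scale)
    nm <- if (!is.null(pending_name) && nzchar(pending_name)) pending_name else
      sprintf("locus_%03d", length(trees) + 1L)
    trees[[nm]] <- tr
    pending_name <- NULL
  }
  trees
}

#' Write a multi-tree Newick file
#'
#' @param trees Named list of `phylo` objects.
#' @param path File path.
#' @param support_scale Passed to [write_newick()].
#' @export
write_gene_trees <- function(trees, path, support_scale = "fraction") {
  con <- file(path, "w")
  on.exit(close(con))
  nms <- names(trees)
  for (i in seq_along(trees)) {
    if (!is.null(nms) && nzchar(nms[i])) writeLines(paste("#", nms[i]), con)
    writeLines(write_newick(trees[[i]], support_scale), con)
  }
  invisible(path)
}

#' Read a clade membership table
#'
#' Two-column tab-separated file `tip_label<TAB>clade_name`; `#` comments
#' allowed.
#'
#' @param path File path.
#' @return A tibble with columns `tip` and `clade`.
#' @export
read_clade_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          col.names = c("tip", "clade"),
                          colClasses = "character", quote = "")
  if (anyDuplicated(df$tip)) stop_validation("duplicate tips in clade table")
  tibble::as_tibble(df)
}

#' Write a clade membership table
#'
#' @param clade_map Tibble/data frame with columns `tip` and `clade`.
#' @param path File path.
#' @export
write_clade_table <- function(clade_map, path) {
  utils::write.table(clade_map[, c("tip", "clade")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
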