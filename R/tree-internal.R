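# Internal parent-array tree representation.
#
# Most tree surgery (support-based collapsing, pruning with support merging,
# assembling simulated gene trees) is easier on a flat parent-pointer form
# than on ape's edge matrix. A "ptree" is a list with parallel vectors over
# node ids 1..N (ids are arbitrary, not ape-ordered):
#   parent  : integer, 0 for the root
#   len     : numeric branch length of the edge above each node (NA = absent)
#   support : numeric in [0,1] for the edge above each *internal* node (NA = absent)
#   label   : character tip label, NA for internal nodes
# Supports ride on the edge above a node, matching the Newick convention of
# internal node labels.

ptree <- function(parent, len, support, label) {
  list(parent = as.integer(parent), len = as.numeric(len),
       support = as.numeric(support), label = as.character(label))
}

ptree_root <- function(pt) which(pt$parent == 0L)

ptree_children <- function(pt) {
  n <- length(pt$parent)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    p <- pt$parent[i]
    if (p > 0L) kids[[p]] <- c(kids[[p]], i)
  }
  kids
}

as_ptree <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  n <- length(phy$tip.label)
  nn <- phy$Nnode
  N <- n + nn
  parent <- integer(N)
  len <- rep(NA_real_, N)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  if (!is.null(phy$edge.length)) len[phy$edge[, 2]] <- phy$edge.length
  support <- rep(NA_real_, N)
  if (!is.null(phy$node.label)) {
    lab <- phy$node.label
    val <- suppressWarnings(as.numeric(lab))
    support[n + seq_len(nn)] <- val
  }
  support[ptree_root_id <- which(parent == 0L)] <- NA_real_
  label <- c(phy$tip.label, rep(NA_character_, nn))
  ptree(parent, len, support, label)
}

# Rebuild a phylo from a ptree, renumbering to ape conventions
# (tips 1..n in label order of appearance, root n+1, internals in preorder).
as_phylo <- function(pt) {
  alive <- !is.na(pt$parent)  # all nodes assumed alive here
  n_all <- length(pt$parent)
  is_tip <- !is.na(pt$label)
  tips <- which(is_tip)
  internals <- which(!is_tip)
  n <- length(tips)
  root <- ptree_root(pt)
  kids <- ptree_children(pt)
  # preorder over internal nodes
  ord <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (!is_tip[v]) {
      ord <- c(ord, v)
      stack <- c(stack, rev(kids[[v]]))
    }
  }
  newid <- integer(n_all)
  newid[tips] <- seq_len(n)
  newid[ord] <- n + seq_along(ord)
  # edge rows in DFS preorder (true cladewise ordering)
  child <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v != root) child <- c(child, v)
    if (!is_tip[v]) stack <- c(stack, rev(kids[[v]]))
  }
  edge <- cbind(newid[pt$parent[child]], newid[child])
  phy <- list(edge = edge, Nnode = length(ord), tip.label = pt$label[tips])
  if (any(!is.na(pt$len[child]))) {
    phy$edge.length <- ifelse(is.na(pt$len[child]), 0, pt$len[child])
  }
  sup <- pt$support[ord]
  if (any(!is.na(sup))) {
    phy$node.label <- ifelse(is.na(sup), "", sprintf("%.10g", sup))
  }
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  phy
}

# Drop a set of nodes (tips), then clean up: remove childless internals,
# suppress degree-2 internals (lengths summed, supports min-merged), and
# re-root below any single-child root.
ptree_prune <- function(pt, drop_tips) {
  n_all <- length(pt$parent)
  alive <- rep(TRUE, n_all)
  alive[drop_tips] <- FALSE
  nchild <- integer(n_all)
  repeat {
    nchild[] <- 0L
    for (i in which(alive)) {
      p <- pt$parent[i]
      if (p > 0L && alive[p]) nchild[p] <- nchild[p] + 1L
    }
    dead <- which(alive & is.na(pt$label) & nchild == 0L)
    if (!length(dead)) break
    alive[dead] <- FALSE
  }
  # suppress degree-2 internals bottom-up
  repeat {
    nchild[] <- 0L
    for (i in which(alive)) {
      p <- pt$parent[i]
      if (p > 0L && alive[p]) nchild[p] <- nchild[p] + 1L
    }
    sing <- which(alive & is.na(pt$label) & nchild == 1L)
    if (!length(sing)) break
    v <- sing[1]
    child <- which(alive & pt$parent == v)[1]
    if (pt$parent[v] == 0L) {
      # root with one child: child becomes root
      pt$parent[child] <- 0L
      pt$len[child] <- NA_real_
      pt$support[child] <- NA_real_
      alive[v] <- FALSE
    } else {
      pt$parent[child] <- pt$parent[v]
      if (!is.na(pt$len[child]) || !is.na(pt$len[v])) {
        pt$len[child] <- sum(c(pt$len[child], pt$len[v]), na.rm = TRUE)
      }
      if (is.na(pt$label[child])) {
        s <- c(pt$support[child], pt$support[v])
        pt$support[child] <- if (all(is.na(s))) NA_real_ else min(s, na.rm = TRUE)
      }
      alive[v] <- FALSE
    }
  }
  ptree_compact(pt, alive)
}

ptree_compact <- function(pt, alive) {
  keep <- which(alive)
  remap <- integer(length(pt$parent))
  remap[keep] <- seq_along(keep)
  parent <- pt$parent[keep]
  parent[parent > 0L] <- remap[parent[parent > 0L]]
  ptree(parent, pt$len[keep], pt$support[keep], pt$label[keep])
}

# Contract the edges above the given (internal, non-root) nodes.
ptree_contract <- function(pt, nodes) {
  alive <- rep(TRUE, length(pt$parent))
  for (v in nodes) {
    stopifnot(is.na(pt$label[v]), pt$parent[v] > 0L)
  }
  # iterate until all marked edges resolved (a node's parent may itself be marked)
  marked <- rep(FALSE, length(pt$parent))
  marked[nodes] <- TRUE
  for (i in seq_along(pt$parent)) {
    p <- pt$parent[i]
    while (p > 0L && marked[p]) p <- pt$parent[p]
    pt$parent[i] <- p
  }
  alive[marked] <- FALSE
  ptree_compact(pt, alive)
}

# number of tips below each node (tips count themselves)
ptree_ntips_below <- function(pt) {
  n_all <- length(pt$parent)
  cnt <- ifelse(is.na(pt$label), 0L, 1L)
  ord <- ptree_postorder(pt)
  for (v in ord) {
    p <- pt$parent[v]
    if (p > 0L) cnt[p] <- cnt[p] + cnt[v]
  }
  cnt
}

ptree_postorder <- function(pt) {
  root <- ptree_root(pt)
  kids <- ptree_children(pt)
  ord <- integer(0)
  stack <- root
  out <- integer(0)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, kids[[v]])
  }
  rev(out)
}

validate_phylo <- function(tree, arg = "tree") {
  if (!inherits(tree, "phylo")) {
    stop_validation(sprintf("`%s` must be a 'phylo' object", arg))
  }
  if (anyDuplicated(tree$tip.label)) {
    stop_validation(sprintf("duplicate tip labels in `%s`: %s", arg,
                            paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                                  collapse = ", ")))
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < -1e-12, na.rm = TRUE)) {
    stop_validation(sprintf("negative branch lengths in `%s`", arg))
  }
  invisible(tree)
}

# condition helpers ---------------------------------------------------------

stop_validation <- function(msg, class = character()) {
  stop(errorCondition(msg, class = c(class, "discordia_validation_error")))
}

stop_runtime <- function(msg, class = character()) {
  stop(errorCondition(msg, class = c(class, "discordia_runtime_error")))
}
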