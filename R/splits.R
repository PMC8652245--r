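# Bipartitions and per-split-pair scores.
#
# A split set is represented as a logical matrix with one row per nontrivial
# split and one column per taxon, columns ordered by the supplied taxon
# vector. Rows are canonicalized so the entry for the first taxon is FALSE
# (the stored side is the one *not* containing the lowest-indexed taxon).

#' Nontrivial splits of a tree
#'
#' Computes the bipartitions induced by the internal edges of the unrooted
#' topology, keeping only nontrivial ones (both sides with at least two
#' taxa). A root edge contributes at most one split; duplicates are merged.
#'
#' @param tree A `phylo` with at least 4 tips.
#' @param taxa Character vector fixing the column order (defaults to sorted
#'   tip labels). Must be a permutation of `tree$tip.label`.
#' @return A logical matrix (splits x taxa) of canonical split masks, with
#'   `taxa` as column names. Zero rows for a star tree.
#' @export
nontrivial_splits <- function(tree, taxa = sort(tree$tip.label)) {
  validate_phylo(tree)
  n <- length(tree$tip.label)
  if (n < 4L) {
    stop(errorCondition("splits require >= 4 tips",
                        class = c("discordia_degenerate_tree_error",
                                  "discordia_validation_error")))
  }
  if (!setequal(taxa, tree$tip.label) || length(taxa) != n) {
    stop_validation("`taxa` must be a permutation of the tree's tip labels")
  }
  pt <- as_ptree(tree)
  n_all <- length(pt$parent)
  below <- matrix(FALSE, n_all, n)
  tip_nodes <- which(!is.na(pt$label))
  below[cbind(tip_nodes, match(pt$label[tip_nodes], taxa))] <- TRUE
  for (v in ptree_postorder(pt)) {
    p <- pt$parent[v]
    if (p > 0L) below[p, ] <- below[p, ] | below[v, ]
  }
  root <- ptree_root(pt)
  internal <- which(is.na(pt$label) & seq_len(n_all) != root)
  if (!length(internal)) {
    m <- matrix(logical(0), 0, n)
    colnames(m) <- taxa
    return(m)
  }
  masks <- below[internal, , drop = FALSE]
  sz <- rowSums(masks)
  masks <- masks[sz >= 2L & sz <= n - 2L, , drop = FALSE]
  if (nrow(masks)) {
    flip <- masks[, 1L]
    masks[flip, ] <- !masks[flip, , drop = FALSE]
    masks <- masks[!duplicated(split_keys(masks)), , drop = FALSE]
  }
  colnames(masks) <- taxa
  masks
}

split_keys <- function(masks) {
  if (!nrow(masks)) return(character(0))
  apply(masks, 1L, function(r) paste(which(r), collapse = ","))
}

#' Entropy of a split
#'
#' The Shannon entropy, in bits, of the two-block partition a split induces
#' on its taxon set: `H = -(|A|/n) log2(|A|/n) - (|B|/n) log2(|B|/n)`.
#'
#' @param mask Logical vector (one side of the split) or a split matrix row.
#' @return Entropy in bits.
#' @export
split_entropy <- function(mask) {
  n <- length(mask)
  a <- sum(mask)
  if (a < 2L || n - a < 2L) stop_validation("split must be nontrivial")
  p <- c(a, n - a) / n
  -sum(p * log2(p))
}

row_entropies <- function(masks) {
  if (!nrow(masks)) return(numeric(0))
  n <- ncol(masks)
  a <- rowSums(masks)
  p <- a / n
  q <- 1 - p
  -(p * log2(p) + q * log2(q))
}

#' Mutual clustering information between two splits
#'
#' The mutual information, in bits, between the two-block partitions induced
#' by the splits on a common taxon set: summing over the four
#' side-intersection cells, `I = sum (n_xy/n) log2(n * n_xy / (n_x * n_y))`,
#' with empty cells contributing zero. Satisfies
#' `0 <= I <= min(H(s1), H(s2))`.
#'
#' @param s1,s2 Logical split masks over the same taxa (same length).
#' @return Mutual information in bits.
#' @export
mutual_clustering_information <- function(s1, s2) {
  if (length(s1) != length(s2)) {
    stop_validation("splits must be defined on the same taxon restriction")
  }
  mci_matrix(matrix(s1, 1L), matrix(s2, 1L))[1L, 1L]
}

# k1 x k2 matrix of pairwise mutual clustering information (bits)
mci_matrix <- function(m1, m2) {
  n <- ncol(m1)
  M1 <- m1 * 1
  M2 <- m2 * 1
  n11 <- M1 %*% t(M2)
  r <- rowSums(M1)
  c2 <- rowSums(M2)
  n10 <- outer(r, rep(1, nrow(m2))) - n11
  n01 <- outer(rep(1, nrow(m1)), c2) - n11
  n00 <- n - n11 - n10 - n01
  term <- function(nxy, nx, ny) {
    out <- matrix(0, nrow(nxy), ncol(nxy))
    pos <- nxy > 0
    out[pos] <- (nxy[pos] / n) * log2(n * nxy[pos] / (nx[pos] * ny[pos]))
    out
  }
  rA <- outer(r, rep(1, nrow(m2)))
  rB <- n - rA
  cA <- outer(rep(1, nrow(m1)), c2)
  cB <- n - cA
  term(n11, rA, cA) + term(n10, rA, cB) + term(n01, rB, cA) + term(n00, rB, cB)
}

#' Nye similarity score between two splits
#'
#' For splits `A|B` and `C|D` on the same taxa, the score is the better of
#' the two side-alignments, each scored by the weaker of its two Jaccard
#' similarities: `max( min(J(A,C), J(B,D)), min(J(A,D), J(B,C)) )`. Equals 1
#' exactly when the splits are identical.
#'
#' @param s1,s2 Logical split masks over the same taxa.
#' @return Similarity in \[0, 1\].
#' @export
nye_split_score <- function(s1, s2) {
  if (length(s1) != length(s2)) {
    stop_validation("splits must be defined on the same taxon restriction")
  }
  nye_matrix(matrix(s1, 1L), matrix(s2, 1L))[1L, 1L]
}

# k1 x k2 matrix of pairwise Nye scores
nye_matrix <- function(m1, m2) {
  n <- ncol(m1)
  M1 <- m1 * 1
  M2 <- m2 * 1
  n11 <- M1 %*% t(M2)              # |A ∩ C|
  r <- rowSums(M1)
  c2 <- rowSums(M2)
  rA <- outer(r, rep(1, nrow(m2)))
  cA <- outer(rep(1, nrow(m1)), c2)
  n10 <- rA - n11                  # |A ∩ D|
  n01 <- cA - n11                  # |B ∩ C|
  n00 <- n - n11 - n10 - n01       # |B ∩ D|
  jac <- function(inter, a, b) inter / (a + b - inter)
  jAC <- jac(n11, rA, cA)
  jBD <- jac(n00, n - rA, n - cA)
  jAD <- jac(n10, rA, n - cA)
  jBC <- jac(n01, n - rA, cA)
  pmax(pmin(jAC, jBD), pmin(jAD, jBC))
}

# Exact maximum-weight one-to-one matching value for a non-negative weight
# matrix (unmatched rows/columns contribute zero). Solved as a maximum-weight
# bipartite matching.
assignment_value <- function(W, eps = 1e-12) {
  if (!length(W) || !nrow(W) || !ncol(W)) return(0)
  keep <- W > eps
  if (!any(keep)) return(0)
  idx <- which(keep, arr.ind = TRUE)
  k1 <- nrow(W)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, k1), rep(TRUE, ncol(W))),
    edges = as.vector(t(cbind(idx[, 1], k1 + idx[, 2]))))
  igraph::E(g)$weight <- W[idx]
  m <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight)
  m$matching_weight
}
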