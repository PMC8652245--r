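# Independent oracles for the distance metrics.
#
# Splits are extracted with phangorn (an implementation unrelated to the
# package's own split code); per-pair scores are computed with plain-R
# formula loops; and the matching is an exhaustive enumeration of every
# injective split pairing. Nothing here touches the package's split or
# matching internals.

# splits of a tree as a list of logical masks over `taxa`, canonicalized so
# mask[1] is FALSE; nontrivial only
oracle_splits <- function(tree, taxa) {
  ut <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  sp <- phangorn::as.splits(ut)
  labs <- attr(sp, "labels")
  out <- list()
  seen <- character(0)
  for (s in sp) {
    mask <- logical(length(taxa))
    mask[match(labs[s], taxa)] <- TRUE
    if (sum(mask) < 2 || sum(!mask) < 2) next
    if (mask[1]) mask <- !mask
    key <- paste(which(mask), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1]] <- mask
  }
  out
}

oracle_entropy <- function(mask) {
  p <- c(sum(mask), sum(!mask)) / length(mask)
  -sum(p * log2(p))
}

oracle_mci <- function(m1, m2) {
  n <- length(m1)
  tot <- 0
  for (a in c(TRUE, FALSE)) for (b in c(TRUE, FALSE)) {
    nxy <- sum((m1 == a) & (m2 == b))
    if (nxy == 0) next
    nx <- sum(m1 == a); ny <- sum(m2 == b)
    tot <- tot + (nxy / n) * log2(n * nxy / (nx * ny))
  }
  tot
}

oracle_nye <- function(m1, m2) {
  jac <- function(x, y) {
    i <- sum(x & y)
    u <- sum(x | y)
    if (u == 0) 0 else i / u
  }
  max(min(jac(m1, m2), jac(!m1, !m2)),
      min(jac(m1, !m2), jac(!m1, m2)))
}

# exhaustive maximum over injective pairings (rows of W to distinct columns)
oracle_match_value <- function(W) {
  k1 <- nrow(W); k2 <- ncol(W)
  if (!k1 || !k2) return(0)
  best <- 0
  rec <- function(i, used, acc) {
    if (i > k1) {
      if (acc > best) best <<- acc
      return(invisible(NULL))
    }
    rec(i + 1, used, acc)                  # row i unmatched
    for (j in seq_len(k2)) {
      if (!used[j]) {
        used[j] <- TRUE
        rec(i + 1, used, acc + W[i, j])
        used[j] <- FALSE
      }
    }
    invisible(NULL)
  }
  rec(1, rep(FALSE, k2), 0)
  best
}

oracle_rf <- function(t1, t2) {
  taxa <- sort(intersect(t1$tip.label, t2$tip.label))
  s1 <- oracle_splits(t1, taxa); s2 <- oracle_splits(t2, taxa)
  key <- function(m) paste(which(m), collapse = ",")
  k1 <- vapply(s1, key, character(1)); k2 <- vapply(s2, key, character(1))
  if (!length(k1) && !length(k2)) return(NA_real_)
  (length(k1) + length(k2) - 2 * length(intersect(k1, k2))) /
    (length(k1) + length(k2))
}

oracle_nye_distance <- function(t1, t2) {
  taxa <- sort(intersect(t1$tip.label, t2$tip.label))
  s1 <- oracle_splits(t1, taxa); s2 <- oracle_splits(t2, taxa)
  if (!length(s1) && !length(s2)) return(NA_real_)
  if (!length(s1) || !length(s2)) return(1)
  W <- outer(seq_along(s1), seq_along(s2),
             Vectorize(function(i, j) oracle_nye(s1[[i]], s2[[j]])))
  1 - 2 * oracle_match_value(W) / (length(s1) + length(s2))
}

oracle_ci_distance <- function(t1, t2) {
  taxa <- sort(intersect(t1$tip.label, t2$tip.label))
  s1 <- oracle_splits(t1, taxa); s2 <- oracle_splits(t2, taxa)
  if (!length(s1) && !length(s2)) return(NA_real_)
  H1 <- sum(vapply(s1, oracle_entropy, numeric(1)))
  H2 <- sum(vapply(s2, oracle_entropy, numeric(1)))
  M <- if (!length(s1) || !length(s2)) 0 else {
    W <- outer(seq_along(s1), seq_along(s2),
               Vectorize(function(i, j) oracle_mci(s1[[i]], s2[[j]])))
    oracle_match_value(W)
  }
  (H1 + H2 - 2 * M) / (H1 + H2)
}

# deterministic random binary trees for property tests
random_tree <- function(n, seed, lengths = TRUE) {
  set.seed(seed)
  tr <- ape::rtree(n, br = if (lengths) stats::runif else NULL)
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr
}
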