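#' Species tree model for coalescent simulation
#'
#' Wraps a rooted species tree whose branch lengths are in coalescent units
#' (time scaled by population size, so two lineages in one population
#' coalesce at rate 1 per unit), together with an optional list of level-1
#' reticulation events created by [reticulation()].
#'
#' @param tree Rooted `phylo`; all branch lengths present and non-negative.
#'   Node ages are computed from the root; the tree is treated as ultrametric
#'   in coalescent time.
#' @param reticulations List of [reticulation()] events (at most one per
#'   recipient edge; level-1).
#' @return A `species_tree_model` object.
#' @export
species_tree_model <- function(tree, reticulations = list()) {
  validate_phylo(tree, "tree")
  if (!ape::is.rooted(tree)) stop_validation("species tree must be rooted")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop_validation("species tree must have branch lengths (coalescent units)")
  }
  if (any(tree$edge.length < 0)) stop_validation("negative branch lengths")
  model <- structure(list(tree = tree, reticulations = list()),
                     class = "species_tree_model")
  model$prep <- prep_species_model(tree)
  for (ev in reticulations) model <- add_reticulation(model, ev)
  model
}

#' Specify a reticulation (gene flow) event
#'
#' Describes one horizontal edge of a level-1 network: with inheritance
#' probability `gamma`, a gene's lineages present on the recipient edge at
#' the event time follow the donor edge instead of the recipient's own
#' history. The whole gene takes one parental path (no within-locus
#' recombination): one Bernoulli(`gamma`) draw per gene per event, matching
#' the reading of gamma as the fraction of the genome involved.
#'
#' @param donor,recipient Character vectors of tip labels; each identifies
#'   the stem edge of the smallest clade containing those tips.
#' @param gamma Inheritance probability in (0, 0.5].
#' @param time Position of the event along the recipient edge as a fraction
#'   in (0, 1), measured from the tipward end. The implied age must fall
#'   strictly inside the donor edge as well.
#' @return A `reticulation` list.
#' @export
reticulation <- function(donor, recipient, gamma, time = 0.5) {
  if (!is.numeric(gamma) || gamma <= 0 || gamma > 0.5) {
    stop_validation("`gamma` must lie in (0, 0.5]")
  }
  if (!is.numeric(time) || time <= 0 || time >= 1) {
    stop_validation("`time` must lie strictly in (0, 1)")
  }
  structure(list(donor = donor, recipient = recipient, gamma = gamma,
                 time = time), class = "reticulation")
}

prep_species_model <- function(tree) {
  pt <- as_ptree(tree)
  n_all <- length(pt$parent)
  root <- ptree_root(pt)
  kids <- ptree_children(pt)
  depth <- numeric(n_all)
  # preorder depths
  stack <- root
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (c in kids[[v]]) {
      depth[c] <- depth[v] + pt$len[c]
      stack <- c(stack, c)
    }
  }
  ages <- max(depth) - depth
  list(pt = pt, root = root, kids = kids, ages = ages,
       tips = which(!is.na(pt$label)))
}

clade_stem_node <- function(prep, taxa) {
  pt <- prep$pt
  tipset <- which(!is.na(pt$label) & pt$label %in% taxa)
  if (!length(tipset)) stop_validation("no matching tips for reticulation edge")
  if (length(tipset) == 1L) return(tipset)
  # smallest node whose descendants include all of tipset
  below <- vector("list", length(pt$parent))
  for (v in ptree_postorder(pt)) {
    below[[v]] <- if (!is.na(pt$label[v])) v else
      unlist(lapply(prep$kids[[v]], function(c) below[[c]]))
  }
  cand <- which(vapply(below, function(b) all(tipset %in% b), logical(1)))
  cand[which.min(lengths(below[cand]))]
}

add_reticulation <- function(model, ev) {
  stopifnot(inherits(ev, "reticulation"))
  prep <- model$prep
  rv <- clade_stem_node(prep, ev$recipient)
  dv <- clade_stem_node(prep, ev$donor)
  if (rv == dv) stop_validation("reticulation donor and recipient edges coincide")
  if (rv == prep$root || dv == prep$root) {
    stop_validation("reticulation edges must not be the root")
  }
  for (e in model$reticulations) {
    if (e$rv == rv) stop_validation("at most one reticulation per recipient edge (level-1)")
  }
  a_r <- prep$ages[rv]; a_rp <- prep$ages[prep$pt$parent[rv]]
  age <- a_r + ev$time * (a_rp - a_r)
  a_d <- prep$ages[dv]; a_dp <- prep$ages[prep$pt$parent[dv]]
  if (!(age > a_d && age < a_dp)) {
    stop_validation(sprintf(
      "reticulation age %.4g lies outside the donor edge (%.4g, %.4g)",
      age, a_d, a_dp))
  }
  model$reticulations <- c(model$reticulations,
                           list(list(rv = rv, dv = dv, age = age,
                                     gamma = ev$gamma, spec = ev)))
  model
}

# Segment table: each species-tree edge (above node v) split at reticulation
# ages so that lineage transfers happen at segment boundaries.
model_segments <- function(model) {
  prep <- model$prep
  pt <- prep$pt
  ages <- prep$ages
  segs <- list()
  first_seg <- last_seg <- integer(length(pt$parent))
  for (v in seq_along(pt$parent)) {
    if (pt$parent[v] == 0L) next
    lo <- ages[v]; hi <- ages[pt$parent[v]]
    cuts <- sort(unique(c(
      lo, hi,
      vapply(model$reticulations, function(e)
        if (e$rv == v || e$dv == v) e$age else NA_real_, numeric(1)))))
    cuts <- cuts[!is.na(cuts) & cuts >= lo & cuts <= hi]
    if (length(cuts) < 2L) cuts <- c(lo, hi)  # zero-length branch
    for (i in seq_len(length(cuts) - 1L)) {
      segs[[length(segs) + 1L]] <- list(v = v, lo = cuts[i], hi = cuts[i + 1L])
      if (i == 1L) first_seg[v] <- length(segs)
    }
    last_seg[v] <- length(segs)
  }
  list(segs = segs, first_seg = first_seg, last_seg = last_seg)
}

seg_at <- function(sg, v, lo) {
  for (i in seq_along(sg$segs)) {
    s <- sg$segs[[i]]
    if (s$v == v && isTRUE(all.equal(s$lo, lo))) return(i)
  }
  stop_runtime("internal error: no segment at transfer point")
}

#' Simulate one gene tree inside a species tree
#'
#' Standard contained coalescent: within each species-tree branch of length
#' `t`, `k` gene lineages coalesce at rate `choose(k, 2)` per coalescent
#' unit; surviving lineages pass to the ancestral branch at each speciation
#' node, and coalescence continues above the root until a single lineage
#' remains. One haploid lineage is sampled per species tip. With
#' reticulations, each event flips one coin per gene: on success all
#' lineages on the recipient edge at the event time follow the donor edge.
#'
#' @param model A [species_tree_model()].
#' @param seed Integer seed; required (simulations must be reproducible).
#' @return A rooted binary `phylo` with tip set equal to the species tips
#'   and branch lengths in coalescent units. The attribute `event_paths`
#'   records, per reticulation, whether this gene took the donor path.
#' @export
simulate_contained_gene_tree <- function(model, seed) {
  stopifnot(inherits(model, "species_tree_model"))
  if (missing(seed) || is.null(seed)) {
    stop_validation("`seed` is required: unseeded simulation is refused")
  }
  set.seed(as.integer(seed))
  sim_gene_tree_impl(model)
}

sim_gene_tree_impl <- function(model, force_paths = NULL,
                               sg = model_segments(model)) {
  prep <- model$prep
  pt <- prep$pt
  ages <- prep$ages
  segs <- sg$segs
  nseg <- length(segs)
  nev <- length(model$reticulations)
  heads <- if (nev) {
    if (!is.null(force_paths)) rep_len(force_paths, nev) else
      stats::runif(nev) < vapply(model$reticulations, `[[`, numeric(1), "gamma")
  } else logical(0)

  # routing: destination pool for each segment's output
  # pools: 1..nseg are segment entry pools; nseg+1 is the root pool
  rootpool <- nseg + 1L
  dest <- integer(nseg)
  for (i in seq_len(nseg)) {
    s <- segs[[i]]
    ev_out <- 0L
    if (nev) {
      for (j in seq_len(nev)) {
        e <- model$reticulations[[j]]
        if (heads[j] && e$rv == s$v && isTRUE(all.equal(e$age, s$hi))) ev_out <- j
      }
    }
    if (ev_out > 0L) {
      e <- model$reticulations[[ev_out]]
      dest[i] <- seg_at(sg, e$dv, e$age)
    } else if (i < nseg && segs[[i + 1L]]$v == s$v &&
               isTRUE(all.equal(segs[[i + 1L]]$lo, s$hi))) {
      dest[i] <- i + 1L
    } else {
      p <- pt$parent[s$v]
      dest[i] <- if (p == prep$root) rootpool else sg$first_seg[p]
    }
  }
  n_prod <- tabulate(dest, nbins = nseg + 1L)

  n_tips <- length(prep$tips)
  # gene lineages: 1..n_tips are tips (in pt tip order)
  lin_age <- ages[prep$tips]
  merge_left <- merge_right <- integer(0)
  merge_age <- numeric(0)

  pools <- vector("list", nseg + 1L)
  # seed tip lineages into the first segment above each tip
  for (ti in seq_along(prep$tips)) {
    v <- prep$tips[ti]
    fs <- sg$first_seg[v]
    pools[[fs]] <- c(pools[[fs]], ti)
  }
  next_node <- n_tips
  coalesce_in <- function(P, lo, hi) {
    t <- lo
    while (length(P) >= 2L) {
      k <- length(P)
      dt <- stats::rexp(1L, k * (k - 1) / 2)
      if (t + dt > hi) break
      t <- t + dt
      pair <- sample.int(k, 2L)
      next_node <<- next_node + 1L
      merge_left <<- c(merge_left, P[pair[1L]])
      merge_right <<- c(merge_right, P[pair[2L]])
      merge_age <<- c(merge_age, t)
      lin_age[next_node] <<- t
      P <- c(P[-pair], next_node)
    }
    P
  }

  done <- rep(FALSE, nseg)
  ready <- which(n_prod[seq_len(nseg)] == 0L)
  while (length(ready)) {
    i <- ready[1L]
    ready <- ready[-1L]
    if (done[i]) next
    done[i] <- TRUE
    s <- segs[[i]]
    out <- coalesce_in(pools[[i]], s$lo, s$hi)
    d <- dest[i]
    # note: assigning NULL would delete the list element, so guard empties
    if (length(out)) pools[[d]] <- c(pools[[d]], out)
    n_prod[d] <- n_prod[d] - 1L
    if (d <= nseg && n_prod[d] == 0L) ready <- c(ready, d)
  }
  if (!all(done)) stop_runtime("internal error: unreachable species-tree segment")
  # above the root
  P <- pools[[rootpool]]
  t <- ages[prep$root]
  while (length(P) >= 2L) {
    k <- length(P)
    t <- t + stats::rexp(1L, k * (k - 1) / 2)
    pair <- sample.int(k, 2L)
    next_node <- next_node + 1L
    merge_left <- c(merge_left, P[pair[1L]])
    merge_right <- c(merge_right, P[pair[2L]])
    merge_age <- c(merge_age, t)
    lin_age[next_node] <- t
    P <- c(P[-pair], next_node)
  }

  N <- next_node
  parent <- integer(N)
  for (m in seq_along(merge_age)) {
    parent[merge_left[m]] <- n_tips + m
    parent[merge_right[m]] <- n_tips + m
  }
  len <- rep(NA_real_, N)
  for (x in seq_len(N)) {
    if (parent[x] > 0L) len[x] <- lin_age[parent[x]] - lin_age[x]
  }
  label <- c(pt$label[prep$tips], rep(NA_character_, N - n_tips))
  gt <- as_phylo(ptree(parent, len, rep(NA_real_, N), label))
  attr(gt, "event_paths") <- heads
  gt
}

#' Simulate a set of independent gene trees
#'
#' Per-gene sub-seeds are derived deterministically from the master seed
#' (counter-based), so results do not depend on iteration order and any
#' single gene can be re-simulated in isolation.
#'
#' @param model A [species_tree_model()].
#' @param n Number of gene trees (>= 1); the conventional null uses 1,000.
#' @param seed Integer master seed.
#' @return Named list of `phylo` gene trees (`sim_0001`, ...).
#' @export
simulate_gene_trees <- function(model, n = 1000, seed) {
  stopifnot(inherits(model, "species_tree_model"))
  if (!is.numeric(n) || n < 1) stop_validation("`n` must be >= 1")
  if (missing(seed) || is.null(seed)) {
    stop_validation("`seed` is required: unseeded simulation is refused")
  }
  n <- as.integer(n)
  sg <- model_segments(model)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(gene_seed(seed, i))
    out[[i]] <- sim_gene_tree_impl(model, sg = sg)
  }
  names(out) <- sprintf("sim_%04d", seq_len(n))
  out
}

# counter-based sub-seed, kept inside 32-bit integer range
gene_seed <- function(seed, i, stream = 0L) {
  as.integer((as.numeric(seed) * 48271 + i * 69621 + stream * 16807) %% 2147483563) + 1L
}

#' Probability a 3-taxon gene tree matches the species tree
#'
#' Closed-form multispecies-coalescent identity used to calibrate the
#' simulator: for an internal branch of length `t` coalescent units
#' separating ((A,B),C), the gene tree topology matches the species tree
#' with probability `1 - (2/3) exp(-t)`; each discordant resolution has
#' probability `(1/3) exp(-t)`.
#'
#' @param t Internal branch length(s), coalescent units, >= 0.
#' @return Probability vector.
#' @export
three_taxon_concordance_probability <- function(t) {
  if (any(t < 0)) stop_validation("`t` must be >= 0")
  1 - (2 / 3) * exp(-t)
}
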