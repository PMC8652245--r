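#' Configuration for a synthetic discordance study
#'
#' Describes a full synthetic dataset with the statistical structure of an
#' anchored-enrichment phylogenomic study: a clade-structured species tree,
#' coalescent gene trees with estimation error and bootstrap-like supports,
#' per-locus taxon dropout, and an optionally reticulate history. Defaults
#' echo a ~190-sample, 114-locus sage dataset: six clade blocks of sizes
#' 93/10/10/37/20 plus a 20-tip outgroup, and a mean of 96.25 recovered loci
#' per sample.
#'
#' @param n_tips Total number of tips (must equal `sum(clade_blocks)`).
#' @param clade_blocks Named integer vector, clade name -> tip count. A block
#'   named `"outgroup"` is placed sister to the ingroup and receives the
#'   dropout multiplier.
#' @param birth_rate Yule speciation rate used for backbone and clade
#'   subtrees (shapes only; depths are rescaled).
#' @param depth_cu Root age of the species tree in coalescent units.
#' @param n_loci Number of gene trees.
#' @param mean_locus_recovery Per-(tip, locus) retention probability for
#'   non-outgroup tips (default 96.25/114).
#' @param outgroup_multiplier Retention multiplier for outgroup tips
#'   (dropout concentrates in outgroups).
#' @param error_nni_rate Expected number of nearest-neighbor-interchange
#'   perturbations per gene tree (gene-tree estimation error).
#' @param support_model List controlling bootstrap-like supports; see
#'   [perturb_gene_tree()].
#' @param reticulations List of lists with fields `donor`, `recipient`
#'   (clade names or tip vectors), `gamma`, `time`; see [reticulation()].
#' @param plastome_scale Branch-length multiplier for the plastome
#'   coalescent (haploid uniparental genome, smaller effective size; default
#'   2, i.e. faster coalescence).
#' @param plastome_capture If `TRUE`, the plastome is routed through every
#'   reticulation event (chloroplast capture).
#' @param seed Master seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_tips = 190,
                              clade_blocks = c(Calosphace = 93, Glutinaria = 10,
                                               Heterosphace = 10, Salvia = 37,
                                               Sclarea = 20, outgroup = 20),
                              birth_rate = 1,
                              depth_cu = 10,
                              n_loci = 114,
                              mean_locus_recovery = 96.25 / 114,
                              outgroup_multiplier = 0.5,
                              error_nni_rate = 1,
                              support_model = default_support_model(),
                              reticulations = list(),
                              plastome_scale = 2,
                              plastome_capture = FALSE,
                              seed = 1) {
  if (sum(clade_blocks) != n_tips) {
    stop_validation("`clade_blocks` must sum to `n_tips`")
  }
  if (is.null(names(clade_blocks)) || any(!nzchar(names(clade_blocks)))) {
    stop_validation("`clade_blocks` must be named")
  }
  if (mean_locus_recovery <= 0 || mean_locus_recovery > 1) {
    stop_validation("`mean_locus_recovery` must lie in (0, 1]")
  }
  if (birth_rate <= 0 || depth_cu <= 0 || error_nni_rate < 0 ||
      n_loci < 1 || plastome_scale <= 0) {
    stop_validation("rates, depths and counts must be positive")
  }
  structure(list(n_tips = as.integer(n_tips), clade_blocks = clade_blocks,
                 birth_rate = birth_rate, depth_cu = depth_cu,
                 n_loci = as.integer(n_loci),
                 mean_locus_recovery = mean_locus_recovery,
                 outgroup_multiplier = outgroup_multiplier,
                 error_nni_rate = error_nni_rate,
                 support_model = support_model,
                 reticulations = reticulations,
                 plastome_scale = plastome_scale,
                 plastome_capture = plastome_capture,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' @rdname simulation_config
#' @param low,high Ranges (min, max) of uniform support draws for edges near
#'   a perturbation and for untouched edges, respectively.
#' @param neighbor_radius Edges within this edge-graph distance of a
#'   perturbed edge also draw from the low range (0 = the perturbed edge
#'   only).
#' @param length_scale If non-`NULL`, supports are instead tied to gene-tree
#'   internal branch length: `1 - exp(-len / length_scale)` plus small
#'   uniform noise, emulating that short (ILS- and error-prone) edges earn
#'   low bootstrap.
#' @param noise Half-width of the uniform jitter for length-based supports.
#' @export
default_support_model <- function(low = c(0.02, 0.30), high = c(0.75, 1.0),
                                  neighbor_radius = 1, length_scale = NULL,
                                  noise = 0.05) {
  list(low = low, high = high, neighbor_radius = neighbor_radius,
       length_scale = length_scale, noise = noise)
}

scale_tree_depth <- function(phy, depth) {
  cur <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length * depth / cur
  phy
}

yule_clade <- function(m, birth_rate, depth) {
  if (m == 1L) return(NULL)
  scale_tree_depth(ape::rphylo(m, birth = birth_rate, death = 0), depth)
}

# Replace backbone tips by clade subtrees (ptree concatenation); `subtrees`
# is a list parallel to backbone tips with NULL for singleton blocks, and
# `crowns` the crown depth of each subtree.
graft_clades <- function(backbone, subtrees, crowns) {
  pt <- as_ptree(backbone)
  tipids <- which(!is.na(pt$label))
  tipids <- tipids[match(backbone$tip.label, pt$label[tipids])]
  parent <- pt$parent; len <- pt$len; support <- pt$support; label <- pt$label
  alive <- rep(TRUE, length(parent))
  for (i in seq_along(subtrees)) {
    sub <- subtrees[[i]]
    if (is.null(sub)) next
    tid <- tipids[i]
    spt <- as_ptree(sub)
    off <- length(parent)
    sparent <- spt$parent
    sparent[sparent > 0L] <- sparent[sparent > 0L] + off
    parent <- c(parent, sparent)
    len <- c(len, spt$len)
    support <- c(support, spt$support)
    label <- c(label, spt$label)
    alive <- c(alive, rep(TRUE, length(spt$parent)))
    sroot <- off + which(spt$parent == 0L)
    parent[sroot] <- parent[tid]
    len[sroot] <- len[tid] - crowns[i]
    if (len[sroot] < 0) stop_runtime("clade crown deeper than its stem")
    alive[tid] <- FALSE
  }
  as_phylo(ptree_compact(ptree(parent, len, support, label), alive))
}

# Join two trees (or a tree and a single tip label) as sisters under a new
# root; stem1/stem2 are the new stem lengths.
join_sister <- function(t1, t2, stem1, stem2) {
  p1 <- as_ptree(t1)
  n1 <- length(p1$parent)
  r1 <- which(p1$parent == 0L)
  if (is.character(t2)) {
    parent <- c(p1$parent, 0L)
    len <- c(p1$len, stem2)
    support <- c(p1$support, NA_real_)
    label <- c(p1$label, t2)
    r2 <- n1 + 1L
  } else {
    p2 <- as_ptree(t2)
    sp <- p2$parent
    sp[sp > 0L] <- sp[sp > 0L] + n1
    parent <- c(p1$parent, sp)
    len <- c(p1$len, p2$len)
    support <- c(p1$support, p2$support)
    label <- c(p1$label, p2$label)
    r2 <- n1 + which(p2$parent == 0L)
    len[r2] <- stem2
  }
  root <- length(parent) + 1L
  parent <- c(parent, 0L)
  parent[r1] <- root
  parent[r2] <- root
  len[r1] <- stem1
  len <- c(len, NA_real_)
  support <- c(support, NA_real_)
  label <- c(label, NA_character_)
  as_phylo(ptree(parent, len, support, label))
}

#' Generate a clade-structured species tree
#'
#' Builds a Yule backbone over the ingroup clade blocks, grafts a Yule
#' subtree of the required size onto each backbone tip (so each named block
#' is monophyletic by construction), attaches the outgroup block as sister
#' to the ingroup, and scales the whole tree to `depth_cu` coalescent units.
#'
#' @param config A [simulation_config()].
#' @return List with `model` (a [species_tree_model()], reticulations
#'   resolved from the config) and `clade_map` (tibble `tip`, `clade`).
#' @export
generate_species_tree <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(gene_seed(config$seed, 0L, 1L))
  blocks <- config$clade_blocks
  og <- names(blocks) == "outgroup"
  in_blocks <- blocks[!og]
  depth <- config$depth_cu
  d_in <- if (any(og)) 0.6 * depth else depth
  k_in <- length(in_blocks)
  if (k_in > 1L) {
    bb <- scale_tree_depth(ape::rphylo(k_in, birth = config$birth_rate, death = 0),
                           d_in)
    bb$tip.label <- names(in_blocks)
    pend <- bb$edge.length[match(seq_len(k_in), bb$edge[, 2])]
    crowns <- ifelse(in_blocks[bb$tip.label] > 1L, 0.5 * pend, 0)
    subs <- purrr::map(seq_len(k_in), function(i) {
      m <- in_blocks[[bb$tip.label[i]]]
      tr <- yule_clade(m, config$birth_rate, crowns[i])
      if (!is.null(tr)) tr$tip.label <- sprintf("%s_%02d", bb$tip.label[i], seq_len(m))
      tr
    })
    ingroup <- graft_clades(bb, subs, crowns)
    singles <- names(in_blocks)[in_blocks == 1L]
    for (s in singles) {
      ingroup$tip.label[ingroup$tip.label == s] <- sprintf("%s_01", s)
    }
  } else {
    # single ingroup block: its crown is the whole ingroup
    m <- in_blocks[[1L]]
    if (m < 2L) stop_validation("the single ingroup block needs >= 2 tips")
    ingroup <- yule_clade(m, config$birth_rate, d_in)
    ingroup$tip.label <- sprintf("%s_%02d", names(in_blocks), seq_len(m))
  }
  if (any(og)) {
    m_og <- blocks[["outgroup"]]
    if (m_og > 1L) {
      ogt <- yule_clade(m_og, config$birth_rate, 0.5 * depth)
      ogt$tip.label <- sprintf("outgroup_%02d", seq_len(m_og))
      tree <- join_sister(ingroup, ogt, depth - d_in, 0.5 * depth)
    } else {
      tree <- join_sister(ingroup, "outgroup_01", depth - d_in, depth)
    }
  } else {
    tree <- ingroup
  }
  clade_map <- tibble::tibble(
    tip = tree$tip.label,
    clade = sub("_[0-9]+$", "", tree$tip.label))
  retics <- purrr::map(config$reticulations, function(r) {
    resolve <- function(x) {
      if (length(x) == 1L && x %in% clade_map$clade) {
        clade_map$tip[clade_map$clade == x]
      } else x
    }
    reticulation(donor = resolve(r$donor), recipient = resolve(r$recipient),
                 gamma = r$gamma, time = if (is.null(r$time)) 0.5 else r$time)
  })
  model <- species_tree_model(tree, retics)
  list(model = model, clade_map = clade_map)
}

#' Perturb a gene tree with estimation error and assign supports
#'
#' Applies a Poisson(`error_nni_rate`) number of random nearest-neighbor
#' interchanges to a binary gene tree, then assigns bootstrap-like supports:
#' edges within `neighbor_radius` (edge-graph distance) of a perturbed edge
#' draw from the low-support range, all others from the high range.
#' Alternatively, with `support_model$length_scale` set, supports are tied
#' to internal branch length (short edges — the ILS-prone, hard-to-estimate
#' ones — earn low support) and perturbation marks are ignored for support.
#'
#' @param tree Binary `phylo` (as produced by the simulator).
#' @param error_nni_rate Expected NNI count.
#' @param support_model See [default_support_model()].
#' @return A `phylo` with supports in its node labels; attributes `n_nni`
#'   (perturbations applied) and `perturbed` (logical per internal node, in
#'   node-label order) record the truth.
#' @export
perturb_gene_tree <- function(tree, error_nni_rate,
                              support_model = default_support_model()) {
  validate_phylo(tree)
  if (!ape::is.binary(tree)) stop_validation("gene tree must be binary")
  pt <- as_ptree(tree)
  root <- ptree_root(pt)
  n_all <- length(pt$parent)
  k <- stats::rpois(1L, error_nni_rate)
  marked <- rep(FALSE, n_all)
  for (rep_i in seq_len(k)) {
    elig <- which(is.na(pt$label) & pt$parent > 0L)
    elig <- elig[vapply(elig, function(v) sum(pt$parent == v) >= 2L, logical(1))]
    if (!length(elig)) break
    v <- if (length(elig) == 1L) elig else sample(elig, 1L)
    u <- pt$parent[v]
    sibs <- setdiff(which(pt$parent == u), v)
    s <- if (length(sibs) == 1L) sibs else sample(sibs, 1L)
    ch <- which(pt$parent == v)
    c1 <- if (length(ch) == 1L) ch else sample(ch, 1L)
    pt$parent[c1] <- u
    pt$parent[s] <- v
    marked[v] <- TRUE
  }
  # support assignment: perturbed edges (and neighbors within the radius)
  # always draw from the low range; untouched edges draw from the high range,
  # or from the branch-length model when `length_scale` is set (short,
  # ILS-prone edges earn low support)
  internal <- which(is.na(pt$label) & pt$parent > 0L)
  sm <- support_model
  near <- vapply(internal, function(w) {
    if (marked[w]) return(TRUE)
    if (sm$neighbor_radius < 1) return(FALSE)
    u <- pt$parent[w]
    any(marked[which(pt$parent == w)]) ||      # edges below w
      (u > 0L && marked[u]) ||                 # edge above parent
      (u > 0L && any(marked[setdiff(which(pt$parent == u), w)]))  # siblings
  }, logical(1))
  sup <- numeric(length(internal))
  if (!is.null(sm$length_scale)) {
    base <- 1 - exp(-pt$len[internal] / sm$length_scale)
    sup <- pmin(1, pmax(0, base + stats::runif(length(internal), -sm$noise, sm$noise)))
    if (any(near)) sup[near] <- stats::runif(sum(near), sm$low[1], sm$low[2])
  } else {
    sup[near] <- stats::runif(sum(near), sm$low[1], sm$low[2])
    sup[!near] <- stats::runif(sum(!near), sm$high[1], sm$high[2])
  }
  pt$support[internal] <- sup
  out <- as_phylo(pt)
  attr(out, "n_nni") <- k
  attr(out, "n_perturbed") <- sum(marked)
  out
}

#' Construct a nested reticulation between two clades
#'
#' Picks a properly nested subclade of `recipient_clade` (so that rerouted
#' genes change the *within-clade* topology, which per-clade distance
#' profiles can detect) and a donor edge inside `donor_clade` whose age range
#' covers the event, and returns the corresponding reticulation spec (tip
#' vectors). Useful for building synthetic gene-flow scenarios on generated
#' species trees.
#'
#' @param model A [species_tree_model()] (tree only is used).
#' @param clade_map Tibble `tip`, `clade`.
#' @param recipient_clade Clade name from `clade_map`.
#' @param donor_clade Clade name, or `NULL` for any donor edge outside the
#'   recipient clade.
#' @param gamma Inheritance probability.
#' @param size_range Allowed tip-count range for the recipient subclade.
#' @param time Position along the recipient edge (fraction).
#' @return A list with fields `donor`, `recipient`, `gamma`, `time`, ready
#'   for `simulation_config(reticulations = list(...))`.
#' @export
pick_nested_reticulation <- function(model, clade_map, recipient_clade,
                                     donor_clade = NULL, gamma = 0.3,
                                     size_range = c(3, 4), time = 0.5) {
  stopifnot(inherits(model, "species_tree_model"))
  prep <- model$prep
  pt <- prep$pt
  below <- vector("list", length(pt$parent))
  for (v in ptree_postorder(pt)) {
    below[[v]] <- if (!is.na(pt$label[v])) pt$label[v] else
      unlist(lapply(which(pt$parent == v), function(c) below[[c]]))
  }
  rec_tips <- clade_map$tip[clade_map$clade == recipient_clade]
  don_tips <- if (is.null(donor_clade)) {
    setdiff(clade_map$tip, rec_tips)
  } else {
    clade_map$tip[clade_map$clade == donor_clade]
  }
  # score each candidate by how many unrooted splits of the clade topology a
  # basal reattachment of the subclade would change: rerouted genes are only
  # detectable within the clade if that number is positive (a subclade whose
  # removal path collapses to the same unrooted topology is a no-op)
  spC <- if (length(rec_tips) >= 4L) prune_to_taxa(model$tree, rec_tips) else NULL
  reroute_changes <- function(S) {
    if (is.null(spC) || length(rec_tips) - length(S) < 2L) return(0L)
    keys1 <- split_keys(nontrivial_splits(spC, sort(rec_tips)))
    rest <- tryCatch(prune_to_taxa(spC, setdiff(rec_tips, S)),
                     error = function(e) NULL)
    if (is.null(rest)) return(0L)
    sub <- if (length(S) >= 2L) prune_to_taxa(spC, S) else S
    moved <- join_sister(rest, sub, 1, 1)
    keys2 <- split_keys(nontrivial_splits(moved, sort(rec_tips)))
    length(setdiff(keys1, keys2)) + length(setdiff(keys2, keys1))
  }
  size_sets <- list(size_range, c(2L, max(size_range[2] + 2L, 6L)))
  # passes: topology-changing subclades first, then anything that fits
  for (min_changed in c(1L, 0L)) {
    for (sz in size_sets) {
      cands <- which(vapply(below, function(b)
        all(b %in% rec_tips) && length(b) >= sz[1] &&
          length(b) <= sz[2] && length(b) < length(rec_tips),
        logical(1)))
      changed <- vapply(cands, function(v) reroute_changes(below[[v]]), integer(1))
      cands <- cands[changed >= min_changed]
      ch <- changed[changed >= min_changed]
      cands <- cands[order(-ch, prep$ages[cands])]
      for (tf in unique(c(time, 0.5, 0.25, 0.1, 0.02))) {
        for (rv in cands) {
          a_r <- prep$ages[rv]; a_rp <- prep$ages[pt$parent[rv]]
          t_e <- a_r + tf * (a_rp - a_r)
          dc <- which(vapply(seq_along(below), function(v)
            pt$parent[v] > 0L && all(below[[v]] %in% don_tips) &&
              prep$ages[v] < t_e && prep$ages[pt$parent[v]] > t_e, logical(1)))
          if (length(dc)) {
            return(list(donor = below[[dc[1]]], recipient = below[[rv]],
                        gamma = gamma, time = tf))
          }
        }
      }
    }
  }
  stop_runtime("no donor edge overlaps the recipient event age")
}

#' Apply per-locus taxon dropout
#'
#' Each (tip, locus) pair is retained independently with probability
#' `mean_locus_recovery`, multiplied by `outgroup_multiplier` for tips of
#' the outgroup clade (locus dropout concentrates in outgroups). Trees left
#' with fewer than 4 tips are dropped.
#'
#' @param gene_trees Named list of `phylo` on the full tip set.
#' @param config A [simulation_config()].
#' @param clade_map Tibble `tip`, `clade` (block named `"outgroup"` gets the
#'   multiplier).
#' @param seed Integer seed.
#' @return Named list of pruned `phylo`; attribute `dropped` names loci that
#'   fell below 4 tips.
#' @export
apply_missingness <- function(gene_trees, config, clade_map, seed) {
  p_base <- config$mean_locus_recovery
  out <- list()
  dropped <- character(0)
  og_tips <- clade_map$tip[clade_map$clade == "outgroup"]
  for (i in seq_along(gene_trees)) {
    gt <- gene_trees[[i]]
    set.seed(gene_seed(seed, i, 4L))
    p <- ifelse(gt$tip.label %in% og_tips,
                p_base * config$outgroup_multiplier, p_base)
    keep <- gt$tip.label[stats::runif(length(p)) < p]
    if (length(keep) < 4L) {
      dropped <- c(dropped, names(gene_trees)[i])
      next
    }
    out[[names(gene_trees)[i]]] <- prune_to_taxa(gt, keep)
  }
  if (!length(out)) {
    stop_runtime("all gene trees dropped: retention too low")
  }
  attr(out, "dropped") <- dropped
  out
}

#' Generate a complete synthetic study
#'
#' Composes [generate_species_tree()], [simulate_gene_trees()],
#' [perturb_gene_tree()] and [apply_missingness()] into a full synthetic
#' dataset, plus a plastome tree simulated as a single contained-coalescent
#' genealogy on the species tree with branch lengths multiplied by
#' `plastome_scale` (a haploid, uniparentally inherited genome coalesces
#' faster) and bootstrap-like supports tied to branch length. With
#' `plastome_capture = TRUE` the plastome deterministically follows the
#' donor path of every reticulation (chloroplast capture). A pure function
#' of the config: equal seeds give identical studies.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_study` list: `model`, `clade_map`, `gene_trees`
#'   (supports and missingness applied), `plastome_tree`, `truth` (applied
#'   perturbation counts, per-locus reticulation paths, dropped loci),
#'   `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  st <- generate_species_tree(config)
  model <- st$model
  complete <- simulate_gene_trees(model, config$n_loci,
                                  seed = gene_seed(config$seed, 1L, 2L))
  names(complete) <- sprintf("locus_%03d", seq_along(complete))
  locus_paths <- do.call(rbind, lapply(complete, attr, "event_paths"))
  n_nni <- integer(length(complete))
  perturbed <- purrr::imap(complete, function(gt, id) {
    i <- match(id, names(complete))
    set.seed(gene_seed(config$seed, i, 3L))
    out <- perturb_gene_tree(gt, config$error_nni_rate, config$support_model)
    n_nni[i] <<- attr(out, "n_nni")
    out
  })
  observed <- apply_missingness(perturbed, config, st$clade_map,
                                seed = config$seed)
  # plastome: scaled-branch-length model, optionally captured
  ptree_sp <- model$tree
  ptree_sp$edge.length <- ptree_sp$edge.length * config$plastome_scale
  retics <- purrr::map(model$reticulations, "spec")
  model_p <- species_tree_model(ptree_sp, retics)
  set.seed(gene_seed(config$seed, 2L, 5L))
  plastome <- sim_gene_tree_impl(model_p,
                                 force_paths = if (length(retics))
                                   rep(config$plastome_capture, length(retics))
                                 else NULL)
  set.seed(gene_seed(config$seed, 3L, 5L))
  pt_len <- plastome$edge.length[plastome$edge[, 2] > length(plastome$tip.label)]
  scale <- max(stats::median(pt_len), 1e-6)
  plastome <- assign_length_supports(plastome, scale, noise = 0.05)
  truth <- list(
    reticulations = purrr::map(config$reticulations, function(r)
      list(donor = r$donor, recipient = r$recipient, gamma = r$gamma)),
    locus_paths = locus_paths,
    n_nni = stats::setNames(n_nni, names(complete)),
    dropped = attr(observed, "dropped"),
    plastome_capture = config$plastome_capture)
  structure(list(model = model, clade_map = st$clade_map,
                 gene_trees = observed, plastome_tree = plastome,
                 truth = truth, config = config),
            class = "synthetic_study")
}

assign_length_supports <- function(tree, length_scale, noise = 0.05) {
  pt <- as_ptree(tree)
  internal <- which(is.na(pt$label) & pt$parent > 0L)
  base <- 1 - exp(-pt$len[internal] / length_scale)
  pt$support[internal] <- pmin(1, pmax(0, base +
    stats::runif(length(internal), -noise, noise)))
  as_phylo(pt)
}

#' Write a synthetic study to a directory
#'
#' Emits `species.nwk`, `genetrees.nwk` (one Newick per line with `# locus`
#' headers), `plastome.nwk`, `clades.tsv`, `truth.json`, `config.yaml`.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(write_newick(study$model$tree), file.path(dir, "species.nwk"))
  write_gene_trees(study$gene_trees, file.path(dir, "genetrees.nwk"))
  writeLines(write_newick(study$plastome_tree), file.path(dir, "plastome.nwk"))
  write_clade_table(study$clade_map, file.path(dir, "clades.tsv"))
  truth <- study$truth
  truth$locus_paths <- if (is.null(truth$locus_paths)) list() else
    apply(truth$locus_paths, 1L, as.logical, simplify = FALSE)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  cfg <- unclass(study$config)
  cfg$clade_blocks <- as.list(cfg$clade_blocks)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
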