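test_that("simulation_config validates block sums and rates", {
  expect_error(simulation_config(n_tips = 10, clade_blocks = c(A = 4, B = 4)),
               "sum", class = "discordia_validation_error")
  expect_error(simulation_config(n_tips = 8, clade_blocks = c(A = 4, B = 4),
                                 mean_locus_recovery = 0),
               class = "discordia_validation_error")
  cfg <- simulation_config()
  expect_equal(cfg$n_tips, 190L)
  expect_equal(sum(cfg$clade_blocks), 190)
  expect_equal(cfg$n_loci, 114L)
  expect_equal(cfg$mean_locus_recovery, 96.25 / 114)
})

test_that("generated species trees have monophyletic blocks at the right depth", {
  cfg <- simulation_config(n_tips = 24, clade_blocks = c(A = 10, B = 5, C = 4,
                                                         outgroup = 5),
                           depth_cu = 12, seed = 3)
  st <- generate_species_tree(cfg)
  tr <- st$model$tree
  expect_equal(length(tr$tip.label), 24)
  expect_equal(max(ape::node.depth.edgelength(tr)), 12, tolerance = 1e-9)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  for (cl in c("A", "B", "C", "outgroup")) {
    taxa <- st$clade_map$tip[st$clade_map$clade == cl]
    expect_length(taxa, cfg$clade_blocks[[cl]])
    expect_true(ape::is.monophyletic(tr, taxa))
  }
  # deterministic under the seed
  st2 <- generate_species_tree(cfg)
  expect_identical(write_newick(st$model$tree), write_newick(st2$model$tree))
})

test_that("single-tip blocks and missing outgroup block are handled", {
  cfg <- simulation_config(n_tips = 7, clade_blocks = c(A = 3, B = 1, C = 3),
                           seed = 5)
  st <- generate_species_tree(cfg)
  expect_equal(length(st$model$tree$tip.label), 7)
  expect_true("B_01" %in% st$model$tree$tip.label)
  cfg2 <- simulation_config(n_tips = 9, clade_blocks = c(A = 4, B = 4, outgroup = 1),
                            seed = 5)
  st2 <- generate_species_tree(cfg2)
  expect_true("outgroup_01" %in% st2$model$tree$tip.label)
})

test_that("perturb_gene_tree: rate zero is the identity with high supports", {
  m <- species_tree_model(parse_newick("(((A:1,B:1):1,(C:1,D:1):1):1,E:3);"))
  g <- simulate_contained_gene_tree(m, seed = 7)
  set.seed(1)
  out <- perturb_gene_tree(g, 0)
  expect_equal(split_keys_for_test(out, sort(g$tip.label)),
               split_keys_for_test(g, sort(g$tip.label)))
  sup <- node_support(out)
  expect_true(all(sup[!is.na(sup)] >= 0.75))
  expect_equal(attr(out, "n_nni"), 0)
})

test_that("RF distance to the input grows with the NNI rate", {
  cfg <- simulation_config(n_tips = 20, clade_blocks = c(A = 16, outgroup = 4),
                           depth_cu = 30, seed = 11, error_nni_rate = 0,
                           mean_locus_recovery = 1)
  st <- generate_species_tree(cfg)
  g <- simulate_contained_gene_tree(st$model, seed = 13)
  mean_rf <- vapply(c(0, 2, 6), function(rate) {
    ds <- vapply(1:30, function(i) {
      set.seed(1000 + i)
      rf_distance(g, perturb_gene_tree(g, rate))
    }, numeric(1))
    mean(ds)
  }, numeric(1))
  expect_equal(mean_rf[1], 0)
  expect_lt(mean_rf[2], mean_rf[3])
})

test_that("perturbed-edge supports sit below untouched-edge supports", {
  m <- species_tree_model(ape::compute.brlen(random_tree(20, 3), 1))
  g <- simulate_contained_gene_tree(m, seed = 17)
  lows <- c(); highs <- c()
  for (i in 1:20) {
    set.seed(i)
    out <- perturb_gene_tree(g, 2)
    sup <- node_support(out)
    sup <- sup[!is.na(sup)]
    lows <- c(lows, sup[sup < 0.33])
    highs <- c(highs, sup[sup >= 0.75])
  }
  expect_gt(length(lows), 0)
  expect_gt(mean(highs), mean(lows))
})

test_that("length-keyed supports rise with branch length", {
  m <- species_tree_model(ape::compute.brlen(random_tree(20, 4), 1))
  g <- simulate_contained_gene_tree(m, seed = 19)
  set.seed(2)
  out <- perturb_gene_tree(g, 0, default_support_model(length_scale = 0.5))
  pt_len <- out$edge.length[out$edge[, 2] > length(out$tip.label)]
  sup <- node_support(out)
  sup <- sup[match(out$edge[out$edge[, 2] > length(out$tip.label), 2] -
                   length(out$tip.label), seq_len(out$Nnode))]
  ok <- !is.na(sup)
  expect_gt(stats::cor(pt_len[ok], sup[ok], method = "spearman"), 0.5)
})

test_that("missingness matches the binomial expectation on ingroup tips", {
  cfg <- simulation_config(n_tips = 40, clade_blocks = c(A = 30, outgroup = 10),
                           n_loci = 60, depth_cu = 10, seed = 23,
                           mean_locus_recovery = 0.844, error_nni_rate = 0)
  st <- generate_species_tree(cfg)
  gts <- simulate_gene_trees(st$model, 60, seed = 29)
  names(gts) <- sprintf("locus_%03d", seq_along(gts))
  out <- apply_missingness(gts, cfg, st$clade_map, seed = 23)
  ing <- st$clade_map$tip[st$clade_map$clade != "outgroup"]
  og <- st$clade_map$tip[st$clade_map$clade == "outgroup"]
  per_tip <- vapply(ing, function(tp)
    sum(vapply(out, function(g) tp %in% g$tip.label, logical(1))), numeric(1))
  expected <- 0.844 * length(out)
  se <- sqrt(0.844 * (1 - 0.844) * length(out))
  expect_lt(abs(mean(per_tip) - expected), 2 * se / sqrt(length(ing)) * 3)
  # outgroups drop out more
  per_og <- vapply(og, function(tp)
    sum(vapply(out, function(g) tp %in% g$tip.label, logical(1))), numeric(1))
  expect_lt(mean(per_og), mean(per_tip))
  # retention 1 is the identity
  cfg1 <- simulation_config(n_tips = 40, clade_blocks = c(A = 30, outgroup = 10),
                            n_loci = 60, depth_cu = 10, seed = 23,
                            mean_locus_recovery = 1, outgroup_multiplier = 1,
                            error_nni_rate = 0)
  out1 <- apply_missingness(gts, cfg1, st$clade_map, seed = 23)
  expect_equal(length(out1[[1]]$tip.label), 40)
})

test_that("generate_study is a pure function of its config", {
  cfg <- simulation_config(n_tips = 20, clade_blocks = c(A = 8, B = 8, outgroup = 4),
                           n_loci = 12, depth_cu = 8, seed = 31)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(vapply(s1$gene_trees, write_newick, character(1)),
                   vapply(s2$gene_trees, write_newick, character(1)))
  expect_identical(write_newick(s1$plastome_tree), write_newick(s2$plastome_tree))
  expect_identical(s1$truth$n_nni, s2$truth$n_nni)
  # truth records reticulation paths per locus
  expect_true(all(names(s1$gene_trees) %in% names(s1$truth$n_nni)))
})

test_that("plastome capture places the recipient subclade with the donor", {
  cfg0 <- simulation_config(n_tips = 20, clade_blocks = c(A = 8, B = 8, outgroup = 4),
                            n_loci = 5, depth_cu = 40, seed = 37,
                            error_nni_rate = 0, mean_locus_recovery = 1)
  st <- generate_species_tree(cfg0)
  ret <- pick_nested_reticulation(st$model, st$clade_map, "A", "B", gamma = 0.5)
  make_cfg <- function(capture) {
    simulation_config(n_tips = 20, clade_blocks = c(A = 8, B = 8, outgroup = 4),
                      n_loci = 5, depth_cu = 40, seed = 37,
                      error_nni_rate = 0, mean_locus_recovery = 1,
                      reticulations = list(ret), plastome_capture = capture)
  }
  sc <- generate_study(make_cfg(TRUE))
  # with capture, recipient tips coalesce with the donor side in the plastome
  Dp <- ape::cophenetic.phylo(sc$plastome_tree)
  rec <- ret$recipient
  other_A <- setdiff(st$clade_map$tip[st$clade_map$clade == "A"], rec)
  d_to_B <- mean(Dp[rec, ret$donor[1]])
  d_to_A <- mean(Dp[rec, other_A])
  expect_lt(d_to_B, d_to_A)
  expect_true(sc$truth$plastome_capture)
})

test_that("write_study emits a complete, parseable study directory", {
  cfg <- simulation_config(n_tips = 16, clade_blocks = c(A = 6, B = 6, outgroup = 4),
                           n_loci = 8, depth_cu = 8, seed = 41)
  study <- generate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(study, dir)
  expect_setequal(list.files(dir),
                  c("species.nwk", "genetrees.nwk", "plastome.nwk",
                    "clades.tsv", "truth.json", "config.yaml"))
  sp <- parse_newick(paste(readLines(file.path(dir, "species.nwk")), collapse = ""))
  expect_equal(length(sp$tip.label), 16)
  gts <- read_gene_trees(file.path(dir, "genetrees.nwk"))
  expect_equal(names(gts), names(study$gene_trees))
  cm <- read_clade_table(file.path(dir, "clades.tsv"))
  expect_equal(nrow(cm), 16)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_true("n_nni" %in% names(truth))
  cfg_back <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg_back$seed, 41)
})
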