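test_that("Welch t-test matches the hand-derived example and base R", {
  w <- welch_t_test(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(w$statistic, -1.0954, tolerance = 1e-4)
  expect_equal(w$df, 6.0, tolerance = 1e-9)
  expect_equal(w$p_value, 0.315, tolerance = 1e-2)
  # identical samples: t = 0, p = 1
  w0 <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p_value, 1)
  # antisymmetry
  w2 <- welch_t_test(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_equal(w2$statistic, -w$statistic)
  expect_equal(w2$p_value, w$p_value)
  expect_error(welch_t_test(1, c(1, 2)), class = "discordia_validation_error")
  expect_error(welch_t_test(c(1, 1), c(2, 2)), class = "discordia_validation_error")
  # tidy output
  td <- tidy(w)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$statistic, w$statistic)
})

test_that("one-way ANOVA matches the hand-decomposed example", {
  a <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(a$statistic, 3)           # SSB = 6, SSW = 6
  expect_equal(a$df, c(2, 6))
  expect_equal(a$p_value, pf(3, 2, 6, lower.tail = FALSE))
  # identical groups: F = 0, p = 1
  a0 <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(a0$statistic, 0)
  expect_equal(a0$p_value, 1)
  # df conservation
  g <- list(rnorm(5), rnorm(7), rnorm(9))
  a2 <- one_way_anova(g)
  expect_equal(sum(a2$df), sum(lengths(g)) - 1)
  expect_error(one_way_anova(list(1, c(1, 2))), class = "discordia_validation_error")
})

test_that("Welch, ANOVA and Tukey agree with the reference implementations", {
  set.seed(101)
  for (rep in 1:100) {
    k <- sample(2:5, 1)
    ns <- sample(4:12, k, replace = TRUE)
    mus <- rnorm(k, 0, sample(c(0, 1, 3), 1))
    groups <- lapply(seq_len(k), function(i) rnorm(ns[i], mus[i], runif(1, 0.5, 2)))
    names(groups) <- paste0("g", seq_len(k))
    # Welch vs t.test on the first two groups
    w <- welch_t_test(groups[[1]], groups[[2]])
    ref_w <- stats::t.test(groups[[1]], groups[[2]])
    expect_lt(abs(w$statistic - unname(ref_w$statistic)), 1e-6)
    expect_lt(abs(w$df - unname(ref_w$parameter)), 1e-6)
    expect_lt(abs(w$p_value - ref_w$p.value), 1e-6)
    # ANOVA vs aov
    a <- one_way_anova(groups)
    df <- data.frame(y = unlist(groups),
                     grp = rep(names(groups), lengths(groups)))
    ref_a <- summary(stats::aov(y ~ grp, df))[[1]]
    expect_lt(abs(a$statistic - ref_a[["F value"]][1]), 1e-6)
    expect_lt(abs(a$p_value - ref_a[["Pr(>F)"]][1]), 1e-6)
    # Tukey vs TukeyHSD (Tukey-Kramer for unbalanced sizes)
    tk <- tukey_letters(groups)
    ref_t <- stats::TukeyHSD(stats::aov(y ~ grp, df))$grp
    for (r in seq_len(nrow(tk$tukey_pairs))) {
      key1 <- paste0(tk$tukey_pairs$group2[r], "-", tk$tukey_pairs$group1[r])
      key2 <- paste0(tk$tukey_pairs$group1[r], "-", tk$tukey_pairs$group2[r])
      key <- if (key1 %in% rownames(ref_t)) key1 else key2
      expect_lt(abs(tk$tukey_pairs$p_adj[r] - ref_t[key, "p adj"]), 1e-6)
    }
  }
})

test_that("compact letters separate groups exactly when Tukey says so", {
  # identical groups share one letter
  same <- tukey_letters(list(a = c(1, 2, 1, 2), b = c(2, 1, 1, 2), c = c(1, 1, 2, 2)))
  expect_true(all(same$letters$letters == "a"))
  # wide separation: distinct letters, ordered by ascending mean
  set.seed(7)
  far <- tukey_letters(list(hi = rnorm(10, 20, 0.1), lo = rnorm(10, 0, 0.1),
                            mid = rnorm(10, 10, 0.1)))
  expect_equal(far$letters$group, c("lo", "mid", "hi"))
  expect_equal(far$letters$letters, c("a", "b", "c"))
  # letter sharing <-> nonsignificant pair, on random data
  set.seed(11)
  for (rep in 1:20) {
    k <- sample(3:5, 1)
    groups <- lapply(seq_len(k), function(i) rnorm(8, sample(0:3, 1), 1))
    names(groups) <- paste0("g", seq_len(k))
    res <- tukey_letters(groups)
    lets <- setNames(res$letters$letters, res$letters$group)
    for (r in seq_len(nrow(res$tukey_pairs))) {
      shared <- length(intersect(strsplit(lets[[res$tukey_pairs$group1[r]]], "")[[1]],
                                 strsplit(lets[[res$tukey_pairs$group2[r]]], "")[[1]])) > 0
      expect_equal(shared, res$tukey_pairs$p_adj[r] >= res$alpha)
    }
  }
  # relabeling invariance (canonical assignment by ascending mean)
  g1 <- list(x = c(1, 1.1, 0.9), y = c(5, 5.1, 4.9), z = c(9, 9.1, 8.9))
  g2 <- g1[c(3, 1, 2)]
  r1 <- tukey_letters(g1); r2 <- tukey_letters(g2)
  expect_equal(r1$letters$letters, r2$letters$letters)
  expect_equal(r1$letters$group, r2$letters$group)
})

test_that("adequacy test: observed copies of the species tree give excess -1", {
  cfg <- simulation_config(n_tips = 12, clade_blocks = c(A = 8, outgroup = 4),
                           n_loci = 5, depth_cu = 6, seed = 61)
  st <- generate_species_tree(cfg)
  obs <- replicate(5, st$model$tree, simplify = FALSE)
  names(obs) <- paste0("locus_", 1:5)
  res <- ils_adequacy_test(st$model, obs, "all", "CI", n_sim = 100, seed = 3)
  expect_equal(res$observed$mean, 0)
  expect_lt(res$welch$statistic, 0)
  expect_equal(res$excess, -1L)
  td <- tidy(res)
  expect_equal(td$expected_n, 100)
  expect_equal(td$excess, -1L)
})

test_that("adequacy test errors name the responsible filter", {
  cfg <- simulation_config(n_tips = 12, clade_blocks = c(A = 8, outgroup = 4),
                           n_loci = 5, depth_cu = 6, seed = 61)
  st <- generate_species_tree(cfg)
  sparse <- list(locus_1 = prune_to_taxa(st$model$tree,
                                         st$model$tree$tip.label[1:5]))
  expect_error(ils_adequacy_test(st$model, sparse, "all", "CI",
                                 n_sim = 50, seed = 3),
               "occupancy", class = "discordia_runtime_error")
})

test_that("among-clade comparison recovers an induced ILS gradient", {
  # clade A gets a much shallower crown (more ILS) than B and C
  cfg <- simulation_config(n_tips = 34, clade_blocks = c(A = 10, B = 10, C = 10,
                                                         outgroup = 4),
                           n_loci = 60, depth_cu = 40, seed = 67,
                           error_nni_rate = 0, mean_locus_recovery = 1)
  st <- generate_species_tree(cfg)
  tr <- st$model$tree
  # compress clade A's crown toward a radiation: scale its internal branches
  pt <- discordia:::as_ptree(tr)
  a_tips <- st$clade_map$tip[st$clade_map$clade == "A"]
  anode <- discordia:::clade_stem_node(st$model$prep, a_tips)
  desc <- function(v) {
    out <- c()
    for (c in which(pt$parent == v)) out <- c(out, c, desc(c))
    out
  }
  inside <- desc(anode)
  crown_depth <- max(ape::node.depth.edgelength(tr)) -
    ape::node.depth.edgelength(tr)[anode]
  pt$len[inside] <- pt$len[inside] * 0.02
  pt$len[anode] <- pt$len[anode] + crown_depth * 0.98
  tr2 <- discordia:::as_phylo(pt)
  gts <- simulate_gene_trees(species_tree_model(tr2), 60, seed = 71)
  names(gts) <- sprintf("locus_%03d", seq_along(gts))
  cmp <- among_clade_comparison(tr2, gts, st$clade_map, "CI",
                                opts = analysis_options(0, 0.75, "CI"))
  g <- glance(cmp)
  expect_equal(g$group[which.max(g$mean)], "A")
  expect_lt(cmp$anova$p_value, 0.01)
  # A's letter is not shared with the least discordant clade
  lets <- setNames(g$letters, g$group)
  other <- g$group[which.min(g$mean)]
  expect_equal(length(intersect(strsplit(lets[["A"]], "")[[1]],
                                strsplit(lets[[other]], "")[[1]])), 0)
  expect_error(among_clade_comparison(tr2, gts,
                                      st$clade_map[st$clade_map$clade %in% c("A", "outgroup"), ],
                                      "CI"),
               class = "discordia_runtime_error")
})
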