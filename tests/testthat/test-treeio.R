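test_that("parse_newick reads supports, lengths, and scales percent automatically", {
  tr <- parse_newick("((a:1,b:1)90:0.5,c:1.5);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("a", "b", "c"))
  sup <- node_support(tr)
  expect_equal(sort(sup[!is.na(sup)]), 0.9)
  # fraction-scale values stay untouched
  tr2 <- parse_newick("((a:1,b:1)0.9:0.5,c:1.5);")
  expect_equal(node_support(tr2)[!is.na(node_support(tr2))], 0.9)
  # explicit percent
  tr3 <- parse_newick("((a,b)1,c);", support_scale = "percent")
  expect_equal(node_support(tr3)[!is.na(node_support(tr3))], 0.01)
  # no supports / lengths
  tr4 <- parse_newick("(a,b);")
  expect_null(tr4$edge.length)
})

test_that("parse_newick rejects malformed input with informative errors", {
  expect_error(parse_newick("((a,b),c;"), "unbalanced",
               class = "discordia_validation_error")
  expect_error(parse_newick("(a,b),c));"), "character",
               class = "discordia_validation_error")
  expect_error(parse_newick("((a,b),(a,c));"), "duplicate",
               class = "discordia_validation_error")
  expect_error(parse_newick("((a,b)150,c);"), "outside",
               class = "discordia_validation_error")
  expect_error(parse_newick("((a,b),c)"), ";")
})

test_that("write_newick round-trips splits, lengths and supports", {
  for (seed in 1:10) {
    n <- sample(4:50, 1)
    tr <- random_tree(n, seed)
    tr$node.label <- c("", sprintf("%.4f", runif(tr$Nnode - 1)))
    txt <- write_newick(tr)
    back <- parse_newick(txt)
    taxa <- sort(tr$tip.label)
    expect_equal(split_keys_for_test(back, taxa), split_keys_for_test(tr, taxa))
    d1 <- ape::cophenetic.phylo(tr)[taxa, taxa]
    d2 <- ape::cophenetic.phylo(back)[taxa, taxa]
    expect_equal(d1, d2, tolerance = 1e-9)
    s1 <- sort(node_support(tr)); s2 <- sort(node_support(back))
    expect_equal(s1[!is.na(s1)], s2[!is.na(s2)], tolerance = 1e-9)
  }
})

test_that("percent-scale output writes 90, not 0.9", {
  tr <- parse_newick("((a:1,b:1)90:0.5,c:1.5);")
  expect_match(write_newick(tr, "percent"), "\\)90:")
  expect_match(write_newick(tr, "fraction"), "\\)0.9:")
})

test_that("root_with_outgroups follows the priority scan and fails cleanly", {
  tr <- parse_newick("(out1,(a,(b,c)));")
  r <- root_with_outgroups(tr, list("out1", "melissa"))
  expect_true(ape::is.rooted(r))
  kids <- r$edge[r$edge[, 1] == length(r$tip.label) + 1L, 2]
  expect_true(any(kids <= 4 & r$tip.label[kids] == "out1"))
  # fallback to the second set when the first is absent
  tr2 <- parse_newick("((a,b),(c,melissa));")
  r2 <- root_with_outgroups(tr2, list("out1", "melissa"))
  expect_true(ape::is.rooted(r2))
  expect_true(ape::is.monophyletic(r2, c("a", "b", "c")))
  # no sets present
  expect_error(root_with_outgroups(parse_newick("((a,b),(c,d));"), list("out1")),
               class = "discordia_unrootable_error")
})

test_that("rooting never changes the unrooted split set", {
  for (seed in 1:8) {
    tr <- random_tree(10, seed)
    og <- sample(tr$tip.label, 2)
    r <- tryCatch(root_with_outgroups(tr, list(og)),
                  discordia_unrootable_error = function(e) NULL)
    if (is.null(r)) next
    taxa <- sort(tr$tip.label)
    expect_equal(split_keys_for_test(r, taxa), split_keys_for_test(tr, taxa))
  }
})

test_that("collapse_low_support contracts strictly-below-threshold edges only", {
  tr <- parse_newick("(((a,b)30:1,c)33:1,(d,e)80:1,f);")
  out <- collapse_low_support(tr, 0.33)
  taxa <- sort(tr$tip.label)
  keys <- split_keys_for_test(out, taxa)
  expect_false(key_of(c("a", "b"), taxa) %in% keys)      # 0.30 < 0.33 collapsed
  expect_true(key_of(c("a", "b", "c"), taxa) %in% keys)  # 0.33 kept (strict <)
  expect_true(key_of(c("d", "e"), taxa) %in% keys)
  expect_setequal(out$tip.label, tr$tip.label)
  # idempotence and identity on fully supported trees
  expect_equal(write_newick(collapse_low_support(out, 0.33)), write_newick(out))
  tr2 <- parse_newick("((a,b)100:1,(c,d)95:1);")
  expect_equal(split_keys_for_test(collapse_low_support(tr2, 0.33), sort(tr2$tip.label)),
               split_keys_for_test(tr2, sort(tr2$tip.label)))
  expect_error(collapse_low_support(tr, 1.2), class = "discordia_validation_error")
})

test_that("prune_to_taxa preserves path lengths and min-merges supports", {
  tr <- parse_newick("((a:1,b:1)0.9:1,c:2);")
  p <- prune_to_taxa(tr, c("a", "c"))
  expect_setequal(p$tip.label, c("a", "c"))
  expect_equal(ape::cophenetic.phylo(p)["a", "c"], 4)
  # support merging takes the minimum across suppressed edges
  tr2 <- parse_newick("((((a,b)0.4:1,c)0.8:1,d)0.6:1,(e,f)0.9:1);")
  p2 <- prune_to_taxa(tr2, c("a", "b", "e", "f"))
  sup <- node_support(p2)
  expect_true(0.4 %in% sup)
  expect_error(prune_to_taxa(tr, "a"), class = "discordia_degenerate_tree_error")
  # pruning to all tips is the identity
  expect_equal(write_newick(prune_to_taxa(tr, tr$tip.label)), write_newick(tr))
})

test_that("pairwise path lengths survive pruning on random trees", {
  for (seed in 1:6) {
    tr <- random_tree(12, seed)
    keep <- sample(tr$tip.label, 6)
    p <- prune_to_taxa(tr, keep)
    expect_setequal(p$tip.label, keep)
    D0 <- ape::cophenetic.phylo(tr)[sort(keep), sort(keep)]
    D1 <- ape::cophenetic.phylo(p)[sort(keep), sort(keep)]
    expect_equal(D0, D1, tolerance = 1e-9)
  }
})

test_that("clade_occupancy is the shared fraction of the clade", {
  tr <- parse_newick("((a,b),(c,d));")
  expect_equal(clade_occupancy(tr, c("a", "b", "x", "y", "z")), 2 / 5)
  expect_equal(clade_occupancy(tr, tr$tip.label), 1)
  expect_equal(clade_occupancy(tr, c("x", "y")), 0)
  expect_error(clade_occupancy(tr, character(0)),
               class = "discordia_validation_error")
})

test_that("gene tree files round-trip with locus ids and comments", {
  trees <- list(locA = parse_newick("((a,b),c);"),
                locB = parse_newick("((a:1,c:1)80:1,b:2);"))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_gene_trees(trees, path)
  back <- read_gene_trees(path)
  expect_named(back, c("locA", "locB"))
  expect_equal(write_newick(back$locB), write_newick(trees$locB))
})

test_that("clade tables round-trip and reject duplicate tips", {
  cm <- tibble::tibble(tip = c("a", "b", "c"), clade = c("X", "X", "out"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clade_table(cm, path)
  expect_equal(as.data.frame(read_clade_table(path)), as.data.frame(cm))
  writeLines(c("a\tX", "a\tY"), path)
  expect_error(read_clade_table(path), "duplicate")
})
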