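# small conveniences shared across test files

split_keys_for_test <- function(tree, taxa = sort(tree$tip.label)) {
  m <- nontrivial_splits(tree, taxa)
  if (!nrow(m)) return(character(0))
  sort(apply(m, 1, function(r) paste(which(r), collapse = ",")))
}

# canonical key for the split separating `tips` from the rest of `taxa`
key_of <- function(tips, taxa) {
  mask <- taxa %in% tips
  if (mask[1]) mask <- !mask
  paste(which(mask), collapse = ",")
}

# quick 3-taxon topology: TRUE if a,b are sisters
ab_sisters <- function(tree, a = "A", b = "B", c = "C") {
  D <- ape::cophenetic.phylo(tree)
  D[a, b] < D[a, c]
}
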