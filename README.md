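# discordia

Phylogenomic datasets routinely recover hundreds of nuclear gene trees that
disagree with each other and with the species tree. Some of that discordance
is expected: under the multispecies coalescent (MSC), incomplete lineage
sorting (ILS) alone makes gene trees differ from the species tree, more so
where internal branches are short in coalescent units. The scientific
question is whether the *observed* discordance exceeds that expectation —
the signature of horizontal gene flow (hybridization, introgression,
chloroplast capture).

`discordia` implements that test as a reusable pipeline for tree-level data
(Newick gene trees with bootstrap supports, a species tree, a clade table),
aimed at phylogeneticists analysing target-capture datasets such as anchored
hybrid enrichment:

* **Tree distances.** Per-locus normalized distances between each gene tree
  and the species tree under three metrics, computed on branching order
  alone: Robinson–Foulds
  `d = (|S1\S2| + |S2\S1|) / (|S1| + |S2|)` on nontrivial split sets, the
  Nye generalized distance `d = 1 − 2S/(|S1|+|S2|)` where `S` is the value
  of an exact maximum-weight one-to-one split matching under the Jaccard
  pair score, and the clustering-information distance
  `d = (H1 + H2 − 2M)/(H1 + H2)` where `M` is the optimal matching value
  under mutual clustering information and `Hi` are summed split entropies.
  Filters follow target-capture practice: branches below 33% support are
  collapsed, and a locus is scored for a clade only if it contains more than
  75% of the clade's terminals.
* **The ILS null.** A contained-coalescent simulator draws gene trees inside
  the species tree (branch lengths in coalescent units; `k` lineages
  coalesce at rate `k(k−1)/2` per unit within each branch), optionally with
  level-1 reticulation events: with inheritance probability γ the whole gene
  follows the donor edge.
* **The statistical layer.** Per clade, a two-tailed Welch *t*-test compares
  observed distances with distances of simulated null gene trees (the
  "expected" distribution); among clades, a one-way ANOVA with Tukey–Kramer
  post hoc comparisons and a compact letter display ranks mean discordance.
* **Concordance accounting.** Phyparts-style per-clade tallies (concordant /
  main conflict / other conflict / uninformative) and the normalized quartet
  score (proportion of resolved gene-tree quartets satisfied by the species
  tree).
* **Synthetic studies.** A generator that emulates a ~190-tip, 114-locus
  enrichment dataset — monophyletic clade blocks on a Yule species tree,
  gene-tree estimation error with bootstrap-like supports, per-tip locus
  dropout, an optional reticulate history, and a plastome genealogy — so the
  entire pipeline is testable without sequence data.

## Worked example

```r
library(discordia)

# a synthetic study: three 10-tip clades + outgroup, 150 loci
blocks <- c(A = 10, B = 10, C = 10, outgroup = 4)
base   <- simulation_config(n_tips = 34, clade_blocks = blocks,
                            n_loci = 150, depth_cu = 60, seed = 42,
                            error_nni_rate = 0, mean_locus_recovery = 1)
st     <- generate_species_tree(base)

# inject gene flow into clade C (the deepest-crowned clade of this tree)
ret    <- pick_nested_reticulation(st$model, st$clade_map, "C", gamma = 0.3)
cfg    <- simulation_config(n_tips = 34, clade_blocks = blocks,
                            n_loci = 150, depth_cu = 60, seed = 42,
                            error_nni_rate = 0, mean_locus_recovery = 1,
                            reticulations = list(ret))
study  <- generate_study(cfg)

# does clade C's discordance exceed the ILS expectation?
res <- ils_adequacy_test(study$model, study$gene_trees,
                         st$clade_map$tip[st$clade_map$clade == "C"],
                         metric = "CI", n_sim = 200, seed = 1, clade_name = "C")
res
#> ILS adequacy test (CI, clade C)
#> observed: n = 150, mean = 0.0679 (SD 0.0817)
#> expected: n = 200, mean = 0.0294 (SD 0.0597)
#> Welch t = 4.874, df = 260.89, p = 1.901e-06, excess = +1
```

The observed mean clustering-information distance (0.068) sits well above
the coalescent expectation (0.029); the positive excess with p ≈ 2×10⁻⁶
correctly flags the γ = 0.3 introgression into clade C, while the same test
on the uninvolved clade A is nonsignificant (t = 1.01, p = 0.31). `tidy(res)`
returns the same numbers as a one-row tibble; `autoplot(res)` overlays the
observed and expected distance densities.

The full pipeline — distances per clade, ANOVA/Tukey letters, adequacy
tests, concordance tallies, quartet score, plastome comparison — runs from
one config and writes a report directory:

```r
run_pipeline(pipeline_config(out_dir = "report", synthetic = cfg,
                             n_sim = 200, seed = 42))
```

or from the shell, `exec/discordia all --config run.yaml`.

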