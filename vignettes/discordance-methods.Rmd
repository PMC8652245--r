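---
title: "Quantifying gene-tree discordance against coalescent expectations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gene-tree discordance against coalescent expectations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(discordia)
```

## The question the package answers

In a multilocus phylogenomic study, individual gene trees disagree with the
species tree. The multispecies coalescent (MSC) predicts how much
disagreement incomplete lineage sorting (ILS) alone should generate, given
the species tree's branch lengths in coalescent units: within a branch of
length $t$, $k$ gene lineages coalesce at rate $\binom{k}{2}$ per unit, so
short internal branches leave ancestral polymorphism unsorted and gene trees
discordant. Discordance *beyond* that expectation points to horizontal gene
flow. `discordia` quantifies observed discordance with three normalized tree
distances, simulates the ILS-only expectation with a contained-coalescent
sampler, and compares the two distributions statistically, per clade.

## Distances and their normalizations

All three metrics compare *branching order only*: branch lengths are ignored
and both trees are first pruned to their shared tips. The comparison unit is
the nontrivial split (bipartition with at least two taxa a side) induced by
each internal edge of the unrooted topology.

* **Robinson–Foulds.** $d = (|S_1 \setminus S_2| + |S_2 \setminus S_1|) /
  (|S_1| + |S_2|)$. The denominator is the total number of splits in the
  pair, which handles polytomous trees naturally: a partially collapsed gene
  tree simply contributes fewer splits. $d$ is 0 exactly for identical split
  sets and 1 when no split is shared.
* **Nye.** Each split pair is scored by the better of the two side
  alignments, each alignment scored by the weaker of its two Jaccard
  similarities; a maximum-weight one-to-one matching $S$ between the split
  sets is then solved *exactly* (an optimal assignment, not a greedy pass),
  and $d = 1 - 2S/(|S_1| + |S_2|)$.
* **Clustering information.** Split pairs are scored by the mutual
  information (in bits; the base cancels after normalization) between the
  two-block clusterings they induce; with $M$ the optimal matching value and
  $H_i$ the summed split entropies, $d = (H_1 + H_2 - 2M)/(H_1 + H_2)$.
  Compared with RF this metric gives partial credit to *almost*-matching
  splits, so it is far less volatile under small perturbations such as a
  single relocated tip.

The matchings are solved as maximum-weight bipartite matchings
(`igraph::max_bipartite_match`); the test suite checks both generalized
distances against an exhaustive enumeration of every injective split pairing
on all 105 six-tip binary topologies and on random seven-tip pairs, at
$10^{-9}$.

Because the literature states normalizations only loosely ("scaled to 0–1"),
the conventions above are fixed here and used identically for observed and
simulated trees. Only observed-versus-expected *contrasts* are interpreted
downstream, so any monotone renormalization would change table values but
not conclusions.

## Filters

Two filters mirror standard target-capture practice and have package-wide
defaults in `analysis_options()`:

* `collapse_threshold = 0.33`: branches of *observed* gene trees with
  support strictly below 33% are collapsed into polytomies before distances
  are computed, so that gene-tree estimation error is not counted as
  discordance. The inequality is strict: a branch at exactly the threshold
  survives. Simulated (expected) trees are error-free and stay binary.
* `occupancy_min = 0.75`: a locus is scored against a clade only if it
  contains strictly more than 75% of the clade's terminals, so distances are
  not dominated by sparsely sampled loci.

Supports are stored as fractions in node labels; percentages are detected
automatically at parse time (any value above 1 switches the whole tree to
the percent reading — both bootstrap percentages and posterior-probability
fractions occur in published trees). When pruning suppresses a path of
edges, the merged edge takes the *minimum* of the supports involved, a
deliberately conservative convention; annotated datasets do not specify one.

## The contained-coalescent null and reticulations

`simulate_gene_trees()` draws gene trees inside the species tree, one
haploid lineage per tip, branch lengths taken as-is in coalescent units (no
separate population-size surface). Above the root, coalescence continues to
a single lineage. The simulator is validated against closed forms: for
three taxa separated by an internal branch of $t$ coalescent units, the
gene tree matches the species tree with probability $1 - \tfrac{2}{3}
e^{-t}$ (`three_taxon_concordance_probability()`), checked empirically at
$n = 10{,}000$; pairwise coalescence times above the root are unit
exponential (Kolmogorov–Smirnov); and the containment property — no gene
coalescence younger than the species divergence — is asserted per tree.

Reticulations are level-1 events on a recipient edge: per gene, one
Bernoulli($\gamma$) draw decides whether *all* of the gene's lineages on
that edge at the event time follow the donor edge instead. The whole gene
takes one parental path — no within-locus recombination — matching the
reading of $\gamma$ as the fraction of the genome involved. Event times must
fall strictly inside both edges. Implementation-wise, species-tree edges are
cut into segments at event ages and processed in dependency order, so
transfers happen exactly at segment boundaries; splitting an exponential
waiting process at a boundary is distribution-neutral by memorylessness.

The ILS-adequacy test (`ils_adequacy_test()`) profiles the observed trees
(with both filters), simulates `n_sim` complete, binary gene trees from the
species tree *without* reticulations, profiles them with the same pruning
but no collapsing, and runs a two-tailed Welch $t$-test on the two distance
samples. The spirit of the test is a directional flag: positive excess with
small $p$ means more discordance than ILS explains. Simulated trees are
complete by default; applying the observed missingness model to the null is
possible by generating the null through the study generator instead, and
matters for the RF metric (below). Raw $p$-values are reported per
clade/metric with no multiplicity adjustment, matching how such tables are
conventionally printed; readers comparing many clades should adjust.

Welch, the one-way ANOVA and Tukey–Kramer comparisons are implemented at
formula level and cross-checked against `t.test`, `aov` and `TukeyHSD` to
$10^{-6}$ on random data; studentized-range tail probabilities come from
`stats::ptukey`. The compact letter display is built by insert-and-absorb,
with letters assigned over groups ordered by ascending mean, so two groups
share a letter exactly when their adjusted $p \ge \alpha$ and the display
does not depend on input order.

## Concordance accounting

`phyparts_tally()` classifies each rooted, support-collapsed gene tree at
every internal species-tree clade $C$: concordant if $C$'s shared taxa form
a clade; in conflict if some gene-tree clade positively conflicts
(intersects but neither contains nor is contained); otherwise
uninformative — which deliberately includes non-monophyly caused only by
polytomies, so collapsed uncertainty is never counted as conflict. The main
conflict is the most frequent conflicting clade by tip-set identity, with
ties broken lexicographically for determinism. Gene trees are rooted with
`root_with_outgroups()`, which scans an ordered list of outgroup sets and
roots on the smallest unrooted side containing all present members;
unrootable trees are excluded and counted, mirroring how rootability is
reported in practice.

`normalized_quartet_score()` pools, over gene trees, the proportion of
resolved four-tip subsets whose induced quartet matches the species tree.
Quartet topology is read from the four-point condition on unit-branch-length
path distances, which handles polytomies (unresolved quartets drop out of
the denominator). Exact enumeration is allowed up to 25 shared tips
($\binom{n}{4}$ growth); above that, quartets are sampled uniformly with a
seed.

## What the synthetic generator does and does not emulate

`generate_study()` produces a full synthetic study: a species tree of
`n_tips` organized into monophyletic clade blocks, `n_loci` coalescent gene
trees with estimation error and bootstrap-like supports, per-tip locus
dropout, an optional reticulate history, and a plastome genealogy. Defaults
emulate the shape of a ~190-sample, 114-locus anchored-enrichment dataset:
clade blocks of 93/10/10/37/20 tips plus a 20-tip outgroup and a mean of
96.25 recovered loci per sample (retention 96.25/114 per tip and locus, with
a 0.5 multiplier for outgroup tips, where dropout concentrates in real
enrichment data).

Construction choices worth knowing:

* **Clade blocks by grafting.** The species tree is built as a Yule backbone
  over block names with a Yule subtree of the required size grafted onto
  each backbone tip (crown depth half the backbone pendant edge), the
  outgroup attached sister to the ingroup, and the whole tree scaled to
  `depth_cu`. Blocks are therefore monophyletic with the exact requested
  sizes *by construction*; searching a plain Yule tree for exact-size
  disjoint clades would almost surely fail at these sizes. A consequence is
  that crown depths — hence within-clade ILS levels — vary across blocks
  with the randomly drawn backbone pendants.
* **Estimation error.** Poisson(`error_nni_rate`) random
  nearest-neighbor interchanges per gene tree; default rate 1, a mild error
  level chosen as typical for ~1 kb loci. Supports are then assigned either
  by perturbation proximity (low draws, default `U(0.02, 0.30)`, within edge
  distance 1 of a perturbed edge; high draws, `U(0.75, 1)`, elsewhere) or,
  with `length_scale` set, keyed to internal branch length as
  $1 - e^{-\ell/\lambda}$ plus small jitter — emulating that short,
  ILS-prone, hard-to-estimate edges earn low bootstrap. No quantitative
  error model is available to fit, so these are stated conventions: tests
  use them for power, never to match any published table numerically.
* **Plastome.** One contained-coalescent genealogy with branch lengths
  multiplied by `plastome_scale` (default 2: a haploid, uniparentally
  inherited genome has smaller effective size, hence longer branches in
  coalescent units), length-keyed supports, and optionally forced through
  every reticulation (`plastome_capture`), emulating chloroplast capture.

What it does *not* emulate: sequence-level realism (alignment length, base
composition, rate variation), correlated dropout beyond the outgroup
multiplier, paralogy/orthology error, or any specific published topology.
Passing tests on synthetic studies therefore demonstrate the pipeline's
statistical behavior under a known truth — calibration, power, sign
conventions — not agreement with any particular empirical dataset.

## Designing detectable gene-flow scenarios

`pick_nested_reticulation()` selects a recipient subclade and a compatible
donor edge on a generated species tree. Two lessons from its design are
scientific, not implementation detail:

* Rerouting a subclade is only *visible within the clade* if a basal
  reattachment changes the clade's unrooted topology. A subclade whose
  sibling is a single tip, for example, can be moved to the clade's base
  without changing any unrooted split — a no-op for every metric. The
  helper scores candidates by the number of splits a basal reattachment
  would change and prefers candidates that change the most.
* Detection needs a moderately concordant null. In a clade whose crown is
  shallow in coalescent units, the ILS null is already near-random, and a
  rerouted subclade — which coalesces deep and therefore *cleanly* — can
  even come out closer to the species tree than the scrambled null genes
  (negative excess). Power experiments in the test suite therefore inject
  gene flow into the deepest-crowned clade. This mirrors the empirical
  logic: excess-discordance tests are informative exactly where ILS alone
  does not already randomize the topology.

## Numerical and determinism choices

* Exact assignment for split matchings; ties among optimal matchings are
  value-equivalent, so tie-breaking is arbitrary by construction.
* Distances on pairs sharing fewer than four tips are skipped with a
  warning during profiling (an error on direct calls); two star trees give
  an undefined distance (`NA`).
* Master seed plus counter-derived per-gene sub-seeds (kept inside 32-bit
  range) make every simulation independent of iteration order;
  `generate_study()` is a pure function of its config, and `run_pipeline()`
  output directories are byte-identical across reruns of one seed (the log
  carries the seed, a config hash and versions, never timestamps).
* Numbers in report files are printed with a fixed `%.8g` format so files
  compare byte-for-byte across platforms.

## Problem sizes used by the checks

The test suite and the acceptance script run end-to-end on one core in
roughly twenty minutes, using: all 5,460 pairs of six-tip binary topologies
(plus 200 seven-tip pairs) for the oracle equivalence; $n = 10{,}000$
three-taxon simulations per branch length for the closed-form calibration;
200 null replicates of a 20-tip, 100-locus study for type-I calibration of
the adequacy test (n_sim = 200 per replicate); 50 replicate 34-tip,
150-locus studies with $\gamma = 0.3$ for power; a six-seed corpus of
20-tip, 400-locus studies with $\gamma = 0.1$, dropout at the default
retention and length-keyed supports for the RF-sign contrast; and the
default 190-tip, 114-locus study for the headline quantities. These sizes
are the package's own choices: large enough for the stated tolerances'
binomial error bands, small enough to run routinely.

## Known limitations

* The adequacy test conditions on the species tree and its coalescent-unit
  branch lengths as given; error in those lengths propagates directly into
  the null. In practice, coalescent-unit lengths from summary methods are
  noisy, and an overestimated ILS level masks gene flow under RF-like
  metrics (see the sign discussion above).
* Collapsing observed trees while keeping the null binary, and scoring
  incomplete observed trees against a complete null, both bias the RF
  contrast downward (missing and collapsed splits are "forgiven"
  differently by the normalization) — the package reproduces this sign
  anomaly deliberately, and the clustering-information metric is the
  recommended primary metric for the excess test.
* One haploid sample per species tip; no within-species sampling.
* Level-1 reticulations only, and the plastome is a single realization: its
  per-clade distances are point estimates with no test attached.
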