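#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic
#' `t = (mean(x) - mean(y)) / sqrt(vx/nx + vy/ny)` with Welch-Satterthwaite
#' degrees of freedom and a two-tailed p-value. Implemented at formula level
#' (cross-checked against `stats::t.test` in the test suite) so the whole
#' observed-versus-expected layer is self-contained and inspectable.
#'
#' @param x,y Numeric samples with at least 2 values each.
#' @return A `discordia_htest` list: `statistic`, `df`, `p_value`,
#'   `group_summaries` tibble. Methods: [tidy()], [glance()].
#' @export
welch_t_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop_validation("both samples need >= 2 values")
  }
  vx <- stats::var(x); vy <- stats::var(y)
  nx <- length(x); ny <- length(y)
  se2 <- vx / nx + vy / ny
  if (se2 <= 0) stop_validation("degenerate samples: zero variance in both")
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  structure(list(
    method = "Welch two-sample t-test",
    statistic = t, df = df, p_value = p,
    group_summaries = tibble::tibble(
      group = c("x", "y"), n = c(nx, ny), mean = c(mean(x), mean(y)),
      sd = c(stats::sd(x), stats::sd(y)))),
    class = "discordia_htest")
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition: `F` with degrees of freedom
#' `(k - 1, N - k)`.
#'
#' @param groups Named list of numeric samples, each with >= 2 values.
#' @return A `discordia_htest` with `statistic` (F), `df = c(df1, df2)`,
#'   `p_value`, `group_summaries`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L) stop_validation("need >= 2 groups")
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) < 2L)) stop_validation("each group needs >= 2 values")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  k <- length(groups)
  ns <- lengths(groups)
  N <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1L
  df2 <- N - k
  msb <- ssb / df1
  msw <- ssw / df2
  f <- if (msw == 0) {
    if (msb == 0) 0 else Inf
  } else msb / msw
  p <- if (is.infinite(f)) 0 else if (msw == 0) 1 else
    stats::pf(f, df1, df2, lower.tail = FALSE)
  if (msw == 0 && msb == 0) p <- 1
  structure(list(
    method = "One-way ANOVA",
    statistic = f, df = c(df1, df2), p_value = p,
    ms_within = msw,
    group_summaries = tibble::tibble(
      group = names(groups), n = as.integer(ns), mean = means,
      sd = vapply(groups, stats::sd, numeric(1)))),
    class = "discordia_htest")
}

#' Tukey-Kramer post hoc comparisons with a compact letter display
#'
#' All pairwise comparisons using the studentized range distribution with
#' pooled within-group variance; unbalanced group sizes use the
#' Tukey-Kramer standard error `sqrt((MSW/2) (1/ni + 1/nj))`. The compact
#' letter display is built by insert-and-absorb so that two groups share a
#' letter if and only if their adjusted p-value is `>= alpha`; letters are
#' assigned over groups ordered by ascending mean, so the display is
#' invariant to input order.
#'
#' @param groups Named list of numeric samples.
#' @param alpha Significance level (default 0.05).
#' @return A `group_comparison` list: `anova` ([one_way_anova()] result),
#'   `tukey_pairs` tibble (`group1`, `group2`, `diff`, `se`, `p_adj`),
#'   `letters` tibble (`group`, `mean`, `letters`), `alpha`.
#' @export
tukey_letters <- function(groups, alpha = 0.05) {
  aov_res <- one_way_anova(groups)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  k <- length(groups)
  ns <- lengths(groups)
  N <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  msw <- aov_res$ms_within
  pairs <- utils::combn(seq_len(k), 2L)
  rows <- apply(pairs, 2L, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(msw / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- if (se == 0) {
      if (means[i] == means[j]) 0 else Inf
    } else abs(means[i] - means[j]) / se
    p <- if (is.infinite(q)) 0 else
      stats::ptukey(q, nmeans = k, df = N - k, lower.tail = FALSE)
    tibble::tibble(group1 = names(groups)[i], group2 = names(groups)[j],
                   diff = unname(means[j] - means[i]), se = unname(se),
                   p_adj = unname(p))
  })
  tukey <- dplyr::bind_rows(rows)
  letters_df <- compact_letters(names(groups), means, tukey, alpha)
  structure(list(anova = aov_res, tukey_pairs = tukey, letters = letters_df,
                 alpha = alpha),
            class = "group_comparison")
}

# insert-and-absorb compact letter display
compact_letters <- function(gnames, means, tukey, alpha) {
  ord <- order(means)
  gnames_o <- gnames[ord]
  sig <- matrix(FALSE, length(gnames), length(gnames),
                dimnames = list(gnames, gnames))
  for (r in seq_len(nrow(tukey))) {
    if (tukey$p_adj[r] < alpha) {
      sig[tukey$group1[r], tukey$group2[r]] <- TRUE
      sig[tukey$group2[r], tukey$group1[r]] <- TRUE
    }
  }
  cols <- list(gnames_o)  # start: one letter containing everyone
  for (i in seq_along(gnames_o)) {
    for (j in seq_along(gnames_o)) {
      if (j <= i) next
      a <- gnames_o[i]; b <- gnames_o[j]
      if (!sig[a, b]) next
      newcols <- list()
      for (col in cols) {
        if (a %in% col && b %in% col) {
          newcols <- c(newcols, list(setdiff(col, a)), list(setdiff(col, b)))
        } else {
          newcols <- c(newcols, list(col))
        }
      }
      # absorb columns that are subsets of another
      keep <- rep(TRUE, length(newcols))
      for (u in seq_along(newcols)) {
        for (v in seq_along(newcols)) {
          if (u != v && keep[u] && keep[v] &&
              all(newcols[[u]] %in% newcols[[v]]) &&
              (length(newcols[[u]]) < length(newcols[[v]]) || u > v)) {
            keep[u] <- FALSE
          }
        }
      }
      cols <- newcols[keep]
    }
  }
  # order letters by the first (lowest-mean) member they contain
  first_member <- vapply(cols, function(col)
    min(match(col, gnames_o)), numeric(1))
  cols <- cols[order(first_member)]
  lets <- vapply(gnames_o, function(g)
    paste(letters[which(vapply(cols, function(col) g %in% col, logical(1)))],
          collapse = ""), character(1))
  tibble::tibble(group = gnames_o, mean = means[ord], letters = unname(lets))
}

#' Test whether observed discordance exceeds the coalescent expectation
#'
#' The adequacy test for incomplete lineage sorting: (1) profile the
#' observed gene trees against the species tree ([distance_profile()], with
#' support collapsing and the occupancy filter); (2) simulate `n_sim`
#' complete gene trees under the multispecies coalescent on the species tree
#' *without* reticulations (the ILS-only null); (3) profile the simulated
#' trees with the same pruning but no collapsing (they are binary and
#' error-free); (4) compare observed and expected distances with a
#' two-tailed Welch t-test. A positive excess (observed mean above the
#' expectation) with a small p-value indicates discordance beyond ILS, the
#' signature of gene flow.
#'
#' @param model A [species_tree_model()] (reticulations, if any, are ignored
#'   for the null) or a rooted `phylo` with coalescent-unit branch lengths.
#' @param observed_gene_trees Named list of `phylo`.
#' @param clade_taxa Taxon vector or `"all"`.
#' @param metric One of `"RF"`, `"NYE"`, `"CI"`.
#' @param n_sim Number of simulated null gene trees (default 1000).
#' @param seed Seed for the null simulation.
#' @param opts [analysis_options()] for the observed profile.
#' @param clade_name Optional label for reporting.
#' @return An `ils_adequacy` list: `clade`, `metric`, `observed` and
#'   `expected` summaries (n, mean, sd), `welch` test, `excess` (+1 / -1).
#'   Methods: [tidy()].
#' @export
ils_adequacy_test <- function(model, observed_gene_trees, clade_taxa = "all",
                              metric = c("CI", "RF", "NYE"), n_sim = 1000,
                              seed = 1, opts = analysis_options(),
                              clade_name = NULL) {
  metric <- match.arg(metric)
  if (inherits(model, "phylo")) model <- species_tree_model(model)
  stopifnot(inherits(model, "species_tree_model"))
  species_tree <- model$tree
  opts_m <- analysis_options(opts$collapse_threshold, opts$occupancy_min, metric)
  obs <- tryCatch(
    distance_profile(species_tree, observed_gene_trees, clade_taxa,
                     opts = opts_m, clade_name = clade_name),
    discordia_empty_profile_error = function(e) {
      stop_runtime(paste("insufficient observed trees:", conditionMessage(e)))
    })
  if (sum(!is.na(obs$distance)) < 2L) {
    stop_runtime("fewer than 2 observed gene trees survive the filters")
  }
  null_model <- species_tree_model(species_tree)  # ILS-only null
  sims <- simulate_gene_trees(null_model, n_sim, seed = seed)
  opts_e <- analysis_options(collapse_threshold = 0,
                             occupancy_min = 0,
                             metrics = metric)
  exp_prof <- distance_profile(species_tree, sims, clade_taxa,
                               opts = opts_e, clade_name = clade_name)
  dx <- obs$distance[!is.na(obs$distance)]
  dy <- exp_prof$distance[!is.na(exp_prof$distance)]
  wt <- welch_t_test(dx, dy)
  structure(list(
    clade = obs$clade[1],
    metric = metric,
    observed = list(n = length(dx), mean = mean(dx), sd = stats::sd(dx)),
    expected = list(n = length(dy), mean = mean(dy), sd = stats::sd(dy)),
    welch = wt,
    excess = if (mean(dx) > mean(dy)) 1L else -1L,
    observed_distances = dx,
    expected_distances = dy),
    class = "ils_adequacy")
}

#' Compare mean gene-tree discordance among clades
#'
#' Builds a per-clade distance profile for each clade in `clade_map`, then
#' tests for among-clade mean differences with a one-way ANOVA and
#' Tukey-Kramer post hoc comparisons summarized as a compact letter display
#' (groups sharing a letter are not significantly different).
#'
#' @param species_tree Rooted `phylo`.
#' @param gene_trees Named list of `phylo`.
#' @param clade_map Tibble `tip`, `clade`; clades with fewer than 4 tips or
#'   fewer than 2 surviving loci are skipped with a warning.
#' @param metric One of `"RF"`, `"NYE"`, `"CI"`.
#' @param opts [analysis_options()].
#' @param alpha Significance level for the letters.
#' @param exclude Clades to leave out (default `"outgroup"`).
#' @return A `group_comparison` (see [tukey_letters()]) with an extra
#'   `clade_sizes` tibble.
#' @export
among_clade_comparison <- function(species_tree, gene_trees, clade_map,
                                   metric = c("CI", "RF", "NYE"),
                                   opts = analysis_options(), alpha = 0.05,
                                   exclude = "outgroup") {
  metric <- match.arg(metric)
  clades <- setdiff(unique(clade_map$clade), exclude)
  opts_m <- analysis_options(opts$collapse_threshold, opts$occupancy_min, metric)
  samples <- list()
  sizes <- list()
  for (cl in clades) {
    taxa <- clade_map$tip[clade_map$clade == cl]
    if (length(taxa) < 4L) next
    prof <- tryCatch(
      distance_profile(species_tree, gene_trees, taxa, opts = opts_m,
                       clade_name = cl),
      discordia_empty_profile_error = function(e) NULL)
    if (is.null(prof) || sum(!is.na(prof$distance)) < 2L) next
    samples[[cl]] <- prof$distance[!is.na(prof$distance)]
    sizes[[cl]] <- tibble::tibble(clade = cl, n_tips = length(taxa),
                                  n_loci = length(samples[[cl]]))
  }
  if (length(samples) < 2L) {
    stop_runtime("fewer than 2 clades with enough surviving loci")
  }
  res <- tukey_letters(samples, alpha = alpha)
  res$clade_sizes <- dplyr::bind_rows(sizes)
  res$metric <- metric
  res
}

# --- tidy / glance methods -------------------------------------------------

#' @export
tidy.discordia_htest <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 df1 = x$df[1], df2 = if (length(x$df) > 1) x$df[2] else NA_real_,
                 p_value = x$p_value)
}

#' @export
glance.discordia_htest <- function(x, ...) tidy.discordia_htest(x)

#' @export
tidy.ils_adequacy <- function(x, ...) {
  tibble::tibble(
    clade = x$clade, metric = x$metric,
    observed_n = x$observed$n, observed_mean = x$observed$mean,
    observed_sd = x$observed$sd,
    expected_n = x$expected$n, expected_mean = x$expected$mean,
    expected_sd = x$expected$sd,
    t = x$welch$statistic, df = x$welch$df, p_value = x$welch$p_value,
    excess = x$excess)
}

#' @export
tidy.group_comparison <- function(x, ...) x$tukey_pairs

#' @export
glance.group_comparison <- function(x, ...) {
  out <- dplyr::left_join(x$letters,
                          if (!is.null(x$clade_sizes)) x$clade_sizes else
                            tibble::tibble(clade = character(), n_tips = integer(),
                                           n_loci = integer()),
                          by = c(group = "clade"))
  out$f_statistic <- x$anova$statistic
  out$anova_p <- x$anova$p_value
  out
}

#' @export
print.discordia_htest <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("statistic = %.4g, df = %s, p = %.4g\n", x$statistic,
              paste(signif(x$df, 6), collapse = ", "), x$p_value))
  invisible(x)
}

#' @export
print.ils_adequacy <- function(x, ...) {
  cat(sprintf("ILS adequacy test (%s, clade %s)\n", x$metric, x$clade))
  cat(sprintf("observed: n = %d, mean = %.4f (SD %.4f)\n",
              x$observed$n, x$observed$mean, x$observed$sd))
  cat(sprintf("expected: n = %d, mean = %.4f (SD %.4f)\n",
              x$expected$n, x$expected$mean, x$expected$sd))
  cat(sprintf("Welch t = %.4g, df = %.2f, p = %.4g, excess = %+d\n",
              x$welch$statistic, x$welch$df, x$welch$p_value, x$excess))
  invisible(x)
}

#' Density overlay of observed vs expected distances
#'
#' @param object An `ils_adequacy` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ils_adequacy <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(distance = object$observed_distances, set = "observed"),
    tibble::tibble(distance = object$expected_distances, set = "expected"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, fill = .data$set)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = sprintf("normalized %s distance", object$metric),
                  y = "density", fill = NULL,
                  title = sprintf("clade %s", object$clade))
}
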