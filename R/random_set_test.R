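#' Random-gene-set centrality test
#'
#' Tests whether a designated gene set has higher average centrality than
#' random gene sets of the same size drawn (without replacement, per draw)
#' from the network's genes excluding the target set. For each metric other
#' than VoteRank, the empirical p value is the fraction of random sets whose
#' mean centrality is at least the target set's mean (ties count against the
#' target). VoteRank is a rank (smaller = more important), so each draw is
#' instead compared with a one-tailed two-sample Wilcoxon rank-sum test of
#' the target's ranks being smaller; its empirical p is the fraction of
#' draws with a non-significant (alpha = 0.05) result.
#'
#' @param table a centrality table from [centrality_table()].
#' @param target character vector of target genes (must all be in the
#'   table, and no larger than its complement).
#' @param n_iter number of random draws (default 1000).
#' @param seed optional integer seed.
#' @param metrics metrics to test (default all seven).
#' @param alpha significance level for the per-draw Wilcoxon test.
#' @return data.frame with one row per metric: `metric`, `mode`
#'   (`"mean"` or `"wilcoxon"`), `observed` (target mean), `p_empirical`,
#'   `null_mean`, `null_q025`, `null_q975`, `n_iter`, `n_target`.
#' @export
random_set_centrality_test <- function(table, target, n_iter = 1000,
                                       seed = NULL,
                                       metrics = CENTRALITY_METRICS,
                                       alpha = 0.05) {
  if (!all(target %in% table$gene))
    stop("target genes missing from the centrality table: ",
         paste(utils::head(setdiff(target, table$gene), 5), collapse = ", "),
         call. = FALSE)
  pool <- setdiff(table$gene, target)
  k <- length(target)
  if (k < 1) stop("empty target set", call. = FALSE)
  if (k > length(pool))
    stop("target set larger than the complement pool", call. = FALSE)
  if (n_iter < 1) stop("'n_iter' must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))

  draws <- replicate(n_iter, sample(pool, k), simplify = FALSE)
  res <- lapply(metrics, function(m) {
    v <- stats::setNames(table[[m]], table$gene)
    obs_vals <- v[target]
    if (m == "c_voterank") {
      obs <- mean(obs_vals)
      pvals <- vapply(draws, function(d) {
        wilcoxon_less_p(obs_vals, v[d])
      }, numeric(1))
      null_means <- vapply(draws, function(d) mean(v[d]), numeric(1))
      p_emp <- mean(pvals >= alpha)
      mode <- "wilcoxon"
    } else {
      obs <- mean(obs_vals)
      null_means <- vapply(draws, function(d) mean(v[d]), numeric(1))
      p_emp <- mean(null_means >= obs)
      mode <- "mean"
    }
    data.frame(metric = m, mode = mode, observed = obs, p_empirical = p_emp,
               null_mean = mean(null_means),
               null_q025 = unname(stats::quantile(null_means, 0.025)),
               null_q975 = unname(stats::quantile(null_means, 0.975)),
               n_iter = n_iter, n_target = k, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# One-tailed rank-sum p value for "x stochastically smaller than y".
# Exact enumeration for small, tie-free samples; normal approximation with
# continuity correction otherwise.
wilcoxon_less_p <- function(x, y) {
  exact <- length(x) < 8 && length(y) < 8 && !any(duplicated(c(x, y)))
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "less", exact = exact,
                       correct = TRUE)$p.value)
}
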