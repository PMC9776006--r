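#' Correlate a centrality metric with a per-gene statistic
#'
#' Pearson correlation over the genes present in both the centrality table
#' and the statistic vector; genes missing either value are dropped and
#' counted. The label follows the per-test p < 0.05 convention: `pos` for
#' r > 0 and p < 0.05, `neg` for r < 0 and p < 0.05, `ns` otherwise.
#'
#' @param table a centrality table from [centrality_table()].
#' @param stat named numeric vector of per-gene values.
#' @param metric one of the seven metric column names (e.g. `"c_out"`).
#' @param network_id optional identifier recorded in the result.
#' @param statistic name of the statistic recorded in the result.
#' @return one-row data.frame: `network`, `metric`, `statistic`, `n_genes`,
#'   `r`, `p`, `label`, `n_dropped`.
#' @export
correlate_centrality <- function(table, stat, metric,
                                 network_id = attr(table, "layer_pair"),
                                 statistic = "stat") {
  if (!metric %in% CENTRALITY_METRICS)
    stop("unknown metric '", metric, "'", call. = FALSE)
  common <- intersect(table$gene, names(stat))
  x <- table[[metric]][match(common, table$gene)]
  y <- as.numeric(stat[common])
  keep <- is.finite(x) & is.finite(y)
  n_dropped <- length(stat) - sum(keep)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3)
    stop("fewer than 3 genes matched between centrality table and statistic",
         call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(data.frame(network = network_id, metric = metric,
                      statistic = statistic, n_genes = length(x),
                      r = NA_real_, p = NA_real_, label = "ns",
                      n_dropped = n_dropped, stringsAsFactors = FALSE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate); p <- ct$p.value
  label <- if (p < 0.05 && r > 0) "pos" else if (p < 0.05 && r < 0) "neg" else "ns"
  data.frame(network = network_id, metric = metric, statistic = statistic,
             n_genes = length(x), r = r, p = p, label = label,
             n_dropped = n_dropped, stringsAsFactors = FALSE)
}

#' Correlate all seven metrics with a statistic
#'
#' @inheritParams correlate_centrality
#' @return data.frame with one row per metric.
#' @export
correlate_all_metrics <- function(table, stat, network_id = attr(table, "layer_pair"),
                                  statistic = "stat") {
  do.call(rbind, lapply(CENTRALITY_METRICS, function(m)
    correlate_centrality(table, stat, m, network_id = network_id,
                         statistic = statistic)))
}

#' Per-cell-line significant correlation counts
#'
#' Correlates a centrality metric with each cell line's dependency scores
#' across genes, and counts the lines whose Pearson correlation is
#' significant (p < 0.05) by sign. Lines with fewer than 3 matched genes are
#' skipped and reported.
#'
#' @param table a centrality table.
#' @param dep genes x cell-lines dependency matrix.
#' @param metric a centrality metric column name.
#' @param alpha per-line significance level.
#' @return list with `n_pos`, `n_neg`, `n_lines` (lines tested) and
#'   `skipped` (line ids with too few genes).
#' @export
per_line_correlation_counts <- function(table, dep, metric, alpha = 0.05) {
  common <- intersect(table$gene, rownames(dep))
  x <- table[[metric]][match(common, table$gene)]
  n_pos <- 0L; n_neg <- 0L; skipped <- character()
  for (line in colnames(dep)) {
    y <- dep[common, line]
    keep <- is.finite(x) & is.finite(y)
    if (sum(keep) < 3 || stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0) {
      skipped <- c(skipped, line); next
    }
    ct <- stats::cor.test(x[keep], y[keep], method = "pearson")
    if (ct$p.value < alpha) {
      if (ct$estimate > 0) n_pos <- n_pos + 1L else n_neg <- n_neg + 1L
    }
  }
  list(n_pos = n_pos, n_neg = n_neg,
       n_lines = ncol(dep) - length(skipped), skipped = skipped)
}

#' Count concordant significant correlations between two networks
#'
#' Given the seven per-metric association labels of two networks for the
#' same statistic, counts the metrics where both networks are significant
#' with the same direction. Because a smaller VoteRank number means a more
#' important gene, a positive correlation with VoteRank is equivalent to a
#' negative correlation with the other metrics; VoteRank labels are inverted
#' before comparison so all metrics are expressed on a common orientation.
#'
#' @param a,b data.frames from [correlate_all_metrics()] covering the same
#'   seven metrics.
#' @param statistic optional statistic name recorded in the result.
#' @return one-row data.frame: `network_a`, `network_b`, `statistic`,
#'   `n_concordant` (0-7).
#' @export
concordance_count <- function(a, b, statistic = NA_character_) {
  if (!setequal(a$metric, CENTRALITY_METRICS) ||
      !setequal(b$metric, CENTRALITY_METRICS))
    stop("both association tables must cover exactly the seven metrics",
         call. = FALSE)
  la <- orient_labels(a)
  lb <- orient_labels(b)
  n <- sum(la != "ns" & la == lb)
  data.frame(network_a = a$network[1], network_b = b$network[1],
             statistic = statistic, n_concordant = n,
             stringsAsFactors = FALSE)
}

orient_labels <- function(assoc) {
  lab <- stats::setNames(assoc$label, assoc$metric)[CENTRALITY_METRICS]
  vr <- lab["c_voterank"]
  lab["c_voterank"] <- if (vr == "pos") "neg" else if (vr == "neg") "pos" else "ns"
  lab
}
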