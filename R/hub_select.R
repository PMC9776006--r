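#' Percentile ranks of the seven centrality metrics
#'
#' Converts each metric to a percentile with 0 = most central: genes are
#' ranked best-first (largest value for six metrics, smallest rank number
#' for VoteRank), ties share the mean rank, and
#' `percentile = 100 * (rank - 1) / N`. A gene "within the top 10th
#' percentile" has percentile <= 10.
#'
#' @param table a centrality table with at least 10 genes.
#' @return data.frame with column `gene` and one percentile column per
#'   metric (same metric names as the input).
#' @export
percentile_ranks <- function(table) {
  N <- nrow(table)
  if (N < 10) stop("percentile ranking needs at least 10 genes", call. = FALSE)
  out <- data.frame(gene = table$gene, stringsAsFactors = FALSE)
  for (m in CENTRALITY_METRICS) {
    v <- table[[m]]
    rk <- if (m == "c_voterank") rank(v, ties.method = "average")
          else rank(-v, ties.method = "average")
    out[[m]] <- 100 * (rk - 1) / N
  }
  out
}

#' Select genes in the top decile of all seven metrics in some network
#'
#' A gene qualifies as a hub iff there exists at least one network in which
#' all seven of its centrality percentiles are within the top 10th
#' percentile (<= 10, inclusive boundary).
#'
#' @param tables named list of centrality tables, one per network.
#' @param cutoff percentile cutoff (default 10).
#' @return data.frame with columns `gene` and `networks` (comma-separated
#'   ids of the qualifying networks); zero rows if no gene qualifies.
#' @export
top_decile_hubs <- function(tables, cutoff = 10) {
  if (!length(tables)) {
    return(data.frame(gene = character(), networks = character(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(names(tables)))
    names(tables) <- paste0("network", seq_along(tables))
  hits <- list()
  for (id in names(tables)) {
    pct <- percentile_ranks(tables[[id]])
    ok <- rowSums(as.matrix(pct[, CENTRALITY_METRICS]) <= cutoff) ==
      length(CENTRALITY_METRICS)
    if (any(ok)) hits[[id]] <- pct$gene[ok]
  }
  if (!length(hits)) {
    return(data.frame(gene = character(), networks = character(),
                      stringsAsFactors = FALSE))
  }
  long <- data.frame(gene = unlist(hits, use.names = FALSE),
                     network = rep(names(hits), lengths(hits)),
                     stringsAsFactors = FALSE)
  agg <- stats::aggregate(network ~ gene, data = long,
                          FUN = function(x) paste(sort(x), collapse = ","))
  names(agg)[2] <- "networks"
  agg[order(agg$gene), , drop = FALSE]
}

#' Concordant-oncogene filter on hub candidates
#'
#' Keeps hub genes that are significant and concordant in all tumorigenesis
#' and survival measurements: higher mRNA in tumors (t > 0, p < 0.05),
#' higher protein in tumors (t > 0, p < 0.05), and an increased hazard ratio
#' whose 95% confidence interval stays at or above 1 (lower bound >= 1 at
#' the comparison precision).
#'
#' @param hubs data.frame from [top_decile_hubs()] (or a character vector of
#'   genes).
#' @param stats data.frame with one row per gene and columns `gene`,
#'   `t_mrna`, `p_mrna`, `t_protein`, `p_protein`, `hr`, `hr_ci_low`.
#' @return the qualifying subset of `stats` (with the hub `networks` column
#'   when available); excluded genes and reasons are attached as the
#'   `excluded` attribute.
#' @export
concordant_oncogene_filter <- function(hubs, stats) {
  genes <- if (is.data.frame(hubs)) hubs$gene else as.character(hubs)
  s <- stats[match(genes, stats$gene), , drop = FALSE]
  reason <- character(length(genes))
  has <- function(col) is.finite(s[[col]])
  miss <- !(has("t_mrna") & has("p_mrna") & has("t_protein") &
              has("p_protein") & has("hr") & has("hr_ci_low"))
  reason[miss] <- "missing_statistic"
  fail_mrna <- !miss & !(s$t_mrna > 0 & s$p_mrna < 0.05)
  reason[fail_mrna] <- "mrna_not_concordant"
  fail_prot <- !miss & !fail_mrna & !(s$t_protein > 0 & s$p_protein < 0.05)
  reason[fail_prot] <- "protein_not_concordant"
  fail_hr <- !miss & !fail_mrna & !fail_prot &
    !(s$hr > 1 & round(s$hr_ci_low, 2) >= 1)
  reason[fail_hr] <- "hazard_not_increased"
  keep <- reason == ""
  out <- s[keep, , drop = FALSE]
  out$gene <- genes[keep]
  if (is.data.frame(hubs) && "networks" %in% names(hubs))
    out$networks <- hubs$networks[match(out$gene, hubs$gene)]
  rownames(out) <- NULL
  attr(out, "excluded") <- data.frame(gene = genes[!keep],
                                      reason = reason[!keep],
                                      stringsAsFactors = FALSE)
  out
}

#' Flag proliferation genes by dependency-line counts
#'
#' A gene is flagged as a proliferation gene when it shows a significant
#' dependency score in at least `min_lines` cell lines in either the CRISPR
#' or the RNAi screen.
#'
#' @param report data.frame with a `gene` column (e.g. the output of
#'   [concordant_oncogene_filter()]).
#' @param dep_crispr,dep_rnai data.frames from [dependency_summary()].
#' @param min_lines minimum number of dependent cell lines (default 41).
#' @return `report` with added columns `crispr_dependent`, `crispr_total`,
#'   `rnai_dependent`, `rnai_total` and logical `proliferation_gene`.
#' @export
proliferation_flag <- function(report, dep_crispr, dep_rnai, min_lines = 41) {
  ci <- match(report$gene, dep_crispr$gene)
  ri <- match(report$gene, dep_rnai$gene)
  report$crispr_dependent <- dep_crispr$n_dependent[ci]
  report$crispr_total <- dep_crispr$n_total[ci]
  report$rnai_dependent <- dep_rnai$n_dependent[ri]
  report$rnai_total <- dep_rnai$n_total[ri]
  report$proliferation_gene <-
    pmax(report$crispr_dependent, report$rnai_dependent, na.rm = TRUE) >= min_lines
  report$proliferation_gene[is.na(report$proliferation_gene)] <- FALSE
  report
}
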