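#' Run the full synthetic hub-gene analysis pipeline
#'
#' End-to-end orchestration on a synthetic cohort: simulate the multi-omics
#' cohort, dependency screens and survival cohort; ternarize the expression
#' layers against the housekeeping genes; build the implication networks;
#' compute centrality tables; correlate centralities with tumor-vs-NAT t
#' statistics, dependency scores and Cox hazard ratios; run the random-set
#' centrality test on the planted hub set; and select and filter top-decile
#' hub genes. All artifacts are written to `out_dir` as tab-separated files
#' together with a JSON run manifest recording parameters and seeds, so a
#' rerun with the same configuration reproduces every output bit-for-bit.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if missing).
#' @param z_min,scope_min implication-rule thresholds.
#' @param k discretization threshold multiplier.
#' @param n_iter random-set test iterations.
#' @param layer_pairs networks to build (default: the tumor-side CNV-CNV,
#'   CNV-mRNA, mRNA co-expression, mRNA-protein and protein co-expression
#'   networks).
#' @return invisibly, a list with the in-memory artifacts (`cohort`,
#'   `networks`, `centralities`, `associations`, `random_set`, `hub_report`)
#'   and the output paths.
#' @export
run_hub_analysis <- function(config = simulation_config(), out_dir,
                             z_min = 1.64, scope_min = NULL, k = 1.64,
                             n_iter = 1000,
                             layer_pairs = c("cnv-cnv", "cnv-mrna",
                                             "mrna-mrna", "mrna-protein",
                                             "protein-protein")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_multiomics(config)
  truth <- cohort$truth
  hk <- truth$housekeeping_ids

  cnv <- validate_cnv_calls(cohort$cnv)
  mrna_t <- ternarize_expression(cohort$mrna_tumor, hk, k = k)
  prot_t <- ternarize_expression(cohort$protein_tumor, hk, k = k)

  mats <- list(
    "cnv-cnv" = list(ante = cnv, cons = NULL),
    "cnv-mrna" = list(ante = cnv, cons = mrna_t),
    "mrna-mrna" = list(ante = mrna_t, cons = NULL),
    "mrna-protein" = list(ante = mrna_t, cons = prot_t),
    "protein-protein" = list(ante = prot_t, cons = NULL)
  )
  networks <- lapply(layer_pairs, function(lp)
    build_network(lp, mats[[lp]]$ante, cons = mats[[lp]]$cons,
                  z_min = z_min, scope_min = scope_min))
  names(networks) <- layer_pairs
  centralities <- lapply(networks, centrality_table)

  # external gene statistics
  de_mrna <- tumor_vs_nat_t(cohort$mrna_tumor, cohort$mrna_nat)
  de_prot <- tumor_vs_nat_t(cohort$protein_tumor, cohort$protein_nat)
  dep_crispr <- simulate_dependency_screen(truth, n_lines = 94,
                                           seed = config$seed + 101L)
  dep_rnai <- simulate_dependency_screen(truth, n_lines = 92,
                                         seed = config$seed + 102L)
  survtab <- simulate_survival_cohort(truth, cohort$mrna_tumor,
                                      seed = config$seed + 103L)
  cox <- cox_screen(survtab, cohort$mrna_tumor)

  stats_tab <- data.frame(
    gene = truth$genes,
    t_mrna = de_mrna$t[match(truth$genes, de_mrna$gene)],
    p_mrna = de_mrna$p[match(truth$genes, de_mrna$gene)],
    fc_mrna = de_mrna$fold_change[match(truth$genes, de_mrna$gene)],
    t_protein = de_prot$t[match(truth$genes, de_prot$gene)],
    p_protein = de_prot$p[match(truth$genes, de_prot$gene)],
    fc_protein = de_prot$fold_change[match(truth$genes, de_prot$gene)],
    hr = cox$hr[match(truth$genes, cox$gene)],
    hr_ci_low = cox$hr_ci_low[match(truth$genes, cox$gene)],
    hr_ci_high = cox$hr_ci_high[match(truth$genes, cox$gene)],
    stringsAsFactors = FALSE
  )

  associations <- do.call(rbind, lapply(names(centralities), function(id) {
    tab <- centralities[[id]]
    rbind(
      correlate_all_metrics(tab, stats::setNames(stats_tab$t_mrna, stats_tab$gene),
                            network_id = id, statistic = "t_mrna"),
      correlate_all_metrics(tab, stats::setNames(stats_tab$t_protein, stats_tab$gene),
                            network_id = id, statistic = "t_protein"),
      correlate_all_metrics(tab, stats::setNames(log(stats_tab$hr), stats_tab$gene),
                            network_id = id, statistic = "log_hr"),
      correlate_all_metrics(tab, stats::setNames(rowMeans(dep_crispr), rownames(dep_crispr)),
                            network_id = id, statistic = "mean_dep_crispr")
    )
  }))

  random_set <- if (length(truth$hub_ids) && "cnv-mrna" %in% names(centralities))
    random_set_centrality_test(centralities[["cnv-mrna"]], truth$hub_ids,
                               n_iter = n_iter, seed = config$seed + 104L)
  else NULL

  hubs <- top_decile_hubs(centralities)
  report <- concordant_oncogene_filter(hubs, stats_tab)
  report <- proliferation_flag(report, dependency_summary(dep_crispr),
                               dependency_summary(dep_rnai))

  # artifacts
  paths <- list()
  paths$cnv <- write_matrix(cnv, file.path(out_dir, "cnv_ternary.tsv"))
  paths$mrna_ternary <- write_matrix(mrna_t, file.path(out_dir, "mrna_ternary.tsv"))
  paths$protein_ternary <- write_matrix(prot_t, file.path(out_dir, "protein_ternary.tsv"))
  for (id in names(networks)) {
    paths[[paste0("edges_", id)]] <-
      write_edge_list(networks[[id]], file.path(out_dir, paste0("edges_", id, ".tsv")))
    tab <- centralities[[id]]
    utils::write.table(tab, file.path(out_dir, paste0("centrality_", id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(associations, file.path(out_dir, "associations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(random_set))
    utils::write.table(random_set, file.path(out_dir, "random_set_test.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report, file.path(out_dir, "hub_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(survtab, file.path(out_dir, "survival.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth_df <- data.frame(
    gene = truth$genes,
    role = ifelse(truth$genes %in% truth$hub_ids, "hub",
           ifelse(truth$genes %in% unlist(truth$target_map), "target",
           ifelse(truth$genes %in% truth$housekeeping_ids, "housekeeping", "free"))),
    oncogene = truth$genes %in% truth$oncogene_ids,
    essential = truth$genes %in% truth$essential_ids,
    hazard_beta = ifelse(truth$genes %in% names(truth$hazard_ids),
                         truth$hazard_ids[truth$genes], 0),
    stringsAsFactors = FALSE
  )
  utils::write.table(truth_df, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "boolhub",
    version = as.character(utils::packageVersion("boolhub")),
    r_version = R.version.string,
    created = format(Sys.time(), tz = "UTC"),
    config = unclass(config),
    z_min = z_min,
    scope_min = if (is.null(scope_min)) "max(0.1, 5/n)" else scope_min,
    discretization_k = k,
    n_iter = n_iter,
    layer_pairs = layer_pairs,
    derived_seeds = list(crispr = config$seed + 101L, rnai = config$seed + 102L,
                         survival = config$seed + 103L,
                         random_set = config$seed + 104L)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cohort = cohort, networks = networks,
                 centralities = centralities, stats = stats_tab,
                 associations = associations, random_set = random_set,
                 hub_report = report, paths = paths))
}
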