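#!/usr/bin/env Rscript
# Stage 5: genome-scale Pearson correlations between the seven centrality
# metrics of every network and the tumorigenesis / proliferation / survival
# statistics, plus cross-network concordance counts.

library(boolhub)
out <- "results/analysis"

stats_tab <- read.delim(file.path(out, "gene_statistics.tsv"))
dep <- read_matrix(file.path(out, "dependency_crispr.tsv"))
ids <- c("cnv-cnv", "cnv-mrna", "mrna-mrna", "mrna-protein", "protein-protein")
tabs <- lapply(ids, function(id)
  read.delim(file.path(out, paste0("centrality_", id, ".tsv"))))
names(tabs) <- ids

stat_vecs <- list(
  t_mrna = setNames(stats_tab$t_mrna, stats_tab$gene),
  t_protein = setNames(stats_tab$t_protein, stats_tab$gene),
  mean_dep_crispr = setNames(rowMeans(dep), rownames(dep)),
  log_hr = setNames(log(stats_tab$hr), stats_tab$gene))

assoc <- do.call(rbind, lapply(ids, function(id)
  do.call(rbind, lapply(names(stat_vecs), function(s)
    correlate_all_metrics(tabs[[id]], stat_vecs[[s]], network_id = id,
                          statistic = s)))))
write.table(assoc, file.path(out, "associations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

conc <- do.call(rbind, lapply(names(stat_vecs), function(s) {
  prs <- t(combn(ids, 2))
  do.call(rbind, lapply(seq_len(nrow(prs)), function(i)
    concordance_count(assoc[assoc$network == prs[i, 1] & assoc$statistic == s, ],
                      assoc[assoc$network == prs[i, 2] & assoc$statistic == s, ],
                      statistic = s)))
}))
write.table(conc, file.path(out, "concordance.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

sig <- assoc[assoc$label != "ns", ]
cat(sprintf("%d of %d network x metric x statistic correlations significant.\n",
            nrow(sig), nrow(assoc)))
cat("Expression-layer networks vs mean CRISPR dependency (label counts):\n")
print(table(sig$network[sig$statistic == "mean_dep_crispr"],
            sig$label[sig$statistic == "mean_dep_crispr"]))
cat("Max cross-network concordance per statistic:\n")
print(aggregate(n_concordant ~ statistic, conc, max))
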