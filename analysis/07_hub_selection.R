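#!/usr/bin/env Rscript
# Stage 7: rank genes by centrality percentile in every network, extract
# genes in the top decile of all seven metrics in at least one network, and
# apply the concordant-oncogene and proliferation filters.

library(boolhub)
out <- "results/analysis"

ids <- c("cnv-cnv", "cnv-mrna", "mrna-mrna", "mrna-protein", "protein-protein")
tabs <- lapply(ids, function(id)
  read.delim(file.path(out, paste0("centrality_", id, ".tsv"))))
names(tabs) <- ids
stats_tab <- read.delim(file.path(out, "gene_statistics.tsv"))
truth <- read.delim(file.path(out, "truth.tsv"))

hubs <- top_decile_hubs(tabs)
cat(sprintf("%d genes in the top decile of all seven metrics in >=1 network\n",
            nrow(hubs)))
print(table(planted_role = truth$role[match(hubs$gene, truth$gene)]))

report <- concordant_oncogene_filter(hubs, stats_tab)
dep_c <- data.frame(gene = stats_tab$gene,
                    n_dependent = stats_tab$crispr_dependent,
                    n_total = stats_tab$crispr_total, flag = "")
dep_r <- data.frame(gene = stats_tab$gene,
                    n_dependent = stats_tab$rnai_dependent,
                    n_total = stats_tab$rnai_total, flag = "")
report <- proliferation_flag(report, dep_c, dep_r)
write.table(report, file.path(out, "hub_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("\n%d hub genes concordant in all tumorigenesis and survival measurements:\n",
            nrow(report)))
cols <- c("gene", "t_mrna", "t_protein", "fc_mrna", "hr", "crispr_dependent",
          "rnai_dependent", "proliferation_gene")
print(report[, intersect(cols, names(report))], row.names = FALSE, digits = 3)
excl <- attr(report, "excluded")
cat("\nExclusion reasons among top-decile candidates:\n")
print(table(excl$reason))
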