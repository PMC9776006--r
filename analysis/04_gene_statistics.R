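#!/usr/bin/env Rscript
# Stage 4: per-gene external statistics: tumor-vs-NAT t statistics and fold
# changes (mRNA and protein), univariate Cox hazard ratios, and dependency
# counts from the CRISPR/RNAi screens.

library(boolhub)
out <- "results/analysis"

mrna_t <- read_matrix(file.path(out, "mrna_tumor.tsv"))
mrna_n <- read_matrix(file.path(out, "mrna_nat.tsv"))
prot_t <- read_matrix(file.path(out, "protein_tumor.tsv"))
prot_n <- read_matrix(file.path(out, "protein_nat.tsv"))
surv <- read.delim(file.path(out, "survival.tsv"))

de_m <- tumor_vs_nat_t(mrna_t, mrna_n)
de_p <- tumor_vs_nat_t(prot_t, prot_n)
cox <- cox_screen(surv, mrna_t)
dep_c <- dependency_summary(read_matrix(file.path(out, "dependency_crispr.tsv")))
dep_r <- dependency_summary(read_matrix(file.path(out, "dependency_rnai.tsv")))

stats_tab <- data.frame(
  gene = de_m$gene,
  t_mrna = de_m$t, p_mrna = de_m$p, fc_mrna = de_m$fold_change,
  t_protein = de_p$t[match(de_m$gene, de_p$gene)],
  p_protein = de_p$p[match(de_m$gene, de_p$gene)],
  fc_protein = de_p$fold_change[match(de_m$gene, de_p$gene)],
  hr = cox$hr[match(de_m$gene, cox$gene)],
  hr_ci_low = cox$hr_ci_low[match(de_m$gene, cox$gene)],
  hr_ci_high = cox$hr_ci_high[match(de_m$gene, cox$gene)],
  crispr_dependent = dep_c$n_dependent[match(de_m$gene, dep_c$gene)],
  crispr_total = dep_c$n_total[match(de_m$gene, dep_c$gene)],
  rnai_dependent = dep_r$n_dependent[match(de_m$gene, dep_r$gene)],
  rnai_total = dep_r$n_total[match(de_m$gene, dep_r$gene)])
write.table(stats_tab, file.path(out, "gene_statistics.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- read.delim(file.path(out, "truth.tsv"))
onco <- truth$gene[truth$oncogene]
cat(sprintf("DE mRNA: %d/%d genes significant (tumor-up), oncogene median t = %.2f\n",
            sum(de_m$p < 0.05 & de_m$t > 0, na.rm = TRUE), nrow(de_m),
            median(de_m$t[de_m$gene %in% onco], na.rm = TRUE)))
cat(sprintf("Cox: %d/%d genes with HR CI excluding 1; hazard-gene median HR = %.2f\n",
            sum(stats_tab$hr_ci_low > 1 | stats_tab$hr_ci_high < 1, na.rm = TRUE),
            nrow(stats_tab),
            median(stats_tab$hr[truth$hazard_beta > 0], na.rm = TRUE)))
cat(sprintf("Dependency: essential genes hit in median %d/94 CRISPR lines (others %d/94)\n",
            median(stats_tab$crispr_dependent[truth$essential]),
            median(stats_tab$crispr_dependent[!truth$essential])))
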