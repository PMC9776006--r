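#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic NSCLC-style multi-omics cohort with
# planted regulatory hubs, plus the matching dependency screens and the
# survival cohort. All downstream stages read the files written here.

library(boolhub)

out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- simulation_config(seed = 1)
co <- simulate_multiomics(cfg)
tr <- co$truth

write_matrix(co$cnv, file.path(out, "cnv_tumor.tsv"))
write_matrix(round(co$mrna_tumor, 4), file.path(out, "mrna_tumor.tsv"))
write_matrix(round(co$mrna_nat, 4), file.path(out, "mrna_nat.tsv"))
write_matrix(round(co$protein_tumor, 4), file.path(out, "protein_tumor.tsv"))
write_matrix(round(co$protein_nat, 4), file.path(out, "protein_nat.tsv"))

ann <- data.frame(sample = c(colnames(co$mrna_tumor), colnames(co$mrna_nat)),
                  group = rep(c("tumor", "nat"),
                              c(ncol(co$mrna_tumor), ncol(co$mrna_nat))))
write.table(ann, file.path(out, "samples.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- data.frame(
  gene = tr$genes,
  role = ifelse(tr$genes %in% tr$hub_ids, "hub",
         ifelse(tr$genes %in% unlist(tr$target_map), "target",
         ifelse(tr$genes %in% tr$housekeeping_ids, "housekeeping", "free"))),
  regulator = vapply(tr$genes, function(g) {
    h <- names(Filter(function(tg) g %in% tg, tr$target_map))
    if (length(h)) h[1] else ""
  }, character(1)),
  oncogene = tr$genes %in% tr$oncogene_ids,
  essential = tr$genes %in% tr$essential_ids,
  hazard_beta = ifelse(tr$genes %in% names(tr$hazard_ids),
                       unname(tr$hazard_ids[tr$genes]), 0))
write.table(truth, file.path(out, "truth.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(tr$housekeeping_ids, file.path(out, "housekeeping.txt"))

dep_crispr <- simulate_dependency_screen(tr, n_lines = 94, seed = 101)
dep_rnai <- simulate_dependency_screen(tr, n_lines = 92, seed = 102)
write_matrix(round(dep_crispr, 4), file.path(out, "dependency_crispr.tsv"))
write_matrix(round(dep_rnai, 4), file.path(out, "dependency_rnai.tsv"))

surv <- simulate_survival_cohort(tr, co$mrna_tumor, seed = 103)
write.table(surv, file.path(out, "survival.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf(
  "Simulated %d genes x (%d tumor + %d NAT) samples: %d hubs x %d targets,\n%d oncogenes, %d essential genes, %d hazard genes; %d/%d dependency lines;\n%d survival patients (%.0f%% events).\n",
  cfg$n_genes, cfg$n_tumor, cfg$n_nat, cfg$n_hub, cfg$fanout,
  length(tr$oncogene_ids), length(tr$essential_ids), length(tr$hazard_ids),
  ncol(dep_crispr), ncol(dep_rnai), nrow(surv), 100 * mean(surv$event)))
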