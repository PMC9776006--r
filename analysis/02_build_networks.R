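#!/usr/bin/env Rscript
# Stage 2: ternarize the expression layers against the housekeeping genes
# and mine the five Boolean implication networks (same-level co-occurrence /
# co-expression networks plus the CNV->mRNA and mRNA->protein cross-level
# networks).

library(boolhub)
out <- "results/analysis"

hk <- readLines(file.path(out, "housekeeping.txt"))
cnv <- validate_cnv_calls(read_matrix(file.path(out, "cnv_tumor.tsv"), "ternary"))
mrna <- read_matrix(file.path(out, "mrna_tumor.tsv"))
prot <- read_matrix(file.path(out, "protein_tumor.tsv"))

mt <- ternarize_expression(mrna, hk)
pt <- ternarize_expression(prot, hk)
write_matrix(mt, file.path(out, "mrna_ternary.tsv"))
write_matrix(pt, file.path(out, "protein_ternary.tsv"))

nets <- list(
  "cnv-cnv" = build_network("cnv-cnv", cnv),
  "cnv-mrna" = build_network("cnv-mrna", cnv, mt),
  "mrna-mrna" = build_network("mrna-mrna", mt),
  "mrna-protein" = build_network("mrna-protein", mt, pt),
  "protein-protein" = build_network("protein-protein", pt)
)
for (id in names(nets)) {
  write_edge_list(nets[[id]], file.path(out, paste0("edges_", id, ".tsv")))
  cat(sprintf("%-16s %5d nodes  %8d edges (%s)\n", id,
              length(nets[[id]]$nodes), edge_count(nets[[id]]),
              if (nets[[id]]$symmetric) "symmetric" else "directed"))
}
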