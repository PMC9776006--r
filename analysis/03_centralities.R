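#!/usr/bin/env Rscript
# Stage 3: compute the seven-centrality table for every network.

library(boolhub)
out <- "results/analysis"

nodes <- read.delim(file.path(out, "truth.tsv"))$gene
for (id in c("cnv-cnv", "cnv-mrna", "mrna-mrna", "mrna-protein",
             "protein-protein")) {
  net <- read_edge_list(file.path(out, paste0("edges_", id, ".tsv")),
                        nodes = nodes)
  tab <- centrality_table(net)
  write.table(tab, file.path(out, paste0("centrality_", id, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%-16s mean degree %.3f, top VoteRank gene %s\n", id,
              mean(tab$c_degree), tab$gene[which.min(tab$c_voterank)]))
}
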