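library(boolhub)
cfg <- simulation_config(seed = 1)
co <- simulate_multiomics(cfg)
tr <- co$truth
mt <- ternarize_expression(co$mrna_tumor, tr$housekeeping_ids)
netm <- build_network("mrna-mrna", mt)
deg <- table(factor(netm$edges$from, levels = netm$nodes))
targets <- unlist(tr$target_map)
free <- setdiff(netm$nodes, c(tr$hub_ids, targets, tr$housekeeping_ids))
cat("E(coexp undirected):", edge_count(netm), "\n")
cat("deg mean hub/target/free/onc:", mean(deg[tr$hub_ids]), mean(deg[targets]), mean(deg[free]),
    mean(deg[intersect(tr$oncogene_ids, targets)]), "\n")
cat("deg sd target/free:", sd(deg[targets]), sd(deg[free]), "\n")
# nonzero mrna state rate per role
nz <- rowMeans(mt != 0)
cat("nonzero rate hub/target/free:", mean(nz[tr$hub_ids]), mean(nz[targets]), mean(nz[free]), "\n")
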