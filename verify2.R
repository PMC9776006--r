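library(boolhub)
for (ne in c(30, 60, 100)) {
  for (seed in 1:4) {
    cfg <- simulation_config(seed = seed, n_essential = ne)
    co <- simulate_multiomics(cfg)
    tr <- co$truth
    mt <- ternarize_expression(co$mrna_tumor, tr$housekeeping_ids)
    netm <- build_network("mrna-mrna", mt)
    tabm <- centrality_table(netm)
    dep <- simulate_dependency_screen(tr, n_lines = 94, seed = seed + 50)
    md <- setNames(rowMeans(dep), rownames(dep))
    a2 <- correlate_centrality(tabm, md, "c_in", statistic = "dep")
    cat("n_essential", ne, "seed", seed, ": r =", round(a2$r,3), "p =", signif(a2$p,2), a2$label, "\n")
  }
}
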