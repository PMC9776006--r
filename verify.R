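library(boolhub)
t0 <- Sys.time()
cfg <- simulation_config(seed = 1)
co <- simulate_multiomics(cfg)
tr <- co$truth
mt <- ternarize_expression(co$mrna_tumor, tr$housekeeping_ids)
net <- build_network("cnv-mrna", co$cnv, mt)
tab <- centrality_table(net)
# random-set test: hubs
rs <- random_set_centrality_test(tab, tr$hub_ids, n_iter = 1000, seed = 11)
cat("hub out-degree empirical p:", rs$p_empirical[rs$metric == "c_out"], "\n")
# control sets, 50 repeats
set.seed(42)
nonhub <- setdiff(tab$gene, tr$hub_ids)
ps <- replicate(50, {
  tgt <- sample(nonhub, 10)
  r <- random_set_centrality_test(tab, tgt, n_iter = 200, seed = sample.int(1e6,1))
  r$p_empirical[r$metric == "c_out"]
})
cat("control median p:", median(ps), "\n")
# association invariants
hub_ind <- setNames(as.numeric(tab$gene %in% tr$hub_ids), tab$gene)
a1 <- correlate_centrality(tab, hub_ind, "c_out", statistic = "hub")
cat("c_out vs hub indicator: r =", round(a1$r,3), "p =", signif(a1$p,3), a1$label, "\n")
dep <- simulate_dependency_screen(tr, n_lines = 94, seed = 5)
md <- setNames(rowMeans(dep), rownames(dep))
netm <- build_network("mrna-mrna", mt)
tabm <- centrality_table(netm)
a2 <- correlate_centrality(tabm, md, "c_in", statistic = "dep")
cat("coexp c_in vs mean dependency: r =", round(a2$r,3), "p =", signif(a2$p,3), a2$label, "\n")
cat("time so far:", format(Sys.time()-t0), "\n")
# null calibration: 1000 genes x 60, no effects
ncfg <- simulation_config(n_genes = 1000, n_hub = 0, fanout = 0, cnv_rate = 0,
                          hub_cnv_rate = 0, cnv_effect = 0, reg_effect = 0, tumor_shift = 0,
                          n_oncogene = 0, n_essential = 0, n_hazard = 0, seed = 7)
nco <- simulate_multiomics(ncfg)
nmt <- ternarize_expression(nco$mrna_tumor, nco$truth$housekeeping_ids)
rules <- mine_rules(nmt, nmt)
nn <- merge_rules_to_edges(rules, nodes = rownames(nmt))
nz <- rowSums(nmt != 0) > 0
tested <- sum(nz) * (sum(nz) - 1)
cat("null edge rate:", nrow(nn$edges) / tested, "over", tested, "pairs\n")
cat("time:", format(Sys.time()-t0), "\n")
# null survival calibration: 1000 genes x 500 patients
scfg <- simulation_config(n_genes = 1000, n_hub = 0, fanout = 0, n_tumor = 500,
                          n_oncogene = 0, n_essential = 0, n_hazard = 0, seed = 9)
sco <- simulate_multiomics(scfg)
sv <- simulate_survival_cohort(sco$truth, sco$mrna_tumor, seed = 10)
cat("event fraction:", mean(sv$event), "\n")
cox <- cox_screen(sv, sco$mrna_tumor)
excl <- with(cox, hr_ci_low > 1 | hr_ci_high < 1)
cat("CI-excludes-1 fraction:", mean(excl, na.rm = TRUE), "\n")
cat("total time:", format(Sys.time()-t0), "\n")
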