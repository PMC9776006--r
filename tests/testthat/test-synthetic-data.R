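test_that("identical seeds give bit-identical cohorts and screens", {
  cfg <- simulation_config(n_genes = 80, n_hub = 3, fanout = 8,
                           n_tumor = 20, n_nat = 10, seed = 7,
                           n_oncogene = 10, n_essential = 10, n_hazard = 6)
  a <- simulate_multiomics(cfg)
  b <- simulate_multiomics(cfg)
  expect_identical(a, b)
  expect_identical(simulate_dependency_screen(a$truth, 10, seed = 3),
                   simulate_dependency_screen(a$truth, 10, seed = 3))
  expect_identical(simulate_survival_cohort(a$truth, a$mrna_tumor, seed = 5),
                   simulate_survival_cohort(a$truth, a$mrna_tumor, seed = 5))
})

test_that("invalid configurations are rejected by name", {
  expect_error(simulation_config(n_genes = 50, n_hub = 5, fanout = 20),
               "n_hub \\* fanout")
  expect_error(simulation_config(cnv_rate = 0.6), "cnv_rate")
  expect_error(simulation_config(noise_sd = 0), "noise_sd")
  expect_error(simulation_config(n_tumor = 1), "n_tumor")
  expect_error(simulation_config(n_essential = 201), "n_essential")
})

test_that("planted roles are disjoint from housekeeping and hubs as designed", {
  co <- simulate_multiomics(simulation_config(seed = 3))
  tr <- co$truth
  targets <- unlist(tr$target_map)
  expect_length(intersect(tr$hub_ids, tr$housekeeping_ids), 0)
  expect_length(intersect(targets, tr$hub_ids), 0)
  expect_length(intersect(targets, tr$housekeeping_ids), 0)
  expect_length(intersect(tr$oncogene_ids, tr$housekeeping_ids), 0)
  expect_length(intersect(tr$oncogene_ids, tr$hub_ids), 0)
  expect_true(all(tr$essential_ids %in% targets))
  # housekeeping genes: no CNV, no shifts
  expect_true(all(co$cnv[tr$housekeeping_ids, ] == 0))
  expect_equal(mean(co$mrna_tumor[tr$housekeeping_ids, ]), 8, tolerance = 0.1)
})

test_that("hub targets shift by reg_effect between hub-up and hub-normal samples", {
  cfg <- simulation_config(seed = 11)
  co <- simulate_multiomics(cfg)
  tr <- co$truth
  hs <- tr$hub_states_tumor
  diffs <- ses <- c()
  for (h in tr$hub_ids) {
    up <- hs[h, ] == 1L
    norm <- hs[h, ] == 0L
    if (sum(up) < 3 || sum(norm) < 3) next
    for (tg in tr$target_map[[h]]) {
      # subtract the target's own CNV term to isolate the regulatory shift
      resid <- co$mrna_tumor[tg, ] - cfg$cnv_effect * co$cnv[tg, ]
      d <- mean(resid[up]) - mean(resid[norm])
      diffs <- c(diffs, d)
      ses <- c(ses, sqrt(1 / sum(up) + 1 / sum(norm)) * cfg$noise_sd)
    }
  }
  # pooled over all planted edges the mean difference is the planted effect
  est <- mean(diffs)
  se <- sqrt(sum(ses^2)) / length(ses)
  expect_lt(abs(est - cfg$reg_effect), 3 * se)
})

test_that("with all effects zero the mRNA layer is exchangeable noise", {
  cfg <- simulation_config(n_genes = 200, n_hub = 0, fanout = 0,
                           cnv_rate = 0, hub_cnv_rate = 0, cnv_effect = 0,
                           reg_effect = 0, tumor_shift = 0, n_oncogene = 0,
                           n_essential = 0, n_hazard = 0, seed = 5)
  co <- simulate_multiomics(cfg)
  expect_true(all(co$cnv == 0))
  # per-gene means are baseline up to noise
  m <- rowMeans(co$mrna_tumor)
  expect_equal(mean(m), 8, tolerance = 0.05)
  expect_equal(sd(as.numeric(co$mrna_tumor)), 1, tolerance = 0.05)
})

test_that("dependency screen separates essential from background genes", {
  co <- simulate_multiomics(simulation_config(seed = 2))
  tr <- co$truth
  dep <- simulate_dependency_screen(tr, n_lines = 90, essential_mean = -1,
                                    noise_sd = 0.1, seed = 9)
  ess <- tr$essential_ids[1]
  bg <- setdiff(tr$genes, tr$essential_ids)[1]
  # Phi((-0.5+1)/0.1) ~ 1: nearly every line is below threshold
  expect_gte(sum(dep[ess, ] < -0.5), 85)
  # Phi(-0.5/0.1) ~ 0 for a background gene
  expect_equal(sum(dep[bg, ] < -0.5), 0)
  expect_error(simulate_dependency_screen(tr, n_lines = 0), "n_lines")
})

test_that("survival generator recovers planted hazards and censoring fractions", {
  co <- simulate_multiomics(simulation_config(n_genes = 40, n_hub = 1,
                                              fanout = 5, n_tumor = 1000,
                                              n_oncogene = 2, n_essential = 2,
                                              n_hazard = 1, hazard_beta = 0.7,
                                              seed = 4))
  tr <- co$truth
  expect_identical(names(tr$hazard_ids), tr$hub_ids)
  sv <- simulate_survival_cohort(tr, co$mrna_tumor, baseline_hazard = 0.2,
                                 censor_rate = 1e-6, seed = 8)
  fit <- univariate_cox(sv, co$mrna_tumor[tr$hub_ids[1], ])
  expect_gt(fit$hr, exp(0.7) * 0.8)
  expect_lt(fit$hr, exp(0.7) * 1.2)
  # null gene: |log HR| < 3 SE
  null_gene <- setdiff(tr$genes, names(tr$hazard_ids))[1]
  fit0 <- univariate_cox(sv, co$mrna_tumor[null_gene, ])
  se0 <- (log(fit0$hr_ci_high) - log(fit0$hr)) / 1.96
  expect_lt(abs(log(fit0$hr)), 3 * se0)
  expect_error(simulate_survival_cohort(tr, co$mrna_tumor, baseline_hazard = 0),
               "baseline_hazard")
})

test_that("censoring follows the competing-exponentials fraction", {
  cfg <- simulation_config(n_genes = 30, n_hub = 0, fanout = 0, n_tumor = 2000,
                           n_oncogene = 0, n_essential = 0, n_hazard = 0,
                           seed = 6)
  co <- simulate_multiomics(cfg)
  sv <- simulate_survival_cohort(co$truth, co$mrna_tumor,
                                 baseline_hazard = 0.1, censor_rate = 0.4,
                                 seed = 2)
  expect_lt(abs(mean(sv$event) - 0.1 / 0.5), 0.025)
})

test_that("protein tracks mRNA whenever the transfer slope dominates the noise", {
  cfg <- simulation_config(seed = 13)
  co <- simulate_multiomics(cfg)
  cors <- vapply(seq_len(nrow(co$mrna_tumor)), function(i) {
    if (sd(co$mrna_tumor[i, ]) * cfg$protein_slope <= cfg$noise_sd) return(NA_real_)
    cor(co$mrna_tumor[i, ], co$protein_tumor[i, ])
  }, numeric(1))
  expect_true(all(cors > 0, na.rm = TRUE))
})
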