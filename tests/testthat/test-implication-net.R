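test_that("the worked contingency example yields z of about 2.582 and is admitted", {
  m <- worked_example()
  rules <- mine_rules(m, m, z_min = 1.64, scope_min = 0.25)
  r <- rules[rules$ante_gene == "A" & rules$cons_gene == "B" &
               rules$ante_state == 1 & rules$cons_state == 1, ]
  expect_equal(nrow(r), 1)
  expect_equal(r$scope, 0.5)
  expect_equal(r$precision, 0.8)
  expect_equal(r$baseline, 0.4)
  expect_equal(r$z, 0.4 / sqrt(0.4 * 0.6 / 10), tolerance = 1e-12)
  expect_equal(r$z, 2.582, tolerance = 1e-3)
})

test_that("independent and vacuous antecedents yield no rules", {
  # precision equal to baseline: z = 0, no rule
  A <- rep(c(1L, 0L), each = 10)
  B <- rep(c(1L, 0L, 1L, 0L), each = 5)     # B=1 in half of each A stratum
  m <- rbind(A = A, B = B); colnames(m) <- paste0("s", 1:20)
  rules <- mine_rules(m, m, scope_min = 0.1)
  expect_equal(nrow(rules[rules$ante_state == 1 & rules$cons_state == 1, ]), 0)
  # n_a = 0 for the -1 state: silently no rule
  expect_false(any(rules$ante_state == -1))
  # sample mismatch and empty inputs error
  m2 <- m; colnames(m2) <- rev(colnames(m))
  expect_error(mine_rules(m, m2), "sample set")
  expect_error(mine_rules(m[0, , drop = FALSE], m), "empty")
})

test_that("every emitted rule re-checks against its own thresholds", {
  set.seed(33)
  m <- matrix(sample(c(-1L, 0L, 1L), 50 * 40, replace = TRUE,
                     prob = c(0.25, 0.5, 0.25)), 50, 40,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:40)))
  rules <- mine_rules(m, m)
  expect_gt(nrow(rules), 0)
  expect_true(all(rules$z >= 1.64))
  expect_true(all(rules$scope >= max(0.1, 5 / 40)))
  # recompute each rule's counts from the matrix
  for (i in sample(nrow(rules), min(25, nrow(rules)))) {
    r <- rules[i, ]
    a <- m[r$ante_gene, ] == r$ante_state
    b <- m[r$cons_gene, ] == r$cons_state
    expect_equal(r$n_a, sum(a))
    expect_equal(r$precision, sum(a & b) / sum(a))
    expect_equal(r$baseline, mean(b))
  }
})

test_that("rule merging collapses rule types and keeps ordered pairs distinct", {
  rules <- data.frame(
    ante_gene = c("A", "A", "B"), ante_state = c(1L, -1L, 1L),
    cons_gene = c("B", "B", "A"), cons_state = c(1L, -1L, 1L),
    n = 20, n_a = 10, scope = 0.5, precision = 0.9, baseline = 0.4,
    z = c(3, 2.5, 2), stringsAsFactors = FALSE)
  net <- merge_rules_to_edges(rules)
  expect_equal(nrow(net$edges), 2)                     # A->B merged, B->A separate
  ab <- net$edges[net$edges$from == "A", ]
  expect_equal(ab$rule_types, "-1>-1,1>1")
  expect_equal(ab$max_z, 3)
  # merging the merged network's rules again cannot create parallel edges
  expect_equal(anyDuplicated(paste(net$edges$from, net$edges$to)), 0)
  # no rules: empty network over the given universe
  empty <- merge_rules_to_edges(rules[0, ], nodes = c("A", "B", "C"))
  expect_equal(nrow(empty$edges), 0)
  expect_equal(empty$nodes, c("A", "B", "C"))
})

test_that("same-level networks are symmetric and cross-level networks directed", {
  set.seed(12)
  m <- matrix(sample(c(-1L, 0L, 1L), 30 * 30, replace = TRUE,
                     prob = c(0.3, 0.4, 0.3)), 30, 30,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:30)))
  net <- build_network("mrna-mrna", m)
  key <- paste(net$edges$from, net$edges$to)
  rkey <- paste(net$edges$to, net$edges$from)
  expect_true(all(rkey %in% key))                      # A_ij = A_ji
  expect_true(net$symmetric)
  expect_lte(nrow(net$edges), 30 * 29)
  expect_error(build_network("cnv-ge", m), "unknown layer_pair")
  expect_error(build_network("cnv-mrna", m), "consequent")
  # cross-level: no self edges even though same-gene rules are mined
  m2 <- m[, ]; rownames(m2) <- rownames(m)
  x <- build_network("cnv-mrna", m, m2)
  expect_false(any(x$edges$from == x$edges$to))
  expect_false(x$symmetric)
})

test_that("planted hub-to-target edges are recovered in the co-expression network", {
  co <- simulate_multiomics(simulation_config(seed = 1))
  tr <- co$truth
  mt <- ternarize_expression(co$mrna_tumor, tr$housekeeping_ids)
  net <- build_network("mrna-mrna", mt)
  key <- paste(net$edges$from, net$edges$to)
  planted <- unlist(lapply(tr$hub_ids, function(h)
    paste(h, tr$target_map[[h]])))
  expect_gt(mean(planted %in% key), 0.8)
})

test_that("independent ternary noise keeps the edge rate within the union bound", {
  cfg <- simulation_config(n_genes = 300, n_hub = 0, fanout = 0, cnv_rate = 0,
                           hub_cnv_rate = 0, cnv_effect = 0, reg_effect = 0,
                           tumor_shift = 0, n_oncogene = 0, n_essential = 0,
                           n_hazard = 0, seed = 19)
  co <- simulate_multiomics(cfg)
  mt <- ternarize_expression(co$mrna_tumor, co$truth$housekeeping_ids)
  rules <- mine_rules(mt, mt)
  net <- merge_rules_to_edges(rules, nodes = rownames(mt))
  nz <- rowSums(mt != 0) > 0
  tested <- sum(nz) * (sum(nz) - 1)
  expect_lte(nrow(net$edges) / tested, 0.10)
})
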