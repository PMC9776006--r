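test_that("degree centralities match closed forms", {
  k4 <- complete_net(4)
  d <- degree_centralities(k4)
  expect_equal(d$c_in, rep(1, 4))
  expect_equal(d$c_out, rep(1, 4))
  expect_equal(d$c_degree, rep(2, 4))
  chain <- make_net(c("a", "b"), c("b", "c"))
  dc <- degree_centralities(chain)
  expect_equal(dc$c_degree, c(0.5, 1, 0.5))
  iso <- make_net("a", "b", nodes = c("a", "b", "z"))
  expect_equal(degree_centralities(iso)$c_degree[3], 0)
  expect_error(degree_centralities(make_net("a", "b", nodes = "a")), "2 nodes")
})

test_that("eigenvector centrality matches closed-form eigenpairs", {
  expect_equal(unname(eigenvector_centrality(cycle4())), rep(0.5, 4),
               tolerance = 1e-6)
  ce <- eigenvector_centrality(star5())
  expect_equal(unname(ce["a"]), 1 / sqrt(2), tolerance = 1e-6)
  expect_equal(unname(ce["b"]), 1 / (2 * sqrt(2)), tolerance = 1e-6)
  # one symmetric edge plus an isolated node
  e <- sym_edges(cbind("a", "b"))
  net <- make_net(e$from, e$to, nodes = c("a", "b", "c"), symmetric = TRUE)
  ce2 <- eigenvector_centrality(net)
  expect_equal(unname(ce2), c(1 / sqrt(2), 1 / sqrt(2), 0), tolerance = 1e-6)
  expect_equal(sum(ce^2), 1, tolerance = 1e-9)
  edgeless <- make_net("a", "b", nodes = c("a", "b"))
  edgeless$edges <- edgeless$edges[0, ]
  expect_error(eigenvector_centrality(edgeless), "at least one edge")
})

test_that("eigenvector power iteration reports non-convergence on a nilpotent chain", {
  chain <- make_net(c("a", "b"), c("b", "c"))   # directed DAG
  expect_error(eigenvector_centrality(chain, max_iter = 200), "converge")
})

test_that("betweenness matches closed forms", {
  bs <- betweenness_centrality(star5())
  expect_equal(unname(bs["a"]), 1)
  expect_equal(unname(bs["b"]), 0)
  bp <- betweenness_centrality(path_net(4))
  expect_equal(unname(bp["b"]), 2 / 3)
  expect_equal(unname(betweenness_centrality(complete_net(5))), rep(0, 5))
  expect_error(betweenness_centrality(make_net("a", "b", nodes = c("a", "b"))),
               "3 nodes")
})

test_that("closeness matches closed forms, with component scaling when disconnected", {
  cp <- closeness_centrality(path_net(3))
  expect_equal(unname(cp), c(2 / 3, 1, 2 / 3))
  expect_equal(unname(closeness_centrality(complete_net(4))), rep(1, 4))
  e <- sym_edges(rbind(c("a", "b"), c("c", "d")))
  net <- make_net(e$from, e$to, symmetric = TRUE)
  expect_equal(unname(closeness_centrality(net)), rep(1 / 3, 4))
  iso <- make_net("a", "b", nodes = c("a", "b", "z"))
  expect_equal(unname(closeness_centrality(iso)["z"]), 0)
})

test_that("VoteRank reproduces hand-simulated elections", {
  vr <- voterank(star5())
  expect_equal(unname(vr["a"]), 1L)
  expect_equal(unname(vr[c("b", "c", "d", "e")]), rep(2L, 4))
  vr2 <- voterank(double_star10())
  expect_equal(unname(vr2["a"]), 1L)
  expect_equal(unname(vr2["f"]), 2L)
  expect_equal(unname(vr2[c("b", "g", "j")]), rep(3L, 3))
  # single symmetric edge: tie broken by smaller gene id
  e <- sym_edges(cbind("a", "b"))
  vr3 <- voterank(make_net(e$from, e$to, symmetric = TRUE))
  expect_equal(unname(vr3["a"]), 1L)
  expect_gt(vr3["b"], 1L)
  # edgeless network: warning, all tied at rank 1
  empty <- merge_rules_to_edges(
    data.frame(ante_gene = character(), ante_state = integer(),
               cons_gene = character(), cons_state = integer(),
               n = integer(), n_a = numeric(), scope = numeric(),
               precision = numeric(), baseline = numeric(), z = numeric()),
    nodes = c("x", "y"))
  expect_warning(vre <- voterank(empty), "edgeless")
  expect_equal(unname(vre), c(1L, 1L))
})

test_that("centrality table is consistent and composable", {
  tab <- centrality_table(star5())
  expect_equal(tab$c_degree, tab$c_in + tab$c_out)
  expect_equal(attr(tab, "N"), 5)
  expect_equal(attr(tab, "E"), 4)
  ctr <- tab[tab$gene == "a", ]
  expect_equal(ctr$c_degree, 2)
  expect_equal(ctr$c_eigen, 1 / sqrt(2), tolerance = 1e-6)
  expect_equal(ctr$c_between, 1)
  expect_equal(ctr$c_voterank, 1L)
  empty <- merge_rules_to_edges(
    data.frame(ante_gene = character(), ante_state = integer(),
               cons_gene = character(), cons_state = integer(),
               n = integer(), n_a = numeric(), scope = numeric(),
               precision = numeric(), baseline = numeric(), z = numeric()),
    nodes = c("x", "y", "z"))
  tabe <- centrality_table(empty)
  expect_true(all(tabe[, c("c_degree", "c_eigen", "c_between", "c_close")] == 0))
  expect_equal(tabe$c_voterank, rep(1L, 3))
})

test_that("centralities agree with brute-force oracles on random small digraphs", {
  set.seed(77)
  n_checked_eigen <- 0
  for (rep in 1:40) {
    n <- sample(3:5, 1)
    adj <- random_digraph(n)
    symmetric <- rep %% 2 == 0
    if (symmetric) adj <- 1 * ((adj + t(adj)) > 0)
    net <- net_from_adj(adj, symmetric = symmetric)
    d <- degree_centralities(net)
    od <- oracle_degree(adj)
    expect_equal(d$c_in, unname(od$c_in))
    expect_equal(d$c_out, unname(od$c_out))
    expect_equal(unname(betweenness_centrality(net)),
                 oracle_betweenness(adj, symmetric), tolerance = 1e-12)
    expect_equal(unname(closeness_centrality(net)), oracle_closeness(adj),
                 tolerance = 1e-12)
    if (sum(adj) > 0) {
      ce <- tryCatch(eigenvector_centrality(net), error = function(e) NULL)
      pred <- oracle_eigenvector(adj)
      if (!is.null(ce) && !is.null(pred)) {
        n_checked_eigen <- n_checked_eigen + 1
        expect_equal(unname(ce), pred, tolerance = 1e-6)
      }
    }
  }
  expect_gt(n_checked_eigen, 10)
})

test_that("degree sums, leaf betweenness and VoteRank seeding invariants hold", {
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    adj <- random_digraph(n, 0.35)
    adj <- 1 * ((adj + t(adj)) > 0)
    net <- net_from_adj(adj, symmetric = TRUE)
    d <- degree_centralities(net)
    E_dir <- nrow(net$edges)
    expect_equal(sum(d$c_in), E_dir / (n - 1))
    expect_equal(sum(d$c_in), sum(d$c_out))
    deg <- rowSums(adj)
    if (any(deg == 1) && n >= 3) {
      b <- betweenness_centrality(net)
      expect_true(all(b[which(deg == 1)] == 0))
    }
    if (sum(adj) > 0) {
      vr <- voterank(net)
      vs0 <- colSums(adj)   # initial voting scores with all VA = 1
      expect_equal(max(vs0[vr == 1L]), max(vs0))
    }
  }
})
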