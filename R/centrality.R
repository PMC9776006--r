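#' Degree centralities
#'
#' In-degree centrality is the number of distinct in-neighbors divided by
#' `N - 1`, out-degree likewise, and degree centrality is their sum. For a
#' symmetric network the two coincide, so degree centrality is twice either.
#'
#' @param net an `implication_network` with at least 2 nodes.
#' @return data.frame with columns `gene`, `c_in`, `c_out`, `c_degree`.
#' @export
degree_centralities <- function(net) {
  N <- length(net$nodes)
  if (N < 2) stop("degree centrality needs at least 2 nodes", call. = FALSE)
  cin <- table(factor(net$edges$to, levels = net$nodes)) / (N - 1)
  cout <- table(factor(net$edges$from, levels = net$nodes)) / (N - 1)
  data.frame(gene = net$nodes, c_in = as.numeric(cin),
             c_out = as.numeric(cout),
             c_degree = as.numeric(cin) + as.numeric(cout),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Eigenvector centrality by power iteration
#'
#' Importance flows along edges: a node's score is proportional to the sum
#' of the scores of its in-neighbors, i.e. the dominant left eigenvector of
#' the adjacency matrix. For a symmetric network this is the classical
#' eigenvector centrality. The fixed point is found by power iteration from
#' the all-ones vector with an identity shift (`x <- A'x + x`), which leaves
#' the eigenvectors unchanged while guaranteeing convergence on bipartite
#' components; the result is L2-normalized, non-negative.
#'
#' @param net an `implication_network` with at least one edge.
#' @param tol sup-norm convergence tolerance on the normalized vector.
#' @param max_iter maximum number of iterations.
#' @return named numeric vector of centralities with unit L2 norm.
#' @export
eigenvector_centrality <- function(net, tol = 1e-10, max_iter = 1000) {
  if (nrow(net$edges) == 0)
    stop("eigenvector centrality needs at least one edge", call. = FALSE)
  N <- length(net$nodes)
  from <- match(net$edges$from, net$nodes)
  to <- match(net$edges$to, net$nodes)
  x <- rep(1 / sqrt(N), N)
  for (it in seq_len(max_iter)) {
    # x_new[i] = x[i] + sum over in-neighbors j of x[j] (identity shift)
    xn <- x
    s <- rowsum(x[from], group = to)
    idx <- as.integer(rownames(s))
    xn[idx] <- xn[idx] + s[, 1]
    xn <- xn / sqrt(sum(xn^2))
    if (max(abs(xn - x)) < tol) {
      names(xn) <- net$nodes
      return(xn)
    }
    x <- xn
  }
  stop(sprintf(
    "eigenvector centrality did not converge in %d iterations (residual %.3g)",
    max_iter, max(abs(xn - x))), call. = FALSE)
}

#' Betweenness centrality
#'
#' The fraction of shortest paths between every pair of other nodes that
#' pass through a node, normalized by `2 / ((N-1)(N-2))` for symmetric
#' networks (unordered pairs) and `1 / ((N-1)(N-2))` for directed networks
#' (ordered pairs). Pairs with no connecting path contribute 0.
#'
#' @param net an `implication_network` with at least 3 nodes.
#' @return named numeric vector.
#' @export
betweenness_centrality <- function(net) {
  N <- length(net$nodes)
  if (N < 3) stop("betweenness centrality needs at least 3 nodes", call. = FALSE)
  if (isTRUE(net$symmetric)) {
    g <- igraph::as_undirected(as_igraph(net), mode = "collapse")
    raw <- igraph::betweenness(g, directed = FALSE, weights = NA)
    norm <- 2 / ((N - 1) * (N - 2))
  } else {
    g <- as_igraph(net)
    raw <- igraph::betweenness(g, directed = TRUE, weights = NA)
    norm <- 1 / ((N - 1) * (N - 2))
  }
  out <- norm * raw[net$nodes]
  names(out) <- net$nodes
  out
}

#' Closeness centrality with component-reachability scaling
#'
#' On a connected network this is the classical closeness
#' `(N - 1) / sum_j d_ij`. Implication networks are rarely connected, so the
#' generalization `((R_i - 1) / (N - 1)) * (R_i - 1) / sum_{j reachable} d_ij`
#' is used, where `R_i` counts the nodes reachable from `i` (including
#' itself); it reduces exactly to the classical formula when the network is
#' connected, and isolated nodes score 0. Directed networks use directed
#' (outgoing) distances.
#'
#' @param net an `implication_network` with at least 2 nodes.
#' @return named numeric vector.
#' @export
closeness_centrality <- function(net) {
  N <- length(net$nodes)
  if (N < 2) stop("closeness centrality needs at least 2 nodes", call. = FALSE)
  if (isTRUE(net$symmetric)) {
    g <- igraph::as_undirected(as_igraph(net), mode = "collapse")
    d <- igraph::distances(g, weights = NA)
  } else {
    g <- as_igraph(net)
    d <- igraph::distances(g, mode = "out", weights = NA)
  }
  d <- d[net$nodes, net$nodes]
  out <- vapply(seq_len(N), function(i) {
    di <- d[i, -i]
    reach <- is.finite(di)
    R <- sum(reach) + 1
    if (R < 2) return(0)
    ((R - 1) / (N - 1)) * ((R - 1) / sum(di[reach]))
  }, numeric(1))
  names(out) <- net$nodes
  out
}

#' VoteRank centrality
#'
#' Iterative influential-node selection. Every node starts with voting
#' ability `VA = 1`. Each round, every unranked node's voting score `VS` is
#' the sum of the `VA` of its in-voting neighbors; the node with maximal
#' `VS` (ties broken by lexicographically smallest gene id) receives the
#' next rank, its `VA` drops to 0 and it leaves the election, and the `VA`
#' of its out-neighbors is decreased by `delta = 1 / <k>` (mean degree:
#' `2E/N` for symmetric networks, `E/N` for directed), floored at 0.
#' Selection stops when the maximal `VS` reaches 0; all remaining nodes
#' share the next rank. Rank 1 is the most influential node.
#'
#' @param net an `implication_network`.
#' @return named integer vector of ranks (1 = most important, ties allowed).
#' @export
voterank <- function(net) {
  N <- length(net$nodes)
  nodes <- net$nodes
  E <- edge_count(net)
  if (E == 0) {
    warning("VoteRank on an edgeless network: all nodes tied at rank 1")
    return(stats::setNames(rep(1L, N), nodes))
  }
  mean_deg <- if (isTRUE(net$symmetric)) 2 * E / N else E / N
  delta <- 1 / mean_deg
  from <- match(net$edges$from, nodes)
  to <- match(net$edges$to, nodes)
  in_nbrs <- split(from, factor(to, levels = seq_len(N)))
  out_nbrs <- split(to, factor(from, levels = seq_len(N)))
  va <- rep(1, N)
  rank <- rep(NA_integer_, N)
  active <- rep(TRUE, N)
  r <- 0L
  repeat {
    if (!any(active)) break
    vs <- vapply(seq_len(N), function(i)
      if (active[i]) sum(va[in_nbrs[[i]]]) else -Inf, numeric(1))
    m <- max(vs)
    if (m < 1e-12) break
    cand <- which(vs >= m - 1e-12 & active)
    sel <- cand[order(nodes[cand])][1]
    r <- r + 1L
    rank[sel] <- r
    active[sel] <- FALSE
    va[sel] <- 0
    nb <- out_nbrs[[sel]]
    if (length(nb)) va[nb] <- pmax(0, va[nb] - delta)
  }
  rank[is.na(rank)] <- r + 1L
  stats::setNames(rank, nodes)
}

#' Assemble the seven-centrality table of a network
#'
#' Computes degree, in-degree, out-degree, eigenvector, betweenness,
#' closeness and VoteRank centralities for every gene. The node and edge
#' counts are attached as attributes `N` and `E` (edge count over unordered
#' pairs for symmetric networks, directed edges otherwise). On an edgeless
#' network all metrics are 0 and VoteRank ties every gene at rank 1.
#'
#' @param net an `implication_network`.
#' @return a data.frame (`gene`, `c_degree`, `c_in`, `c_out`, `c_eigen`,
#'   `c_between`, `c_close`, `c_voterank`) with attributes `N`, `E` and
#'   `layer_pair`.
#' @export
centrality_table <- function(net) {
  deg <- degree_centralities(net)
  if (nrow(net$edges) == 0) {
    tab <- data.frame(gene = net$nodes, c_degree = 0, c_in = 0, c_out = 0,
                      c_eigen = 0, c_between = 0, c_close = 0,
                      c_voterank = suppressWarnings(as.integer(voterank(net))),
                      row.names = NULL, stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(
      gene = deg$gene, c_degree = deg$c_degree, c_in = deg$c_in,
      c_out = deg$c_out,
      c_eigen = as.numeric(eigenvector_centrality(net)[deg$gene]),
      c_between = as.numeric(betweenness_centrality(net)[deg$gene]),
      c_close = as.numeric(closeness_centrality(net)[deg$gene]),
      c_voterank = as.integer(voterank(net)[deg$gene]),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  attr(tab, "N") <- length(net$nodes)
  attr(tab, "E") <- edge_count(net)
  attr(tab, "layer_pair") <- net$layer_pair
  tab
}

#' Names of the seven centrality metric columns
#' @export
CENTRALITY_METRICS <- c("c_degree", "c_in", "c_out", "c_eigen", "c_between",
                        "c_close", "c_voterank")
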