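# Independent brute-force oracles for the centrality metrics, based on
# exhaustive simple-path enumeration (no shortest-path library calls) and
# dense eigendecomposition. Only feasible for tiny graphs.

oracle_paths <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n); diag(dist) <- 0
  nsp <- matrix(0, n, n)
  through <- array(0, c(n, n, n))
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    paths <- list()
    dfs <- function(node, visited, path) {
      if (node == t) {
        paths[[length(paths) + 1]] <<- path
        return(invisible())
      }
      for (nb in which(adj[node, ] == 1)) if (!visited[nb]) {
        v2 <- visited; v2[nb] <- TRUE
        dfs(nb, v2, c(path, nb))
      }
    }
    visited <- rep(FALSE, n); visited[s] <- TRUE
    dfs(s, visited, s)
    if (length(paths)) {
      lens <- vapply(paths, length, integer(1))
      sp <- paths[lens == min(lens)]
      dist[s, t] <- min(lens) - 1
      nsp[s, t] <- length(sp)
      for (p in sp) for (i in setdiff(p, c(s, t)))
        through[s, t, i] <- through[s, t, i] + 1
    }
  }
  list(dist = dist, nsp = nsp, through = through)
}

oracle_degree <- function(adj) {
  n <- nrow(adj)
  list(c_in = colSums(adj) / (n - 1), c_out = rowSums(adj) / (n - 1),
       c_degree = (colSums(adj) + rowSums(adj)) / (n - 1))
}

oracle_betweenness <- function(adj, symmetric) {
  n <- nrow(adj)
  o <- oracle_paths(adj)
  raw <- vapply(seq_len(n), function(i) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n))
      if (s != t && s != i && t != i && o$nsp[s, t] > 0)
        tot <- tot + o$through[s, t, i] / o$nsp[s, t]
    tot
  }, numeric(1))
  if (symmetric) raw <- raw / 2           # ordered pairs counted twice
  norm <- if (symmetric) 2 / ((n - 1) * (n - 2)) else 1 / ((n - 1) * (n - 2))
  raw * norm
}

oracle_closeness <- function(adj) {
  n <- nrow(adj)
  o <- oracle_paths(adj)
  vapply(seq_len(n), function(i) {
    di <- o$dist[i, -i]
    reach <- is.finite(di)
    R <- sum(reach) + 1
    if (R < 2) return(0)
    ((R - 1) / (n - 1)) * ((R - 1) / sum(di[reach]))
  }, numeric(1))
}

# Dense-eigendecomposition prediction for the shifted left-eigenvector power
# iteration. Returns NULL when the dominant eigenvalue is not strictly
# separated or the start vector has no overlap (the iteration's limit is
# then not characterized by the dominant eigenvector alone).
oracle_eigenvector <- function(adj) {
  M <- t(adj) + diag(nrow(adj))
  e <- eigen(M)
  mods <- Mod(e$values)
  ord <- order(mods, decreasing = TRUE)
  if (length(ord) > 1 && (mods[ord[1]] - mods[ord[2]]) < 1e-6 * mods[ord[1]])
    return(NULL)
  v <- e$vectors[, ord[1]]
  if (max(abs(Im(v))) > 1e-9) return(NULL)
  v <- Re(v)
  # overlap of the all-ones start vector with the dominant mode
  cf <- tryCatch(solve(e$vectors, rep(1, nrow(adj))), error = function(e) NULL)
  if (is.null(cf) || Mod(cf[ord[1]]) < 1e-8) return(NULL)
  v <- v * sign(sum(v))
  v / sqrt(sum(v^2))
}

# Breslow log partial likelihood for a single covariate (oracle for Cox).
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

oracle_cox_beta <- function(time, event, x) {
  stats::optimize(function(b) -breslow_loglik(b, time, event, x),
                  interval = c(-8, 8), tol = 1e-10)$minimum
}
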