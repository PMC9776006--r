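# Graph fixtures built in code. Networks store every directed edge
# explicitly; symmetric fixtures list both directions.

make_net <- function(from, to, nodes = NULL, symmetric = FALSE,
                     layer = "mrna-mrna") {
  if (is.null(nodes)) nodes <- sort(unique(c(from, to)))
  edges <- data.frame(from = as.character(from), to = as.character(to),
                      rule_types = rep("1>1", length(from)),
                      max_z = rep(2, length(from)),
                      max_scope = rep(0.5, length(from)),
                      max_precision = rep(0.9, length(from)),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, layer_pair = layer,
                 symmetric = symmetric),
            class = "implication_network")
}

net_from_adj <- function(adj, symmetric = FALSE) {
  n <- nrow(adj)
  nodes <- sprintf("n%02d", seq_len(n))
  idx <- which(adj == 1, arr.ind = TRUE)
  make_net(nodes[idx[, 1]], nodes[idx[, 2]], nodes = nodes,
           symmetric = symmetric)
}

sym_edges <- function(pairs) {
  # pairs: 2-column matrix of unordered edges; returns both directions
  list(from = c(pairs[, 1], pairs[, 2]), to = c(pairs[, 2], pairs[, 1]))
}

star5 <- function() {
  e <- sym_edges(cbind("a", c("b", "c", "d", "e")))
  make_net(e$from, e$to, symmetric = TRUE)
}

double_star10 <- function() {
  e <- sym_edges(rbind(cbind("a", c("b", "c", "d", "e")),
                       cbind("f", c("g", "h", "i", "j"))))
  make_net(e$from, e$to, symmetric = TRUE)
}

path_net <- function(k) {
  nodes <- letters[seq_len(k)]
  e <- sym_edges(cbind(nodes[-k], nodes[-1]))
  make_net(e$from, e$to, symmetric = TRUE)
}

cycle4 <- function() {
  e <- sym_edges(cbind(c("a", "b", "c", "d"), c("b", "c", "d", "a")))
  make_net(e$from, e$to, symmetric = TRUE)
}

complete_net <- function(k) {
  nodes <- letters[seq_len(k)]
  pr <- t(utils::combn(nodes, 2))
  e <- sym_edges(pr)
  make_net(e$from, e$to, symmetric = TRUE)
}

# Ternary fixture realizing the worked contingency example: n = 20 samples,
# antecedent A = 1 in 10 (scope 0.5), consequent B = 1 in 8, all within the
# A = 1 samples (precision 0.8, baseline 0.4).
worked_example <- function() {
  A <- c(rep(1L, 10), rep(0L, 10))
  B <- c(rep(1L, 8), rep(0L, 12))
  m <- rbind(A = A, B = B)
  colnames(m) <- paste0("s", 1:20)
  m
}

random_digraph <- function(n, p = 0.4) {
  adj <- matrix(rbinom(n * n, 1, p), n, n)
  diag(adj) <- 0
  adj
}
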