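#' Mine Boolean implication rules between two ternary matrices
#'
#' For every ordered gene pair (A in `ante`, B in `cons`) and every state
#' pair `(a, b)` with `a, b` in `{1, -1}`, the rule "A = a implies B = b" is
#' scored by a one-proportion z test of its precision against the
#' consequent's marginal baseline:
#' `z = (precision - p0) / sqrt(p0 * (1 - p0) / n_a)`, where `n_a` is the
#' number of samples with A = a, `precision = #(A = a and B = b) / n_a` and
#' `p0 = #(B = b) / n`. A rule is emitted iff `n_a > 0`, `0 < p0 < 1`,
#' `scope = n_a / n >= scope_min` and `z >= z_min`.
#'
#' The default `scope_min = max(0.1, 5/n)` guarantees at least five
#' antecedent samples behind any rule; `z_min = 1.64` is the one-tailed 5%
#' critical value. Both concordant (`(1,1)`, `(-1,-1)`) and discordant
#' (`(1,-1)`, `(-1,1)`) state pairs are mined.
#'
#' @param ante,cons integer ternary matrices (genes x samples) sharing an
#'   identical ordered sample set. Pass the same matrix twice for a
#'   same-level (co-expression style) rule search.
#' @param z_min minimum one-tailed z statistic (default 1.64).
#' @param scope_min minimum scope; default `max(0.1, 5/n)`.
#' @param allow_self mine rules whose antecedent and consequent gene id
#'   coincide (meaningful only across omics layers). Default `FALSE`.
#' @return data.frame of emitted rules with columns `ante_gene`,
#'   `ante_state`, `cons_gene`, `cons_state`, `n`, `n_a`, `scope`,
#'   `precision`, `baseline`, `z`.
#' @export
mine_rules <- function(ante, cons, z_min = 1.64, scope_min = NULL,
                       allow_self = FALSE) {
  if (nrow(ante) == 0 || nrow(cons) == 0 || ncol(ante) == 0)
    stop("empty matrix supplied to rule mining", call. = FALSE)
  if (ncol(ante) != ncol(cons) ||
      !identical(colnames(ante), colnames(cons)))
    stop("antecedent and consequent matrices must share an identical ordered sample set",
         call. = FALSE)
  if (!is.finite(z_min) || z_min <= 0)
    stop("'z_min' must be positive", call. = FALSE)
  n <- ncol(ante)
  if (is.null(scope_min)) scope_min <- max(0.1, 5 / n)

  ind <- function(m, s) {
    x <- (m == s)
    storage.mode(x) <- "double"
    x
  }
  A <- list(`1` = ind(ante, 1L), `-1` = ind(ante, -1L))
  B <- list(`1` = ind(cons, 1L), `-1` = ind(cons, -1L))
  n_a <- lapply(A, rowSums)
  p0 <- lapply(B, function(x) rowSums(x) / n)

  res <- vector("list", 4)
  i <- 0
  for (a in c("1", "-1")) for (b in c("1", "-1")) {
    i <- i + 1
    na_vec <- n_a[[a]]
    p0_vec <- p0[[b]]
    ok_a <- which(na_vec / n >= scope_min)
    ok_b <- which(p0_vec > 0 & p0_vec < 1)
    if (!length(ok_a) || !length(ok_b)) next
    joint <- tcrossprod(A[[a]][ok_a, , drop = FALSE],
                        B[[b]][ok_b, , drop = FALSE])
    prec <- joint / na_vec[ok_a]
    z <- (prec - rep(p0_vec[ok_b], each = length(ok_a))) /
      sqrt(outer(1 / na_vec[ok_a], p0_vec[ok_b] * (1 - p0_vec[ok_b])))
    hit <- z >= z_min
    if (!allow_self) {
      same <- outer(rownames(ante)[ok_a], rownames(cons)[ok_b], "==")
      hit <- hit & !same
    }
    idx <- which(hit, arr.ind = TRUE)
    if (!nrow(idx)) next
    res[[i]] <- data.frame(
      ante_gene = rownames(ante)[ok_a][idx[, 1]],
      ante_state = as.integer(a),
      cons_gene = rownames(cons)[ok_b][idx[, 2]],
      cons_state = as.integer(b),
      n = n,
      n_a = na_vec[ok_a][idx[, 1]],
      scope = na_vec[ok_a][idx[, 1]] / n,
      precision = prec[idx],
      baseline = p0_vec[ok_b][idx[, 2]],
      z = z[idx],
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(ante_gene = character(), ante_state = integer(),
                      cons_gene = character(), cons_state = integer(),
                      n = integer(), n_a = numeric(), scope = numeric(),
                      precision = numeric(), baseline = numeric(),
                      z = numeric(), stringsAsFactors = FALSE)
  attr(out, "z_min") <- z_min
  attr(out, "scope_min") <- scope_min
  out
}

#' Merge implication rules into a directed gene network
#'
#' All significant rules for an ordered gene pair A -> B collapse into a
#' single directed edge annotated with its supporting state pairs (e.g. the
#' amplification-implies-amplification and deletion-implies-deletion rules
#' of a pair count as one association). Self-pairs never create edges.
#'
#' @param rules a data.frame from [mine_rules()].
#' @param nodes gene universe of the network; defaults to the genes
#'   appearing in `rules`.
#' @param layer_pair label for the omics layer pair.
#' @param symmetric logical flag recorded on the network.
#' @return an `implication_network`: list with `nodes`, `edges` (data.frame
#'   `from`, `to`, `rule_types`, `max_z`, `max_scope`, `max_precision`),
#'   `layer_pair` and `symmetric`.
#' @export
merge_rules_to_edges <- function(rules, nodes = NULL, layer_pair = NA_character_,
                                 symmetric = FALSE) {
  if (is.null(nodes))
    nodes <- sort(unique(c(rules$ante_gene, rules$cons_gene)))
  rules <- rules[rules$ante_gene != rules$cons_gene, , drop = FALSE]
  if (nrow(rules)) {
    key <- paste(rules$ante_gene, rules$cons_gene, sep = "\r")
    type <- paste0(rules$ante_state, ">", rules$cons_state)
    o <- order(key, type)
    rules <- rules[o, ]; key <- key[o]; type <- type[o]
    first <- !duplicated(key)
    edges <- data.frame(
      from = rules$ante_gene[first],
      to = rules$cons_gene[first],
      rule_types = vapply(split(type, factor(key, levels = key[first])),
                          paste, character(1), collapse = ","),
      max_z = vapply(split(rules$z, factor(key, levels = key[first])),
                     max, numeric(1)),
      max_scope = vapply(split(rules$scope, factor(key, levels = key[first])),
                         max, numeric(1)),
      max_precision = vapply(split(rules$precision, factor(key, levels = key[first])),
                             max, numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE
    )
  } else {
    edges <- data.frame(from = character(), to = character(),
                        rule_types = character(), max_z = numeric(),
                        max_scope = numeric(), max_precision = numeric(),
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, layer_pair = layer_pair,
                 symmetric = symmetric),
            class = "implication_network")
}

#' @export
print.implication_network <- function(x, ...) {
  cat(sprintf("Implication network [%s]: %d nodes, %d directed edges (%s)\n",
              x$layer_pair, length(x$nodes), nrow(x$edges),
              if (isTRUE(x$symmetric)) "symmetric" else "directed"))
  invisible(x)
}

LAYER_PAIRS <- c("cnv-cnv", "cnv-mrna", "mrna-mrna", "mrna-protein",
                 "protein-protein")

#' Build a same-level or cross-level implication network
#'
#' Same-level networks (`cnv-cnv`, `mrna-mrna`, `protein-protein`) are mined
#' within one ternary matrix and, by default, symmetrized: a reciprocal edge
#' is added whenever either direction carries a significant rule, matching
#' the symmetric in-/out-degree of gene association networks. Cross-level
#' networks (`cnv-mrna`, `mrna-protein`) direct edges from the mediating
#' layer's gene to the mediated layer's gene (regulator to regulated) and
#' stay directed. Cross-level same-gene rules are mined but never become
#' self-edges.
#'
#' @param layer_pair one of `"cnv-cnv"`, `"cnv-mrna"`, `"mrna-mrna"`,
#'   `"mrna-protein"`, `"protein-protein"`.
#' @param ante ternary matrix of the (mediating) antecedent layer.
#' @param cons ternary matrix of the mediated layer; omit for same-level
#'   networks.
#' @param z_min,scope_min rule thresholds passed to [mine_rules()].
#' @param symmetrize add reciprocal edges; defaults to `TRUE` for
#'   same-level pairs and `FALSE` otherwise.
#' @return an `implication_network`.
#' @export
build_network <- function(layer_pair, ante, cons = NULL, z_min = 1.64,
                          scope_min = NULL, symmetrize = NULL) {
  if (!layer_pair %in% LAYER_PAIRS)
    stop("unknown layer_pair '", layer_pair, "'; expected one of: ",
         paste(LAYER_PAIRS, collapse = ", "), call. = FALSE)
  parts <- strsplit(layer_pair, "-", fixed = TRUE)[[1]]
  same_level <- parts[1] == parts[2]
  if (is.null(symmetrize)) symmetrize <- same_level
  if (same_level) {
    if (is.null(cons)) cons <- ante
    rules <- mine_rules(ante, cons, z_min = z_min, scope_min = scope_min,
                        allow_self = FALSE)
    nodes <- sort(rownames(ante))
  } else {
    if (is.null(cons))
      stop("cross-level networks need both an antecedent and a consequent matrix",
           call. = FALSE)
    rules <- mine_rules(ante, cons, z_min = z_min, scope_min = scope_min,
                        allow_self = TRUE)
    nodes <- sort(union(rownames(ante), rownames(cons)))
  }
  net <- merge_rules_to_edges(rules, nodes = nodes, layer_pair = layer_pair,
                              symmetric = FALSE)
  if (symmetrize) net <- symmetrize_network(net)
  net
}

symmetrize_network <- function(net) {
  e <- net$edges
  if (nrow(e)) {
    key <- paste(e$from, e$to, sep = "\r")
    rkey <- paste(e$to, e$from, sep = "\r")
    missing_rev <- !(rkey %in% key)
    if (any(missing_rev)) {
      rev <- e[missing_rev, ]
      names(rev)[1:2] <- c("to", "from")
      e <- rbind(e, rev[, names(e)])
    }
    # equalize annotations across the two directions
    key <- paste(pmin(e$from, e$to), pmax(e$from, e$to), sep = "\r")
    e$max_z <- stats::ave(e$max_z, key, FUN = max)
    e$max_scope <- stats::ave(e$max_scope, key, FUN = max)
    e$max_precision <- stats::ave(e$max_precision, key, FUN = max)
    e <- e[order(e$from, e$to), ]
    rownames(e) <- NULL
  }
  net$edges <- e
  net$symmetric <- TRUE
  net
}

as_igraph <- function(net, directed = TRUE) {
  igraph::graph_from_data_frame(net$edges[, c("from", "to"), drop = FALSE],
                                directed = directed,
                                vertices = data.frame(name = net$nodes))
}

#' Number of edges of an implication network
#'
#' For symmetric networks the count is over unordered gene pairs (each
#' reciprocal edge pair counts once); for directed networks it is the number
#' of directed edges.
#' @param net an `implication_network`.
#' @return integer edge count.
#' @export
edge_count <- function(net) {
  if (isTRUE(net$symmetric)) nrow(net$edges) / 2 else nrow(net$edges)
}
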