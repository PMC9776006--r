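#' Read a gene x sample matrix from a tab-separated file
#'
#' Expects genes as rows, the first column holding gene ids and a header row
#' of sample ids. Duplicate gene ids are an error (with the line number);
#' `"NA"` entries are allowed for continuous matrices and rejected, along
#' with any non-ternary value, for ternary matrices.
#'
#' @param path file path.
#' @param kind `"continuous"` or `"ternary"`.
#' @return numeric (or integer, for ternary) matrix with gene rownames and
#'   sample colnames.
#' @export
read_matrix <- function(path, kind = c("continuous", "ternary")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix file needs a gene column and at least one sample",
                         call. = FALSE)
  genes <- as.character(df[[1]])
  dup <- which(duplicated(genes))
  if (length(dup))
    stop(sprintf("duplicate gene id '%s' at line %d of %s",
                 genes[dup[1]], dup[1] + 1, path), call. = FALSE)
  raw <- as.matrix(df[, -1, drop = FALSE])
  m <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                               dimnames = list(genes, colnames(raw))))
  bad <- is.na(m) & !(is.na(raw) | raw == "NA" | raw == "")
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value '%s' at (%s, %s) in %s",
                 raw[bad][1], genes[idx[1]], colnames(raw)[idx[2]], path),
         call. = FALSE)
  }
  if (kind == "ternary") {
    if (any(is.na(m)))
      stop("missing values are not allowed in a ternary matrix: ", path,
           call. = FALSE)
    m <- validate_cnv_calls(m)
    attr(m, "state_freq") <- NULL
  }
  m
}

#' Write a gene x sample matrix as a tab-separated file
#'
#' @param m matrix with gene rownames and sample colnames.
#' @param path output file path.
#' @param id_column header name of the gene-id column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_column = "gene") {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network edge list as a tab-separated file
#'
#' Columns: source, target, layer_pair, rule_types, max_z, scope, precision.
#'
#' @param net an `implication_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  e <- net$edges
  out <- data.frame(source = e$from, target = e$to,
                    layer_pair = net$layer_pair,
                    rule_types = e$rule_types,
                    max_z = e$max_z, scope = e$max_scope,
                    precision = e$max_precision,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge list written by [write_edge_list()]
#'
#' @param path file path.
#' @param nodes optional gene universe; defaults to the genes in the file.
#' @param symmetric network symmetry flag; defaults to `TRUE` when every
#'   edge has its reciprocal in the file.
#' @return an `implication_network`.
#' @export
read_edge_list <- function(path, nodes = NULL, symmetric = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  edges <- data.frame(from = as.character(df$source),
                      to = as.character(df$target),
                      rule_types = df$rule_types, max_z = df$max_z,
                      max_scope = df$scope, max_precision = df$precision,
                      stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  if (is.null(symmetric))
    symmetric <- nrow(edges) > 0 &&
      all(paste(edges$to, edges$from) %in% paste(edges$from, edges$to))
  structure(list(nodes = nodes, edges = edges,
                 layer_pair = if (nrow(df)) df$layer_pair[1] else NA_character_,
                 symmetric = symmetric),
            class = "implication_network")
}

#' Export a network to GraphML
#'
#' @param net an `implication_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
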