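#' Ternarize a continuous expression matrix against housekeeping genes
#'
#' For each sample `s`, the mean and standard deviation of the housekeeping
#' genes in that sample define the reference band: a value above
#' `mu_s + k * sigma_s` is called up-regulated (`1`), below
#' `mu_s - k * sigma_s` down-regulated (`-1`), and normal (`0`) otherwise.
#' The default `k = 1.64` is the one-tailed standard-normal critical value
#' at p = 0.05, so roughly 10% of housekeeping-like values fall outside the
#' band. Missing values are mapped to the non-informative `0` state and
#' their count is reported via the `n_missing` attribute.
#'
#' @param m numeric genes x samples matrix (log-scale expression).
#' @param housekeeping_ids character vector of housekeeping gene ids; at
#'   least 3 must be present in `m`.
#' @param k threshold multiplier (default 1.64).
#' @return an integer matrix over `{-1, 0, 1}` with the same dimnames,
#'   carrying attributes `n_missing` (values mapped to 0) and `reference`
#'   (per-sample mu and sigma).
#' @export
ternarize_expression <- function(m, housekeeping_ids, k = 1.64) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix must have gene rownames and sample colnames",
         call. = FALSE)
  hk <- intersect(housekeeping_ids, rownames(m))
  if (length(hk) < 3)
    stop(sprintf("only %d housekeeping genes found in the matrix (need >= 3)",
                 length(hk)), call. = FALSE)
  ref <- m[hk, , drop = FALSE]
  mu <- colMeans(ref, na.rm = TRUE)
  sigma <- apply(ref, 2, stats::sd, na.rm = TRUE)
  bad <- which(!is.finite(sigma) | sigma == 0)
  if (length(bad))
    stop("zero or undefined housekeeping standard deviation in sample(s): ",
         paste(colnames(m)[bad], collapse = ", "), call. = FALSE)
  up <- sweep(m, 2, mu + k * sigma, ">")
  dn <- sweep(m, 2, mu - k * sigma, "<")
  states <- matrix(0L, nrow = nrow(m), ncol = ncol(m), dimnames = dimnames(m))
  states[up] <- 1L
  states[dn] <- -1L
  n_missing <- sum(is.na(m))
  if (n_missing > 0) states[is.na(m)] <- 0L
  attr(states, "n_missing") <- n_missing
  attr(states, "reference") <- data.frame(sample = colnames(m), mu = mu,
                                          sigma = sigma, row.names = NULL)
  states
}

#' Validate an externally supplied ternary CNV call matrix
#'
#' Checks that every entry lies in `{-1, 0, 1}` and returns the matrix
#' unchanged, with per-gene state frequencies attached as the `state_freq`
#' attribute. Any out-of-set entry raises an error naming the offending
#' gene and sample.
#'
#' @param m a genes x samples matrix of CNV calls.
#' @return `m`, as an integer matrix, with a `state_freq` attribute
#'   (data.frame of per-gene counts of deletion/normal/amplification).
#' @export
validate_cnv_calls <- function(m) {
  bad <- which(!(m %in% c(-1, 0, 1)) | is.na(m))
  if (length(bad)) {
    idx <- arrayInd(bad[1], dim(m))
    g <- if (!is.null(rownames(m))) rownames(m)[idx[1]] else idx[1]
    s <- if (!is.null(colnames(m))) colnames(m)[idx[2]] else idx[2]
    stop(sprintf("invalid ternary value %s at (%s, %s): entries must be -1, 0 or 1",
                 format(m[bad[1]]), g, s), call. = FALSE)
  }
  out <- m
  storage.mode(out) <- "integer"
  freq <- data.frame(
    gene = if (!is.null(rownames(m))) rownames(m) else as.character(seq_len(nrow(m))),
    n_del = rowSums(m == -1),
    n_normal = rowSums(m == 0),
    n_amp = rowSums(m == 1),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "state_freq") <- freq
  out
}
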