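#' Tumor versus NAT differential expression per gene
#'
#' Unpaired two-tailed two-sample t tests with pooled variance, computed for
#' every gene shared by the two matrices. Positive t statistics indicate
#' higher expression in tumors. Fold change is the ratio of group means on
#' the scale of the input matrix (no de-logging is applied).
#'
#' Genes with fewer than 2 non-missing samples in either group, or with zero
#' pooled variance, are flagged and get `NA` statistics.
#'
#' @param tumor,nat numeric genes x samples matrices with gene rownames.
#' @return data.frame with columns `gene`, `n_tumor`, `n_nat`, `t`, `p`,
#'   `fold_change`, `flag` (`""`, `"too_few_samples"` or `"zero_variance"`).
#' @export
tumor_vs_nat_t <- function(tumor, nat) {
  genes <- intersect(rownames(tumor), rownames(nat))
  if (!length(genes)) stop("no shared genes between the two matrices",
                           call. = FALSE)
  x <- tumor[genes, , drop = FALSE]
  y <- nat[genes, , drop = FALSE]
  n1 <- rowSums(!is.na(x)); n0 <- rowSums(!is.na(y))
  m1 <- rowMeans(x, na.rm = TRUE); m0 <- rowMeans(y, na.rm = TRUE)
  v1 <- rowSums((x - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  v0 <- rowSums((y - m0)^2, na.rm = TRUE) / pmax(n0 - 1, 1)
  df <- n1 + n0 - 2
  sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  t <- (m1 - m0) / se
  p <- 2 * stats::pt(-abs(t), df)
  flag <- rep("", length(genes))
  flag[n1 < 2 | n0 < 2] <- "too_few_samples"
  flag[flag == "" & sp2 == 0] <- "zero_variance"
  bad <- flag != ""
  t[bad] <- NA_real_; p[bad] <- NA_real_
  data.frame(gene = genes, n_tumor = n1, n_nat = n0, t = t, p = p,
             fold_change = m1 / m0, flag = flag,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Univariate Cox proportional-hazards screen
#'
#' Fits one univariate Cox model per gene (Breslow tie handling) of
#' survival time on that gene's expression and reports the hazard ratio
#' with its Wald 95% confidence interval. Hazard ratios above 1 indicate
#' increased risk per expression unit.
#'
#' Constant covariates and cohorts without events are flagged with no
#' estimate; monotone likelihood (risk separation, no finite maximizer) is
#' flagged with the divergence direction.
#'
#' @param surv data.frame with columns `time` (> 0) and `event` (0/1),
#'   one row per patient.
#' @param expression genes x patients matrix, columns aligned with the rows
#'   of `surv`.
#' @return data.frame with columns `gene`, `beta`, `hr`, `hr_ci_low`,
#'   `hr_ci_high`, `p`, `flag`.
#' @export
cox_screen <- function(surv, expression) {
  stopifnot(all(c("time", "event") %in% names(surv)))
  if (ncol(expression) != nrow(surv))
    stop("expression columns must align with survival rows", call. = FALSE)
  if (any(surv$time <= 0)) stop("survival times must be positive", call. = FALSE)
  if (!all(surv$event %in% c(0, 1))) stop("events must be 0/1", call. = FALSE)
  ss <- survival::Surv(surv$time, surv$event)
  res <- lapply(rownames(expression), function(g)
    univariate_cox_one(ss, expression[g, ], sum(surv$event)))
  out <- do.call(rbind, res)
  out$gene <- rownames(expression)
  out[, c("gene", "beta", "hr", "hr_ci_low", "hr_ci_high", "p", "flag")]
}

#' Univariate Cox model for a single gene
#'
#' @param surv data.frame with `time` and `event` columns.
#' @param x numeric covariate vector (one value per patient).
#' @return one-row data.frame as in [cox_screen()].
#' @export
univariate_cox <- function(surv, x) {
  stopifnot(all(c("time", "event") %in% names(surv)))
  ss <- survival::Surv(surv$time, surv$event)
  out <- univariate_cox_one(ss, x, sum(surv$event))
  out$gene <- NA_character_
  out[, c("beta", "hr", "hr_ci_low", "hr_ci_high", "p", "flag")]
}

univariate_cox_one <- function(ss, x, n_events) {
  empty <- data.frame(beta = NA_real_, hr = NA_real_, hr_ci_low = NA_real_,
                      hr_ci_high = NA_real_, p = NA_real_, flag = "",
                      stringsAsFactors = FALSE)
  if (n_events < 1) { empty$flag <- "no_events"; return(empty) }
  if (stats::sd(x, na.rm = TRUE) == 0 || all(is.na(x))) {
    empty$flag <- "constant_covariate"; return(empty)
  }
  diverged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(ss ~ x, ties = "breslow"),
    warning = function(w) {
      if (grepl("infinite|did not converge|out of bounds", conditionMessage(w)))
        diverged <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  if (diverged || !is.finite(beta) || !is.finite(se)) {
    empty$flag <- paste0("monotone_likelihood",
                         if (is.finite(beta) && beta < 0) "_negative" else "_positive")
    return(empty)
  }
  data.frame(beta = beta, hr = exp(beta),
             hr_ci_low = exp(beta - 1.96 * se),
             hr_ci_high = exp(beta + 1.96 * se),
             p = 2 * stats::pnorm(-abs(beta / se)),
             flag = "", stringsAsFactors = FALSE)
}

#' Summarize a dependency screen per gene
#'
#' Counts, per gene, the cell lines whose dependency score falls strictly
#' below the threshold (default -0.5), i.e. lines whose growth shows a
#' significant knockout/knockdown effect.
#'
#' @param dep genes x cell-lines numeric matrix of dependency scores.
#' @param threshold negative significance threshold; scores strictly below
#'   it count.
#' @return data.frame with columns `gene`, `n_dependent`, `n_total`, `flag`
#'   (`"all_missing"` for genes with no scores).
#' @export
dependency_summary <- function(dep, threshold = -0.5) {
  if (!is.finite(threshold) || threshold >= 0)
    stop("'threshold' must be negative", call. = FALSE)
  n_dep <- rowSums(dep < threshold, na.rm = TRUE)
  n_tot <- rowSums(!is.na(dep))
  data.frame(gene = rownames(dep), n_dependent = n_dep, n_total = n_tot,
             flag = ifelse(n_tot == 0, "all_missing", ""),
             row.names = NULL, stringsAsFactors = FALSE)
}
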