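#' Configuration for a planted-hub synthetic multi-omics cohort
#'
#' Defines the generative model for a tumor/NAT cohort with a planted
#' regulatory hub structure: `n_hub` regulator genes each drive the mRNA of
#' `fanout` disjoint target genes, copy-number aberrations shift mRNA
#' additively, protein tracks mRNA linearly, and a designated set of
#' housekeeping genes carries baseline noise only (they serve as the
#' discretization reference downstream).
#'
#' Phenotype roles are planted on top of the regulatory structure:
#' oncogenes (tumor-vs-NAT mean shift) and essential genes (negative
#' dependency scores) are drawn from the regulated targets and free genes,
#' never from the housekeeping set; survival hazard genes (nonzero Cox
#' log-hazard) are the hubs plus a sample of the oncogenes (oncogenic
#' programs drive both tumor expression and survival hazard). Hubs
#' themselves carry no tumor shift, so their discretized state reflects
#' copy-number dosage and noise alone.
#'
#' @param n_genes total number of genes.
#' @param n_hub number of planted regulator (hub) genes.
#' @param fanout number of regulated targets per hub; target sets are disjoint.
#' @param n_tumor,n_nat tumor and NAT sample counts.
#' @param n_housekeeping number of housekeeping reference genes.
#' @param cnv_rate per-gene per-sample probability of amplification, and
#'   likewise of deletion (each in `[0, 0.5)`), for non-hub genes
#'   (passenger-level sporadic aberrations).
#' @param hub_cnv_rate the same probability for hub genes. The default is
#'   higher than `cnv_rate`, reflecting recurrent focal copy-number
#'   aberrations at driver loci versus sporadic passenger events.
#' @param cnv_effect additive mRNA shift per copy-number unit (expression
#'   units, i.e. multiples of `noise_sd` when `noise_sd = 1`).
#' @param reg_effect additive mRNA shift on a target when its hub regulator
#'   is in the up (`+1`) state; the negative shift applies in the down state.
#' @param protein_slope linear mRNA-to-protein transfer coefficient.
#' @param noise_sd residual Gaussian standard deviation for both layers.
#' @param tumor_shift mean tumor-minus-NAT mRNA shift planted on oncogenes.
#' @param reg_deadband half-width, in units of `noise_sd`, of the "normal"
#'   band of a hub's regulatory state: a hub is in the up (down) state in a
#'   sample when its mRNA deviates from baseline by more than
#'   `reg_deadband * noise_sd`. The default 0.5 makes regulator activity
#'   dosage-driven: an amplified hub (`cnv_effect = 2`) is active in ~93%
#'   of its amplified samples, while a copy-neutral hub is active in a
#'   sample only through noise.
#' @param n_oncogene,n_essential,n_hazard sizes of the planted phenotype sets
#'   (see Details for how they are drawn).
#' @param hazard_beta per-gene log-hazard coefficient planted on hazard genes.
#' @param baseline common mRNA baseline (log-scale expression units).
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return an object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_genes = 300, n_hub = 10, fanout = 20,
                              n_tumor = 60, n_nat = 30, n_housekeeping = 14,
                              cnv_rate = 0.05, hub_cnv_rate = 0.3,
                              cnv_effect = 2, reg_effect = 2,
                              protein_slope = 0.8, noise_sd = 1,
                              tumor_shift = 1.5, reg_deadband = 0.5,
                              n_oncogene = 30, n_essential = 150, n_hazard = 30,
                              hazard_beta = 0.7, baseline = 8, seed = 1L) {
  cfg <- list(n_genes = n_genes, n_hub = n_hub, fanout = fanout,
              n_tumor = n_tumor, n_nat = n_nat,
              n_housekeeping = n_housekeeping, cnv_rate = cnv_rate,
              hub_cnv_rate = hub_cnv_rate,
              cnv_effect = cnv_effect, reg_effect = reg_effect,
              protein_slope = protein_slope, noise_sd = noise_sd,
              tumor_shift = tumor_shift, reg_deadband = reg_deadband,
              n_oncogene = n_oncogene,
              n_essential = n_essential, n_hazard = n_hazard,
              hazard_beta = hazard_beta, baseline = baseline,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid simulation config: ", msg,
                                 call. = FALSE)
  counts <- c("n_genes", "n_hub", "fanout", "n_tumor", "n_nat",
              "n_housekeeping", "n_oncogene", "n_essential", "n_hazard")
  for (f in counts) {
    v <- cfg[[f]]
    if (length(v) != 1 || is.na(v) || v < 0 || v != round(v))
      stop_cfg(sprintf("'%s' must be a single non-negative integer", f))
  }
  if (cfg$n_tumor < 2 || cfg$n_nat < 2)
    stop_cfg("'n_tumor' and 'n_nat' must each be at least 2")
  if (cfg$n_hub * cfg$fanout > cfg$n_genes - cfg$n_hub - cfg$n_housekeeping)
    stop_cfg("'n_hub * fanout' exceeds n_genes - n_hub - n_housekeeping")
  if (cfg$cnv_rate < 0 || cfg$cnv_rate >= 0.5)
    stop_cfg("'cnv_rate' must lie in [0, 0.5)")
  if (cfg$hub_cnv_rate < 0 || cfg$hub_cnv_rate >= 0.5)
    stop_cfg("'hub_cnv_rate' must lie in [0, 0.5)")
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd <= 0)
    stop_cfg("'noise_sd' must be positive")
  if (!is.finite(cfg$reg_deadband) || cfg$reg_deadband < 0)
    stop_cfg("'reg_deadband' must be non-negative")
  n_free <- cfg$n_genes - cfg$n_housekeeping
  if (cfg$n_oncogene > n_free || cfg$n_hazard > n_free)
    stop_cfg("phenotype set sizes exceed the non-housekeeping gene pool")
  if (cfg$n_essential > cfg$n_hub * cfg$fanout)
    stop_cfg("'n_essential' exceeds the number of regulated target genes")
  invisible(cfg)
}

#' Simulate a multi-omics tumor/NAT cohort with planted hubs
#'
#' Draws ternary CNV states i.i.d. per gene and tumor sample with
#' `P(amp) = P(del) = cnv_rate`, then generates mRNA as
#' `baseline + cnv_effect * cnv + reg_effect * hub_state + tumor_shift * onco
#' + N(0, noise_sd)` and protein as
#' `protein_slope * mRNA + N(0, noise_sd)`. A hub's regulatory state is the
#' ternary state (sign) of its own mRNA deviation from baseline: `+1`/`-1`
#' when the deviation exceeds the `reg_deadband * noise_sd` dead band, else
#' `0`. NAT samples carry no CNV aberrations and no tumor shift.
#' Housekeeping genes receive baseline and noise only.
#'
#' @param config a [simulation_config()].
#' @return a list with ternary `cnv` (genes x tumor samples), continuous
#'   `mrna_tumor`, `mrna_nat`, `protein_tumor`, `protein_nat` matrices, and
#'   `truth`, a `synthetic_truth` list recording planted roles
#'   (`hub_ids`, `target_map`, `oncogene_ids`, `essential_ids`, named
#'   `hazard_ids` with log-hazard coefficients, `housekeeping_ids`) plus the
#'   realized hub regulatory states per sample.
#' @export
simulate_multiomics <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, as.list(config))
  validate_simulation_config(config)
  cfg <- config
  set.seed(cfg$seed)

  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  hk <- sort(sample(genes, cfg$n_housekeeping))
  non_hk <- setdiff(genes, hk)
  hubs <- sort(sample(non_hk, cfg$n_hub))
  pool <- setdiff(non_hk, hubs)
  targets <- if (cfg$n_hub > 0) sample(pool, cfg$n_hub * cfg$fanout) else character()
  target_map <- if (cfg$n_hub > 0)
    split(targets, factor(rep(hubs, each = cfg$fanout), levels = hubs))
  else stats::setNames(list(), character())
  free <- setdiff(pool, targets)

  # oncogenes/essential/hazard genes: never housekeeping; hubs stay shift-free
  onco_pool <- c(targets, free)
  oncogenes <- sort(sample(onco_pool, min(cfg$n_oncogene, length(onco_pool))))
  essential <- if (cfg$n_essential > 0) sort(sample(targets, cfg$n_essential)) else character()
  hz_extra <- max(0, cfg$n_hazard - cfg$n_hub)
  hazard_genes <- c(hubs, if (hz_extra > 0)
    sample(oncogenes, min(hz_extra, length(oncogenes))))
  hazard <- stats::setNames(rep(cfg$hazard_beta, length(hazard_genes)), hazard_genes)

  tumor_ids <- sprintf("t%03d", seq_len(cfg$n_tumor))
  nat_ids <- sprintf("n%03d", seq_len(cfg$n_nat))

  draw_cnv <- function(n_samp) {
    rate <- stats::setNames(rep(cfg$cnv_rate, cfg$n_genes), genes)
    rate[hubs] <- cfg$hub_cnv_rate
    u <- matrix(stats::runif(cfg$n_genes * n_samp), nrow = cfg$n_genes,
                dimnames = list(genes, NULL))
    m <- matrix(0L, nrow = cfg$n_genes, ncol = n_samp,
                dimnames = list(genes, NULL))
    m[u < rate] <- 1L
    m[u > 1 - rate] <- -1L
    m[hk, ] <- 0L
    m
  }
  cnv <- draw_cnv(cfg$n_tumor)
  colnames(cnv) <- tumor_ids

  thr <- cfg$reg_deadband * cfg$noise_sd
  gen_layer <- function(sample_ids, cnv_mat, tumor) {
    ns <- length(sample_ids)
    noise <- matrix(stats::rnorm(cfg$n_genes * ns, sd = cfg$noise_sd),
                    nrow = cfg$n_genes, dimnames = list(genes, sample_ids))
    mrna <- cfg$baseline + cfg$cnv_effect * cnv_mat + noise
    if (tumor && length(oncogenes))
      mrna[oncogenes, ] <- mrna[oncogenes, ] + cfg$tumor_shift
    # hub regulatory state = ternary state of the hub's own mRNA
    hub_state <- matrix(0L, nrow = cfg$n_hub, ncol = ns,
                        dimnames = list(hubs, sample_ids))
    if (cfg$n_hub > 0) {
      dev <- mrna[hubs, , drop = FALSE] - cfg$baseline
      hub_state[] <- (dev > thr) - (dev < -thr)
      for (h in hubs) {
        tg <- target_map[[h]]
        mrna[tg, ] <- mrna[tg, ] +
          cfg$reg_effect * matrix(hub_state[h, ], nrow = length(tg),
                                  ncol = ns, byrow = TRUE)
      }
    }
    prot <- cfg$protein_slope * mrna +
      matrix(stats::rnorm(cfg$n_genes * ns, sd = cfg$noise_sd),
             nrow = cfg$n_genes)
    dimnames(prot) <- dimnames(mrna)
    list(mrna = mrna, protein = prot, hub_state = hub_state)
  }

  tum <- gen_layer(tumor_ids, cnv, tumor = TRUE)
  zero_cnv <- matrix(0L, nrow = cfg$n_genes, ncol = cfg$n_nat,
                     dimnames = list(genes, nat_ids))
  nat <- gen_layer(nat_ids, zero_cnv, tumor = FALSE)

  truth <- structure(list(
    genes = genes,
    housekeeping_ids = hk,
    hub_ids = hubs,
    target_map = target_map,
    oncogene_ids = oncogenes,
    essential_ids = essential,
    hazard_ids = hazard,
    hub_states_tumor = tum$hub_state,
    hub_states_nat = nat$hub_state
  ), class = "synthetic_truth")

  list(cnv = cnv,
       mrna_tumor = tum$mrna, mrna_nat = nat$mrna,
       protein_tumor = tum$protein, protein_nat = nat$protein,
       truth = truth)
}

#' Simulate a CRISPR/RNAi-style dependency screen
#'
#' Planted essential genes draw scores around `essential_mean` (negative:
#' cell growth depends on the gene), all other genes around 0, with Gaussian
#' noise per cell line.
#'
#' @param truth a `synthetic_truth` object from [simulate_multiomics()].
#' @param n_lines number of cell lines (`>= 1`).
#' @param essential_mean mean dependency score for planted essential genes.
#' @param noise_sd score standard deviation.
#' @param seed integer seed.
#' @return a genes x cell-lines numeric matrix of dependency scores.
#' @export
simulate_dependency_screen <- function(truth, n_lines = 94,
                                       essential_mean = -1, noise_sd = 0.25,
                                       seed = 1L) {
  if (n_lines < 1) stop("'n_lines' must be at least 1", call. = FALSE)
  set.seed(as.integer(seed))
  genes <- truth$genes
  mu <- stats::setNames(rep(0, length(genes)), genes)
  mu[truth$essential_ids] <- essential_mean
  scores <- matrix(stats::rnorm(length(genes) * n_lines, mean = mu, sd = noise_sd),
                   nrow = length(genes),
                   dimnames = list(genes, sprintf("line%03d", seq_len(n_lines))))
  scores
}

#' Simulate a survival cohort under a proportional-hazards model
#'
#' Event times are exponential with rate
#' `baseline_hazard * exp(sum_g beta_g * (x_g - mean(x_g)))` over the planted
#' hazard genes, with independent exponential censoring at `censor_rate`.
#' Covariates are centered internally so the linear predictor is on a sane
#' scale; Cox hazard-ratio estimates are invariant to this centering.
#'
#' @param truth a `synthetic_truth`; `truth$hazard_ids` is a named vector of
#'   log-hazard coefficients (may be empty for a null cohort).
#' @param expression genes x patients expression matrix covering all hazard
#'   genes.
#' @param baseline_hazard,censor_rate positive exponential rates.
#' @param seed integer seed.
#' @return a data.frame with columns `patient`, `time` (> 0) and `event`
#'   (1 = event observed, 0 = censored).
#' @export
simulate_survival_cohort <- function(truth, expression,
                                     baseline_hazard = 0.1,
                                     censor_rate = 0.05, seed = 1L) {
  if (!is.finite(baseline_hazard) || baseline_hazard <= 0)
    stop("'baseline_hazard' must be positive", call. = FALSE)
  if (!is.finite(censor_rate) || censor_rate <= 0)
    stop("'censor_rate' must be positive", call. = FALSE)
  hz <- truth$hazard_ids
  if (length(hz) && !all(names(hz) %in% rownames(expression)))
    stop("expression matrix does not cover all hazard genes", call. = FALSE)
  set.seed(as.integer(seed))
  n <- ncol(expression)
  lp <- rep(0, n)
  if (length(hz)) {
    x <- expression[names(hz), , drop = FALSE]
    x <- x - rowMeans(x)
    lp <- as.numeric(crossprod(x, hz))
  }
  t_event <- stats::rexp(n, rate = baseline_hazard * exp(lp))
  t_cens <- stats::rexp(n, rate = censor_rate)
  data.frame(patient = colnames(expression),
             time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             row.names = NULL, stringsAsFactors = FALSE)
}
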