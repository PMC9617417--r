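#' Simulation parameters for a synthetic glioma-like cohort
#'
#' The generator plants the structure the NAS pipeline assumes: two sample
#' clusters with differentially expressed gene blocks, lncRNAs correlated
#' with parent RNA-modification regulators at a tunable latent correlation,
#' and exponential proportional-hazards survival driven by a standardized
#' latent risk axis with independent uniform censoring.
#'
#' Defaults describe the standard study conditions used throughout the test
#' suite: 100 samples per cluster, 20 regulators, 30 lncRNAs of which 12 are
#' MHC-I peptide-coding (6 planted risk, 6 protective), 100 DEG block genes,
#' 300 background genes, latent correlation 0.7, planted fold change of 2
#' log2 units, log-hazard slope 0.7 per SD of risk score, baseline hazard
#' 1/1000 per day (median survival around two years, glioma-like), 30%
#' censoring, NB dispersion 0.2.
#'
#' @param n_samples_per_cluster samples per planted cluster.
#' @param n_regulators number of RNA-modification regulator genes.
#' @param n_lncrna number of candidate lncRNAs.
#' @param mhc1_fraction fraction of lncRNAs flagged MHC-I peptide-coding;
#'   these carry the planted survival effects (half risk, half protective).
#' @param n_deg number of planted differentially expressed genes (half up in
#'   cluster 2, half down).
#' @param n_background number of null genes.
#' @param corr_rho latent Gaussian correlation between each lncRNA and its
#'   parent regulator, in \[0, 1\].
#' @param lfc_planted planted log2 fold change (cluster 2 vs cluster 1).
#' @param beta_risk log hazard ratio per standard deviation of the latent
#'   risk score.
#' @param baseline_hazard exponential baseline hazard per day.
#' @param censor_rate target fraction of censored samples, in \[0, 1).
#' @param dispersion negative-binomial dispersion (var = mu + dispersion *
#'   mu^2).
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_samples_per_cluster = 100, n_regulators = 20,
                       n_lncrna = 30, mhc1_fraction = 0.4, n_deg = 100,
                       n_background = 300, corr_rho = 0.7, lfc_planted = 2,
                       beta_risk = 0.7, baseline_hazard = 1e-3,
                       censor_rate = 0.3, dispersion = 0.2, seed = 1L) {
  stopifnot(n_samples_per_cluster >= 1, n_regulators >= 1, n_lncrna >= 1,
            mhc1_fraction >= 0, mhc1_fraction <= 1, n_deg >= 1,
            n_background >= 1, corr_rho >= 0, corr_rho <= 1,
            baseline_hazard > 0, censor_rate >= 0, censor_rate < 1,
            dispersion > 0)
  p <- list(n_samples_per_cluster = as.integer(n_samples_per_cluster),
            n_regulators = as.integer(n_regulators),
            n_lncrna = as.integer(n_lncrna), mhc1_fraction = mhc1_fraction,
            n_deg = as.integer(n_deg), n_background = as.integer(n_background),
            corr_rho = corr_rho, lfc_planted = lfc_planted,
            beta_risk = beta_risk, baseline_hazard = baseline_hazard,
            censor_rate = censor_rate, dispersion = dispersion,
            seed = as.integer(seed))
  class(p) <- "sim_params"
  p
}

#' Simulate a synthetic cohort
#'
#' Gene-level latents are standard normal with a Gaussian-copula dependence
#' structure: each lncRNA's latent is `rho * z_parent + sqrt(1 - rho^2) *
#' noise` for its parent regulator's latent, so the latent correlation is
#' exactly `corr_rho` regardless of the count marginals. MHC-I-coding
#' lncRNAs and their parents additionally load on a per-sample latent risk
#' axis (positively for the planted risk half, negatively for the protective
#' half); the risk axis itself is shifted between the two clusters so
#' cluster 2 is the aggressive cluster. Counts are negative-binomial via the
#' quantile transform `qnbinom(pnorm(z))`, with the planted log2 fold change
#' applied to the NB mean of DEG genes and MHC-I lncRNAs in cluster 2. FPKM
#' is counts rescaled by gene length and a common library size, so per-gene
#' sample ranks are identical between the two matrices. Survival times are
#' exponential with rate `baseline_hazard * exp(beta_risk * risk)` and
#' independent uniform censoring calibrated to `censor_rate`.
#'
#' @param params a `sim_params` object.
#' @return A list with `counts` and `fpkm` (`ExpressionMatrix`), `clinical`
#'   (data.frame), `annotation` (data.frame), and `truth` (list with
#'   `cluster`, `risk_score`, and a per-gene `genes` table giving role,
#'   planted log2FC, planted survival sign and parent regulator).
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  n_genes_total <- p$n_regulators + p$n_lncrna + p$n_deg + p$n_background
  if (p$n_deg > n_genes_total) stop("infeasible params")
  n <- 2L * p$n_samples_per_cluster

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(p$seed)

  cluster <- rep(1:2, each = p$n_samples_per_cluster)
  sample_ids <- sprintf("S%03d", seq_len(n))

  # latent risk axis: cluster-shifted, then standardized
  risk_raw <- ifelse(cluster == 2, 1, -1) + stats::rnorm(n)
  risk <- as.numeric(scale(risk_raw))

  reg_ids <- sprintf("REG%02d", seq_len(p$n_regulators))
  lnc_ids <- sprintf("LNC%02d", seq_len(p$n_lncrna))
  deg_ids <- sprintf("DEG%03d", seq_len(p$n_deg))
  bg_ids <- sprintf("BG%03d", seq_len(p$n_background))

  n_mhc1 <- round(p$mhc1_fraction * p$n_lncrna)
  mhc1 <- rep(FALSE, p$n_lncrna)
  mhc1[seq_len(n_mhc1)] <- TRUE
  # planted survival signs on the MHC-I-coding lncRNAs: half risk, half protective
  beta_sign <- integer(p$n_lncrna)
  if (n_mhc1 > 0) {
    half <- ceiling(n_mhc1 / 2)
    beta_sign[seq_len(half)] <- 1L
    if (n_mhc1 > half) beta_sign[(half + 1):n_mhc1] <- -1L
  }
  parent <- reg_ids[((seq_len(p$n_lncrna) - 1L) %% p$n_regulators) + 1L]

  # loading of each parent regulator on the risk axis, inherited from the
  # sign of its (first) mhc1 child; regulators without a signed child are null
  lambda_risk <- 0.7
  reg_sign <- integer(p$n_regulators)
  for (j in seq_len(p$n_lncrna)) {
    ridx <- match(parent[j], reg_ids)
    if (beta_sign[j] != 0 && reg_sign[ridx] == 0) reg_sign[ridx] <- beta_sign[j]
  }

  z_reg <- matrix(stats::rnorm(p$n_regulators * n), p$n_regulators, n)
  for (g in seq_len(p$n_regulators)) {
    if (reg_sign[g] != 0)
      z_reg[g, ] <- reg_sign[g] * lambda_risk * risk +
        sqrt(1 - lambda_risk^2) * z_reg[g, ]
  }
  rho <- p$corr_rho
  z_lnc <- matrix(stats::rnorm(p$n_lncrna * n), p$n_lncrna, n)
  for (g in seq_len(p$n_lncrna)) {
    zp <- z_reg[match(parent[g], reg_ids), ]
    z_lnc[g, ] <- rho * zp + sqrt(1 - rho^2) * z_lnc[g, ]
  }
  # DEG-block genes express a graded aggressiveness program: besides the
  # cluster mean shift they load on the continuous risk axis with the sign
  # of their planted fold change, so each carries its own survival
  # association and the block is co-expressed within clusters; the loading
  # is planted structure, so it vanishes in the null configuration
  lambda_deg <- if (p$lfc_planted == 0) 0 else 0.5
  deg_sign <- rep(c(1, -1), c(ceiling(p$n_deg / 2), floor(p$n_deg / 2)))
  z_deg <- matrix(stats::rnorm(p$n_deg * n), p$n_deg, n)
  for (g in seq_len(p$n_deg))
    z_deg[g, ] <- deg_sign[g] * lambda_deg * risk +
      sqrt(1 - lambda_deg^2) * z_deg[g, ]
  z_bg <- matrix(stats::rnorm(p$n_background * n), p$n_background, n)

  z <- rbind(z_reg, z_lnc, z_deg, z_bg)
  gene_ids <- c(reg_ids, lnc_ids, deg_ids, bg_ids)
  rownames(z) <- gene_ids

  # planted log2 fold changes (cluster 2 vs 1)
  lfc <- numeric(n_genes_total)
  names(lfc) <- gene_ids
  lfc[deg_ids[seq_len(ceiling(p$n_deg / 2))]] <- p$lfc_planted
  lfc[deg_ids[seq(ceiling(p$n_deg / 2) + 1, length.out = floor(p$n_deg / 2))]] <-
    -p$lfc_planted
  lfc[lnc_ids] <- beta_sign * p$lfc_planted

  base_mu <- 2^stats::runif(n_genes_total, 4, 9)  # baseline NB means ~16..512
  names(base_mu) <- gene_ids
  mu <- base_mu * 2^(outer(lfc, as.numeric(cluster == 2)))
  size <- 1 / p$dispersion
  counts <- matrix(stats::qnbinom(stats::pnorm(z), size = size, mu = mu),
                   n_genes_total, n, dimnames = list(gene_ids, sample_ids))

  gene_len_kb <- 2^stats::runif(n_genes_total, -1, 2)  # 0.5..4 kb
  lib <- mean(colSums(counts))
  fpkm <- counts / gene_len_kb / (lib / 1e6)

  surv <- simulate_survival(p$beta_risk * risk, p$baseline_hazard,
                            p$censor_rate)
  clinical <- data.frame(sample_id = sample_ids,
                         os_days = surv$times, os_event = surv$events,
                         cohort = "synthetic",
                         stringsAsFactors = FALSE)

  annotation <- data.frame(
    gene_id = gene_ids,
    is_lncrna = gene_ids %in% lnc_ids,
    mhc1_coding = gene_ids %in% lnc_ids[mhc1],
    regulator_class = "none", regulator_role = "none",
    stringsAsFactors = FALSE)
  classes <- c("psi", "m5C", "m1A")
  roles <- c("writer", "reader", "eraser")
  ridx <- match(reg_ids, annotation$gene_id)
  annotation$regulator_class[ridx] <- classes[((seq_along(reg_ids) - 1L) %% 3L) + 1L]
  annotation$regulator_role[ridx] <- roles[((seq_along(reg_ids) - 1L) %/% 3L) %% 3L + 1L]

  genes_truth <- data.frame(
    gene_id = gene_ids,
    role = c(rep("regulator", p$n_regulators), rep("lncrna", p$n_lncrna),
             rep("deg", p$n_deg), rep("background", p$n_background)),
    planted_lfc = unname(lfc),
    planted_beta_sign = c(rep(0L, p$n_regulators), beta_sign,
                          rep(0L, p$n_deg + p$n_background)),
    parent = c(rep(NA_character_, p$n_regulators), parent,
               rep(NA_character_, p$n_deg + p$n_background)),
    stringsAsFactors = FALSE)

  list(counts = expression_matrix(counts, "counts"),
       fpkm = expression_matrix(fpkm, "fpkm"),
       clinical = clinical,
       annotation = annotation,
       truth = list(cluster = stats::setNames(cluster, sample_ids),
                    risk_score = stats::setNames(risk, sample_ids),
                    genes = genes_truth))
}

#' Simulate exponential proportional-hazards survival
#'
#' Event times are exponential with rate `baseline_hazard * exp(lp)`.
#' Censoring is independent Uniform(0, T_max) with `T_max` found by
#' bisection so the realized censoring fraction approximates `censor_rate`;
#' `censor_rate = 0` produces no censoring.
#'
#' @param linear_predictor numeric vector of per-sample log-hazard offsets.
#' @param baseline_hazard exponential baseline hazard (per day).
#' @param censor_rate target censored fraction in \[0, 1).
#' @param seed optional integer seed; when NULL the current RNG stream is
#'   used (so [simulate_cohort()] stays reproducible from its own seed).
#' @return A list with `times` (positive, day-scale) and `events` (0/1).
#' @export
simulate_survival <- function(linear_predictor, baseline_hazard, censor_rate,
                              seed = NULL) {
  stopifnot(all(is.finite(linear_predictor)), baseline_hazard > 0,
            censor_rate >= 0, censor_rate < 1)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  n <- length(linear_predictor)
  t_event <- stats::rexp(n, rate = baseline_hazard * exp(linear_predictor))
  if (censor_rate == 0)
    return(list(times = pmax(t_event, 0.5), events = rep(1, n)))
  u <- stats::runif(n)
  frac_censored <- function(tmax) mean(u * tmax < t_event)
  lo <- 1e-6; hi <- max(t_event) * 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (frac_censored(mid) > censor_rate) lo <- mid else hi <- mid
  }
  tmax <- (lo + hi) / 2
  cens <- u * tmax
  events <- as.numeric(t_event <= cens)
  times <- pmin(t_event, cens)
  list(times = pmax(times, 0.5), events = events)
}

# save/restore the global RNG state so seeded generators do not perturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
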