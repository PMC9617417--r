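# Shared fixtures, built once per test run.
#
# std_cohort is the standard study-condition cohort (100 samples/cluster,
# planted lfc 2, latent correlation 0.7, beta 0.7/SD, 30% censoring).
std_cohort <- simulate_cohort(sim_params(seed = 42))

std_truth <- std_cohort$truth
std_mhc1 <- std_cohort$annotation$gene_id[std_cohort$annotation$mhc1_coding]
std_regulators <- std_cohort$annotation$gene_id[
  std_cohort$annotation$regulator_class != "none"]
std_lnc <- std_cohort$annotation$gene_id[std_cohort$annotation$is_lncrna]

# Scaled-down null configuration for end-to-end calibration replicates.
null_sim_params <- function(seed) {
  sim_params(n_samples_per_cluster = 40, n_regulators = 10, n_lncrna = 12,
             mhc1_fraction = 0.5, n_deg = 30, n_background = 60,
             lfc_planted = 0, beta_risk = 0, seed = seed)
}

null_config <- function(seed) nas_config(seed = seed, k_range = 2:3, reps = 40)

# k well-separated gaussian clouds (10 features), for cluster-number recovery
make_clouds <- function(k_true, n_per = 40, sep = 8, seed = 1) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(k_true * 10, sd = sep), k_true, 10)
  x <- do.call(cbind, lapply(seq_len(k_true), function(cl)
    t(centers[rep(cl, n_per), ] + matrix(stats::rnorm(n_per * 10), n_per, 10))))
  dimnames(x) <- list(sprintf("g%02d", 1:10),
                      sprintf("s%03d", seq_len(k_true * n_per)))
  list(x = x, labels = rep(seq_len(k_true), each = n_per))
}

# brute-force step-up FDR oracle, independent of stats::p.adjust
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- Inf
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- min(prev, 1)
  }
  adj
}

# brute-force AUC by pair counting with half-credit ties
auc_bruteforce <- function(score, outcome) {
  pos <- score[outcome == 1]; neg <- score[outcome == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

run_small_pipeline <- function(seed, validation = FALSE) {
  suppressWarnings(suppressMessages(run_nas_pipeline(
    nas_config(seed = seed, k_range = 2:5, reps = 60),
    sim_params(seed = seed), validation_cohort = validation)))
}
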