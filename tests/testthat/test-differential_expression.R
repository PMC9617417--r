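test_that("the shared fold change is the simple pseudocounted log ratio", {
  v <- rbind(g1 = c(1, 1, 7, 7), g2 = c(5, 5, 5, 5))
  colnames(v) <- paste0("s", 1:4)
  lab <- c(1, 1, 2, 2)
  lfc <- shared_log2fc(v, lab)
  expect_equal(unname(lfc["g1"]), 2)      # log2((7+1)/(1+1))
  expect_equal(unname(lfc["g2"]), 0)
  expect_equal(shared_log2fc(v, 3 - lab), -lfc)
})

test_that("moderated t reduces to the classical t when variances are equal", {
  set.seed(41)
  resid <- stats::rnorm(20)
  resid <- resid - ave(resid, rep(1:2, each = 10))  # same residuals per gene
  v <- rbind(g1 = 1 + resid, g2 = c(rep(0, 10), rep(3, 10)) + resid,
             g3 = 5 + 2 * c(rep(0, 10), rep(1, 10)) + resid)
  colnames(v) <- paste0("s", 1:20)
  lab <- rep(1:2, each = 10)
  r <- de_mod_t(v, lab)
  for (g in rownames(v)) {
    tt <- stats::t.test(v[g, lab == 2], v[g, lab == 1], var.equal = TRUE)
    # the statistic is recoverable from the returned p through the augmented df
    tstat <- stats::qt(r$p[r$gene_id == g] / 2, df = 18 + 4)
    expect_equal(abs(tstat), abs(unname(tt$statistic)), tolerance = 1e-8)
  }
})

test_that("moderated t is calibrated under the null and powered under shift", {
  set.seed(42)
  v <- matrix(stats::rnorm(2000 * 40), 2000, 40,
              dimnames = list(sprintf("g%04d", 1:2000), sprintf("s%d", 1:40)))
  lab <- rep(1:2, each = 20)
  r <- de_mod_t(v, lab)
  expect_lt(unname(stats::ks.test(r$p, "punif")$statistic), 0.05)

  set.seed(43)
  n <- 100
  shift <- c(rep(2, 100), rep(0, 900))
  v2 <- matrix(stats::rnorm(1000 * n), 1000, n) +
    outer(shift, as.numeric(rep(1:2, each = 50) == 2))
  dimnames(v2) <- list(sprintf("g%04d", 1:1000), sprintf("s%d", 1:n))
  r2 <- de_mod_t(v2, rep(1:2, each = 50))
  expect_gte(mean(r2$fdr[1:100] < 0.05), 0.9)
})

test_that("rank-sum matches exact enumeration and is monotone-invariant", {
  v <- rbind(gsep = c(1, 2, 3, 4, 5, 11, 12, 13, 14, 15),
             gconst = rep(2, 10))
  colnames(v) <- paste0("s", 1:10)
  lab <- rep(1:2, each = 5)
  expect_warning(r <- de_rank_sum(v, lab), "constant")
  expect_equal(r$p[r$gene_id == "gsep"], 2 / 252, tolerance = 1e-12)
  expect_equal(r$p[r$gene_id == "gconst"], 1)

  vexp <- v; vexp["gsep", ] <- exp(v["gsep", ])
  r2 <- suppressWarnings(de_rank_sum(vexp, lab))
  expect_equal(r2$p[r2$gene_id == "gsep"], r$p[r$gene_id == "gsep"])
})

test_that("NB exact test converges to the Poisson conditional test", {
  # binomial-conditional oracle for the Poisson limit
  poisson_oracle <- function(y1, y2, n1, n2) {
    tot <- y1 + y2
    pr <- stats::dbinom(0:tot, tot, n1 / (n1 + n2))
    sum(pr[pr <= pr[y1 + 1] * (1 + 1e-8)])
  }
  cases <- list(c(10, 25), c(3, 3), c(0, 12), c(40, 22))
  for (cs in cases) {
    got <- nascore:::nb_exact_p(cs[1], cs[2], 5, 5, 1e-6)
    expect_equal(got, poisson_oracle(cs[1], cs[2], 5, 5), tolerance = 1e-3)
  }
})

test_that("NB exact test is symmetric-null at equal sums and recovers 4-fold genes", {
  v <- matrix(5L, 4, 6, dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  v[2, ] <- c(9L, 1L, 5L, 5L, 9L, 1L)  # equal group sums, equal libraries
  r <- de_nb_exact(v, rep(1:2, each = 3), dispersion = 0.1)
  expect_true(all(r$p == 1))

  set.seed(44)
  n <- 60; mu <- 100
  up <- matrix(stats::rnbinom(50 * n, mu = rep(c(rep(mu, 30), rep(4 * mu, 30)),
                                               each = 50), size = 5), 50, n)
  down <- matrix(stats::rnbinom(50 * n, mu = rep(c(rep(4 * mu, 30), rep(mu, 30)),
                                                 each = 50), size = 5), 50, n)
  null <- matrix(stats::rnbinom(400 * n, mu = mu, size = 5), 400, n)
  cnt <- rbind(up, down, null)
  dimnames(cnt) <- list(sprintf("g%03d", 1:500), sprintf("s%02d", 1:n))
  r2 <- de_nb_exact(cnt, rep(1:2, each = 30))
  expect_gte(mean(r2$fdr[1:100] < 0.05), 0.85)
  expect_lte(mean(r2$fdr[101:500] < 0.05), 0.05)
})

test_that("BH adjustment reproduces the worked step-up example and its properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.5)),
               c(0.04, 0.04, 0.16 / 3, 0.5), tolerance = 1e-12)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  set.seed(45)
  p <- stats::runif(200)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("engines are invariant to sample order", {
  co <- simulate_cohort(sim_params(n_samples_per_cluster = 20, seed = 8))
  lab <- co$truth$cluster
  v <- expr_values(co$fpkm)
  set.seed(47)
  perm <- sample(ncol(v))
  a <- de_mod_t(log2(v + 1), lab)
  b <- de_mod_t(log2(v + 1)[, perm], lab[perm])
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("the intersection rule and its single-engine fallback behave as stated", {
  rec <- function(engine, genes, fdr, lfc) {
    data.frame(gene_id = genes, log2fc = lfc, p = fdr, fdr = fdr,
               engine = engine, stringsAsFactors = FALSE)
  }
  genes <- paste0("g", 1:4)
  records <- list(
    mod_t = rec("mod_t", genes, c(0.01, 0.01, 0.5, 0.01), c(2, 2, 2, 2)),
    rank_sum = rec("rank_sum", genes, c(0.01, 0.01, 0.01, 0.01), c(2, 2, 2, 0.5)),
    nb_exact = rec("nb_exact", genes, c(0.01, 0.5, 0.01, 0.01), c(2, 2, 2, 2)))
  # g1 passes all three; g2 fails nb; g3 fails mod_t; g4 fails |lfc| in rank_sum
  out <- intersect_degs(records)
  expect_identical(out$genes, "g1")
  expect_identical(out$rule_used, "intersection")

  # empty intersection: fallback picks the designated engine at the relaxed lfc
  records2 <- list(
    mod_t = rec("mod_t", genes, rep(0.5, 4), rep(2, 4)),
    nb_exact = rec("nb_exact", genes, c(0.01, 0.01, 0.5, 0.01),
                   c(0.5, 0.3, 2, 2)))
  out2 <- intersect_degs(records2)
  expect_identical(out2$rule_used, "fallback_single")
  expect_identical(out2$fallback_engine, "nb_exact")
  expect_setequal(out2$genes, c("g1", "g4"))  # fdr<0.05 & |lfc|>0.4

  # thresholds disabled: every gene tested by all engines
  out3 <- intersect_degs(records, fdr_max = 1.01, lfc_min = -1)
  expect_setequal(out3$genes, genes)
  expect_error(intersect_degs(list()), "no differential")
})

test_that("intersection is no more permissive than the strictest engine on nulls", {
  set.seed(46)
  co <- simulate_cohort(sim_params(n_samples_per_cluster = 30,
                                   lfc_planted = 0, beta_risk = 0, seed = 9))
  lab <- co$truth$cluster
  degs <- suppressWarnings(run_deg(co$fpkm, lab, counts = co$counts,
                                   fdr_max = 0.5, lfc_min = 0.1,
                                   fallback_lfc = 0))
  if (degs$rule_used == "intersection") {
    per_engine <- vapply(degs$records, function(df)
      sum(df$fdr < 0.5 & abs(df$log2fc) > 0.1, na.rm = TRUE), numeric(1))
    expect_lte(length(degs$genes), min(per_engine))
  } else {
    succeed("intersection empty; fallback exercised")
  }
})

test_that("moderated-t agrees with an established empirical-Bayes engine on ranking", {
  skip_if_not_installed("limma")
  co <- simulate_cohort(sim_params(n_samples_per_cluster = 25, seed = 10))
  lab <- co$truth$cluster
  lg <- log2(expr_values(co$fpkm) + 1)
  mine <- de_mod_t(lg, lab)
  design <- stats::model.matrix(~ factor(lab))
  fit <- limma::eBayes(limma::lmFit(lg, design))
  ref_p <- fit$p.value[, 2]
  expect_gt(stats::cor(-log10(mine$p), -log10(ref_p[mine$gene_id]),
                       method = "spearman"), 0.98)
})
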