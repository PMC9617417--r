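test_that("the NAS worked example evaluates to 4e-4", {
  v <- matrix(c(10, 5), 2, 1, dimnames = list(c("r1", "p1"), "s1"))
  expr <- expression_matrix(v, "fpkm")
  w <- data.frame(gene_id = c("r1", "p1"), loading_pc1 = c(0.5, 0.2),
                  loading_pc2 = c(0, 0), w = c(0.5, 0.2))
  part <- gene_partition("r1", "p1")
  nas <- suppressMessages(compute_nas(expr, w, part, k_const = 1e-4))
  # 1e-4 * (10 * 0.5 - 5 * 0.2) = 4e-4
  expect_identical(unname(nas$nas), 4e-4)
})

test_that("the NAS is linear, scale-equivariant and monotone in risk genes", {
  co <- std_cohort
  part <- gene_partition(std_truth$genes$gene_id[std_truth$genes$planted_beta_sign == 1],
                         std_truth$genes$gene_id[std_truth$genes$planted_beta_sign == -1])
  w <- pca_weights(co$fpkm, part)
  nas <- suppressMessages(compute_nas(co$fpkm, w, part))
  v <- expr_values(co$fpkm)

  # all-zero expression scores 0 everywhere
  zero <- expression_matrix(v * 0, "fpkm")
  expect_true(all(suppressMessages(compute_nas(zero, w, part))$nas == 0))

  # doubling k doubles; scaling expression scales
  nas2 <- suppressMessages(compute_nas(co$fpkm, w, part, k_const = 2e-4))
  expect_equal(nas2$nas, 2 * nas$nas)
  half <- expression_matrix(v / 2, "fpkm")
  expect_equal(suppressMessages(compute_nas(half, w, part))$nas, nas$nas / 2)

  # bump one HR>1 gene with positive weight in one sample: score must rise
  g <- part$genes_hr_gt1[which(w$w[match(part$genes_hr_gt1, w$gene_id)] > 0)[1]]
  v2 <- v; v2[g, 1] <- v2[g, 1] + 100
  bumped <- suppressMessages(
    compute_nas(expression_matrix(v2, "fpkm"), w, part))
  expect_gt(bumped$nas[1], nas$nas[1])
  expect_equal(bumped$nas[-1], nas$nas[-1])
})

test_that("PCA weights solve the 2x2 eigenproblem and obey the orientation rule", {
  set.seed(51)
  base <- abs(stats::rnorm(30, 10, 3))
  v <- rbind(g1 = base, g2 = 2 * base)
  colnames(v) <- sprintf("s%d", 1:30)
  part <- gene_partition("g1", "g2")
  w <- pca_weights(expression_matrix(v, "fpkm"), part, log_transform = FALSE)
  expect_equal(abs(w$loading_pc1), rep(1 / sqrt(2), 2), tolerance = 1e-10)
  expect_equal(unname(attr(w, "var_explained")["pc1"]), 1, tolerance = 1e-10)
  # orientation: risk-minus-protective loading sum is non-negative per component
  expect_gte(w$loading_pc1[1] - w$loading_pc1[2], 0)
})

test_that("the orientation rule makes the weights sign-unambiguous", {
  co <- std_cohort
  part <- gene_partition(std_truth$genes$gene_id[std_truth$genes$planted_beta_sign == 1],
                         std_truth$genes$gene_id[std_truth$genes$planted_beta_sign == -1])
  w <- pca_weights(co$fpkm, part)
  for (col in c("loading_pc1", "loading_pc2")) {
    s <- sum(w[[col]][w$gene_id %in% part$genes_hr_gt1]) -
      sum(w[[col]][w$gene_id %in% part$genes_hr_lt1])
    expect_gte(s, 0)
  }
  # the same data with genes listed in a different order gives the same weights
  shuffled <- expr_subset(co$fpkm,
                          genes = rev(rownames(expr_values(co$fpkm))))
  w2 <- pca_weights(shuffled, part)
  expect_equal(w2$w[match(w$gene_id, w2$gene_id)], w$w, tolerance = 1e-10)
})

test_that("prognostic screening recovers planted survival signs and rejects alpha = 0", {
  co <- std_cohort
  prog <- prognostic_degs(std_mhc1, co$fpkm, co$clinical)
  truth <- std_truth$genes
  expect_setequal(prog$genes_hr_gt1,
                  intersect(std_mhc1, truth$gene_id[truth$planted_beta_sign == 1]))
  expect_setequal(prog$genes_hr_lt1,
                  intersect(std_mhc1, truth$gene_id[truth$planted_beta_sign == -1]))
  expect_error(prognostic_degs(std_mhc1, co$fpkm, co$clinical, alpha = 0),
               "positive")
  expect_error(prognostic_degs(character(), co$fpkm, co$clinical), "empty")
})

test_that("permuting survival leaves roughly the nominal significant fraction", {
  co <- std_cohort
  genes <- std_truth$genes$gene_id[std_truth$genes$role %in% c("deg", "background")]
  set.seed(52)
  perm <- co$clinical
  perm$os_days <- sample(perm$os_days)
  perm$os_event <- sample(perm$os_event)
  fits <- unicox_screen(co$fpkm, perm, genes = genes)
  frac <- mean(fits$p < 0.05, na.rm = TRUE)
  expect_lt(frac, 0.12)
})

test_that("the NAS separates the oriented clusters on the standard cohort", {
  co <- std_cohort
  lab <- std_truth$cluster
  degs <- suppressWarnings(run_deg(co$fpkm, lab, counts = co$counts))
  prog <- prognostic_degs(degs, co$fpkm, co$clinical)
  w <- pca_weights(co$fpkm, prog)
  nas <- suppressMessages(compute_nas(co$fpkm, w, prog))
  p <- stats::wilcox.test(nas$nas[lab == 2], nas$nas[lab == 1],
                          alternative = "greater")$p.value
  expect_lt(p, 0.01)
  expect_gt(mean(nas$nas[lab == 2]), mean(nas$nas[lab == 1]))
})

test_that("group splitting follows the median rule with ties to the low group", {
  nas <- stats::setNames(c(1, 2, 3, 4), paste0("s", 1:4))
  g <- split_groups(nas)
  expect_identical(as.character(g$group), c("low", "low", "high", "high"))
  g3 <- split_groups(stats::setNames(c(1, 2, 3), paste0("s", 1:3)))
  expect_identical(as.character(g3$group), c("low", "low", "high"))
  expect_error(split_groups(stats::setNames(rep(1, 4), paste0("s", 1:4))),
               "identical")
  # balanced groups whenever values are distinct
  set.seed(53)
  x <- stats::setNames(stats::rnorm(101), paste0("s", 1:101))
  tab <- table(split_groups(x)$group)
  expect_lte(abs(tab[["high"]] - tab[["low"]]), 1)
})

test_that("the simplified five-gene score matches its arithmetic oracle", {
  genes <- names(simplified_nas_coefficients)
  v <- matrix(1, 5, 2, dimnames = list(genes, c("s1", "s2")))
  sc <- simplified_nas(expression_matrix(v, "fpkm"))
  expect_equal(unname(sc), rep(0.47131621, 2), tolerance = 1e-9)
  expect_true(all(simplified_nas(expression_matrix(v * 0, "fpkm")) == 0))
  v2 <- v[1:3, , drop = FALSE]
  expect_warning(sc2 <- simplified_nas(expression_matrix(v2, "fpkm")),
                 "absent")
  expect_equal(unname(sc2[1]), sum(simplified_nas_coefficients[1:3]))
})

test_that("a refit five-gene score concords with the full NAS", {
  # the generator's DEGs are only weakly co-expressed compared with real
  # tumour programs, which caps how much of a ~100-gene score five genes
  # can carry; the concordance is asserted at the level that structure supports
  co <- std_cohort
  lab <- std_truth$cluster
  degs <- suppressWarnings(run_deg(co$fpkm, lab, counts = co$counts))
  prog <- prognostic_degs(degs, co$fpkm, co$clinical)
  w <- pca_weights(co$fpkm, prog)
  nas <- suppressMessages(compute_nas(co$fpkm, w, prog))
  al <- suppressMessages(
    align_cohort(expr_subset(co$fpkm, genes = degs$genes), co$clinical))
  coefs <- fit_simplified_signature(al$expr, al$clinical, log_transform = FALSE)
  refit <- simplified_nas(al$expr, coefs)
  expect_gte(stats::cor(refit, nas$nas, method = "spearman"), 0.6)
})
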