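#' Screen lncRNAs for correlation with RNA-modification regulators
#'
#' Tests every (regulator, candidate) pair with `cor.test` and keeps edges
#' with |r| >= `r_min` and p <= `p_max` (defaults 0.4 and 0.001, the
#' published screen). Expression is log2(x + 1)-transformed by default
#' before correlating, since FPKM is heavy-tailed. Zero-variance genes are
#' skipped with a warning.
#'
#' @param expr an `ExpressionMatrix`.
#' @param regulators character vector of regulator gene ids (must be rows of
#'   `expr`); empty is an error.
#' @param candidates character vector of candidate lncRNA gene ids.
#' @param method `"pearson"` (default of the screening function) or
#'   `"spearman"`.
#' @param r_min,p_max retention thresholds on |r| and p.
#' @param log_transform log2(x + 1)-transform non-log input first.
#' @return A data.frame of retained edges: `regulator`, `lncrna`, `r`, `p`.
#' @export
correlation_screen <- function(expr, regulators, candidates,
                               method = c("pearson", "spearman"),
                               r_min = 0.4, p_max = 0.001,
                               log_transform = TRUE) {
  method <- match.arg(method)
  if (!length(regulators)) stop("empty regulator set")
  x <- if (log_transform) expr_log2(expr) else expr
  v <- expr_values(x)
  if (ncol(v) < 3) stop("need at least 3 samples for correlation screening")
  regulators <- intersect(regulators, rownames(v))
  candidates <- intersect(candidates, rownames(v))
  if (!length(regulators)) stop("no regulators present in expression matrix")
  keep_var <- function(ids) {
    varz <- apply(v[ids, , drop = FALSE], 1, stats::var)
    if (any(varz == 0)) {
      warning(sprintf("skipping %d zero-variance gene(s) in correlation screen",
                      sum(varz == 0)))
      ids <- ids[varz > 0]
    }
    ids
  }
  regulators <- keep_var(regulators)
  candidates <- keep_var(candidates)
  out <- vector("list", length(regulators) * length(candidates))
  i <- 0L
  for (rg in regulators) {
    xr <- v[rg, ]
    for (cd in candidates) {
      ct <- suppressWarnings(
        stats::cor.test(xr, v[cd, ], method = method, exact = FALSE))
      if (abs(ct$estimate) >= r_min && ct$p.value <= p_max) {
        i <- i + 1L
        out[[i]] <- data.frame(regulator = rg, lncrna = cd,
                               r = unname(ct$estimate), p = ct$p.value,
                               stringsAsFactors = FALSE)
      }
    }
  }
  if (i == 0L)
    return(data.frame(regulator = character(), lncrna = character(),
                      r = numeric(), p = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out[seq_len(i)])
}

#' Univariate Cox proportional-hazards fit for one gene
#'
#' Wraps `survival::coxph` with Efron tie handling (day-resolution survival
#' data carries ties). Reports the log hazard ratio, its Wald p-value and
#' 95% CI from the observed information. Zero-variance expression or
#' non-convergence returns NA with the `converged` flag unset so callers can
#' exclude the fit.
#'
#' @param x numeric vector of per-sample expression (same order as
#'   `clinical` rows).
#' @param clinical clinical data.frame with `os_days`, `os_event`.
#' @param gene_id identifier recorded in the output row.
#' @return One-row data.frame: `gene_id`, `beta`, `hr`, `se`, `p`,
#'   `ci_low`, `ci_high`, `score` (the efficient score test statistic,
#'   which equals the log-rank chi-square for a binary tie-free covariate),
#'   `converged`.
#' @export
unicox <- function(x, clinical, gene_id = "gene") {
  stopifnot(length(x) == nrow(clinical))
  na_row <- data.frame(gene_id = gene_id, beta = NA_real_, hr = NA_real_,
                       se = NA_real_, p = NA_real_, ci_low = NA_real_,
                       ci_high = NA_real_, score = NA_real_, converged = FALSE,
                       stringsAsFactors = FALSE)
  if (sum(clinical$os_event) < 2) stop("need at least 2 events for unicox")
  if (!all(is.finite(x))) stop("non-finite expression passed to unicox")
  if (stats::var(x) == 0) return(na_row)
  fit <- tryCatch(
    survival::coxph(survival::Surv(clinical$os_days, clinical$os_event) ~ x,
                    ties = "efron",
                    control = survival::coxph.control(iter.max = 50)),
    error = function(e) NULL, warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(survival::Surv(clinical$os_days, clinical$os_event) ~ x,
                        ties = "efron",
                        control = survival::coxph.control(iter.max = 50)))
      f
    })
  if (is.null(fit) || !is.finite(fit$coefficients) ||
      abs(fit$coefficients) > 50)
    return(na_row)
  beta <- unname(fit$coefficients)
  se <- sqrt(unname(fit$var[1, 1]))
  zst <- beta / se
  data.frame(gene_id = gene_id, beta = beta, hr = exp(beta), se = se,
             p = 2 * stats::pnorm(-abs(zst)),
             ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
             score = unname(fit$score), converged = TRUE,
             stringsAsFactors = FALSE)
}

#' Univariate Cox screen across genes
#'
#' Runs [unicox()] on each requested gene of an expression matrix, on the
#' log2(x + 1) scale by default (the screen treats expression as a
#' continuous covariate).
#'
#' @param expr an `ExpressionMatrix`; samples must match `clinical` order
#'   (use [align_cohort()] first).
#' @param clinical clinical data.frame.
#' @param genes gene ids to fit (default: all rows).
#' @param log_transform log2(x + 1)-transform non-log input first.
#' @return A data.frame with one [unicox()] row per gene (non-converged fits
#'   included with `converged = FALSE`).
#' @export
unicox_screen <- function(expr, clinical, genes = NULL, log_transform = TRUE) {
  x <- if (log_transform) expr_log2(expr) else expr
  v <- expr_values(x)
  stopifnot(identical(colnames(v), clinical$sample_id))
  if (is.null(genes)) genes <- rownames(v)
  genes <- intersect(genes, rownames(v))
  fits <- lapply(genes, function(g) unicox(v[g, ], clinical, g))
  do.call(rbind, fits)
}

#' Select the MHC-I-coding prognostic lncRNA signature
#'
#' A gene enters the signature when it (i) appears in at least one retained
#' regulator-correlation edge, (ii) has univariate Cox p below `alpha`, and
#' (iii) is flagged MHC-I peptide-coding. The selection is partitioned by
#' hazard ratio into risk (HR > 1) and protective (HR < 1) genes; an HR of
#' exactly 1 would fall in the protective set.
#'
#' @param edges data.frame from [correlation_screen()].
#' @param coxfits data.frame from [unicox_screen()].
#' @param annotation annotation data.frame (see [read_annotation()]).
#' @param alpha Cox significance threshold.
#' @return A list of class `GenePartition` with `genes_hr_gt1` and
#'   `genes_hr_lt1` character vectors.
#' @export
select_candidates <- function(edges, coxfits, annotation, alpha = 0.05) {
  stopifnot(alpha >= 0, alpha <= 1)
  correlated <- unique(edges$lncrna)
  fits <- coxfits[coxfits$converged & !is.na(coxfits$p), , drop = FALSE]
  significant <- fits$gene_id[fits$p < alpha |
                                (alpha == 1 & fits$p <= 1)]
  mhc1 <- annotation$gene_id[annotation$mhc1_coding]
  selected <- Reduce(intersect, list(correlated, significant, mhc1))
  if (!length(selected)) {
    warning("no genes pass the combined selection; returning empty partition")
    return(gene_partition(character(), character()))
  }
  hr <- fits$hr[match(selected, fits$gene_id)]
  gene_partition(selected[hr > 1], selected[hr <= 1])
}

#' Construct a hazard-ratio gene partition
#'
#' @param genes_hr_gt1 risk genes (HR > 1).
#' @param genes_hr_lt1 protective genes (HR < 1).
#' @return A list of class `GenePartition`.
#' @export
gene_partition <- function(genes_hr_gt1, genes_hr_lt1) {
  genes_hr_gt1 <- unique(as.character(genes_hr_gt1))
  genes_hr_lt1 <- unique(as.character(genes_hr_lt1))
  if (length(intersect(genes_hr_gt1, genes_hr_lt1)))
    stop("partition sets must be disjoint")
  structure(list(genes_hr_gt1 = genes_hr_gt1, genes_hr_lt1 = genes_hr_lt1),
            class = "GenePartition")
}

#' @export
print.GenePartition <- function(x, ...) {
  cat(sprintf("GenePartition: %d risk (HR>1), %d protective (HR<1) gene(s)\n",
              length(x$genes_hr_gt1), length(x$genes_hr_lt1)))
  invisible(x)
}
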