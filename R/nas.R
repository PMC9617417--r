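#' Published simplified NAS coefficients
#'
#' The five-gene linear model reported by the penalized Cox refit of the
#' full score on the merged discovery and validation cohorts. Used as the
#' default by [simplified_nas()].
#'
#' @format Named numeric vector of per-gene coefficients.
#' @export
simplified_nas_coefficients <- c(
  COL5A2 = 0.22864885, PVT1 = 0.1083532, CHI3L2 = 0.07381116,
  SERPINE1 = 0.03597545, SOCS3 = 0.02452755)

#' Prognostic screen of differentially expressed genes
#'
#' Univariate Cox on every DEG; genes with Wald p below `alpha` are kept and
#' partitioned into risk (HR > 1) and protective (HR < 1) sets — the two
#' sums of the NAS formula.
#'
#' @param degs a `DEGSet` (or character vector of gene ids).
#' @param expr an `ExpressionMatrix` aligned to `clinical`.
#' @param clinical clinical data.frame.
#' @param alpha significance threshold; must be positive.
#' @param log_transform log2(x + 1)-transform before the Cox fits.
#' @return A `GenePartition`, with the full Cox table attached as attribute
#'   `"coxfits"`.
#' @export
prognostic_degs <- function(degs, expr, clinical, alpha = 0.05,
                            log_transform = TRUE) {
  genes <- if (inherits(degs, "DEGSet")) degs$genes else as.character(degs)
  if (!length(genes)) stop("empty DEG set")
  if (alpha <= 0)
    stop("alpha must be positive; no gene can be selected at alpha = 0")
  fits <- unicox_screen(expr, clinical, genes = genes,
                        log_transform = log_transform)
  fits <- fits[fits$converged & !is.na(fits$p), , drop = FALSE]
  sig <- fits[fits$p < alpha, , drop = FALSE]
  if (!nrow(sig))
    stop("no DEG reaches Cox p < ", alpha,
         "; consider relaxing the DEG or alpha thresholds")
  part <- gene_partition(sig$gene_id[sig$hr > 1], sig$gene_id[sig$hr <= 1])
  attr(part, "coxfits") <- fits
  part
}

#' PC1/PC2 loading weights over the prognostic genes
#'
#' Principal components of the gene-z-scored log2(FPKM + 1) matrix over
#' samples (the gene-gene correlation structure). Each gene's weight is the
#' sum of its loadings on the first two components. Eigenvectors are
#' sign-ambiguous, so each component is oriented such that the sum of its
#' loadings over the risk genes minus the sum over the protective genes is
#' non-negative — this makes the NAS well defined and risk-increasing.
#'
#' @param expr `ExpressionMatrix` containing the partition genes.
#' @param partition a `GenePartition` (drives the orientation rule).
#' @param log_transform log2(x + 1)-transform non-log input before the PCA.
#' @return data.frame of class `PCAWeightTable`: `gene_id`, `loading_pc1`,
#'   `loading_pc2`, `w`, with attribute `"var_explained"` (length 2).
#' @export
pca_weights <- function(expr, partition, log_transform = TRUE) {
  genes <- c(partition$genes_hr_gt1, partition$genes_hr_lt1)
  genes <- intersect(genes, rownames(expr_values(expr)))
  if (length(genes) < 2) stop("need at least 2 partition genes for PCA")
  x <- if (log_transform) expr_log2(expr) else expr
  v <- expr_values(x)[genes, , drop = FALSE]
  if (ncol(v) < 3) stop("need at least 3 samples for PCA")
  sds <- apply(v, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d zero-variance gene(s) before PCA", sum(sds == 0)))
    v <- v[sds > 0, , drop = FALSE]
    genes <- rownames(v)
    if (length(genes) < 2) stop("fewer than 2 non-degenerate genes for PCA")
  }
  pc <- stats::prcomp(t(v), center = TRUE, scale. = TRUE)
  load1 <- pc$rotation[, 1]
  load2 <- if (ncol(pc$rotation) >= 2) pc$rotation[, 2] else
    stats::setNames(rep(0, length(genes)), genes)
  orient <- function(l) {
    s <- sum(l[intersect(genes, partition$genes_hr_gt1)]) -
      sum(l[intersect(genes, partition$genes_hr_lt1)])
    if (s < 0) -l else l
  }
  load1 <- orient(load1); load2 <- orient(load2)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  out <- data.frame(gene_id = genes, loading_pc1 = unname(load1[genes]),
                    loading_pc2 = unname(load2[genes]),
                    w = unname(load1[genes] + load2[genes]),
                    stringsAsFactors = FALSE)
  attr(out, "var_explained") <- c(pc1 = ve[1],
                                  pc2 = if (length(ve) >= 2) ve[2] else 0)
  class(out) <- c("PCAWeightTable", "data.frame")
  out
}

#' Compute the neoantigen activation score
#'
#' The per-sample score is
#' `NAS_s = k * sum_{g in HR>1} x_gs * w_g  -  k * sum_{g in HR<1} x_gs * w_g`
#' where `x` is FPKM-scale expression, `w_g` the summed PC1+PC2 loading of
#' gene `g`, and `k` a fixed scaling constant (published value 1e-4).
#' Partition genes absent from the matrix are excluded with a warning and
#' the coverage fraction is reported.
#'
#' @param expr `ExpressionMatrix` on the FPKM (linear) scale.
#' @param weights a `PCAWeightTable` covering the partition genes.
#' @param partition a `GenePartition`.
#' @param k_const the scaling constant k.
#' @return A list of class `NASVector`: `nas` (named numeric), `k_const`,
#'   `coverage`.
#' @export
compute_nas <- function(expr, weights, partition, k_const = 1e-4) {
  v <- expr_values(expr)
  wmap <- stats::setNames(weights$w, weights$gene_id)
  use_set <- function(genes) {
    present <- intersect(genes, rownames(v))
    present <- intersect(present, names(wmap))
    present
  }
  gt1 <- use_set(partition$genes_hr_gt1)
  lt1 <- use_set(partition$genes_hr_lt1)
  wanted <- length(partition$genes_hr_gt1) + length(partition$genes_hr_lt1)
  got <- length(gt1) + length(lt1)
  if (got < wanted)
    warning(sprintf("%d partition gene(s) missing from expression or weights",
                    wanted - got))
  if (got == 0) stop("no partition genes available for scoring")
  message(sprintf("NAS coverage: %d/%d partition genes", got, wanted))
  term <- function(genes) {
    if (!length(genes)) return(rep(0, ncol(v)))
    colSums(v[genes, , drop = FALSE] * wmap[genes])
  }
  nas <- k_const * term(gt1) - k_const * term(lt1)
  names(nas) <- colnames(v)
  structure(list(nas = nas, k_const = k_const, coverage = got / wanted),
            class = "NASVector")
}

#' @export
print.NASVector <- function(x, ...) {
  cat(sprintf("NASVector: %d samples, range [%.4g, %.4g], k = %g\n",
              length(x$nas), min(x$nas), max(x$nas), x$k_const))
  invisible(x)
}

#' Split samples into high and low score groups
#'
#' Default rule: high when the score exceeds the median, low otherwise (the
#' median element itself goes to the low group on odd n).
#'
#' @param nas a `NASVector` or named numeric vector of scores.
#' @param rule currently `"median"`.
#' @return A list: `group` (named factor, levels low/high), `cutpoint`,
#'   `rule`.
#' @export
split_groups <- function(nas, rule = c("median")) {
  rule <- match.arg(rule)
  x <- if (inherits(nas, "NASVector")) nas$nas else nas
  if (length(x) < 2) stop("need at least 2 samples to split")
  if (length(unique(x)) == 1) stop("all scores identical; cannot split")
  cut <- stats::median(x)
  group <- factor(ifelse(x > cut, "high", "low"), levels = c("low", "high"))
  names(group) <- names(x)
  list(group = group, cutpoint = cut, rule = rule)
}

#' Simplified five-gene NAS
#'
#' Linear score `sum_g coef_g * x_gs` with the published coefficients as the
#' default model. Model genes missing from the matrix contribute 0, with a
#' warning.
#'
#' @param expr `ExpressionMatrix` (FPKM scale in the published model).
#' @param coefficients named numeric vector of per-gene coefficients.
#' @return Named numeric vector of per-sample scores.
#' @export
simplified_nas <- function(expr, coefficients = simplified_nas_coefficients) {
  stopifnot(length(coefficients) > 0, !is.null(names(coefficients)))
  v <- expr_values(expr)
  present <- intersect(names(coefficients), rownames(v))
  if (length(present) < length(coefficients))
    warning(sprintf("%d model gene(s) absent from expression; contributing 0",
                    length(coefficients) - length(present)))
  if (!length(present)) return(stats::setNames(rep(0, ncol(v)), colnames(v)))
  colSums(v[present, , drop = FALSE] * coefficients[present])
}
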