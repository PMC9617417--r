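#' Shared log2 fold change between two groups
#'
#' One fold-change definition is used by all three engines:
#' log2((mean2 + pc) / (mean1 + pc)) of the linear-scale group means
#' (group 2 vs group 1). Swapping the groups negates the value.
#'
#' @param expr `ExpressionMatrix` on a linear scale (counts or fpkm), or a
#'   plain genes-by-samples matrix.
#' @param labels vector of group labels in \{1, 2\}, one per sample.
#' @param pseudocount added to both means before the ratio.
#' @return Named numeric vector of per-gene log2 fold changes.
#' @export
shared_log2fc <- function(expr, labels, pseudocount = 1) {
  v <- if (inherits(expr, "ExpressionMatrix")) expr_values(expr) else expr
  stopifnot(ncol(v) == length(labels), all(labels %in% c(1, 2)))
  if (sum(labels == 1) < 2 || sum(labels == 2) < 2)
    stop("each group needs at least 2 samples")
  m1 <- rowMeans(v[, labels == 1, drop = FALSE])
  m2 <- rowMeans(v[, labels == 2, drop = FALSE])
  log2((m2 + pseudocount) / (m1 + pseudocount))
}

#' Moderated two-sample t-test engine
#'
#' Gene-wise pooled variances are shrunk toward the mean variance of all
#' genes with a fixed prior weight of `d0` pseudo-degrees of freedom; the t
#' statistic uses the shrunk variance and p-values come from a t
#' distribution with `d0` extra degrees of freedom. When every gene has the
#' same pooled variance the statistic reduces to the classical t.
#'
#' @param log_expr `ExpressionMatrix` on the lognorm scale (or a matrix of
#'   log2 expression).
#' @param labels group labels in \{1, 2\}.
#' @param d0 prior degrees of freedom for the variance shrinkage.
#' @param lfc optional shared log2 fold changes to attach (defaults to the
#'   difference of log-scale group means converted through
#'   [shared_log2fc()] being supplied by the caller; if NULL the log-mean
#'   difference is used).
#' @return data.frame: `gene_id`, `log2fc`, `p`, `fdr`, `engine`.
#' @export
de_mod_t <- function(log_expr, labels, d0 = 4, lfc = NULL) {
  v <- if (inherits(log_expr, "ExpressionMatrix")) {
    stopifnot(expr_scale(log_expr) == "lognorm")
    expr_values(log_expr)
  } else log_expr
  stopifnot(ncol(v) == length(labels), all(labels %in% c(1, 2)))
  n1 <- sum(labels == 1); n2 <- sum(labels == 2)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  x1 <- v[, labels == 1, drop = FALSE]
  x2 <- v[, labels == 2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2); ss2 <- rowSums((x2 - m2)^2)
  df <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / df
  s0_sq <- mean(s2)
  s2_post <- (d0 * s0_sq + df * s2) / (d0 + df)
  tstat <- (m2 - m1) / sqrt(s2_post * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tstat), df = df + d0)
  if (is.null(lfc)) lfc <- m2 - m1
  data.frame(gene_id = rownames(v), log2fc = unname(lfc[rownames(v)]),
             p = unname(p), fdr = bh_adjust(unname(p)), engine = "mod_t",
             stringsAsFactors = FALSE)
}

#' Rank-sum (Mann-Whitney) engine
#'
#' Per-gene two-sided Wilcoxon rank-sum test via `stats::wilcox.test` (exact
#' for small tie-free samples, normal approximation otherwise). Constant
#' genes get p = 1 with a warning. The statistic is invariant to monotone
#' transforms, so any expression scale may be supplied.
#'
#' @param expr `ExpressionMatrix` or matrix.
#' @param labels group labels in \{1, 2\}.
#' @param lfc optional shared log2 fold changes to attach.
#' @return data.frame: `gene_id`, `log2fc`, `p`, `fdr`, `engine`.
#' @export
de_rank_sum <- function(expr, labels, lfc = NULL) {
  v <- if (inherits(expr, "ExpressionMatrix")) expr_values(expr) else expr
  stopifnot(ncol(v) == length(labels), all(labels %in% c(1, 2)))
  if (sum(labels == 1) < 2 || sum(labels == 2) < 2)
    stop("each group needs at least 2 samples")
  const <- apply(v, 1, function(x) length(unique(x)) == 1)
  if (any(const))
    warning(sprintf("%d constant gene(s) assigned p = 1", sum(const)))
  p <- vapply(seq_len(nrow(v)), function(i) {
    if (const[i]) return(1)
    suppressWarnings(
      stats::wilcox.test(v[i, labels == 2], v[i, labels == 1])$p.value)
  }, numeric(1))
  if (is.null(lfc)) lfc <- stats::setNames(rep(NA_real_, nrow(v)), rownames(v))
  data.frame(gene_id = rownames(v), log2fc = unname(lfc[rownames(v)]),
             p = p, fdr = bh_adjust(p), engine = "rank_sum",
             stringsAsFactors = FALSE)
}

#' Negative-binomial exact-test engine
#'
#' Counts are normalized by median-of-ratios size factors, a common
#' dispersion is estimated by the method of moments, and each gene is tested
#' with a conditional exact test: given the total of the two group sums, the
#' two-sided p-value sums the probabilities of all splits as or less likely
#' than the observed one under group-wise negative-binomial sums with equal
#' means. As dispersion approaches zero the test converges to the Poisson
#' (binomial-conditional) exact test. All-zero genes are skipped.
#'
#' @param counts `ExpressionMatrix` on the counts scale (or integer matrix).
#' @param labels group labels in \{1, 2\}.
#' @param dispersion optional fixed dispersion; when NULL it is estimated by
#'   the method of moments across genes.
#' @param lfc optional shared log2 fold changes to attach.
#' @return data.frame: `gene_id`, `log2fc`, `p`, `fdr`, `engine` (skipped
#'   genes are absent).
#' @export
de_nb_exact <- function(counts, labels, dispersion = NULL, lfc = NULL) {
  v <- if (inherits(counts, "ExpressionMatrix")) {
    stopifnot(expr_scale(counts) == "counts")
    expr_values(counts)
  } else counts
  stopifnot(ncol(v) == length(labels), all(labels %in% c(1, 2)))
  n1 <- sum(labels == 1); n2 <- sum(labels == 2)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  nonzero <- rowSums(v) > 0
  v <- v[nonzero, , drop = FALSE]
  sf <- median_of_ratios(v)
  norm <- sweep(v, 2, sf, "/")
  if (is.null(dispersion)) dispersion <- mom_common_dispersion(norm)
  # pseudo-counts at a common library size, rounded back to integers
  pseudo <- round(norm)
  y1 <- rowSums(pseudo[, labels == 1, drop = FALSE])
  y2 <- rowSums(pseudo[, labels == 2, drop = FALSE])
  p <- vapply(seq_len(nrow(pseudo)), function(i)
    nb_exact_p(y1[i], y2[i], n1, n2, dispersion), numeric(1))
  if (is.null(lfc)) lfc <- stats::setNames(rep(NA_real_, nrow(v)), rownames(v))
  data.frame(gene_id = rownames(v), log2fc = unname(lfc[rownames(v)]),
             p = p, fdr = bh_adjust(p), engine = "nb_exact",
             stringsAsFactors = FALSE)
}

# median-of-ratios size factors (reference = geometric mean over samples,
# computed on genes positive in every sample)
median_of_ratios <- function(v) {
  allpos <- rowSums(v > 0) == ncol(v)
  if (!any(allpos)) return(colSums(v) / mean(colSums(v)))
  lg <- log(v[allpos, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- apply(lg, 2, function(col) exp(stats::median(col - ref)))
  sf / exp(mean(log(sf)))
}

# method-of-moments common dispersion on normalized counts:
# var = mu + phi mu^2  =>  phi_g = (s2 - mu)/mu^2, pooled by median
mom_common_dispersion <- function(norm) {
  mu <- rowMeans(norm)
  s2 <- apply(norm, 1, stats::var)
  ok <- mu > 1
  if (!any(ok)) return(0.01)
  phi <- (s2[ok] - mu[ok]) / mu[ok]^2
  max(stats::median(phi), 1e-8)
}

# two-sided conditional exact NB test on group sums y1, y2 (equal effective
# library sizes); sums the probabilities of splits no more likely than
# observed, restricted to a negligible-mass-truncated support
nb_exact_p <- function(y1, y2, n1, n2, phi) {
  tot <- y1 + y2
  if (tot == 0) return(1)
  mu_hat <- tot / (n1 + n2)
  size1 <- n1 / phi; size2 <- n2 / phi
  lo <- stats::qnbinom(1e-13, size = size1, mu = n1 * mu_hat)
  hi <- stats::qnbinom(1 - 1e-13, size = size1, mu = n1 * mu_hat)
  a <- max(0, min(lo, y1)):min(tot, max(hi, y1))
  logp <- stats::dnbinom(a, size = size1, mu = n1 * mu_hat, log = TRUE) +
    stats::dnbinom(tot - a, size = size2, mu = n2 * mu_hat, log = TRUE)
  pr <- exp(logp - max(logp))
  obs <- pr[match(y1, a)]
  min(1, sum(pr[pr <= obs * (1 + 1e-8)]) / sum(pr))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' `stats::p.adjust(method = "BH")`): monotone, capped at 1, never below the
#' raw p-value.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted values of the same length.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Intersect differential-expression calls across engines
#'
#' A gene is a DEG when it passes FDR < `fdr_max` and |log2FC| > `lfc_min`
#' in every supplied engine. When that intersection is empty the rule falls
#' back to a single designated engine at the relaxed |log2FC| > `fallback_lfc`
#' (published thresholds: 1 and 0.4), and the applied rule is recorded.
#'
#' @param records named list of engine data.frames (from [de_mod_t()],
#'   [de_rank_sum()], [de_nb_exact()]); each must carry `log2fc` (attach the
#'   shared definition via the `lfc` argument of the engines).
#' @param fdr_max,lfc_min primary thresholds.
#' @param fallback_lfc relaxed fold-change threshold for the fallback.
#' @param fallback_engine name of the engine used by the fallback (default
#'   the count-based engine when present, else the first).
#' @return A list of class `DEGSet`: `genes`, `rule_used`
#'   (`"intersection"` or `"fallback_single"`), `thresholds`.
#' @export
intersect_degs <- function(records, fdr_max = 0.05, lfc_min = 1,
                           fallback_lfc = 0.4, fallback_engine = NULL) {
  if (!length(records)) stop("no differential-expression engines supplied")
  pass <- lapply(records, function(df)
    df$gene_id[df$fdr < fdr_max & !is.na(df$log2fc) & abs(df$log2fc) > lfc_min])
  genes <- Reduce(intersect, pass)
  if (length(genes)) {
    return(structure(list(genes = genes, rule_used = "intersection",
                          thresholds = c(fdr_max = fdr_max, lfc_min = lfc_min)),
                     class = "DEGSet"))
  }
  if (is.null(fallback_engine))
    fallback_engine <- if ("nb_exact" %in% names(records)) "nb_exact"
      else names(records)[1]
  if (!fallback_engine %in% names(records))
    stop("fallback engine '", fallback_engine, "' not among supplied records")
  df <- records[[fallback_engine]]
  genes <- df$gene_id[df$fdr < fdr_max & !is.na(df$log2fc) &
                        abs(df$log2fc) > fallback_lfc]
  structure(list(genes = genes, rule_used = "fallback_single",
                 fallback_engine = fallback_engine,
                 thresholds = c(fdr_max = fdr_max, lfc_min = fallback_lfc)),
            class = "DEGSet")
}

#' @export
print.DEGSet <- function(x, ...) {
  cat(sprintf("DEGSet: %d gene(s), rule = %s\n", length(x$genes), x$rule_used))
  invisible(x)
}

#' Run all available engines and intersect
#'
#' Convenience wrapper: computes the shared fold change on the linear scale,
#' runs the moderated-t engine on log2(x + 1), the rank-sum engine on the
#' linear scale, and — when counts are available — the NB exact engine, then
#' applies [intersect_degs()]. When counts are absent the intersection runs
#' over the remaining two engines and the degradation is recorded in the
#' result's `engines` field.
#'
#' @param fpkm `ExpressionMatrix` (fpkm scale).
#' @param labels group labels in \{1, 2\}.
#' @param counts optional `ExpressionMatrix` (counts scale).
#' @param fdr_max,lfc_min,fallback_lfc thresholds (see [intersect_degs()]).
#' @return A `DEGSet` with extra fields `engines` (names used) and
#'   `records` (per-engine tables).
#' @export
run_deg <- function(fpkm, labels, counts = NULL, fdr_max = 0.05,
                    lfc_min = 1, fallback_lfc = 0.4) {
  lfc <- shared_log2fc(fpkm, labels)
  records <- list(
    mod_t = de_mod_t(expr_log2(fpkm), labels, lfc = lfc),
    rank_sum = de_rank_sum(fpkm, labels, lfc = lfc))
  if (!is.null(counts))
    records$nb_exact <- de_nb_exact(counts, labels,
                                    lfc = shared_log2fc(counts, labels))
  degs <- intersect_degs(records, fdr_max = fdr_max, lfc_min = lfc_min,
                         fallback_lfc = fallback_lfc)
  degs$engines <- names(records)
  degs$records <- records
  degs
}
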