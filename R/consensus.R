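#' Resampling-based consensus k-means
#'
#' Repeatedly subsamples `ceiling(p_item * n)` samples without replacement,
#' runs euclidean k-means on each subsample, and records for every sample
#' pair how often it co-clusters relative to how often it was co-sampled
#' (the consensus). Final labels come from average-linkage hierarchical
#' clustering of 1 - consensus cut at `k`, which is deterministic given the
#' consensus matrix. Genes are z-scored first by default so high-abundance
#' genes do not dominate the euclidean metric.
#'
#' @param expr an `ExpressionMatrix` restricted to the signature genes, or a
#'   plain genes-by-samples numeric matrix.
#' @param k number of clusters.
#' @param reps number of resampling iterations.
#' @param p_item fraction of samples drawn per iteration.
#' @param seed integer seed; fixed seed gives an identical consensus matrix.
#' @param scale_genes z-score each gene before clustering.
#' @param schedule optional list of integer sample-index vectors overriding
#'   the random subsampling (one element per iteration; used for exact
#'   small-case verification).
#' @return A list of class `ConsensusModel`: `k`, `consensus` (symmetric
#'   sample-by-sample matrix in \[0, 1\]), `co_sampled` (pair sampling
#'   counts), `labels` (named integer vector), `cluster_consensus` (mean
#'   within-cluster consensus per cluster).
#' @export
run_consensus <- function(expr, k, reps = 250, p_item = 0.8, seed = 1L,
                          scale_genes = TRUE, schedule = NULL) {
  v <- if (inherits(expr, "ExpressionMatrix")) expr_values(expr) else expr
  stopifnot(is.matrix(v), is.numeric(v))
  n <- ncol(v)
  if (k > n) stop("k exceeds the number of samples")
  if (n < k + 1) stop("need at least k + 1 samples")
  if (scale_genes) {
    sds <- apply(v, 1, stats::sd)
    keep <- sds > 0
    v <- (v[keep, , drop = FALSE] - rowMeans(v[keep, , drop = FALSE])) /
      sds[keep]
  }
  if (is.null(schedule)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    m <- max(ceiling(p_item * n), k + 1)
    schedule <- lapply(seq_len(reps), function(i) sort(sample.int(n, m)))
  }
  co_cluster <- matrix(0, n, n)
  co_sampled <- matrix(0, n, n)
  for (idx in schedule) {
    sub <- t(v[, idx, drop = FALSE])
    km <- stats::kmeans(sub, centers = k, nstart = 3, iter.max = 25)
    sel <- rep(0, n); sel[idx] <- 1
    co_sampled <- co_sampled + outer(sel, sel)
    for (cl in seq_len(k)) {
      mem <- rep(0, n); mem[idx[km$cluster == cl]] <- 1
      co_cluster <- co_cluster + outer(mem, mem)
    }
  }
  consensus <- ifelse(co_sampled > 0, co_cluster / co_sampled, 0)
  diag(consensus)[diag(co_sampled) > 0] <- 1
  dimnames(consensus) <- list(colnames(v), colnames(v))
  hc <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
  labels <- stats::cutree(hc, k = k)
  names(labels) <- colnames(v)
  cluster_consensus <- vapply(seq_len(k), function(cl) {
    members <- which(labels == cl)
    if (length(members) < 2) return(1)
    sub <- consensus[members, members]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  structure(list(k = as.integer(k), consensus = consensus,
                 co_sampled = co_sampled, labels = labels,
                 cluster_consensus = cluster_consensus),
            class = "ConsensusModel")
}

#' @export
print.ConsensusModel <- function(x, ...) {
  cat(sprintf("ConsensusModel: k = %d, min cluster-consensus = %.3f\n",
              x$k, min(x$cluster_consensus)))
  invisible(x)
}

#' Run consensus clustering over a range of k
#'
#' @inheritParams run_consensus
#' @param k_range integer vector of candidate k (the published grid is 2..9).
#' @return A named list of `ConsensusModel`s, names `"k2"`, `"k3"`, ...
#' @export
consensus_sweep <- function(expr, k_range = 2:9, reps = 250, p_item = 0.8,
                            seed = 1L, scale_genes = TRUE) {
  models <- lapply(k_range, function(k)
    run_consensus(expr, k, reps = reps, p_item = p_item, seed = seed + k,
                  scale_genes = scale_genes))
  names(models) <- paste0("k", k_range)
  models
}

#' Choose k by cluster-consensus
#'
#' Returns the k whose model maximizes the minimum per-cluster consensus
#' (the most reliable clustering); ties break toward smaller k.
#'
#' @param models list of `ConsensusModel`s (e.g. from [consensus_sweep()]).
#' @return The chosen integer k.
#' @export
choose_k <- function(models) {
  if (length(models) < 2) stop("need at least 2 models to choose k")
  ks <- vapply(models, function(m) m$k, integer(1))
  score <- vapply(models, function(m) min(m$cluster_consensus), numeric(1))
  ord <- order(ks)
  ks <- ks[ord]; score <- score[ord]
  unname(ks[which.max(score)])  # which.max takes the first (smallest k) on ties
}

#' Orient two cluster labels so cluster 2 is the aggressive cluster
#'
#' Relabels a two-cluster assignment so that cluster 2 is the cluster with
#' the higher mean expression of the risk (HR > 1) genes. Idempotent: an
#' already-oriented labelling is returned unchanged, and swapping the input
#' labels yields the same output.
#'
#' @param labels named integer vector in \{1, 2\}.
#' @param expr `ExpressionMatrix` containing the partition genes.
#' @param partition a `GenePartition`; if its risk set is empty the labels
#'   are returned unchanged with a warning.
#' @return Relabelled named integer vector.
#' @export
orient_clusters <- function(labels, expr, partition) {
  stopifnot(length(unique(labels)) == 2)
  risk <- intersect(partition$genes_hr_gt1, rownames(expr_values(expr)))
  if (!length(risk)) {
    warning("empty risk gene set; labels returned unchanged")
    return(labels)
  }
  v <- expr_values(expr)[risk, names(labels), drop = FALSE]
  m1 <- mean(v[, labels == 1, drop = FALSE])
  m2 <- mean(v[, labels == 2, drop = FALSE])
  if (m1 == m2) {
    warning("risk-gene means equal between clusters; labels kept")
    return(labels)
  }
  if (m1 > m2) labels <- stats::setNames(3L - labels, names(labels))
  labels
}
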