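#' Construct an expression matrix
#'
#' Thin validated container for a gene-by-sample expression matrix with a
#' declared value scale. The scale travels with the object so downstream
#' stages can refuse, or transform, inputs on the wrong scale (the NAS sum
#' consumes FPKM; correlation and Cox screens work on log2(x + 1) by
#' default).
#'
#' @param values numeric matrix, genes in rows, samples in columns; rownames
#'   and colnames are required and must be unique; all values finite and >= 0.
#' @param scale one of `"counts"`, `"fpkm"`, `"lognorm"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `scale`.
#' @export
expression_matrix <- function(values, scale = c("counts", "fpkm", "lognorm")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers in expression matrix")
  if (any(!is.finite(values)))
    stop("expression values must all be finite")
  if (any(values < 0))
    stop("expression values must be non-negative")
  structure(list(values = values, scale = scale), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples, scale = %s\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @rdname expression_matrix
#' @param x an `ExpressionMatrix`.
#' @export
expr_values <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  x$values
}

#' @rdname expression_matrix
#' @export
expr_scale <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  x$scale
}

#' Subset an ExpressionMatrix by genes and/or samples
#'
#' @param x an `ExpressionMatrix`.
#' @param genes,samples character vectors of identifiers (or NULL to keep all).
#' @return An `ExpressionMatrix` restricted to the requested rows/columns.
#' @export
expr_subset <- function(x, genes = NULL, samples = NULL) {
  v <- expr_values(x)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing))
      stop("genes not present in expression matrix: ",
           paste(utils::head(missing, 5), collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(v))
    if (length(missing))
      stop("samples not present in expression matrix: ",
           paste(utils::head(missing, 5), collapse = ", "))
    v <- v[, samples, drop = FALSE]
  }
  expression_matrix(v, expr_scale(x))
}

#' Convert expression to log2(x + 1)
#'
#' @param x an `ExpressionMatrix` on the counts or fpkm scale (lognorm input
#'   is returned unchanged).
#' @return An `ExpressionMatrix` on the `lognorm` scale.
#' @export
expr_log2 <- function(x) {
  if (expr_scale(x) == "lognorm") return(x)
  expression_matrix(log2(expr_values(x) + 1), "lognorm")
}

#' Read a gene-by-sample expression TSV
#'
#' The canonical interchange format is tab-separated UTF-8 with '.' decimals:
#' a header row of sample identifiers and gene identifiers in the first
#' column. Duplicate gene rows are collapsed by the per-sample maximum, with
#' a warning naming the genes involved.
#'
#' @param path path to the TSV file.
#' @param scale declared value scale of the file (`"counts"`, `"fpkm"`,
#'   `"lognorm"`).
#' @return An `ExpressionMatrix`.
#' @export
read_expression <- function(path, scale = c("counts", "fpkm", "lognorm")) {
  scale <- match.arg(scale)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(raw) < 2) stop("expression TSV needs a gene column and >= 1 sample")
  gene_ids <- raw[[1]]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells),
                                  dimnames = dimnames(cells)))
  if (any(is.na(vals))) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("malformed numeric cell at gene '%s', sample '%s' in %s",
                 gene_ids[bad[1]], colnames(cells)[bad[2]], path))
  }
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative expression value at gene '%s', sample '%s'",
                 gene_ids[bad[1]], colnames(vals)[bad[2]]))
  }
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    warning(sprintf("collapsing %d duplicated gene id(s) by per-sample max: %s",
                    length(dup), paste(utils::head(dup, 5), collapse = ", ")))
    vals <- do.call(rbind, lapply(split(seq_along(gene_ids), gene_ids), function(i)
      apply(vals[i, , drop = FALSE], 2, max)))
    vals <- vals[unique(gene_ids), , drop = FALSE]
  } else {
    rownames(vals) <- gene_ids
  }
  expression_matrix(vals, scale)
}

#' Write an expression matrix as TSV
#'
#' @param x an `ExpressionMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  v <- expr_values(x)
  df <- data.frame(gene_id = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample clinical table
#'
#' Requires columns `sample_id`, `os_days` (overall survival in days) and
#' `os_event` (1 = death observed, 0 = censored). Optional columns `grade`
#' and `cohort` are retained. Rows with non-positive follow-up are excluded
#' with a message; an event indicator outside \{0, 1\} is an error.
#'
#' @param path path to the TSV file.
#' @return A `data.frame` with validated columns.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "")
  validate_clinical(df)
}

#' Validate an in-memory clinical table
#'
#' @param df a data.frame with `sample_id`, `os_days`, `os_event`.
#' @return The validated (possibly row-filtered) data.frame.
#' @export
validate_clinical <- function(df) {
  required <- c("sample_id", "os_days", "os_event")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("clinical table missing required column(s): ",
         paste(missing, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$os_days <- as.numeric(df$os_days)
  df$os_event <- as.numeric(df$os_event)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in clinical table")
  if (any(is.na(df$os_days)) || any(is.na(df$os_event)))
    stop("os_days/os_event contain non-numeric values")
  if (!all(df$os_event %in% c(0, 1)))
    stop("os_event must be 0 or 1")
  drop <- df$os_days <= 0
  if (any(drop)) {
    message(sprintf("excluding %d sample(s) with non-positive os_days", sum(drop)))
    df <- df[!drop, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Write a clinical table as TSV
#'
#' @param df clinical data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Columns: `gene_id`, `is_lncrna`, `mhc1_coding` (logical flags; the MHC-I
#' flag marks lncRNAs whose predicted peptides are presentable by MHC class
#' I), `regulator_class` in \{psi, m5C, m1A, none\} and `regulator_role` in
#' \{writer, reader, eraser, none\}. Class and role are `none` together.
#'
#' @param path path to the TSV file.
#' @return A validated `data.frame`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "")
  validate_annotation(df)
}

#' @rdname read_annotation
#' @param df an in-memory annotation data.frame.
#' @export
validate_annotation <- function(df) {
  required <- c("gene_id", "is_lncrna", "mhc1_coding", "regulator_class",
                "regulator_role")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("annotation missing required column(s): ", paste(missing, collapse = ", "))
  df$gene_id <- as.character(df$gene_id)
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in annotation")
  df$is_lncrna <- as.logical(df$is_lncrna)
  df$mhc1_coding <- as.logical(df$mhc1_coding)
  if (!all(df$regulator_class %in% c("psi", "m5C", "m1A", "none")))
    stop("regulator_class must be one of psi, m5C, m1A, none")
  if (!all(df$regulator_role %in% c("writer", "reader", "eraser", "none")))
    stop("regulator_role must be one of writer, reader, eraser, none")
  if (any((df$regulator_class == "none") != (df$regulator_role == "none")))
    stop("regulator_class is 'none' exactly when regulator_role is 'none'")
  if (any(df$mhc1_coding & !df$is_lncrna))
    stop("mhc1_coding genes must be flagged is_lncrna for selection purposes")
  rownames(df) <- NULL
  df
}

#' Write an annotation table as TSV
#'
#' @param df annotation data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict an expression matrix and clinical table to shared samples
#'
#' Both objects are restricted to the intersection of their sample
#' identifiers, in the same order; the intersection size is reported. An
#' empty intersection is an error.
#'
#' @param expr an `ExpressionMatrix`.
#' @param clinical a clinical data.frame.
#' @return A list with elements `expr` and `clinical`.
#' @export
align_cohort <- function(expr, clinical) {
  shared <- intersect(colnames(expr_values(expr)), clinical$sample_id)
  if (!length(shared))
    stop("no samples shared between expression matrix and clinical table")
  message(sprintf("aligned cohort on %d shared sample(s)", length(shared)))
  expr2 <- expr_subset(expr, samples = shared)
  clin2 <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  rownames(clin2) <- NULL
  list(expr = expr2, clinical = clin2)
}

#' Analysis configuration
#'
#' Collects every tunable threshold and constant of the pipeline with its
#' published or conventional default: the regulator-correlation screen
#' (|R| >= 0.4, p <= 0.001), the DEG rule (FDR < 0.05, |log2FC| > 1 with a
#' single-engine fallback at 0.4), the Cox significance level, the consensus
#' clustering grid (k in 2..9, 250 resamples at 80% of samples), the NAS
#' scaling constant k = 1e-4, and the label-transfer split (75% train,
#' 10-fold CV).
#'
#' @param r_min minimum |correlation| for the regulator screen.
#' @param p_corr_max maximum correlation p-value.
#' @param fdr_max maximum BH-adjusted p for differential expression.
#' @param lfc_min minimum |log2 fold change|.
#' @param lfc_fallback relaxed |log2FC| used by the single-engine fallback.
#' @param alpha significance level for univariate Cox screens.
#' @param k_range integer vector of candidate cluster numbers, within 2..9.
#' @param reps number of consensus resampling iterations.
#' @param p_item fraction of samples drawn per resample.
#' @param k_const NAS scaling constant.
#' @param split_fraction training fraction for label transfer.
#' @param cv_folds cross-validation folds for classifier tuning.
#' @param seed integer seed recorded in every derived artifact.
#' @return A list of class `nas_config`.
#' @export
nas_config <- function(r_min = 0.4, p_corr_max = 0.001, fdr_max = 0.05,
                       lfc_min = 1, lfc_fallback = 0.4, alpha = 0.05,
                       k_range = 2:9, reps = 250, p_item = 0.8,
                       k_const = 1e-4, split_fraction = 0.75, cv_folds = 10,
                       seed = 1L) {
  stopifnot(r_min > 0, r_min < 1, p_corr_max > 0, fdr_max > 0,
            lfc_min >= 0, lfc_fallback >= 0, alpha >= 0, alpha <= 1,
            all(k_range >= 2), all(k_range <= 9),
            reps >= 1, p_item > 0, p_item <= 1, k_const > 0,
            split_fraction > 0, split_fraction < 1, cv_folds >= 2)
  cfg <- list(r_min = r_min, p_corr_max = p_corr_max, fdr_max = fdr_max,
              lfc_min = lfc_min, lfc_fallback = lfc_fallback, alpha = alpha,
              k_range = as.integer(k_range), reps = as.integer(reps),
              p_item = p_item, k_const = k_const,
              split_fraction = split_fraction, cv_folds = as.integer(cv_folds),
              seed = as.integer(seed))
  class(cfg) <- "nas_config"
  cfg
}

#' Fingerprint of a configuration
#'
#' 32-bit polynomial rolling hash of the deparsed configuration, embedded in
#' pipeline outputs so every artifact records the exact settings that
#' produced it.
#'
#' @param config any R object (normally a `nas_config`).
#' @return An 8-character hexadecimal string.
#' @export
config_fingerprint <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
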