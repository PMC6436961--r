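# Expression matrices are genes x cells. Normalized matrices are on the
# log2 scale with a detection floor: normalized values below 1 are
# considered non-detected and set to 0 BEFORE the log, so 0 always means
# "not detected" and all stored values are >= 0. No pseudocount is used.

log2_floor <- function(x) {
  x[x < 1] <- 0
  ifelse(x > 0, log2(x), 0)
}

# back-transform to the linear scale consistent with the floor
linear_scale <- function(em) ifelse(em > 0, 2^em, 0)

#' RPKM normalization with detection floor
#'
#' Converts raw counts to reads per kilobase of exon model per million
#' mapped reads, treats genes with RPKM below 1 as non-detected (set to
#' 0), and log2-transforms the rest. Cells with a zero mapped-read total
#' are flagged and excluded.
#'
#' @param counts Genes x cells raw count matrix.
#' @param gene_lengths Named vector of union-exon gene lengths in bp.
#' @param mapped_totals Per-cell mapped-read totals; defaults to the
#'   column sums of `counts`.
#' @return Log2 expression matrix (attribute `normalization = "RPKM"`;
#'   excluded cells in attribute `excluded_cells`).
#' @export
rpkm_normalize <- function(counts, gene_lengths,
                           mapped_totals = colSums(counts)) {
  if (!all(rownames(counts) %in% names(gene_lengths)))
    stop("gene lengths missing for some genes")
  len <- gene_lengths[rownames(counts)]
  if (any(len <= 0)) stop("gene lengths must be positive")
  bad <- mapped_totals <= 0
  if (any(bad))
    warning(sprintf("excluding %d cell(s) with zero mapped reads",
                    sum(bad)))
  cm <- counts[, !bad, drop = FALSE]
  rpkm <- cm / (len / 1e3) /
    rep(mapped_totals[!bad] / 1e6, each = nrow(cm))
  em <- log2_floor(rpkm)
  structure(em, normalization = "RPKM",
            excluded_cells = colnames(counts)[bad])
}

#' Library-size normalization for 3'-counting data
#'
#' Divides each cell's counts by its total library size and multiplies by
#' a common target (by default the mean library size of all cells), so
#' pre-threshold per-cell sums equal the target exactly; then applies the
#' <1 detection floor and log2 transform.
#'
#' @param counts Genes x cells raw count matrix.
#' @param target Target library size; defaults to the mean of the
#'   per-cell totals.
#' @return Log2 expression matrix (attribute `normalization = "norm3p"`,
#'   attribute `target`).
#' @export
normalize_3p <- function(counts, target = NULL) {
  lib <- colSums(counts)
  bad <- lib <= 0
  if (any(bad))
    warning(sprintf("excluding %d cell(s) with zero library size",
                    sum(bad)))
  cm <- counts[, !bad, drop = FALSE]
  lib <- lib[!bad]
  if (is.null(target)) target <- mean(lib)
  scaled <- sweep(cm, 2, target / lib, `*`)
  em <- log2_floor(scaled)
  structure(em, normalization = "norm3p", target = target,
            excluded_cells = colnames(counts)[bad])
}

#' Per-cell quality-control filter
#'
#' Applies the dataset-appropriate per-cell filters with strict
#' inequalities. Full-length mode: percentage of reads in exons > 50,
#' percentage of mapped reads > 50, detected genes > `min_genes` (1500
#' for primary HSPCs; 5000-6000 for cell lines). 3'-counting mode:
#' library size > 2000 reads, mitochondrial read percentage < 10, ERCC
#' read percentage < 50, detected genes > 500. A missing metric fails
#' the cell with reason `metric_missing:<name>`.
#'
#' @param metrics `data.frame` with a `cell_id` column plus, per mode:
#'   full_length: `pct_exonic`, `pct_mapped`, `n_genes`; three_prime:
#'   `total_reads`, `pct_mito`, `pct_ercc`, `n_genes`.
#' @param mode `"full_length"` or `"three_prime"`.
#' @param min_genes Detected-gene floor (full-length mode; default 1500).
#' @param thresholds Optional named list overriding individual cutoffs
#'   (`pct_exonic`, `pct_mapped`, `min_reads`, `pct_mito`, `pct_ercc`,
#'   `min_genes`).
#' @return `data.frame(cell_id, pass, reasons)`.
#' @export
qc_filter <- function(metrics, mode = c("full_length", "three_prime"),
                      min_genes = NULL, thresholds = list()) {
  mode <- match.arg(mode)
  defaults <- if (mode == "full_length")
    list(pct_exonic = 50, pct_mapped = 50, min_genes = 1500)
  else
    list(min_reads = 2000, pct_mito = 10, pct_ercc = 50, min_genes = 500)
  if (!is.null(min_genes)) defaults$min_genes <- min_genes
  th <- utils::modifyList(defaults, thresholds)
  checks <- if (mode == "full_length") list(
    c("pct_exonic", "gt", "pct_exonic"),
    c("pct_mapped", "gt", "pct_mapped"),
    c("n_genes", "gt", "min_genes"))
  else list(
    c("total_reads", "gt", "min_reads"),
    c("pct_mito", "lt", "pct_mito"),
    c("pct_ercc", "lt", "pct_ercc"),
    c("n_genes", "gt", "min_genes"))
  out <- lapply(seq_len(nrow(metrics)), function(i) {
    reasons <- character(0)
    for (ck in checks) {
      metric <- ck[1]; op <- ck[2]; cut <- th[[ck[3]]]
      v <- if (metric %in% names(metrics)) metrics[[metric]][i] else NA
      if (is.na(v)) {
        reasons <- c(reasons, sprintf("metric_missing:%s", metric))
      } else if (op == "gt" && !(v > cut)) {
        reasons <- c(reasons, sprintf("%s<=%g", metric, cut))
      } else if (op == "lt" && !(v < cut)) {
        reasons <- c(reasons, sprintf("%s>=%g", metric, cut))
      }
    }
    data.frame(cell_id = metrics$cell_id[i], pass = !length(reasons),
               reasons = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-gene dropout frequency
#'
#' Fraction of cells in which each gene of a bulk-expressed reference set
#' is not detected (post-threshold value 0).
#'
#' @param em Log2 expression matrix.
#' @param bulk_expressed Genes known expressed in matched bulk samples.
#' @return Named vector of dropout fractions.
#' @export
dropout_frequency <- function(em, bulk_expressed) {
  if (!length(bulk_expressed)) stop("bulk_expressed must be non-empty")
  missing_g <- setdiff(bulk_expressed, rownames(em))
  if (length(missing_g))
    stop(sprintf("genes absent from matrix: %s",
                 paste(utils::head(missing_g, 3), collapse = ", ")))
  rowMeans(em[bulk_expressed, , drop = FALSE] == 0)
}

#' Library amplification bias
#'
#' Per cell: the ratio between the mean linear-scale expression of the
#' top 10% expressed genes in that library and the mean over all genes.
#' The top-gene count is `ceiling(0.10 * detected genes)`; ties are
#' broken by descending value, then input order.
#'
#' @param em Expression matrix; log2 scale by default, or linear-scale
#'   (e.g. raw RPKM) with `scale = "linear"`.
#' @param scale Scale of `em`.
#' @return Named vector of per-cell bias ratios.
#' @export
library_bias <- function(em, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  lin <- if (scale == "log2") linear_scale(em) else em
  apply(lin, 2, function(v) {
    det <- which(v > 0)
    if (length(det) < 10L) stop("library bias needs >= 10 detected genes")
    k <- ceiling(0.10 * length(det))
    top <- det[order(-v[det])[seq_len(k)]]
    mean(v[top]) / mean(v)
  })
}

#' Select highly variable genes above the mean-CV trend
#'
#' Computes per-gene coefficient of variation (sd/mean on linear-scale
#' values across cells), fits a lowess trend of CV against log2(mean),
#' and selects genes whose CV exceeds the fitted trend and whose
#' log2(mean) is at least 0.
#'
#' @param em Log2 expression matrix.
#' @param span Lowess span (default 0.3).
#' @param iter Lowess robustifying iterations (default 3).
#' @param min_log2_mean Mean-expression floor on the log2 scale.
#' @return `hvg_fit` data.frame: gene, mean, log2_mean, cv, cv_fit,
#'   selected.
#' @export
highly_variable_genes <- function(em, span = 0.3, iter = 3L,
                                  min_log2_mean = 0) {
  lin <- linear_scale(em)
  mu <- rowMeans(lin)
  keep <- mu > 0
  if (sum(keep) < 50L) stop("need >= 50 genes with positive mean")
  sdv <- apply(lin[keep, , drop = FALSE], 1, stats::sd)
  cv <- sdv / mu[keep]
  lmu <- log2(mu[keep])
  if (length(unique(lmu)) < 2L || stats::var(cv) == 0) {
    cv_fit <- rep(mean(cv), length(cv))   # flat trend for degenerate input
  } else {
    fit <- stats::lowess(lmu, cv, f = span, iter = iter)
    cv_fit <- stats::approx(fit$x, fit$y, xout = lmu, rule = 2,
                            ties = mean)$y
  }
  res <- data.frame(gene = rownames(em)[keep], mean = mu[keep],
                    log2_mean = lmu, cv = cv, cv_fit = cv_fit,
                    selected = cv > cv_fit & lmu >= min_log2_mean,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("hvg_fit", "data.frame")
  res
}

#' Allelic dropout estimated from known heterozygous sites
#'
#' At sites known to be heterozygous, a cell-site observation with
#' coverage of at least `min_cov` informative reads is biallelic when
#' 0.05 < AF < 0.95 and monoallelic otherwise; the per-site ADO rate is
#' the monoallelic fraction among covered cells. Base-quality filtering
#' (minBQ 30) is applied upstream during allele counting.
#'
#' @param counts `data.frame` with columns `cell_id`, `site_id`,
#'   `n_ref`, `n_alt`.
#' @param min_cov Minimum informative coverage (default 10).
#' @param af_window Open AF interval called biallelic
#'   (default `c(0.05, 0.95)`).
#' @return `data.frame` per site: site_id, n_informative, n_monoallelic,
#'   ado_rate.
#' @export
ado_from_het_sites <- function(counts, min_cov = 10L,
                               af_window = c(0.05, 0.95)) {
  cov <- counts$n_ref + counts$n_alt
  keep <- cov >= min_cov
  af <- counts$n_alt[keep] / cov[keep]
  mono <- !(af > af_window[1] & af < af_window[2])
  site <- counts$site_id[keep]
  agg <- tapply(mono, site, function(x)
    c(n = length(x), mono = sum(x)))
  out <- do.call(rbind, agg)
  data.frame(site_id = rownames(out),
             n_informative = as.integer(out[, "n"]),
             n_monoallelic = as.integer(out[, "mono"]),
             ado_rate = out[, "mono"] / out[, "n"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cell-cycle phase scores
#'
#' Per-cell S-phase and G2M-phase scores: the mean log2 expression over
#' the genes of each phase set. Set members absent from the matrix are
#' ignored with a warning.
#'
#' @param em Log2 expression matrix.
#' @param s_genes,g2m_genes Phase gene sets.
#' @return `data.frame(cell_id, s_score, g2m_score)`.
#' @export
cell_cycle_scores <- function(em, s_genes, g2m_genes) {
  score <- function(set, label) {
    present <- intersect(set, rownames(em))
    if (!length(present))
      stop(sprintf("no %s genes present in the matrix", label))
    if (length(present) < length(set))
      warning(sprintf("%d %s gene(s) absent from the matrix; ignored",
                      length(set) - length(present), label))
    colMeans(em[present, , drop = FALSE])
  }
  data.frame(cell_id = colnames(em),
             s_score = score(s_genes, "S-phase"),
             g2m_score = score(g2m_genes, "G2M-phase"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Remove covariate effects by per-gene linear regression
#'
#' Fits, per gene, an ordinary-least-squares model of expression on the
#' supplied covariates (e.g. cell-cycle scores) and returns the
#' residuals plus the gene mean, so the mean of every gene is preserved
#' exactly (covariates are centered internally).
#'
#' @param em Log2 expression matrix.
#' @param covariates Cells x covariates numeric matrix or data.frame.
#' @return Corrected expression matrix of the same shape.
#' @export
regress_out <- function(em, covariates) {
  Z <- as.matrix(covariates)
  if (nrow(Z) != ncol(em))
    stop("covariates must have one row per cell")
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  X <- cbind(`(Intercept)` = 1, Zc)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient covariates; collinear column(s): %s",
                 paste(drop_cols, collapse = ", ")))
  }
  coefs <- qr.coef(qx, t(em))
  fitted <- X %*% coefs
  resid <- t(em) - fitted
  out <- t(resid + rep(coefs["(Intercept)", ], each = nrow(X)))
  dimnames(out) <- dimnames(em)
  attrs <- attributes(em)
  attr(out, "normalization") <- attrs$normalization
  out
}

#' Within-group cell-to-cell correlation distributions
#'
#' Filters genes to those expressed in at least `min_cells_expr` cells
#' (globally), then returns all pairwise Pearson correlations between
#' cells within each group. Distributions can be compared with a
#' Kolmogorov-Smirnov test via [compare_group_correlations()].
#'
#' @param em Log2 expression matrix.
#' @param groups Per-cell group labels.
#' @param min_cells_expr Gene-inclusion floor (default 5 cells).
#' @return Named list of correlation vectors, one per group, with the
#'   gene filter size in `attr(, "n_genes_used")`.
#' @export
group_correlations <- function(em, groups, min_cells_expr = 5L) {
  stopifnot(length(groups) == ncol(em))
  keep <- rowSums(em > 0) >= min_cells_expr
  sub <- em[keep, , drop = FALSE]
  out <- lapply(split(seq_along(groups), groups), function(idx) {
    if (length(idx) < 2L)
      stop("every group must contain at least two cells")
    cc <- stats::cor(sub[, idx, drop = FALSE])
    cc[lower.tri(cc)]
  })
  attr(out, "n_genes_used") <- sum(keep)
  out
}

#' @rdname group_correlations
#' @param gc Result of [group_correlations()].
#' @param a,b Names of the two groups to compare.
#' @export
compare_group_correlations <- function(gc, a, b) {
  suppressWarnings(stats::ks.test(gc[[a]], gc[[b]]))
}
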