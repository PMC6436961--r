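#' Gene inclusion filter for differential expression
#'
#' Keeps genes expressed (value > 0 after the detection threshold) in at
#' least `min_cells` cells. The default floor follows the analysis size:
#' 2 cells when fewer than 200 cells are analyzed, 5 cells otherwise.
#'
#' @param em Log2 expression matrix.
#' @param min_cells Expressing-cell floor; `NULL` selects the default.
#' @return Character vector of retained gene names.
#' @export
gene_inclusion_filter <- function(em, min_cells = NULL) {
  if (is.null(min_cells)) min_cells <- if (ncol(em) < 200L) 2L else 5L
  rownames(em)[rowSums(em > 0) >= min_cells]
}

#' Combine p values with Fisher's method
#'
#' X = -2 * sum(log p) is referred to the upper tail of a chi-square
#' distribution with 2k degrees of freedom. NA entries are dropped
#' (reducing k); p values are clipped below at 1e-300. With a single p
#' the method is the identity.
#'
#' @param pvals Numeric vector of p values in (0, 1].
#' @return Combined p value, or `NA` when no valid p remains.
#' @export
fishers_method <- function(pvals) {
  p <- pvals[!is.na(pvals)]
  if (!length(p)) return(NA_real_)
  if (any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  p <- pmax(p, 1e-300)
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment
#' (`stats::p.adjust(method = "BH")`).
#'
#' @param pvals Numeric vector of p values.
#' @return Adjusted p values in the input order.
#' @export
bh_adjust <- function(pvals) stats::p.adjust(pvals, method = "BH")

# Per-gene tests. Wilcoxon compares expression values (stats::wilcox.test:
# exact for small untied samples, normal approximation with tie and
# continuity correction otherwise); Fisher's exact compares the
# expressed / not-expressed frequencies. Either test is inapplicable when
# its input is degenerate (all values tied for Wilcoxon; no variation in
# expression status for Fisher), in which case the other p passes through
# with k = 1.
de_gene_tests <- function(a, b) {
  ea <- a > 0; eb <- b > 0
  p_w <- if (length(unique(c(a, b))) < 2L) NA_real_ else
    suppressWarnings(stats::wilcox.test(a, b)$p.value)
  n_exp <- sum(ea) + sum(eb)
  p_f <- if (n_exp == 0L || n_exp == length(a) + length(b)) NA_real_ else
    stats::fisher.test(matrix(c(sum(ea), length(a) - sum(ea),
                                sum(eb), length(b) - sum(eb)), 2))$p.value
  c(p_w = p_w, p_f = p_f)
}

#' Combined Wilcoxon / Fisher's-exact differential expression test
#'
#' For each gene, a two-sided Wilcoxon rank-sum test compares the
#' expression values of the two groups and a Fisher's exact test compares
#' their expressing-cell frequencies; the two p values are combined with
#' Fisher's method and adjusted across genes with the
#' Benjamini-Hochberg procedure. The log2 fold change is the difference
#' of group means on the log2 matrix (zeros included). A gene is
#' significant when the adjusted p is below 0.1 and |log2FC| exceeds
#' 0.5.
#'
#' @param em Log2 expression matrix.
#' @param cells_a,cells_b Column names or indices of the two groups
#'   (each at least 3 cells).
#' @param genes Genes to test; defaults to [gene_inclusion_filter()] on
#'   the two groups combined.
#' @param alpha Adjusted-p significance cutoff (default 0.1).
#' @param lfc_cutoff Absolute log2 fold-change cutoff (default 0.5).
#' @return `data.frame` per gene: freq_a, freq_b, log2fc, p_wilcoxon,
#'   p_fisher, p_combined, p_adj, significant.
#' @export
combined_de_test <- function(em, cells_a, cells_b, genes = NULL,
                             alpha = 0.1, lfc_cutoff = 0.5) {
  A <- em[, cells_a, drop = FALSE]
  B <- em[, cells_b, drop = FALSE]
  if (ncol(A) < 3L || ncol(B) < 3L)
    stop("both groups must contain at least 3 cells")
  if (is.null(genes))
    genes <- gene_inclusion_filter(cbind(A, B))
  if (!length(genes)) stop("no genes pass the inclusion filter")
  res <- t(vapply(genes, function(g) {
    a <- A[g, ]; b <- B[g, ]
    p <- de_gene_tests(a, b)
    c(freq_a = mean(a > 0), freq_b = mean(b > 0),
      log2fc = mean(a) - mean(b), p)
  }, numeric(5)))
  p_comb <- apply(res[, c("p_w", "p_f"), drop = FALSE], 1, fishers_method)
  p_comb[is.na(p_comb)] <- 1      # both tests degenerate: no evidence
  out <- data.frame(gene = genes, freq_a = res[, "freq_a"],
                    freq_b = res[, "freq_b"], log2fc = res[, "log2fc"],
                    p_wilcoxon = res[, "p_w"], p_fisher = res[, "p_f"],
                    p_combined = p_comb, stringsAsFactors = FALSE)
  out$p_adj <- bh_adjust(out$p_combined)
  out$significant <- out$p_adj < alpha & abs(out$log2fc) > lfc_cutoff
  rownames(out) <- NULL
  out
}

#' One-way ANOVA screen across genetic subclones
#'
#' Per gene, a one-way fixed-effects analysis of variance of log2
#' expression on subclone labels, computed vectorized across genes; a
#' gene is selected at p < 0.05. Constant genes have an undefined F and
#' are assigned p = 1 by convention.
#'
#' @param em Log2 expression matrix.
#' @param labels Per-cell subclone labels (>= 2 groups with >= 2 cells
#'   each).
#' @param alpha Selection cutoff (default 0.05).
#' @return `data.frame` per gene: F, p, selected.
#' @export
anova_subclones <- function(em, labels, alpha = 0.05) {
  labels <- as.factor(labels)
  k <- nlevels(labels)
  n <- ncol(em)
  sizes <- table(labels)
  if (k < 2L || sum(sizes >= 2L) < 2L)
    stop("need at least two subclones with at least two cells each")
  G <- stats::model.matrix(~ labels - 1)           # n x k indicator
  sums <- em %*% G
  means <- sweep(sums, 2, as.numeric(sizes), `/`)
  gmean <- rowMeans(em)
  ss_between <- as.vector(sweep(means, 1, gmean)^2 %*% as.numeric(sizes))
  ss_total <- rowSums((em - gmean)^2)
  ss_within <- pmax(ss_total - ss_between, 0)
  df1 <- k - 1L
  df2 <- n - k
  Fv <- (ss_between / df1) / (ss_within / df2)
  p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  constant <- ss_total < .Machine$double.eps * n
  Fv[constant] <- 0
  p[constant] <- 1
  data.frame(gene = rownames(em), F = Fv, p = p, selected = p < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a differential-expression table as TSV
#'
#' @param de Result of [combined_de_test()] or [anova_subclones()].
#' @param path File path.
#' @export
write_de_tsv <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
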