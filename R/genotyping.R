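#' Calibrate per-amplicon detection and mutation-calling thresholds
#'
#' Detection thresholds come from non-template (blank) controls and
#' mutation-calling thresholds from wild-type control cells, customized
#' per amplicon. The detection floor is twice the highest blank coverage
#' seen for the amplicon, never below the 30-read minimum; the minimum
#' mutant allele fraction is twice the highest alt AF seen in WT
#' controls, clamped to the 1.5%-4% range. The control statistics that
#' produced each threshold are kept alongside it so calibrations are
#' auditable and overridable.
#'
#' @param blank_counts Allele-count table for blank wells.
#' @param wt_counts Allele-count table for wild-type control cells.
#' @param panel An [amplicon_panel()].
#' @param min_coverage Minimum reads per amplicon for any mutational
#'   readout (default 30).
#' @param af_clamp Lower/upper clamp for the mutant-AF threshold
#'   (default `c(0.015, 0.04)`).
#' @return A `threshold_set` data.frame, one row per amplicon, with
#'   columns amplicon_id, min_coverage, detection_min_reads,
#'   mutation_af_min and the calibration provenance (max blank coverage,
#'   max WT alt AF, control counts).
#' @export
calibrate_thresholds <- function(blank_counts, wt_counts, panel,
                                 min_coverage = 30L,
                                 af_clamp = c(0.015, 0.04)) {
  out <- lapply(names(panel), function(aid) {
    b <- blank_counts[blank_counts$amplicon_id == aid, , drop = FALSE]
    w <- wt_counts[wt_counts$amplicon_id == aid, , drop = FALSE]
    if (nrow(b) == 0L && nrow(w) == 0L)
      stop(sprintf("amplicon '%s' absent from all controls", aid))
    n_blank <- length(unique(b$cell_id))
    n_wt <- length(unique(w$cell_id))
    if (n_blank < 10L || n_wt < 10L)
      warning(sprintf(
        "amplicon '%s': only %d blanks / %d WT controls; calibration may be unstable",
        aid, n_blank, n_wt))
    max_blank_cov <- if (nrow(b)) max(b$coverage) else 0
    max_wt_af <- if (nrow(w)) max(w$af) else 0
    data.frame(amplicon_id = aid, min_coverage = as.integer(min_coverage),
               detection_min_reads = as.integer(max(2 * max_blank_cov,
                                                    min_coverage)),
               mutation_af_min = min(max(2 * max_wt_af, af_clamp[1]),
                                     af_clamp[2]),
               max_blank_coverage = max_blank_cov, max_wt_af = max_wt_af,
               n_blank_controls = n_blank, n_wt_controls = n_wt,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("threshold_set", "data.frame")
  res
}

# ND allele-frequency windows per dataset mode and molecule class.
# Windows are open intervals on AF; NULL means no window for that combo.
nd_window_for <- function(dataset_mode, molecule) {
  switch(dataset_mode,
         full_length = if (molecule == "gDNA") c(0.03, 0.1) else NULL,
         three_prime = if (molecule == "gDNA") c(0.04, 0.1) else c(0.03, 0.1),
         stop(sprintf("unknown dataset_mode '%s'", dataset_mode)))
}

#' Call per-molecule genotypes from allele counts
#'
#' Applies the calibrated thresholds to each (cell, amplicon, variant)
#' allele count. Coverage below the detection floor gives FAIL. For
#' zygosity-critical sites, an allele fraction inside the open ND window
#' for the dataset mode and molecule class (gDNA: 0.03-0.1 full-length,
#' 0.04-0.1 3'-counting; mRNA: 0.03-0.1 in 3' mode) gives ND. Otherwise
#' a cell is HET when both the alt and the ref fractions reach the
#' mutant-AF threshold, HOM when only the alt does, and WT when the alt
#' fraction is below threshold.
#'
#' @param counts Allele-count table (see [count_alleles_all()]).
#' @param thresholds A `threshold_set` from [calibrate_thresholds()].
#' @param panel An [amplicon_panel()].
#' @param dataset_mode `"full_length"` or `"three_prime"`.
#' @return Molecule-call table: cell_id, amplicon_id, variant_id, gene,
#'   molecule, call (FAIL/WT/HET/HOM/ND), af, coverage.
#' @export
call_molecule <- function(counts, thresholds, panel,
                          dataset_mode = c("full_length", "three_prime")) {
  dataset_mode <- match.arg(dataset_mode)
  th <- thresholds[match(counts$amplicon_id, thresholds$amplicon_id), ]
  if (anyNA(th$amplicon_id))
    stop("thresholds missing for some amplicons in the count table")
  vinfo <- panel_variants(panel)
  zc <- vinfo$zygosity_critical[match(paste(counts$amplicon_id,
                                            counts$variant_id),
                                      paste(vinfo$amplicon_id,
                                            vinfo$variant_id))]
  floor_cov <- pmax(th$min_coverage, th$detection_min_reads)
  af <- counts$af
  ref_frac <- 1 - af
  m <- th$mutation_af_min
  call <- ifelse(af >= m & ref_frac >= m, "HET",
          ifelse(af >= m, "HOM", "WT"))
  for (mol in unique(counts$molecule)) {
    w <- nd_window_for(dataset_mode, mol)
    if (!is.null(w)) {
      nd <- counts$molecule == mol & zc & af > w[1] & af < w[2]
      call[nd] <- "ND"
    }
  }
  call[counts$coverage < floor_cov] <- "FAIL"
  data.frame(cell_id = counts$cell_id, amplicon_id = counts$amplicon_id,
             variant_id = counts$variant_id, gene = counts$gene,
             molecule = counts$molecule, call = call, af = af,
             coverage = counts$coverage, stringsAsFactors = FALSE)
}

#' Integrate gDNA and cDNA molecule calls into one genotype
#'
#' Deterministic truth table over the (gDNA, cDNA) call pair. A
#' heterozygous readout on either molecule dominates; a homozygous
#' readout on one molecule with a WT readout on the other is also called
#' heterozygous. HOM and WT calls are otherwise anchored to the genomic
#' DNA: a cell is HOM when only the mutant allele is seen at the gDNA
#' level and WT when only the WT allele is. A cell whose gene is seen
#' only at the mRNA level (gDNA FAIL, cDNA WT or HOM) is EXCLUDED; both
#' molecules failing gives MISSING. An ND molecule is removed from
#' consideration and the other molecule's readout stands; if the other is
#' uninformative the integrated call is ND.
#'
#' @param g,c gDNA and cDNA calls (FAIL/WT/HET/HOM/ND), vectorized.
#' @return Integrated call(s): WT/HET/HOM/ND/EXCLUDED/MISSING.
#' @export
integrate_genotype <- function(g, c) {
  stopifnot(length(g) == length(c))
  valid <- c("FAIL", "WT", "HET", "HOM", "ND")
  if (!all(g %in% valid) || !all(c %in% valid))
    stop("calls must be FAIL, WT, HET, HOM or ND")
  one <- function(g, c) {
    if (g == "ND" || c == "ND") {
      other <- if (g == "ND") c else g
      if (other %in% c("ND", "FAIL")) return("ND")
      return(other)            # the informative molecule's readout stands
    }
    if (g == "HET" || c == "HET") return("HET")
    if ((g == "HOM" && c == "WT") || (g == "WT" && c == "HOM"))
      return("HET")
    if (g == "HOM") return("HOM")          # c in {HOM, FAIL}
    if (g == "WT") return("WT")            # c in {WT, FAIL}
    if (c == "FAIL") return("MISSING")     # g == FAIL
    "EXCLUDED"                             # g FAIL, c in {WT, HOM}
  }
  mapply(one, g, c, USE.NAMES = FALSE)
}

#' Build the integrated genotype matrix from molecule calls
#'
#' Pairs each cell/variant's gDNA and cDNA molecule calls (a missing
#' molecule is treated as FAIL) and applies [integrate_genotype()].
#'
#' @param mol_calls Molecule-call table from [call_molecule()].
#' @return A `genotype_matrix`: character matrix cells x variants of
#'   integrated calls, with the provenance pairs in
#'   `attr(, "provenance")`.
#' @export
integrate_calls <- function(mol_calls) {
  cells <- unique(mol_calls$cell_id)
  vids <- unique(mol_calls$variant_id)
  pick <- function(mol) {
    sub <- mol_calls[mol_calls$molecule == mol, ]
    m <- matrix("FAIL", length(cells), length(vids),
                dimnames = list(cells, vids))
    m[cbind(match(sub$cell_id, cells), match(sub$variant_id, vids))] <-
      sub$call
    m
  }
  gm <- pick("gDNA")
  cm <- pick("mRNA")
  out <- matrix(integrate_genotype(as.vector(gm), as.vector(cm)),
                length(cells), length(vids), dimnames = list(cells, vids))
  genes <- mol_calls$gene[match(vids, mol_calls$variant_id)]
  structure(out, provenance = list(gDNA = gm, cDNA = cm),
            genes = stats::setNames(genes, vids),
            class = c("genotype_matrix", class(out)))
}

#' Cell-level genotyping QC
#'
#' Drops single cells in which any targeted gene failed to be detected on
#' both the gDNA and the mRNA amplicons (integrated call MISSING for some
#' variant of that gene). EXCLUDED calls do not drop the cell globally:
#' they exclude it from analyses of that variant only, and are retained
#' in the matrix with per-cell reason codes.
#'
#' @param gm A `genotype_matrix` from [integrate_calls()].
#' @return `list(matrix, dropped)`: the QC-passed matrix and a
#'   `data.frame` of dropped cells with reason codes
#'   (`gene_undetected:<GENE>`).
#' @export
qc_cells <- function(gm) {
  if (nrow(gm) == 0L)
    return(list(matrix = gm,
                dropped = data.frame(cell_id = character(0),
                                     reason = character(0))))
  genes <- attr(gm, "genes")
  reasons <- apply(gm, 1, function(row) {
    bad <- colnames(gm)[row == "MISSING"]
    if (!length(bad)) return(NA_character_)
    paste(sprintf("gene_undetected:%s", unique(genes[bad])), collapse = ";")
  })
  keep <- is.na(reasons)
  kept <- gm[keep, , drop = FALSE]
  attr(kept, "provenance") <- lapply(attr(gm, "provenance"),
                                     function(m) m[keep, , drop = FALSE])
  attr(kept, "genes") <- genes
  class(kept) <- class(gm)
  list(matrix = kept,
       dropped = data.frame(cell_id = rownames(gm)[!keep],
                            reason = reasons[!keep],
                            stringsAsFactors = FALSE))
}

#' Group cells into clones by integrated genotype
#'
#' Cells with identical integrated-call vectors form a clone, named
#' deterministically as the panel-ordered `GENE:CALL` pairs joined with
#' ';'. A cell with MISSING entries is wildcard-matched against the
#' complete genotypes observed in the population and assigned only if a
#' unique consistent clone exists; otherwise it is left unassigned.
#' Clones failing both size rules (fewer than `min_cells` cells and less
#' than `min_frac` of assigned cells) are flagged `minor`.
#'
#' @param gm A QC-passed `genotype_matrix`.
#' @param min_cells Minimum clone size in cells (default 5).
#' @param min_frac Minimum clone size as a fraction (default 0.05).
#' @return `list(clones, assignments)`: the clone table (label, n_cells,
#'   frac, minor) and the per-cell assignment.
#' @export
assign_clones <- function(gm, min_cells = 5L, min_frac = 0.05) {
  label_of <- function(row) paste(sprintf("%s:%s", attr(gm, "genes"),
                                          row), collapse = ";")
  informative <- function(row) !row %in% c("MISSING", "EXCLUDED", "ND")
  complete <- apply(gm, 1, function(r) all(informative(r)))
  labels <- rep(NA_character_, nrow(gm))
  labels[complete] <- apply(gm[complete, , drop = FALSE], 1, label_of)
  observed <- unique(stats::na.omit(labels))
  obs_mat <- do.call(rbind, lapply(strsplit(observed, ";"), function(x)
    sub("^[^:]+:", "", x)))
  for (i in which(!complete)) {
    row <- gm[i, ]
    known <- informative(row)
    if (!any(known)) next
    cons <- which(apply(obs_mat, 1, function(o)
      all(o[known] == row[known])))
    if (length(cons) == 1L) labels[i] <- observed[cons]
  }
  assigned <- !is.na(labels)
  tab <- table(labels[assigned])
  clones <- data.frame(label = names(tab), n_cells = as.integer(tab),
                       frac = as.integer(tab) / sum(tab),
                       stringsAsFactors = FALSE)
  clones$minor <- clones$n_cells < min_cells & clones$frac < min_frac
  # deterministic order: by panel-order genotype string
  clones <- clones[order(clones$label), , drop = FALSE]
  rownames(clones) <- NULL
  list(clones = clones,
       assignments = data.frame(cell_id = rownames(gm), clone = labels,
                                stringsAsFactors = FALSE))
}

#' Count false-positive mutation calls in control wells
#'
#' Pipeline-level specificity check: the number of HET or HOM molecule
#' calls among wild-type control cells and blanks. Under the calibrated
#' threshold regime this count is expected to be zero.
#'
#' @param control_calls Molecule-call table for control wells (see
#'   [call_molecule()]).
#' @return Integer count of mutation calls.
#' @export
false_positive_audit <- function(control_calls) {
  if (is.null(control_calls) || nrow(control_calls) == 0L) return(0L)
  sum(control_calls$call %in% c("HET", "HOM"))
}

#' Write a genotype matrix as TSV
#'
#' @param gm A `genotype_matrix`.
#' @param path File path.
#' @export
write_genotype_tsv <- function(gm, path) {
  df <- data.frame(cell_id = rownames(gm), unclass(gm)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
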