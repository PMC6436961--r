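panel <- example_panel()

mk_counts <- function(amplicon_id, cell_id, n_ref, n_alt, n_other = 0L) {
  vinfo <- panel_variants(panel)
  vi <- vinfo[vinfo$amplicon_id == amplicon_id, ]
  cov <- n_ref + n_alt + n_other
  den <- n_ref + n_alt
  data.frame(cell_id = cell_id, amplicon_id = amplicon_id,
             variant_id = vi$variant_id, gene = vi$gene,
             molecule = vi$molecule, n_ref = n_ref, n_alt = n_alt,
             n_other = n_other, coverage = cov,
             af = ifelse(den > 0, n_alt / den, 0),
             stringsAsFactors = FALSE)
}

test_that("threshold calibration applies the doubling rule and clamps", {
  # blanks all zero coverage, clean WT controls -> floor values
  blanks <- do.call(rbind, lapply(names(panel), mk_counts,
                                  cell_id = "b1", n_ref = 0L, n_alt = 0L))
  wt <- do.call(rbind, lapply(names(panel), mk_counts, cell_id = "w1",
                              n_ref = 995L, n_alt = 5L))  # af 0.005
  th <- suppressWarnings(calibrate_thresholds(blanks, wt, panel))
  expect_true(all(th$detection_min_reads == 30L))
  expect_true(all(th$mutation_af_min == 0.015))
  # noisy WT control clamps at the 4% ceiling
  wt2 <- do.call(rbind, lapply(names(panel), mk_counts, cell_id = "w1",
                               n_ref = 970L, n_alt = 30L))  # af 0.03
  th2 <- suppressWarnings(calibrate_thresholds(blanks, wt2, panel))
  expect_true(all(th2$mutation_af_min == 0.04))
  # blank coverage 40 doubles to a detection floor of 80
  blanks3 <- do.call(rbind, lapply(names(panel), mk_counts,
                                   cell_id = "b1", n_ref = 40L, n_alt = 0L))
  th3 <- suppressWarnings(calibrate_thresholds(blanks3, wt, panel))
  expect_true(all(th3$detection_min_reads == 80L))
  # provenance retained
  expect_true(all(c("max_blank_coverage", "max_wt_af") %in% names(th3)))
  expect_true(all(th3$max_blank_coverage == 40))
  # amplicon absent from all controls is an error
  expect_error(calibrate_thresholds(blanks[blanks$amplicon_id != "gJAK2", ],
                                    wt[wt$amplicon_id != "gJAK2", ], panel),
               "absent from all controls")
})

fixed_th <- function(af_min = 0.02) {
  data.frame(amplicon_id = names(panel), min_coverage = 30L,
             detection_min_reads = 30L, mutation_af_min = af_min,
             stringsAsFactors = FALSE)
}

test_that("molecule calls follow coverage, ND window and AF rules", {
  th <- fixed_th()
  call_of <- function(amp, n_ref, n_alt)
    call_molecule(mk_counts(amp, "c1", n_ref, n_alt), th, panel,
                  "full_length")$call
  expect_identical(call_of("gJAK2", 20L, 5L), "FAIL")   # coverage 25
  expect_identical(call_of("gJAK2", 940L, 60L), "ND")   # af 0.06, critical
  expect_identical(call_of("gJAK2", 500L, 500L), "HET")
  expect_identical(call_of("gJAK2", 5L, 995L), "HOM")   # af 0.995
  expect_identical(call_of("gJAK2", 998L, 2L), "WT")    # af 0.002
  # non-critical site: same af is a mutation call, not ND
  expect_identical(call_of("gTET2", 940L, 60L), "HET")
  # mode-specific gDNA window: af 0.035 is ND only in full-length mode;
  # in 3' mode it sits below the 0.04-0.1 window and above the mutation
  # threshold, so it is an ordinary HET call
  expect_identical(call_of("gJAK2", 965L, 35L), "ND")
  expect_identical(
    call_molecule(mk_counts("gJAK2", "c1", 965L, 35L), th, panel,
                  "three_prime")$call, "HET")
  # mRNA window applies only in 3'-counting mode
  expect_identical(call_of("mJAK2", 940L, 60L), "HET")
  expect_identical(
    call_molecule(mk_counts("mJAK2", "c1", 940L, 60L), th, panel,
                  "three_prime")$call, "ND")
})

test_that("raising the mutation AF threshold never creates mutation calls", {
  af_grid <- seq(0, 1, by = 0.01)
  counts <- mk_counts("gTET2", sprintf("c%03d", seq_along(af_grid)),
                      n_ref = as.integer(round(1000 * (1 - af_grid))),
                      n_alt = as.integer(round(1000 * af_grid)))
  prev <- NULL
  for (m in c(0.015, 0.02, 0.03, 0.04)) {
    cur <- call_molecule(counts, fixed_th(m), panel, "full_length")$call
    if (!is.null(prev)) {
      was_wt <- prev == "WT"
      expect_true(all(cur[was_wt] == "WT"))
    }
    prev <- cur
  }
})

test_that("gDNA/cDNA integration reproduces the full truth table", {
  calls <- c("FAIL", "WT", "HET", "HOM", "ND")
  expected <- matrix(c(
    # cDNA:  FAIL        WT          HET    HOM         ND       (gDNA:)
    "MISSING", "EXCLUDED", "HET", "EXCLUDED", "ND",     # FAIL
    "WT",      "WT",       "HET", "HET",      "WT",     # WT
    "HET",     "HET",      "HET", "HET",      "HET",    # HET
    "HOM",     "HET",      "HET", "HOM",      "HOM",    # HOM
    "ND",      "WT",       "HET", "HOM",      "ND"),    # ND
    nrow = 5, byrow = TRUE, dimnames = list(calls, calls))
  for (g in calls) for (c in calls)
    expect_identical(integrate_genotype(g, c), expected[g, c],
                     label = sprintf("g=%s c=%s", g, c))
  # the HET rule is symmetric; WT/HOM are anchored to gDNA
  expect_identical(integrate_genotype("HET", "WT"),
                   integrate_genotype("WT", "HET"))
  expect_false(identical(integrate_genotype("FAIL", "HOM"),
                         integrate_genotype("HOM", "FAIL")))
})

# build an integrated matrix from explicit per-molecule call strings
mk_gm <- function(gcalls, ccalls, variants = c("JAK2", "TET2")) {
  rows <- list()
  for (i in seq_len(nrow(gcalls))) for (v in variants) {
    gene <- v
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = rownames(gcalls)[i],
      amplicon_id = c(paste0("g", gene), paste0("m", gene)),
      variant_id = v, gene = gene, molecule = c("gDNA", "mRNA"),
      call = c(gcalls[i, v], ccalls[i, v]), af = 0, coverage = 100L,
      stringsAsFactors = FALSE)
  }
  integrate_calls(do.call(rbind, rows))
}

test_that("cell QC drops cells with a gene undetected on both molecules", {
  g <- matrix(c("HET", "WT", "FAIL", "FAIL", "WT", "WT"), 3, 2,
              byrow = TRUE, dimnames = list(c("c1", "c2", "c3"),
                                            c("JAK2", "TET2")))
  c_ <- matrix(c("HET", "WT", "FAIL", "WT", "WT", "WT"), 3, 2,
               byrow = TRUE, dimnames = dimnames(g))
  gm <- mk_gm(g, c_)
  qc <- qc_cells(gm)
  expect_identical(rownames(qc$matrix), c("c1", "c3"))
  expect_identical(qc$dropped$cell_id, "c2")
  expect_match(qc$dropped$reason, "gene_undetected:JAK2")
  # empty matrix passes through
  empty <- qc_cells(gm[0, , drop = FALSE])
  expect_identical(nrow(empty$matrix), 0L)
})

test_that("clone assignment flags minor clones and wildcards MISSING", {
  set.seed(1)
  labels <- c(rep("WT", 60), rep("HET", 36), rep("HOM", 4))
  g <- matrix("WT", 100, 2, dimnames = list(sprintf("c%03d", 1:100),
                                            c("JAK2", "TET2")))
  g[, "JAK2"] <- labels
  gm <- mk_gm(g, g)
  cl <- assign_clones(gm, min_cells = 5, min_frac = 0.05)
  hom_row <- grepl("JAK2:HOM", cl$clones$label)
  expect_identical(cl$clones$n_cells[hom_row], 4L)
  expect_true(cl$clones$minor[hom_row])
  expect_true(all(!cl$clones$minor[!hom_row]))
  # a MISSING entry consistent with two clones leaves the cell unassigned
  g2 <- g; c2 <- g
  g2["c001", "JAK2"] <- "FAIL"; c2["c001", "JAK2"] <- "FAIL"
  gm2 <- mk_gm(g2, c2)
  cl2 <- assign_clones(gm2)
  expect_true(is.na(cl2$assignments$clone[cl2$assignments$cell_id == "c001"]))
  # unique consistent clone: make TET2 informative only for one genotype
  g3 <- g; g3[61:100, "TET2"] <- "HET"
  g3["c001", "JAK2"] <- "FAIL"
  c3 <- g3; c3["c001", "JAK2"] <- "FAIL"
  gm3 <- mk_gm(g3, c3)
  cl3 <- assign_clones(gm3)
  lab <- cl3$assignments$clone[cl3$assignments$cell_id == "c001"]
  expect_identical(lab, "JAK2:WT;TET2:WT")
})

test_that("clone frequencies are recovered from a simulated population", {
  set.seed(42)
  freqs <- c(WT = 0.5, HET = 0.35, HOM = 0.15)
  n <- 1000
  labels <- sample(names(freqs), n, replace = TRUE, prob = freqs)
  g <- matrix(labels, n, 1, dimnames = list(sprintf("c%04d", 1:n), "JAK2"))
  cl <- assign_clones(mk_gm(g, g, variants = "JAK2"))
  got <- cl$clones$frac[match(paste0("JAK2:", names(freqs)),
                              cl$clones$label)]
  expect_true(all(abs(got - freqs) < 3 * sqrt(freqs * (1 - freqs) / n)))
})

test_that("false-positive audit counts mutation calls in controls", {
  expect_identical(false_positive_audit(NULL), 0L)
  mc <- data.frame(call = c("WT", "FAIL", "WT"))
  expect_identical(false_positive_audit(mc), 0L)
  mc$call[2] <- "HET"
  expect_identical(false_positive_audit(mc), 1L)
})
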