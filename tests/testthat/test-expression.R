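test_that("RPKM normalization matches the closed form with detection floor", {
  counts <- matrix(as.integer(c(100, 0, 1, 0)), 4, 1,
                   dimnames = list(c("g1", "g2", "g3", "g4"), "c1"))
  len <- c(g1 = 1000, g2 = 1000, g3 = 500, g4 = 1000)
  em <- rpkm_normalize(counts, len, mapped_totals = c(c1 = 1e6))
  # 100 / (1 kb * 1 M) = 100 RPKM -> log2 = 6.6439
  expect_equal(unname(em["g1", "c1"]), log2(100), tolerance = 1e-12)
  expect_identical(unname(em["g2", "c1"]), 0)
  # g3: 1 / 0.5 / 1 = 2 RPKM
  expect_equal(unname(em["g3", "c1"]), 1, tolerance = 1e-12)
  # sub-1 RPKM is non-detected
  counts2 <- matrix(99L, 1, 1, dimnames = list("g1", "c1"))
  em2 <- rpkm_normalize(counts2, c(g1 = 1e5), mapped_totals = c(c1 = 1e6))
  expect_identical(unname(em2[1, 1]), 0)   # RPKM 0.99 -> 0
  expect_identical(attr(em, "normalization"), "RPKM")
  # zero-total cell flagged and excluded
  counts3 <- cbind(counts, c2 = c(0L, 0L, 0L, 0L))
  expect_warning(em3 <- rpkm_normalize(counts3, len), "zero mapped")
  expect_identical(attr(em3, "excluded_cells"), "c2")
})

test_that("3' normalization conserves the target exactly, then thresholds", {
  set.seed(1)
  counts <- matrix(rpois(200 * 20, 30), 200, 20,
                   dimnames = list(sprintf("g%d", 1:200),
                                   sprintf("c%d", 1:20)))
  em <- normalize_3p(counts)
  target <- attr(em, "target")
  expect_equal(target, mean(colSums(counts)), tolerance = 1e-12)
  pre <- sweep(counts, 2, target / colSums(counts), `*`)
  expect_true(all(abs(colSums(pre) - target) < 1e-8))
  # spec arithmetic: count 10, libsize 5000, target 68412
  c1 <- matrix(c(10L, 4990L), 2, 1, dimnames = list(c("a", "b"), "c1"))
  em1 <- normalize_3p(c1, target = 68412)
  expect_equal(unname(em1["a", 1]), log2(10 / 5000 * 68412),
               tolerance = 1e-12)
  # identity when libsize equals the target
  c2 <- matrix(c(40L, 60L), 2, 1, dimnames = list(c("a", "b"), "c1"))
  em2 <- normalize_3p(c2, target = 100)
  expect_equal(unname(em2[, 1]), log2(c(40, 60)), tolerance = 1e-12)
  # all-zero gene stays zero; thresholding is idempotent
  expect_true(all(em[rowSums(counts) == 0, ] == 0))
  lin <- ifelse(em > 0, 2^em, 0)
  expect_true(all(em[lin < 1] == 0))
})

test_that("QC filters apply the printed strict inequalities", {
  fl <- data.frame(cell_id = c("pass", "edge_genes", "low_exonic"),
                   pct_exonic = c(60, 60, 50), pct_mapped = c(70, 70, 70),
                   n_genes = c(1501, 1500, 3000))
  res <- qc_filter(fl, "full_length", min_genes = 1500)
  expect_identical(res$pass, c(TRUE, FALSE, FALSE))
  expect_match(res$reasons[2], "n_genes<=1500")
  expect_match(res$reasons[3], "pct_exonic<=50")
  tp <- data.frame(cell_id = c("edge_reads", "ok", "high_mito"),
                   total_reads = c(2000, 3000, 3000),
                   pct_mito = c(5, 9.9, 10), pct_ercc = c(10, 10, 10),
                   n_genes = c(600, 600, 600))
  res2 <- qc_filter(tp, "three_prime")
  expect_identical(res2$pass, c(FALSE, TRUE, FALSE))
  expect_match(res2$reasons[1], "total_reads<=2000")
  expect_match(res2$reasons[3], "pct_mito>=10")
  # missing metric fails with a reason code
  res3 <- qc_filter(data.frame(cell_id = "x", pct_exonic = 60,
                               n_genes = 2000), "full_length")
  expect_false(res3$pass)
  expect_match(res3$reasons, "metric_missing:pct_mapped")
})

test_that("dropout frequency recovers configured rates", {
  em <- matrix(c(rep(4, 10), rep(0, 10), rep(c(4, 0), 5)), 3, 10,
               byrow = TRUE, dimnames = list(c("all", "none", "half"),
                                             sprintf("c%d", 1:10)))
  df <- dropout_frequency(em, c("all", "none", "half"))
  expect_identical(unname(df), c(0, 1, 0.5))
  expect_error(dropout_frequency(em, character(0)), "non-empty")
  # simulated known dropout
  sim <- simulate_expression(seed = 2, labels = rep("A", 500),
                             n_genes = 200,
                             base_mean_lognormal = c(log(200), 0.2),
                             dispersion = 10, dropout_prob = 0.3)
  em2 <- normalize_3p(sim$counts)
  est <- dropout_frequency(em2, rownames(sim$counts))
  expect_lt(abs(mean(est) - 0.3), 3 * sqrt(0.3 * 0.7 / 500))
})

test_that("library bias matches hand arithmetic and is monotone", {
  lin <- matrix(c(10, rep(1, 9)), 10, 1,
                dimnames = list(sprintf("g%d", 1:10), "c1"))
  expect_equal(unname(library_bias(lin, scale = "linear")), 10 / 1.9,
               tolerance = 1e-12)
  # all genes equal -> 1
  lin2 <- matrix(5, 10, 1, dimnames = dimnames(lin))
  expect_equal(unname(library_bias(lin2, scale = "linear")), 1,
               tolerance = 1e-12)
  # raising the top value strictly increases the bias
  lin3 <- lin; lin3[1, 1] <- 20
  expect_gt(library_bias(lin3, scale = "linear"),
            library_bias(lin, scale = "linear"))
  expect_error(library_bias(lin[1:5, , drop = FALSE], scale = "linear"),
               ">= 10 detected")
})

test_that("highly variable genes are recovered above the mean-CV trend", {
  hvg <- 1:50
  sim <- simulate_expression(seed = 3, labels = rep("A", 500),
                             n_genes = 1000, hvg_genes = hvg,
                             hvg_sdlog = 1,
                             base_mean_lognormal = c(log(30), 0.8))
  em <- normalize_3p(sim$counts)
  fit <- highly_variable_genes(em)
  sel <- fit$gene[fit$selected]
  recall <- mean(rownames(sim$counts)[hvg] %in% sel)
  expect_gte(recall, 0.95)
  # low-mean gene with huge CV is rejected by the log2(mean) >= 0 rule
  low <- fit[fit$log2_mean < 0, ]
  expect_true(all(!low$selected))
  # constant matrix selects nothing
  emc <- matrix(3, 100, 20, dimnames = list(sprintf("g%d", 1:100),
                                            sprintf("c%d", 1:20)))
  expect_identical(sum(highly_variable_genes(emc)$selected), 0L)
})

test_that("ADO estimation classifies AF against the het window", {
  counts <- data.frame(
    cell_id = sprintf("c%d", 1:4), site_id = "s1",
    n_ref = c(50L, 96L, 5L, 100L), n_alt = c(50L, 4L, 95L, 0L))
  est <- ado_from_het_sites(counts, min_cov = 10)
  # af = 0.5 biallelic; 0.04 and 0.95 and 0 monoallelic
  expect_identical(est$n_informative, 4L)
  expect_identical(est$n_monoallelic, 3L)
  # low-coverage observations are ignored
  counts2 <- rbind(counts, data.frame(cell_id = "c5", site_id = "s1",
                                      n_ref = 4L, n_alt = 0L))
  expect_identical(ado_from_het_sites(counts2)$n_informative, 4L)
})

test_that("cell-cycle scores are set means, blind to outside genes", {
  em <- matrix(0, 4, 3, dimnames = list(c("s1", "s2", "g1", "other"),
                                        c("c1", "c2", "c3")))
  em["s1", ] <- 4
  sc <- cell_cycle_scores(em, s_genes = "s1", g2m_genes = "g1")
  expect_identical(sc$s_score, rep(4, 3))
  expect_identical(sc$g2m_score, rep(0, 3))
  em2 <- em; em2["other", ] <- 99
  expect_identical(cell_cycle_scores(em2, "s1", "g1")$s_score, sc$s_score)
  expect_warning(cell_cycle_scores(em, c("s1", "absent"), "g1"), "absent")
})

test_that("covariate regression removes effects and preserves gene means", {
  set.seed(5)
  n <- 500
  score <- rnorm(n)
  base <- matrix(rnorm(3 * n, mean = 5), 3, n,
                 dimnames = list(c("null", "exact", "noisy"), NULL))
  em <- base
  em["exact", ] <- 2 * score
  em["noisy", ] <- base["noisy", ] + 1.5 * score
  out <- regress_out(em, cbind(score = score))
  # a gene proportional to the covariate collapses to its mean
  expect_lt(var(out["exact", ]), 1e-20)
  # the injected slope is removed: refit is ~0, and the original ~1.5
  beta_pre <- unname(coef(lm(em["noisy", ] ~ score))[2])
  beta_post <- unname(coef(lm(out["noisy", ] ~ score))[2])
  expect_lt(abs(beta_pre - 1.5), 0.1)
  expect_lt(abs(beta_post), 1e-10)
  # gene means preserved exactly
  expect_equal(rowMeans(out), rowMeans(em), tolerance = 1e-12)
  # orthogonal covariate leaves a gene unchanged
  v <- rnorm(n)
  v <- v - mean(v)
  y <- rnorm(n)
  y_orth <- y - mean(y)
  y_orth <- y_orth - sum(y_orth * v) / sum(v * v) * v + 5
  emo <- matrix(y_orth, 1, n, dimnames = list("g", NULL))
  expect_equal(regress_out(emo, cbind(v = v))[1, ], emo[1, ],
               tolerance = 1e-10)
  # collinear covariates are refused by name
  expect_error(regress_out(em, cbind(a = score, b = 2 * score)),
               "collinear")
})

test_that("within-group correlations behave at the fixed points", {
  set.seed(6)
  base <- rnorm(2000, mean = 5)
  ident <- matrix(rep(base, 4), 2000, 4,
                  dimnames = list(sprintf("g%d", 1:2000),
                                  sprintf("c%d", 1:4)))
  noise <- matrix(rnorm(2000 * 4, mean = 5), 2000, 4,
                  dimnames = dimnames(ident))
  em <- cbind(ident, noise)
  colnames(em) <- sprintf("c%d", 1:8)
  groups <- rep(c("same", "indep"), each = 4)
  gc <- group_correlations(em, groups)
  expect_true(all(abs(gc$same - 1) < 1e-12))
  expect_lt(abs(mean(gc$indep)), 0.1)
  ks_self <- compare_group_correlations(gc, "same", "same")
  expect_identical(unname(ks_self$statistic), 0)
  ks <- compare_group_correlations(gc, "same", "indep")
  expect_lt(ks$p.value, 0.05)
})
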