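# Independent brute-force oracles; deliberately naive implementations
# kept separate from the package's vectorized paths.

# Per-read allele tally: dedup fragments keeping the best base, filter by
# quality, classify against ref/alt.
oracle_count_alleles <- function(group, ref, alt, min_bq) {
  n_ref <- 0L; n_alt <- 0L; n_other <- 0L
  for (rid in unique(group$read_id)) {
    sub <- group[group$read_id == rid, , drop = FALSE]
    best <- sub[which.max(sub$qual), ]
    if (best$qual < min_bq) next
    if (best$allele == ref) n_ref <- n_ref + 1L
    else if (best$allele == alt) n_alt <- n_alt + 1L
    else n_other <- n_other + 1L
  }
  c(n_ref = n_ref, n_alt = n_alt, n_other = n_other)
}

# Mutation-tree likelihood by direct enumeration of attachments, with its
# own root-path walk.
oracle_tree_loglik <- function(mm, parent, fd, ad) {
  m <- length(parent)
  path_genotype <- function(a) {
    g <- rep(0L, m)
    v <- a
    while (v != 0L) { g[v] <- 1L; v <- parent[v] }
    g
  }
  total <- 0
  for (i in seq_len(nrow(mm))) {
    probs <- vapply(0:m, function(a) {
      g <- path_genotype(a)
      pr <- 1
      for (j in seq_len(m)) {
        x <- mm[i, names(parent)[j]]
        if (is.na(x)) next
        pr <- pr * if (x == 1L) { if (g[j] == 1L) 1 - ad else fd }
                   else         { if (g[j] == 1L) ad else 1 - fd }
      }
      pr
    }, numeric(1))
    total <- total + log(mean(probs))
  }
  total
}

# Literal Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  cm <- 1
  for (i in m:1) {
    cm <- min(cm, p[o[i]] * m / i)
    adj[o[i]] <- cm
  }
  adj
}

# Chi-square survival closed forms for Fisher's method with k = 1, 2.
oracle_fisher_df2 <- function(p) p                       # identity
oracle_fisher_df4 <- function(p1, p2) {
  x <- -2 * (log(p1) + log(p2))
  exp(-x / 2) * (1 + x / 2)
}

# Small helper: run the full genotyping pipeline (calibrate on controls,
# call, integrate) on a counts simulation and return the integrated
# genotype matrix plus the calls on the evaluation wells.
run_genotyping <- function(eval_counts, control_sim, panel,
                           dataset_mode = "full_length") {
  ctrl <- control_sim$counts
  blanks <- ctrl[ctrl$cell_id %in% control_sim$truth$blanks, ]
  wt <- ctrl[!ctrl$cell_id %in% control_sim$truth$blanks, ]
  th <- suppressWarnings(calibrate_thresholds(blanks, wt, panel))
  mc <- call_molecule(eval_counts, th, panel, dataset_mode)
  list(thresholds = th, calls = mc, matrix = integrate_calls(mc))
}
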