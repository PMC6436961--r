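#' Simulation configuration for targeted amplicon reads
#'
#' Bundles the parameters of the amplicon-read simulator. The defaults
#' mirror the assay's operating point: mean per-amplicon coverage 2641
#' reads, sequencing error 0.5% per base, and low-level background reads
#' in blank (non-template) wells so detection thresholds have
#' non-degenerate calibration input.
#'
#' @param seed Integer seed (mandatory; all generators are deterministic
#'   under a fixed seed).
#' @param panel An [amplicon_panel()].
#' @param n_cells Number of test cells.
#' @param n_blanks Number of blank wells (background reads only).
#' @param depth_mean Mean reads per amplicon per cell (Poisson).
#' @param seq_error_rate Per-base sequencing error probability.
#' @param ado_prob Per-molecule allelic dropout probability: the chance
#'   that one of the two allele copies of a cell-amplicon molecule pool is
#'   lost before amplification.
#' @param contamination_mean Mean background reads per amplicon in blanks
#'   (Poisson).
#' @param qual_high_prob Fraction of bases at the high quality point of
#'   the two-point (q37/q10) base-quality mixture.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed, panel, n_cells = 100L, n_blanks = 10L,
                       depth_mean = 2641, seq_error_rate = 0.005,
                       ado_prob = 0, contamination_mean = 5,
                       qual_high_prob = 0.9) {
  if (missing(seed) || !is.numeric(seed)) stop("seed is mandatory")
  stopifnot(inherits(panel, "amplicon_panel"), depth_mean > 0)
  for (p in c(seq_error_rate, ado_prob, qual_high_prob))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  structure(list(seed = as.integer(seed), panel = panel,
                 n_cells = as.integer(n_cells),
                 n_blanks = as.integer(n_blanks),
                 depth_mean = depth_mean, seq_error_rate = seq_error_rate,
                 ado_prob = ado_prob,
                 contamination_mean = contamination_mean,
                 qual_high_prob = qual_high_prob,
                 qual_high = 37L, qual_low = 10L),
            class = "sim_config")
}

# Resolve the genotype matrix argument: a single call recycled, a vector
# per cell, or a full cells x variants character matrix.
resolve_genotypes <- function(genotypes, n_cells, variant_ids) {
  if (is.null(genotypes)) genotypes <- "WT"
  if (!is.matrix(genotypes)) {
    genotypes <- matrix(rep(genotypes, length.out = n_cells),
                        nrow = n_cells, ncol = length(variant_ids))
    colnames(genotypes) <- variant_ids
  }
  if (!all(genotypes %in% c("WT", "HET", "HOM")))
    stop("genotypes must be WT, HET or HOM")
  if (nrow(genotypes) != n_cells ||
      !all(variant_ids %in% colnames(genotypes)))
    stop("genotype matrix must be n_cells x variants")
  genotypes[, variant_ids, drop = FALSE]
}

# Allele pool fraction of alt copies after a possible dropout event.
# Returns list(p_alt, dropped) where dropped is NA / "ref" / "alt".
pool_after_ado <- function(genotype, ado_prob) {
  copies <- switch(genotype, WT = c(0, 0), HET = c(0, 1), HOM = c(1, 1))
  dropped <- NA_character_
  if (ado_prob > 0 && stats::runif(1) < ado_prob) {
    i <- sample(2L, 1L)
    dropped <- if (copies[i] == 1) "alt" else "ref"
    copies <- copies[-i]
  }
  list(p_alt = mean(copies), dropped = dropped)
}

#' Simulate targeted amplicon reads with known truth
#'
#' Generates one row per sequenced read in the aligned-read TSV dialect
#' (`cell_id`, `read_id`, `amplicon_id`, `variant_id`, `allele`, `qual`):
#' the allele string observed at the target site plus its base quality,
#' drawn from a two-point q37/q10 mixture. Per cell and amplicon, read
#' depth is Poisson; a heterozygous cell's molecule pool loses one allele
#' copy with probability `ado_prob` (the dropout event is recorded in the
#' truth log); each read's observed base is perturbed by the sequencing
#' error rate. Blank wells receive only background reads carrying the
#' reference allele. With `sequences = TRUE` full read sequences
#' (forward primer + amplicon insert) are also returned for the
#' demultiplexing path.
#'
#' @param cfg A [sim_config()].
#' @param genotypes Per-cell true genotypes: a single call (recycled), a
#'   vector, or a cells-by-variants character matrix of WT/HET/HOM.
#' @param sequences Also build full read sequences (slower; intended for
#'   small read sets exercising [demux_reads()]).
#' @return `list(reads, sequences, truth)`; `truth` holds the genotype
#'   matrix, the dropout-event log and the blank flags.
#' @export
simulate_panel_reads <- function(cfg, genotypes = NULL, sequences = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  vinfo <- panel_variants(cfg$panel)
  vids <- unique(vinfo$variant_id)
  gt <- resolve_genotypes(genotypes, cfg$n_cells, vids)
  cells <- sprintf("cell%04d", seq_len(cfg$n_cells))
  blanks <- if (cfg$n_blanks > 0) sprintf("blank%03d", seq_len(cfg$n_blanks))
            else character(0)
  rownames(gt) <- cells

  rows <- list()
  events <- list()
  for (cid in c(cells, blanks)) {
    is_blank <- startsWith(cid, "blank")
    for (amp in cfg$panel) {
      depth <- stats::rpois(1, if (is_blank) cfg$contamination_mean
                               else cfg$depth_mean)
      if (depth == 0) next
      for (k in seq_len(nrow(amp$variants))) {
        site <- amp$variants[k, ]
        if (is_blank) {
          p_alt <- 0
        } else {
          pool <- pool_after_ado(gt[cid, site$variant_id], cfg$ado_prob)
          p_alt <- pool$p_alt
          if (!is.na(pool$dropped))
            events[[length(events) + 1L]] <- data.frame(
              cell_id = cid, amplicon_id = amp$amplicon_id,
              variant_id = site$variant_id, molecule = amp$molecule,
              genotype = gt[cid, site$variant_id],
              dropped_allele = pool$dropped, stringsAsFactors = FALSE)
        }
        true_allele <- ifelse(stats::runif(depth) < p_alt, site$alt,
                              site$ref)
        obs <- true_allele
        err <- stats::runif(depth) < cfg$seq_error_rate
        if (any(err)) {
          if (site$vtype == "SNV") {
            obs[err] <- vapply(obs[err], function(b)
              sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
          } else obs[err] <- "OTHER"
        }
        qual <- ifelse(stats::runif(depth) < cfg$qual_high_prob,
                       cfg$qual_high, cfg$qual_low)
        rows[[length(rows) + 1L]] <- data.frame(
          cell_id = cid,
          read_id = sprintf("%s_%s_r%05d", cid, amp$amplicon_id,
                            seq_len(depth)),
          amplicon_id = amp$amplicon_id, variant_id = site$variant_id,
          allele = obs, qual = as.integer(qual), stringsAsFactors = FALSE)
      }
    }
  }
  reads <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = character(0), read_id = character(0),
               amplicon_id = character(0), variant_id = character(0),
               allele = character(0), qual = integer(0))
  truth <- list(genotypes = gt,
                dropout_events = if (length(events)) do.call(rbind, events)
                                 else NULL,
                blanks = blanks)
  seqs <- if (sequences) build_read_sequences(reads, cfg$panel) else NULL
  list(reads = reads, sequences = seqs, truth = truth)
}

# Expand TSV-dialect reads into full sequences: forward primer + a
# deterministic filler insert with the observed allele substituted at the
# variant offset. SNV sites only (indel alleles have no fixed width).
build_read_sequences <- function(reads, panel) {
  refseqs <- lapply(panel, amplicon_reference)
  out <- character(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    amp <- panel[[reads$amplicon_id[i]]]
    site <- amp$variants[amp$variants$variant_id == reads$variant_id[i], ]
    if (site$vtype != "SNV")
      stop("sequence expansion supports SNV sites only")
    s <- refseqs[[amp$amplicon_id]]
    off <- site$pos - amp$start + 1L
    substr(s, off, off) <- reads$allele[i]
    out[i] <- s
  }
  data.frame(cell_id = reads$cell_id, read_id = reads$read_id,
             seq = out, qual = reads$qual, stringsAsFactors = FALSE)
}

# Deterministic pseudo-reference for an amplicon: primer prefix, then a
# filler sequence derived from hashing the amplicon id (seed-independent).
amplicon_reference <- function(amp) {
  len <- amp$end - amp$start + 1L
  h <- sum(utf8ToInt(amp$amplicon_id) * seq_along(utf8ToInt(amp$amplicon_id)))
  idx <- (h + cumsum(rep(7L, len))) %% 4L + 1L
  s <- paste(c("A", "C", "G", "T")[idx], collapse = "")
  np <- nchar(amp$fwd_primer)
  s <- paste0(amp$fwd_primer, substr(s, np + 1L, len))
  ref <- amp$variants$ref[amp$variants$vtype == "SNV"]
  off <- amp$variants$pos[amp$variants$vtype == "SNV"] - amp$start + 1L
  for (k in seq_along(off)) substr(s, off[k], off[k]) <- ref[k]
  s
}

#' Simulate allele counts directly (aggregate read simulator)
#'
#' Marginally equivalent to [simulate_panel_reads()] followed by
#' base-quality-filtered allele counting, but draws the per-site allele
#' counts from the corresponding multinomial instead of materializing
#' individual reads. This is the scalable path for thousand-cell
#' simulations; only reads at the high point of the quality mixture
#' (q37, passing the minBQ 30 filter) are counted.
#'
#' @inheritParams simulate_panel_reads
#' @return `list(counts, truth)`; `counts` is an allele-count table with
#'   columns cell_id, amplicon_id, variant_id, gene, molecule, n_ref,
#'   n_alt, n_other, coverage, af.
#' @export
simulate_panel_counts <- function(cfg, genotypes = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  vinfo <- panel_variants(cfg$panel)
  vids <- unique(vinfo$variant_id)
  gt <- resolve_genotypes(genotypes, cfg$n_cells, vids)
  cells <- sprintf("cell%04d", seq_len(cfg$n_cells))
  blanks <- if (cfg$n_blanks > 0) sprintf("blank%03d", seq_len(cfg$n_blanks))
            else character(0)
  rownames(gt) <- cells
  e <- cfg$seq_error_rate

  all_ids <- c(cells, blanks)
  grid <- expand.grid(cid = seq_along(all_ids), j = seq_len(nrow(vinfo)),
                      KEEP.OUT.ATTRS = FALSE)
  # variant-major order so each cell's sites are contiguous
  grid <- grid[order(grid$cid, grid$j), ]
  cid <- all_ids[grid$cid]
  is_blank <- grid$cid > length(cells)
  vi <- vinfo[grid$j, ]
  nr <- nrow(grid)

  depth <- stats::rpois(nr, ifelse(is_blank, cfg$contamination_mean,
                                   cfg$depth_mean))
  covq <- stats::rbinom(nr, depth, cfg$qual_high_prob)

  geno <- rep("WT", nr)
  geno[!is_blank] <- gt[cbind(grid$cid[!is_blank],
                              match(vi$variant_id[!is_blank], vids))]
  p_alt <- ifelse(geno == "HOM", 1, ifelse(geno == "HET", 0.5, 0))
  # per-molecule-pool allelic dropout: one of the two copies is lost
  ado <- !is_blank & stats::runif(nr) < cfg$ado_prob
  lost_copy_alt <- stats::runif(nr) < p_alt     # copy sampled prop. to pool
  dropped <- ifelse(ado, ifelse(lost_copy_alt, "alt", "ref"), NA)
  p_alt[ado & geno == "HET"] <-
    ifelse(dropped[ado & geno == "HET"] == "alt", 0, 1)

  # sequencing error moves a base to one of the 3 other bases
  p_obs_alt <- p_alt * (1 - e) + (1 - p_alt) * e / 3
  p_obs_ref <- (1 - p_alt) * (1 - e) + p_alt * e / 3
  n_alt <- stats::rbinom(nr, covq, p_obs_alt)
  n_ref <- stats::rbinom(nr, covq - n_alt,
                         p_obs_ref / pmax(1 - p_obs_alt, 1e-300))
  n_other <- covq - n_alt - n_ref

  counts <- data.frame(cell_id = cid, amplicon_id = vi$amplicon_id,
                       variant_id = vi$variant_id, gene = vi$gene,
                       molecule = vi$molecule, n_ref = n_ref,
                       n_alt = n_alt, n_other = n_other,
                       coverage = covq, stringsAsFactors = FALSE)
  den <- counts$n_ref + counts$n_alt
  counts$af <- ifelse(den > 0, counts$n_alt / den, 0)
  rownames(counts) <- NULL
  events <- if (any(ado))
    data.frame(cell_id = cid[ado], amplicon_id = vi$amplicon_id[ado],
               variant_id = vi$variant_id[ado],
               molecule = vi$molecule[ado], genotype = geno[ado],
               dropped_allele = dropped[ado], stringsAsFactors = FALSE)
  else NULL
  list(counts = counts,
       truth = list(genotypes = gt, dropout_events = events,
                    blanks = blanks))
}

#' Simulate a clonal cell population from a mutation tree
#'
#' Cells attach uniformly (or with supplied clone frequencies) to the
#' nodes of a rooted mutation tree, including the wild-type root; a cell's
#' true genotype is the set of mutations on its root path. Observation
#' noise follows the tree error model: a true 0 is observed as 1 with
#' probability `fd` (false discovery) and a true 1 as 0 with probability
#' `ad` (allelic dropout); entries are set missing at `missing_rate`.
#'
#' @param parent Named integer parent vector over the m mutation nodes
#'   (0 denotes the wild-type root); see [tree_loglik()].
#' @param n_cells Number of cells.
#' @param fd,ad Error rates in `[0, 0.5)`.
#' @param missing_rate Probability an entry is unobserved.
#' @param clone_freqs Optional attachment probabilities over the m+1 nodes
#'   (root first).
#' @param seed Integer seed.
#' @return `list(matrix, truth)`: the observed cells-by-characters matrix
#'   in {0, 1, NA} and the truth record (attachments, true matrix).
#' @export
simulate_clonal_population <- function(parent, n_cells, fd = 0.001,
                                       ad = 0.01, missing_rate = 0,
                                       clone_freqs = NULL, seed = 1L) {
  validate_parent(parent)
  if (fd < 0 || fd >= 1 || ad < 0 || ad >= 1)
    stop("fd and ad must lie in [0, 1)")
  set.seed(seed)
  m <- length(parent)
  E <- attachment_genotypes(parent)  # (m+1) x m
  probs <- if (is.null(clone_freqs)) rep(1 / (m + 1), m + 1) else {
    stopifnot(length(clone_freqs) == m + 1)
    clone_freqs / sum(clone_freqs)
  }
  att <- sample.int(m + 1L, n_cells, replace = TRUE, prob = probs) - 1L
  true <- E[att + 1L, , drop = FALSE]
  flip <- matrix(stats::runif(n_cells * m), n_cells, m)
  obs <- true
  obs[true == 0 & flip < fd] <- 1L
  obs[true == 1 & flip < ad] <- 0L
  if (missing_rate > 0)
    obs[matrix(stats::runif(n_cells * m), n_cells, m) < missing_rate] <- NA
  dimnames(obs) <- dimnames(true) <-
    list(sprintf("cell%04d", seq_len(n_cells)), names(parent))
  list(matrix = obs,
       truth = list(attachments = att, true_matrix = true,
                    parent = parent, fd = fd, ad = ad))
}

#' Simulate a single-cell expression count matrix
#'
#' Draws gene-by-cell counts from a negative binomial with lognormal
#' per-cell library-size factors and lognormal baseline gene means.
#' Differential genes listed in `de_spec` are shifted by the stated log2
#' effect in the stated genotype group; `hvg_genes` receive extra
#' per-cell multiplicative lognormal noise to inflate their coefficient
#' of variation; `dropout_prob` zeroes counts at a known per-gene rate.
#' All injected structure is recorded in the truth log.
#'
#' @param seed Integer seed.
#' @param labels Per-cell genotype/group labels.
#' @param n_genes Number of genes (>= 100).
#' @param de_spec Optional `data.frame(gene, log2_effect, group)`; `gene`
#'   indexes rows, `group` must be a level of `labels`.
#' @param libsize_lognormal `(meanlog, sdlog)` of the per-cell size
#'   factors (normalized to mean 1).
#' @param base_mean_lognormal `(meanlog, sdlog)` of baseline gene means.
#' @param dispersion Negative-binomial size parameter.
#' @param hvg_genes Optional integer vector of genes given inflated
#'   variance.
#' @param hvg_sdlog sdlog of the extra noise factor for `hvg_genes`.
#' @param dropout_prob Per-gene dropout probability (scalar or vector).
#' @return `list(counts, truth)`.
#' @export
simulate_expression <- function(seed, labels, n_genes = 2000L,
                                de_spec = NULL,
                                libsize_lognormal = c(0, 0.3),
                                base_mean_lognormal = c(log(5), 1.2),
                                dispersion = 2,
                                hvg_genes = integer(0), hvg_sdlog = 1,
                                dropout_prob = 0) {
  if (n_genes < 100L) stop("n_genes must be >= 100")
  n_cells <- length(labels)
  if (!is.null(de_spec)) {
    if (length(unique(labels)) < 2L)
      stop("de_spec requires at least two genotype groups")
    if (!all(de_spec$group %in% labels))
      stop("unknown genotype label in de_spec")
  }
  set.seed(seed)
  sf <- stats::rlnorm(n_cells, libsize_lognormal[1], libsize_lognormal[2])
  sf <- sf / mean(sf)
  mu0 <- stats::rlnorm(n_genes, base_mean_lognormal[1],
                       base_mean_lognormal[2])
  mu <- outer(mu0, sf)
  if (!is.null(de_spec))
    for (k in seq_len(nrow(de_spec))) {
      g <- de_spec$gene[k]
      idx <- labels == de_spec$group[k]
      mu[g, idx] <- mu[g, idx] * 2^de_spec$log2_effect[k]
    }
  if (length(hvg_genes)) {
    noise <- matrix(stats::rlnorm(length(hvg_genes) * n_cells,
                                  -hvg_sdlog^2 / 2, hvg_sdlog),
                    length(hvg_genes), n_cells)
    mu[hvg_genes, ] <- mu[hvg_genes, ] * noise
  }
  counts <- matrix(stats::rnbinom(n_genes * n_cells, mu = mu,
                                  size = dispersion), n_genes, n_cells)
  dropout_prob <- rep(dropout_prob, length.out = n_genes)
  if (any(dropout_prob > 0)) {
    drop <- matrix(stats::runif(n_genes * n_cells), n_genes, n_cells) <
      dropout_prob
    counts[drop] <- 0L
  }
  dimnames(counts) <- list(sprintf("gene%04d", seq_len(n_genes)),
                           sprintf("cell%04d", seq_len(n_cells)))
  list(counts = counts,
       truth = list(de_spec = de_spec, hvg_genes = hvg_genes,
                    size_factors = sf, base_means = mu0,
                    dropout_prob = dropout_prob, labels = labels))
}

#' Write simulated reads as FASTQ
#'
#' @param sequences Read table with `read_id`, `seq` and `qual` columns
#'   (see [simulate_panel_reads()] with `sequences = TRUE`).
#' @param path Output file.
#' @export
write_reads_fastq <- function(sequences, path) {
  qual_chr <- vapply(sequences$qual, function(q)
    paste(rep(rawToChar(as.raw(q + 33L)), 1L), collapse = ""), character(1))
  qline <- mapply(function(q, s) strrep(q, nchar(s)), qual_chr,
                  sequences$seq)
  writeLines(as.vector(rbind(paste0("@", sequences$read_id),
                             sequences$seq, "+", qline)), path)
  invisible(path)
}
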