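#' Demultiplex amplicon reads by forward-primer match
#'
#' Assigns each read to the unique amplicon whose forward primer matches
#' the read's 5' end within the allowed mismatch budget. Matching is
#' 5'-anchored (no scanning): amplicon reads begin at their primer, and
#' scanning would invite chimera misassignment. Reads matching no primer
#' are tallied as unassigned; a read matching two primers raises an
#' ambiguity error naming the offending primer pair.
#'
#' @param sequences Read table with columns `cell_id`, `read_id`, `seq`
#'   (and optionally `qual`).
#' @param panel An [amplicon_panel()].
#' @param max_mismatch Mismatch budget for the primer prefix (default 1).
#' @return `list(assigned, unassigned)`: `assigned` is the input with an
#'   `amplicon_id` column; `unassigned` the discarded reads.
#' @export
demux_reads <- function(sequences, panel, max_mismatch = 1L) {
  n <- nrow(sequences)
  mm <- matrix(NA_integer_, n, length(panel),
               dimnames = list(NULL, names(panel)))
  for (aid in names(panel)) {
    p <- panel[[aid]]$fwd_primer
    L <- nchar(p)
    pref <- substr(sequences$seq, 1L, L)
    pc <- strsplit(p, "")[[1]]
    ok <- nchar(pref) == L
    d <- rep(NA_integer_, n)
    if (any(ok)) {
      M <- matrix(unlist(strsplit(pref[ok], ""), use.names = FALSE), nrow = L)
      d[ok] <- colSums(M != pc)
    }
    mm[, aid] <- d
  }
  hit <- !is.na(mm) & mm <= max_mismatch
  nhit <- rowSums(hit)
  if (any(nhit > 1L)) {
    i <- which(nhit > 1L)[1]
    pair <- colnames(mm)[hit[i, ]][1:2]
    stop(sprintf(
      "ambiguous primer match: read '%s' matches primers of '%s' and '%s'",
      sequences$read_id[i], pair[1], pair[2]))
  }
  assigned <- sequences[nhit == 1L, , drop = FALSE]
  assigned$amplicon_id <- colnames(mm)[apply(hit[nhit == 1L, , drop = FALSE],
                                             1, which)]
  list(assigned = assigned,
       unassigned = sequences[nhit == 0L, , drop = FALSE])
}

#' Count alleles at a variant site in one read group
#'
#' Tallies reads supporting the reference, alternate or a third allele at
#' one target site within a single (cell, amplicon) read group, keeping
#' only bases with quality at or above `min_base_quality` (default 30).
#' Overlapping mates are deduplicated by read/fragment id, keeping the
#' higher-quality observation on disagreement; orphan reads are included.
#' The allele fraction AF uses denominator `n_ref + n_alt` (third alleles
#' excluded) and is 0 when that denominator is 0. A site covered by no
#' read yields coverage 0, not an error.
#'
#' Read groups may carry either an `allele` column (the aligned-TSV
#' dialect: observed allele string at the site) or a `seq` column plus
#' amplicon coordinates, from which the base at the site is extracted
#' (SNV sites only on the sequence path).
#'
#' @param group Read group `data.frame`.
#' @param site One-row variant `data.frame` (see [variant_site()]).
#' @param amplicon The `amplicon_spec` the group belongs to (required on
#'   the sequence path for the site offset).
#' @param min_base_quality Minimum base quality (Phred).
#' @return One-row `data.frame`: n_ref, n_alt, n_other, coverage, af.
#' @export
count_alleles <- function(group, site, amplicon = NULL,
                          min_base_quality = 30L) {
  if (nrow(group) == 0L)
    return(data.frame(n_ref = 0L, n_alt = 0L, n_other = 0L,
                      coverage = 0L, af = 0))
  if (!"allele" %in% names(group)) {
    if (is.null(amplicon)) stop("sequence path requires the amplicon spec")
    if (site$vtype != "SNV")
      stop("sequence path supports SNV sites only")
    off <- site$pos - amplicon$start + 1L
    group$allele <- substr(group$seq, off, off)
  }
  # one observation per fragment: keep the higher-quality base
  o <- order(group$read_id, -group$qual)
  group <- group[o, , drop = FALSE]
  group <- group[!duplicated(group$read_id), , drop = FALSE]
  group <- group[group$qual >= min_base_quality, , drop = FALSE]
  n_ref <- sum(group$allele == site$ref)
  n_alt <- sum(group$allele == site$alt)
  n_other <- nrow(group) - n_ref - n_alt
  den <- n_ref + n_alt
  data.frame(n_ref = n_ref, n_alt = n_alt, n_other = n_other,
             coverage = nrow(group), af = if (den > 0) n_alt / den else 0)
}

#' Allele counts for all cells, amplicons and sites
#'
#' Applies [count_alleles()] across a full read table in the aligned-TSV
#' dialect (columns `cell_id`, `read_id`, `amplicon_id`, `variant_id`,
#' `allele`, `qual`), returning one row per (cell, amplicon, variant).
#' Cell/amplicon pairs with no reads are emitted with coverage 0 when
#' `cells` is supplied.
#'
#' @param reads Read table.
#' @param panel An [amplicon_panel()].
#' @param min_base_quality Minimum base quality.
#' @param cells Optional vector of cell ids to force into the output.
#' @return Allele-count table with columns cell_id, amplicon_id,
#'   variant_id, gene, molecule, n_ref, n_alt, n_other, coverage, af.
#' @export
count_alleles_all <- function(reads, panel, min_base_quality = 30L,
                              cells = NULL) {
  vinfo <- panel_variants(panel)
  if (is.null(cells)) cells <- unique(reads$cell_id)
  out <- vector("list", length(cells) * nrow(vinfo))
  n <- 0L
  key <- paste(reads$cell_id, reads$amplicon_id, reads$variant_id)
  groups <- split(seq_len(nrow(reads)), key)
  for (cid in cells) for (j in seq_len(nrow(vinfo))) {
    vi <- vinfo[j, ]
    idx <- groups[[paste(cid, vi$amplicon_id, vi$variant_id)]]
    site <- panel[[vi$amplicon_id]]$variants[
      panel[[vi$amplicon_id]]$variants$variant_id == vi$variant_id, ]
    ac <- count_alleles(reads[idx, , drop = FALSE], site,
                        panel[[vi$amplicon_id]], min_base_quality)
    n <- n + 1L
    out[[n]] <- cbind(data.frame(cell_id = cid,
                                 amplicon_id = vi$amplicon_id,
                                 variant_id = vi$variant_id, gene = vi$gene,
                                 molecule = vi$molecule,
                                 stringsAsFactors = FALSE), ac)
  }
  res <- do.call(rbind, out[seq_len(n)])
  rownames(res) <- NULL
  res
}

#' Split an allele-count table by molecule class
#'
#' Partitions counts into gDNA- and mRNA-derived tables keyed by
#' (cell, gene, variant); a gene assayed by both amplicon classes appears
#' in both tables. Row counts are conserved.
#'
#' @param counts Allele-count table (see [count_alleles_all()]).
#' @return `list(gDNA, mRNA)`.
#' @export
split_by_molecule <- function(counts) {
  if (!"molecule" %in% names(counts) || anyNA(counts$molecule))
    stop("every amplicon must carry a declared molecule class")
  bad <- setdiff(unique(counts$molecule), c("gDNA", "mRNA"))
  if (length(bad))
    stop(sprintf("unknown molecule class: %s", paste(bad, collapse = ", ")))
  list(gDNA = counts[counts$molecule == "gDNA", , drop = FALSE],
       mRNA = counts[counts$molecule == "mRNA", , drop = FALSE])
}

#' Write / read an allele-count table as TSV
#'
#' @param counts Allele-count table.
#' @param path File path.
#' @export
write_counts_tsv <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
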