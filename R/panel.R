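#' Define a target variant site
#'
#' A variant site is a 1-based genomic position with a reference and an
#' alternate allele. SNVs have single-base alleles; indels have alleles of
#' different lengths, left-normalized and anchored at the base before the
#' event. Sites flagged `zygosity_critical` are subject to the
#' not-determined (ND) allele-frequency window during molecule calling.
#'
#' @param variant_id Unique identifier (conventionally the gene symbol when
#'   a gene carries a single target mutation).
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @param ref,alt Reference and alternate allele strings (uppercase ACGT).
#' @param zygosity_critical Logical; apply the ND window to this site.
#' @return A one-row `data.frame` describing the site.
#' @export
variant_site <- function(variant_id, chrom, pos, ref, alt,
                         zygosity_critical = FALSE) {
  stopifnot(is.character(ref), is.character(alt), nchar(ref) >= 1L,
            nchar(alt) >= 1L, pos >= 1L)
  if (!grepl("^[ACGT]+$", ref) || !grepl("^[ACGT]+$", alt))
    stop("alleles must be uppercase ACGT strings")
  vtype <- if (nchar(ref) == 1L && nchar(alt) == 1L) "SNV"
           else if (nchar(alt) > nchar(ref)) "insertion" else "deletion"
  if (vtype != "SNV" && nchar(ref) == nchar(alt))
    stop("indel alleles must differ in length")
  data.frame(variant_id = variant_id, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, vtype = vtype,
             zygosity_critical = zygosity_critical,
             stringsAsFactors = FALSE)
}

#' Define a targeted amplicon
#'
#' An amplicon is a primer-delimited PCR product assaying one or more
#' variant sites, derived either from genomic DNA (gDNA; primers anchored
#' in an intron) or from reverse-transcribed mRNA (cDNA). Coordinates are
#' 1-based inclusive.
#'
#' @param amplicon_id Unique identifier.
#' @param gene Gene symbol.
#' @param molecule `"gDNA"` or `"mRNA"`.
#' @param fwd_primer,rev_primer Primer sequences (uppercase ACGT).
#' @param chrom,start,end Amplicon interval, 1-based inclusive.
#' @param variants `data.frame` of variant sites (see [variant_site()]);
#'   every site must lie within `[start, end]`.
#' @return An object of class `amplicon_spec`.
#' @export
amplicon_spec <- function(amplicon_id, gene, molecule, fwd_primer,
                          rev_primer, chrom, start, end, variants) {
  molecule <- match.arg(molecule, c("gDNA", "mRNA"))
  if (!nzchar(fwd_primer) || !nzchar(rev_primer) ||
      !grepl("^[ACGT]+$", fwd_primer) || !grepl("^[ACGT]+$", rev_primer))
    stop("primers must be non-empty uppercase ACGT strings")
  stopifnot(start >= 1L, end >= start)
  if (any(variants$pos < start | variants$pos > end))
    stop(sprintf("variant outside amplicon interval for '%s'", amplicon_id))
  structure(list(amplicon_id = amplicon_id, gene = gene,
                 molecule = molecule, fwd_primer = fwd_primer,
                 rev_primer = rev_primer, chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 variants = variants),
            class = "amplicon_spec")
}

#' Assemble an amplicon panel
#'
#' @param ... `amplicon_spec` objects.
#' @return An object of class `amplicon_panel` (a named list of amplicons).
#' @export
amplicon_panel <- function(...) {
  amps <- list(...)
  if (length(amps) == 1L && is.list(amps[[1]]) &&
      !inherits(amps[[1]], "amplicon_spec"))
    amps <- amps[[1]]
  if (!length(amps)) stop("panel must contain at least one amplicon")
  if (!all(vapply(amps, inherits, logical(1), "amplicon_spec")))
    stop("all panel entries must be amplicon_spec objects")
  ids <- vapply(amps, `[[`, character(1), "amplicon_id")
  if (anyDuplicated(ids)) stop("duplicate amplicon ids in panel")
  names(amps) <- ids
  structure(amps, class = "amplicon_panel")
}

#' @export
print.amplicon_panel <- function(x, ...) {
  cat(sprintf("Amplicon panel: %d amplicons, %d variant sites\n",
              length(x), nrow(panel_variants(x))))
  for (a in x)
    cat(sprintf("  %-12s %-6s %-4s %s:%d-%d (%d variant%s)\n",
                a$amplicon_id, a$gene, a$molecule, a$chrom, a$start, a$end,
                nrow(a$variants), if (nrow(a$variants) == 1L) "" else "s"))
  invisible(x)
}

#' Table of all variant sites in a panel
#'
#' @param panel An `amplicon_panel`.
#' @return `data.frame` with one row per (amplicon, variant) pair; the
#'   deduplicated variant list (one row per `variant_id`) is available via
#'   `unique = TRUE`.
#' @param unique Collapse to one row per variant id.
#' @export
panel_variants <- function(panel, unique = FALSE) {
  out <- do.call(rbind, lapply(panel, function(a) {
    cbind(amplicon_id = a$amplicon_id, gene = a$gene, molecule = a$molecule,
          a$variants, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (unique)
    out <- out[!duplicated(out$variant_id),
               c("variant_id", "gene", "chrom", "pos", "ref", "alt",
                 "vtype", "zygosity_critical")]
  out
}

#' Read / write a panel as JSON
#'
#' @param panel An `amplicon_panel`.
#' @param path File path.
#' @return `write_panel_json` returns `path` invisibly; `read_panel_json`
#'   returns an `amplicon_panel`.
#' @export
write_panel_json <- function(panel, path) {
  amps <- lapply(unclass(panel), function(a) {
    a$variants <- a$variants
    a
  })
  jsonlite::write_json(amps, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_panel_json
#' @export
read_panel_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  amps <- lapply(raw, function(a) {
    v <- as.data.frame(a$variants, stringsAsFactors = FALSE)
    amplicon_spec(a$amplicon_id, a$gene, a$molecule, a$fwd_primer,
                  a$rev_primer, a$chrom, a$start, a$end, v)
  })
  amplicon_panel(amps)
}

#' Export / import panel variants as a minimal VCF
#'
#' Writes CHROM, POS, ID, REF and ALT columns of a site-only VCF (v4.2
#' header); all other columns are '.'. The importer reads any VCF carrying
#' at least those columns and ignores genotypes.
#'
#' @param panel An `amplicon_panel`.
#' @param path File path.
#' @export
write_variants_vcf <- function(panel, path) {
  v <- panel_variants(panel, unique = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                     v$chrom, v$pos, v$variant_id, v$ref, v$alt), con)
  invisible(path)
}

#' @rdname write_variants_vcf
#' @export
read_variants_vcf <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  f <- strsplit(ln, "\t", fixed = TRUE)
  do.call(rbind, lapply(f, function(x)
    variant_site(x[3], x[1], as.integer(x[2]), x[4], x[5])))
}

#' Built-in demonstration panel
#'
#' A 12-amplicon panel assaying six recurrently mutated myeloid-malignancy
#' genes, each from both a gDNA and an mRNA amplicon, with one SNV per
#' gene. The JAK2 site is flagged zygosity-critical so the ND window
#' applies. Primer and flanking sequences are synthetic.
#'
#' @return An `amplicon_panel` with 12 amplicons.
#' @export
example_panel <- function() {
  genes <- c("JAK2", "TET2", "ASXL1", "SF3B1", "SRSF2", "EZH2")
  chroms <- c("9", "4", "20", "2", "17", "7")
  pos <- c(5073770L, 106197001L, 31022441L, 198267371L, 74732959L,
           148514471L)
  ref <- c("G", "C", "G", "G", "C", "A")
  alt <- c("T", "T", "A", "T", "T", "G")
  # fixed, mutually distant 20-mers (pairwise Hamming distance >= 8)
  fwd <- c(
    gJAK2  = "ACGTTGCAGGTCAAGTCCTA", mJAK2  = "TGCACCTTAGACGGATTCAG",
    gTET2  = "GATCCAGTTGCTACGAGGTT", mTET2  = "CCTAGGTAACGTGTCAGCAT",
    gASXL1 = "TTGGCACGATACCTGAGTCA", mASXL1 = "AGTCGTTACAGGCATGCTTG",
    gSF3B1 = "CATGGATCGTTGACCATGGA", mSF3B1 = "GGAATTCCAGTCGATACGCT",
    gSRSF2 = "TCAGACGGTATGCCATTGCA", mSRSF2 = "ACCTGTAGCATTGGCAAGTC",
    gEZH2  = "GTTCAGCCTAGTGACATCGA", mEZH2  = "CGATAGGCTTCACTGTAGCA")
  rev_p <- "TACGGTAGCAGAGACTTGGT"
  amps <- list()
  for (i in seq_along(genes)) {
    v <- variant_site(genes[i], chroms[i], pos[i], ref[i], alt[i],
                      zygosity_critical = genes[i] == "JAK2")
    for (mol in c("gDNA", "mRNA")) {
      aid <- paste0(if (mol == "gDNA") "g" else "m", genes[i])
      amps[[aid]] <- amplicon_spec(
        aid, genes[i], mol, unname(fwd[aid]), rev_p, chroms[i],
        pos[i] - 150L, pos[i] + 150L, v)
    }
  }
  amplicon_panel(amps)
}
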