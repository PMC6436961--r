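---
title: "Methods: single-cell amplicon genotyping, clonal trees, and genotype-aware expression statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell amplicon genotyping, clonal trees, and genotype-aware expression statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliclone)
```

This vignette documents the models and procedures implemented in
`ampliclone`, the assumptions behind them, the parameters a user may want
to change, and the choices made where the design was genuinely open.

## 1. Targeted amplicon genotyping

### Read assignment and allele counting

Each panel amplicon is a primer pair assaying one or more variant sites,
classified as **gDNA** (primers anchored in an intron, so the template is
genomic DNA) or **mRNA/cDNA** (exonic primers on reverse-transcribed
transcript). Reads of an amplicon sequencing library begin at the forward
primer, so `demux_reads()` matches the primer as a 5'-anchored prefix
with a configurable mismatch budget (default 1). Anchoring, rather than
scanning the whole read, avoids assigning PCR chimeras to the wrong
amplicon; the budget absorbs a sequencing error in the primer while
keeping well-designed panels (pairwise primer distance well above 2)
unambiguous. A read matching two primers within budget is treated as a
panel-design error, not silently dropped.

`count_alleles()` tallies the base (or indel allele) observed at the
target site per read, keeping bases with Phred quality ≥ 30 (the
`min_base_quality` argument), counting each fragment once — when mates
overlap the site the higher-quality observation wins, which is our
resolution of a rule that standard pileup tools leave unspecified — and
keeping orphan reads. The allele fraction is

AF = n_alt / (n_ref + n_alt),

with third alleles excluded from the denominator so that the ND windows
below retain their meaning at sites with occasional error bases; AF is
defined as 0 when the denominator is 0. Coordinates are 1-based inclusive
throughout, and indels are left-normalized and anchored at the base
before the event.

### Control-calibrated thresholds

Two kinds of control wells calibrate the caller per amplicon:

- **blank (non-template) wells** set the detection floor:
  `detection_min_reads = max(2 × max blank coverage, 30)`;
- **wild-type control cells** set the mutant-AF threshold:
  `mutation_af_min = clamp(2 × max WT alt AF, 0.015, 0.04)`.

The clamp range (1.5–4% of reads) is the operating band of the assay;
the doubling rules are this package's calibration formulas — the
controls define the inputs, and doubling the worst control statistic
gives a margin that scales with the observed background. Both formulas
are deliberately simple, and the control statistics that produced every
threshold are stored next to it (`max_blank_coverage`, `max_wt_af`,
control counts) so any amplicon's thresholds can be audited or
overridden by editing the threshold table.

A minimum coverage of 30 reads per amplicon is always required for a
mutational readout; below it the molecule call is FAIL.

### Molecule calls and the ND window

Given calibrated thresholds, `call_molecule()` applies, in order:
coverage below the detection floor → **FAIL**; for zygosity-critical
sites, AF strictly inside the ND window → **ND**; otherwise both allele
fractions ≥ `mutation_af_min` → **HET**, only the alt fraction → **HOM**,
alt below threshold → **WT**. The HOM/WT boundary applies the mutant
threshold symmetrically to the reference fraction; only the mutant-call
threshold is externally specified, and symmetry is the least-surprising
completion.

The ND ("not determined") window withholds zygosity calls when the AF is
too high for background noise but too low for a confident heterozygous
call — the signature of template imbalance. The windows are mode- and
molecule-specific: gDNA 0.03–0.1 (full-length datasets) or 0.04–0.1
(3'-counting datasets), mRNA 0.03–0.1 (3'-counting datasets); no window
is applied to full-length mRNA, for which no calibrated window is
available. Windows apply only to variants flagged `zygosity_critical`
(in practice, loci like JAK2 where heterozygous versus homozygous status
carries biological meaning); other variants get ordinary calls at the
same AF.

### Integration of gDNA and cDNA calls

`integrate_genotype()` is a total, deterministic function of the
(gDNA, cDNA) call pair:

| gDNA \\ cDNA | FAIL | WT | HET | HOM | ND |
|---|---|---|---|---|---|
| **FAIL** | MISSING | EXCLUDED | HET | EXCLUDED | ND |
| **WT**  | WT  | WT  | HET | HET | WT |
| **HET** | HET | HET | HET | HET | HET |
| **HOM** | HOM | HET | HET | HOM | HOM |
| **ND**  | ND  | WT  | HET | HOM | ND |

The rules: a heterozygous readout on either molecule dominates; a HOM on
one molecule with WT on the other is heterozygous (one template pool
failed to amplify one allele); pure WT and HOM calls are anchored to the
gDNA, because mRNA-only evidence is confounded by allele-specific and
stochastic expression — a cell seen only at the mRNA level (gDNA FAIL)
is EXCLUDED rather than genotyped. An ND molecule is removed from
consideration and the other molecule's readout stands; if the other
molecule is uninformative, the integrated call is ND. ND removal falls
back to the informative molecule (rather than propagating EXCLUDED)
because an ND gDNA amplicon *was* detected — the gene did not drop out,
its zygosity is merely ambiguous.

`qc_cells()` drops a cell only when some targeted gene is undetected on
*both* molecules (integrated MISSING); EXCLUDED is scoped to the variant,
not the cell, which is the conservative reading when exclusion events are
counted per amplicon. Reason codes (`gene_undetected:<GENE>`) are kept
for every dropped cell.

`assign_clones()` groups cells by identical integrated-call vectors.
Clone labels are the panel-ordered `GENE:CALL` pairs joined by `;`, which
makes naming bit-stable across runs. A cell with MISSING entries is
assigned only if exactly one observed complete genotype is consistent
with its non-missing calls; wildcarding against multiple candidates would
silently inflate the largest clone. Clones below both size rules
(< `min_cells` = 5 cells **and** < `min_frac` = 5%) are flagged `minor`
rather than removed, so downstream analyses choose their own rule.

## 2. Clonal-hierarchy inference

The mutation tree model places the m mutation characters at the nodes of
a rooted tree (root = wild type); a cell attaches at any node and carries
exactly the mutations on its root path. Observations are noisy binary
characters with

P(observe 1 | true 0) = fd (false positive),
P(observe 0 | true 1) = ad (allelic dropout),

defaults fd = 0.001, ad = 0.01. The attachment of each cell is
marginalized with a uniform prior over all m+1 nodes (root included),
and the tree score is the sum over cells of the log marginal likelihood.
Missing entries contribute a factor of 1. Everything is computed in log
space with a per-cell log-sum-exp, so matrices with up to ~20 characters
and 10^5 cells are safe from underflow; probabilities are clamped at
1e-300 so degenerate error rates (fd or ad equal to 0) remain finite.

Homozygosity through loss of heterozygosity is handled at the encoding
step: `encode_matrix()` splits an LOH variant into two allele characters
(WT → 0,0; HET → 1,0; HOM → 1,1), so the loss of the wild-type allele is
itself a heritable event the tree can place. The two allele characters
are deliberately *not* constrained to be ancestor and descendant; the
data decide.

`infer_tree()` maximizes the score either exhaustively — all
(m+1)^(m−1) rooted labeled trees via Prüfer-sequence enumeration,
practical to m = 7 — or by a seeded steepest-ascent hill climb over two
move classes: prune-and-reattach of a subtree under any non-descendant,
and pairwise label swaps. Reattach moves alone have deep local optima on
chain topologies (a chain with two labels transposed cannot be repaired
by any single reattachment), which is why the swap class exists. The
default is a single restart, configurable; co-optimal trees (within
`tol = 1e-9` log units) are all returned in lexicographic parent-vector
order, since ties are real on small or noisy data and silently picking
one would overstate certainty. A single hill-climb dropout rate is used
per character; with the LOH allele split, every character is binary and
a single `ad` is the natural parameterization.

`mutation_order()` turns the tree into the statements users actually
want: every (earlier, later) ancestor pair, plus the incomparable pairs
reported as independently acquired (branching).

## 3. Expression statistics

### Normalization and the detection floor

Both normalizations share one convention: normalized values below 1 are
considered non-detected and set to 0 *before* the log2 transform, and no
pseudocount is used, so a stored 0 always means "not detected" and all
stored values are ≥ 0. The floor makes the transform idempotent; its one
ambiguity — a gene at exactly 1 maps to log2 = 0 — is measure-zero in
practice and documented here.

- `rpkm_normalize()`: RPKM = count / (gene length in kb × mapped reads
  in millions), with union-exon gene lengths supplied as a plain table.
- `normalize_3p()`: counts / library size × target, the target defaulting
  to the mean library size of the cells processed. Pre-threshold cell
  sums equal the target exactly (this is asserted in the tests). The
  target is configurable because its natural value is dataset-specific.

### QC filters

`qc_filter()` applies the per-cell filters with strict inequalities
exactly as stated: full-length mode — exonic% > 50, mapped% > 50,
detected genes > `min_genes` (1500 for primary HSPCs; 5000–6000 for cell
lines, set via `min_genes`); 3'-counting mode — library size > 2000,
mitochondrial% < 10, ERCC% < 50 (computed on reads), detected genes
> 500. Every failing criterion is recorded as a reason code; a missing
metric is itself a failure (`metric_missing:<name>`), never silently
passed.

### Variable genes, dropout, bias, ADO

`highly_variable_genes()` computes the per-gene coefficient of variation
on linear-scale values across cells, fits a lowess trend of CV against
log2(mean) (span 0.3, 3 robustifying iterations — defaults, since no
canonical values exist), and selects genes with CV above the trend and
log2(mean) ≥ 0. CV is computed on the linear scale (configurable by
transforming the input) — the convention that keeps CV interpretable as
sd/mean. Degenerate inputs (constant matrix, single mean value) get a
flat trend and therefore an empty selection.

`dropout_frequency()` is the fraction of cells with a post-threshold
zero, per gene of a bulk-expressed reference set. `library_bias()` is
the mean expression of the top `ceil(0.10 × detected)` genes over the
mean of all genes, ties broken by descending value then input order;
it accepts linear or log2 input via `scale`.

`ado_from_het_sites()` estimates allelic dropout at known heterozygous
sites: a cell–site observation with ≥ 10 informative reads is biallelic
iff 0.05 < AF < 0.95, and the ADO rate is the monoallelic fraction among
covered cells. The published het/hom boundary contains an evident
transcription slip (both inequalities pointing down); the implemented
rule is the complement of the heterozygous window.

### Cell cycle, residualization, correlations

`cell_cycle_scores()` averages log2 expression over S-phase and
G2M-phase gene sets (absent members warned and ignored).
`regress_out()` removes covariate effects per gene by OLS, returning
residuals plus the gene mean; covariates are centered internally so the
mean is preserved exactly, and rank-deficient covariate matrices are
refused with the collinear columns named. `group_correlations()` filters
genes to those expressed in ≥ 5 cells globally, returns all within-group
pairwise Pearson correlations, and pairs of groups are compared with a
Kolmogorov–Smirnov test.

## 4. Differential expression

`combined_de_test()` tests, per gene, *how much* (two-sided Wilcoxon
rank-sum on values — exact for small untied samples, normal
approximation with tie and continuity correction otherwise, via
`stats::wilcox.test`) and *how often* (Fisher's exact test on the 2×2
expressed/not × group table). The two p values are combined with
Fisher's method; BH adjustment runs across the genes passing the
inclusion filter (expressed in ≥ 2 cells below 200 analyzed cells, ≥ 5
above — per comparison, which defines the multiple-testing universe).
log2FC is the difference of group means on the log2 matrix, zeros
included, matching the scale all other statistics use. Significance:
adjusted p < 0.1 and |log2FC| > 0.5.

Degenerate inputs are handled by reducing k in Fisher's method: when all
(or no) cells express a gene the frequency table carries no information
and the Wilcoxon p passes through alone; a constant gene leaves no
applicable test and gets combined p = 1. Combination happens before
adjustment — one adjusted p per gene is the quantity the significance
rule consumes.

A calibration note: Fisher's exact test is discrete and conservative, so
with substantial per-gene dropout the combined statistic is conservative
too (its null rejection rate falls below nominal). The null-calibration
check in the acceptance suite therefore uses a fully detected null
matrix, where the combination provably reduces to the Wilcoxon p; with
dropout present, expect conservative (not anticonservative) behavior.

`anova_subclones()` screens genes across ≥ 3 subclones with a one-way
fixed-effects ANOVA computed vectorized from group sums (verified
against `stats::aov` in the tests); constant genes get p = 1 by
convention; selection at p < 0.05.

## 5. What the simulators emulate — and what they do not

`simulate_panel_reads()` / `simulate_panel_counts()` generate
per-cell-per-amplicon Poisson read depths (default mean 2641, the
assay's observed operating depth), per-base sequencing error (default
0.5%) that moves a base to one of the three alternatives uniformly,
per-molecule-pool allelic dropout (one of the two allele copies lost
with probability `ado_prob`, logged in the truth record), a two-point
q37/q10 base-quality mixture (90% high) to exercise the quality filter,
and blank wells receiving Poisson background reads (default mean
5/amplicon) so threshold calibration has non-degenerate input — the
background level in real blanks is not externally specified, and 5 reads
is a realistic low-level contamination figure. The read-level and
count-level generators share one marginal model; the count-level path is
the one used at thousand-cell scale.

`simulate_clonal_population()` attaches cells uniformly (or with given
frequencies) to tree nodes and applies the fd/ad/missing observation
model — exactly the inference model, which is the point: it measures the
estimator, not model misspecification.

`simulate_expression()` draws negative-binomial counts with lognormal
gene means and lognormal per-cell size factors, plus injected DE shifts,
variance-inflated genes, and forced dropout with known rates.

Not emulated: transcript structure and splicing, amplification chimeras
and index hopping, cell doublets, batch effects, zero inflation beyond
the NB + forced dropout, and any dependence of dropout on expression
level. Passing tests therefore demonstrate correctness of the
algorithms under their stated models, not robustness to every artifact
of real libraries.

## 6. Problem sizes and numerical conventions

The validation suite runs, among others: specificity on 874 simulated
control cells + 114 blanks at depth 2641; whole-pipeline genotype
recovery on 1000 cells at depth 500 (recovery must be exact); 50 tree
replicates (m = 4, 200 cells) with exhaustive/hill-climb
cross-validation; brute-force likelihood checks on all trees with m ≤ 3
at tolerance 1e-12; 20 null DE datasets of 2000 genes at n = 100/group;
and estimator-recovery checks at 500 cells. These sizes were chosen so
the full suite completes in about a minute while keeping every binomial
acceptance band meaningful (3 SDs at n ≥ 500).

Conventions collected in one place: coordinates 1-based inclusive; AF
denominator excludes third alleles; probabilities clamped at 1e-300 in
log-space likelihoods; co-optimality tolerance 1e-9 log units with
lexicographic ordering; p values clipped at 1e-300 before Fisher's
method; top-10% gene count `ceil(0.10 × detected)` with
value-then-input-order tie-break; clone labels in panel order.

## 7. Limitations

- Calls depend on calibration quality: with few control wells the
  doubled-maximum rules are noisy (a warning fires below 10 controls per
  amplicon).
- The tree model assumes infinite sites (a mutation arises once, never
  reverts) and uniform attachment; doublets and copy-number events are
  out of scope, and the search mode, while validated against exhaustive
  enumeration at small m, carries no global-optimality guarantee at
  large m.
- The combined DE test is conservative under heavy dropout (see §4) and,
  like any two-group test on normalized data, inherits whatever
  batch/covariate structure was not removed upstream.
- BAM input is not parsed; reads enter as FASTQ-derived sequences or the
  aligned tabular dialect produced by the simulators and upstream
  pipelines.
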