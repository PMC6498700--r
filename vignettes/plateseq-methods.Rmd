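---
title: "plateseq: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plateseq: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The preprocessing model

Plate-based UMI protocols (CEL-Seq, CEL-Seq2, SORT-seq) pool wells into one
sequencing library. Read 1 of each pair carries a fixed-position cell
barcode identifying the well and a unique molecular identifier (UMI)
marking the reverse-transcribed mRNA molecule; read 2 is the transcript
sequence, 3'-biased and strand-preserving. Preprocessing must therefore
(i) route each read pair back to its well, (ii) protect the barcode/UMI
bases that all downstream identity decisions depend on, (iii) assign each
aligned read to at most one gene, and (iv) count *molecules*, not reads, by
collapsing reads that share a (cell, gene, UMI) triple.

`plateseq` implements this as five composable stages
(`demultiplex_run()`, `align_cells()`, `load_gene_models()` +
`count_experiment()`, `build_qc_table()`/plotting, `tenx_bamqc()`), plus a
first-class synthetic-data generator used by the test suite.

# Demultiplexing

**Quality rule.** "Reads below a Phred threshold are removed" is
interpreted strictly: *every* base of the barcode *and* the UMI must reach
`min_phred` (default 10). One corrupt UMI base silently inflates molecule
counts, so the minimum-base rule is the safe default; a `quality_rule =
"mean"` switch exposes the laxer mean-quality alternative for users who
want it.

**Barcode matching.** Whitelist matching uses Hamming distance (plate
barcodes are fixed-length; indels would shift the read frame and are not a
realistic error mode here). A read is assigned to the *unique* whitelist
entry at minimal distance `d <= max_mismatch` (default 1). Two entries
tying at the minimal qualifying distance make the read `ambiguous`, which
is rejected and tallied separately rather than broken arbitrarily —
misassignment contaminates another cell, whereas rejection only loses one
read. `N` bases count as mismatches against everything. This
unique-nearest-with-tie-rejection rule is a documented interpretation: the
alternative (accept any within-threshold entry) is not well defined when
several qualify.

**Filter order.** Quality is evaluated before whitelist matching, so a pair
failing both is counted `low_quality`; the four stat buckets
(`assigned`, `low_quality`, `unmatched`, `ambiguous`) partition the input
exactly, and this conservation is asserted on every run. Read-1 records
shorter than the layout span have no bucket of their own and are counted
`low_quality` (their barcode/UMI bases are unreadable); this keeps the
partition total and is documented on `demultiplex_run()`.

**UMI transport.** The UMI is appended to the whitespace-free read id as
`<id>:UMI:<seq>`. Any aligner that preserves read names therefore
transports the UMI for free; `align_cells()` verifies the tag survived and
aborts if an aligner strips names, because counting without UMIs would be
silently wrong. Phred offset defaults to 33 (modern instruments) with a 64
option for legacy data.

# Gene models and union-mode assignment

`load_gene_models()` consumes only `exon` features of a GTF (Ensembl
attribute dialect; GENCODE's `gene_type` spelling is tolerated). Per gene,
the exon union is the minimal disjoint cover of all exons of all its
transcripts, with touching intervals merged; per-transcript structure is
kept for isoform plotting. Overlapping genes are never merged across
`gene_id`s, and genes on opposite strands are indexed independently —
strandedness is a counting policy, not an annotation property.

Assignment follows featureCounts-style union mode: CIGAR reference blocks
(`M/=/X/D` consume reference, `N` splits blocks, `S/I/H` consume nothing)
are intersected with the exon-union index; candidate genes must overlap
some block by at least one base and be strand-compatible under
`strand_mode`. Exactly one candidate: `assigned`; zero: `no_feature`; two
or more: `ambiguous` and discarded. The default `strand_mode = "sense"`
matches CEL-Seq chemistry, which preserves the mRNA strand; `antisense`
and `unstranded` cover other chemistries. Secondary and supplementary
records are skipped (tallied, never counted) to avoid double counting.

Classification decisions: mitochondrial genes are those on a mitochondrial
chromosome name (`MT`, `chrM`, `mt`, configurable) or with a `mt-` gene
name prefix; protein-coding means `gene_biotype == "protein_coding"`
exactly; spike-ins are flagged by gene-id prefix (default `ERCC-`).
Spike-in genes are counted in the matrix but excluded from
`total_umis`, mitochondrial/protein-coding summaries and `genes_detected`,
since controls are analysed separately.

# UMI deduplication

The reported count for (gene, cell) is the number of *distinct* UMI
strings among that gene's assigned reads — per gene, not genome-wide, so
the same UMI under two genes counts twice. UMIs containing `N` are kept as
literal strings; the quality filter already guards UMI fidelity, and
treating `N` as a wildcard would make counts depend on processing order.

"Corrected" UMI counts use the directional single-pass collapse: distinct
UMIs are visited by decreasing read support (ties broken lexicographically
for determinism); a UMI is absorbed when an already-kept UMI is within
Hamming distance 1 and has at least twice its support. This differs
slightly from the `2n - 1` threshold popularised by UMI-tools; the simpler
`2n` rule is used here and is isolated in one function
(`umi_clusters()`) should a user want the other convention. Deliberately,
correction feeds only the reads-per-corrected-UMI QC metrics — the count
matrix itself uses raw distinct-UMI counts, because the matrix definition
is "number of unique UMIs" while correction is a QC refinement whose exact
form is a matter of convention.

Metrics with undefined denominators (a cell with zero reads or zero UMIs)
report 0 and raise `qc_flag`, keeping the QC table rectangular.

# Visualization

All plot builders are pure functions returning data frames
(`qc_plot_data()`, `rview_data()`, `gview_data()`), so tests assert on
plot *data*, never on rendered pixels; renderers only consume builder
output. QC boxplots use 1.5×IQR whiskers with all cells overlaid as
points (fixed jitter seed). Track views use 1-based display coordinates
(genome-browser convention) although all internal data are 0-based
half-open. Reads are drawn as one arrow per read spanning its leftmost to
rightmost aligned base — a spliced read is a single arrow, which keeps the
display compact; drawing split blocks joined by a line would be the main
alternative and is noted as such. Arrow colour is a deterministic hash of
the UMI string into a fixed palette, so identical UMIs share colour across
figures and across sessions. Row packing is greedy first-fit, which
guarantees no within-row collisions and at most one row per read.

# Cell Ranger BAM QC

`tenx_bamqc()` reads the corrected cell barcode from the `CB` tag (falling
back to raw `CR` with a warning) and treats the presence of a `GX` tag
(fallback `GN`) as gene assignment — Cell Ranger's documented conventions.
Only primary, mapped records are counted; each read counts once. Records
from barcodes outside the filtered list are dropped, never reassigned, and
listed barcodes absent from the BAM yield explicit zero rows so cohorts
stay rectangular across runs.

# The synthetic world

`simulate_run()` is the package's stated test world, not a tunable dial.
Defaults: 20 genes × 12 cells, 1–3 transcripts per gene with 2–4 exons of
120–300 bp, Poisson(2) molecules per gene per cell, duplication factor 3,
UMI length 6, barcode length 8 (pairwise distance ≥ 2·`max_mismatch`+1 so
matching is never ambiguous between true barcodes), constant base quality
37, zero error rates unless asked. This yields roughly 1,500 read pairs —
small enough that the full pipeline runs in seconds, large enough that
every gene class (plus mitochondrial and spike-in contigs) is exercised.

Three demultiplexing fates can be injected per read: `bc_error` replaces
`max_mismatch + 1` barcode bases with `N`, making the read unmatched
against *every* whitelist entry by construction (mutating real bases could
land within threshold of another barcode and misassign); `umi_error`
substitutes one UMI base; `low_quality` drops one barcode/UMI base below
`min_phred`. Fates are drawn once and recorded in `per_read_truth`, so
every downstream expectation is exact bookkeeping, not a statistical
claim. Similarly `simulate_alignments()` can divert recorded fractions of
reads to unmapped, ambiguous (spliced across two adjacent same-strand
genes — the reference generator forces the first two main-chromosome genes
onto `+` to guarantee such a pair exists) or intronic records.

True UMIs are drawn *without replacement* within each (cell, gene), so
error-free truth recovery is exact; real data can collide, but at 4^6
UMIs and Poisson(2) molecules the probability is negligible, and making
recovery exact is what lets the acceptance tests assert equality rather
than approximation. What the generator deliberately does **not** emulate:
realistic expression distributions (no negative binomial), position- or
context-dependent sequencing error, indels, droplet (10x) reads, doublets
or ambient RNA. A green pipeline test therefore establishes correctness of
the bookkeeping and counting logic under the stated error model — not
robustness to every artefact of real libraries.

# Numerical and degenerate-input conventions

* Counts are integers throughout; fractional molecule counts do not exist.
* The count-matrix TSV dialect is fixed (UTF-8, tabs, Unix newlines, no
  quoting, gene rows in GTF encounter order, cell columns in whitelist
  order) so outputs are byte-reproducible; the same inputs always produce
  byte-identical per-cell FASTQ, matrix and stats files.
* Empty cells get empty (but present) FASTQ and alignment entries; failed
  cells get zero matrix columns plus a flag rather than aborting the run.
* `exon_union()` rejects empty intervals (`start >= end`); readers report
  the offending line number for ragged, non-integer, negative or
  duplicated entries.

# Known limitations

No barcode-list inference (knee-point calling), no indel-aware barcode
correction, no isoform-level quantification, no UMI graph methods beyond
the directional collapse, no built-in aligner (by design — alignment is a
pluggable contract), and GFF3 is not parsed (GTF only).
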