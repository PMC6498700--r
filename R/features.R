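#' Merge half-open intervals into their minimal disjoint cover
#'
#' Intervals are 0-based half-open `[start, end)`; touching intervals (for
#' example `[0,5)` and `[5,10)`) are merged. This is the substrate for
#' per-gene exon unions.
#'
#' @param intervals two-column numeric matrix (start, end), `start < end`.
#' @return two-column integer matrix, sorted and disjoint.
#' @export
exon_union <- function(intervals) {
  intervals <- matrix(as.numeric(intervals), ncol = 2)
  if (nrow(intervals) == 0)
    return(matrix(integer(), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  if (any(intervals[, 1] >= intervals[, 2]))
    stop("invalid interval: start must be < end")
  # IRanges is 1-based closed: [s,e) -> [s+1, e]; reduce merges touching runs
  ir <- IRanges::reduce(IRanges::IRanges(start = intervals[, 1] + 1L,
                                         end = intervals[, 2]))
  out <- cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  storage.mode(out) <- "integer"
  out
}

# 0-based half-open matrix -> GRanges (1-based closed); single boundary helper
blocks_to_granges <- function(chrom, blocks, strand = "*") {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = blocks[, 1] + 1L, end = blocks[, 2]),
    strand = strand)
}

#' Load gene models from a GTF annotation
#'
#' Consumes only `exon` features. Per gene, the exon union is the merge of
#' all exon intervals of all its transcripts; per-transcript exon structure
#' is retained for isoform plotting. Coordinates are converted from GTF's
#' 1-based inclusive convention to 0-based half-open. Spike-in controls are
#' flagged by gene-id prefix (ERCC by default); mitochondrial genes by
#' chromosome name or gene-name prefix.
#'
#' @param gtf_path GTF file (Ensembl attribute dialect; GENCODE tolerated).
#' @param spike_prefix gene-id prefix marking spike-in controls.
#' @param mito_chroms chromosome names considered mitochondrial.
#' @param mito_name_prefix gene-name prefix also marking mitochondrial genes.
#' @return An object of class `gene_models`: `genes` (data.frame in GTF
#'   encounter order: `gene_id`, `gene_name`, `biotype`, `chrom`, `strand`,
#'   `is_spike_in`, `is_mito`), `exon_union` (named list of 0-based
#'   half-open interval matrices), `transcripts` (per gene, named list of
#'   exon matrices), and an internal interval index.
#' @export
load_gene_models <- function(gtf_path, spike_prefix = "ERCC-",
                             mito_chroms = c("MT", "chrM", "mt"),
                             mito_name_prefix = "mt-") {
  validate_gtf(gtf_path)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) stop("GTF contains no exon features: ", gtf_path)
  meta <- S4Vectors::mcols(gr)
  gene_id <- as.character(meta$gene_id)
  tx_id <- as.character(meta$transcript_id)
  gene_name <- if ("gene_name" %in% names(meta))
    as.character(meta$gene_name) else gene_id
  gene_name[is.na(gene_name)] <- gene_id[is.na(gene_name)]
  biotype <- if ("gene_biotype" %in% names(meta))
    as.character(meta$gene_biotype)
  else if ("gene_type" %in% names(meta))  # GENCODE spelling
    as.character(meta$gene_type)
  else rep(NA_character_, length(gr))

  ord <- unique(gene_id)  # encounter order
  first <- match(ord, gene_id)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  genes <- data.frame(
    gene_id = ord,
    gene_name = gene_name[first],
    biotype = biotype[first],
    chrom = chrom[first],
    strand = strand[first],
    stringsAsFactors = FALSE)
  genes$is_spike_in <- startsWith(genes$gene_id, spike_prefix)
  genes$is_mito <- genes$chrom %in% mito_chroms |
    startsWith(genes$gene_name, mito_name_prefix)

  st0 <- GenomicRanges::start(gr) - 1L  # to 0-based half-open
  en0 <- GenomicRanges::end(gr)
  eu <- lapply(ord, function(g) {
    sel <- gene_id == g
    exon_union(cbind(st0[sel], en0[sel]))
  })
  names(eu) <- ord
  tx <- lapply(ord, function(g) {
    sel <- which(gene_id == g)
    split_tx <- split(sel, tx_id[sel])
    lapply(split_tx, function(i) {
      m <- cbind(start = st0[i], end = en0[i])
      m[order(m[, 1]), , drop = FALSE]
    })
  })
  names(tx) <- ord

  # interval index: one GRanges over all exon-union intervals
  n_iv <- vapply(eu, nrow, integer(1))
  idx <- GenomicRanges::GRanges(
    seqnames = rep(genes$chrom, n_iv),
    ranges = IRanges::IRanges(
      start = unlist(lapply(eu, function(m) m[, 1])) + 1L,
      end = unlist(lapply(eu, function(m) m[, 2]))),
    strand = rep(genes$strand, n_iv))
  idx$gene_id <- rep(genes$gene_id, n_iv)

  structure(list(genes = genes, exon_union = eu, transcripts = tx,
                 index = idx, spike_prefix = spike_prefix,
                 mito_chroms = mito_chroms),
            class = "gene_models")
}

# cheap structural scan so errors carry line numbers; real parse is
# delegated to rtracklayer
validate_gtf <- function(path) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9)
      stop(sprintf("GTF line %d: expected 9 tab-separated fields", i))
    if (f[3] != "exon") next
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e) || e < s)
      stop(sprintf("GTF line %d: exon end < start", i))
    if (!grepl("gene_id", f[9], fixed = TRUE))
      stop(sprintf("GTF line %d: exon lacks gene_id attribute", i))
  }
  invisible(TRUE)
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes (%d spike-in, %d mitochondrial) on %d sequence(s)\n",
              nrow(x$genes), sum(x$genes$is_spike_in), sum(x$genes$is_mito),
              length(unique(x$genes$chrom))))
  invisible(x)
}

#' Genes whose exon union overlaps a query interval
#'
#' @param models a `gene_models` object.
#' @param chrom chromosome name.
#' @param start,end query interval, 0-based half-open.
#' @param strand optional strand filter (`"+"` or `"-"`).
#' @return character vector of gene ids (unique, index order).
#' @export
lookup_genes <- function(models, chrom, start, end, strand = NULL) {
  stopifnot(inherits(models, "gene_models"), end > start)
  q <- blocks_to_granges(chrom, cbind(start, end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, models$index, ignore.strand = TRUE))
  ids <- models$index$gene_id[S4Vectors::subjectHits(hits)]
  if (!is.null(strand)) {
    st <- as.character(GenomicRanges::strand(
      models$index[S4Vectors::subjectHits(hits)]))
    ids <- ids[st == strand]
  }
  unique(ids)
}
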