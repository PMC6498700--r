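#' Read alignment records from SAM or BAM into a plain table
#'
#' SAM input is converted through an on-disk BAM in the session temp
#' directory. Positions are reported 0-based half-open; `blocks` holds the
#' reference-consuming segments of each record's CIGAR (M/=/X/D extend a
#' block, N splits blocks, S/I/H consume nothing).
#'
#' @param path SAM or BAM file.
#' @return data.frame with columns `qname`, `flag`, `chrom`, `strand`,
#'   `pos` (0-based leftmost), `cigar`, plus logical `unmapped`,
#'   `secondary` (secondary or supplementary), and a list-column `blocks`
#'   of 0-based half-open interval matrices (`NULL` for unmapped records).
#' @export
read_alignments <- function(path) {
  bam <- ensure_bam(path)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar"))
  r <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(r$qname)
  flag <- r$flag
  unmapped <- bitwAnd(flag, 4L) != 0L
  secondary <- bitwAnd(flag, 256L) != 0L | bitwAnd(flag, 2048L) != 0L
  blocks <- vector("list", n)
  mapped <- which(!unmapped & !is.na(r$pos))
  if (length(mapped)) {
    rl <- GenomicAlignments::extractAlignmentRangesOnReference(
      r$cigar[mapped], pos = r$pos[mapped], drop.D.ranges = FALSE)
    for (k in seq_along(mapped)) {
      ir <- rl[[k]]
      blocks[[mapped[k]]] <- cbind(start = IRanges::start(ir) - 1L,
                                   end = IRanges::end(ir))
    }
  }
  out <- data.frame(
    qname = r$qname,
    flag = flag,
    chrom = as.character(r$rname),
    strand = as.character(r$strand),
    pos = ifelse(is.na(r$pos), NA_integer_, r$pos - 1L),
    cigar = r$cigar,
    unmapped = unmapped,
    secondary = secondary,
    stringsAsFactors = FALSE)
  out$blocks <- blocks
  out
}

# SAM text -> temp BAM; BAM passed through untouched
ensure_bam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) return(path)
  dest <- tempfile(fileext = ".bam")
  Rsamtools::asBam(path, sub("\\.bam$", "", dest), overwrite = TRUE,
                   indexDestination = FALSE)
}

# engine shared by assign_read_to_gene and count_cell: candidate gene ids
# per read from block overlap + strand compatibility, union mode
assign_engine <- function(blocks_list, chroms, read_strands, models,
                          strand_mode) {
  n <- length(blocks_list)
  nb <- vapply(blocks_list, nrow, integer(1))
  if (sum(nb) == 0) return(rep(list(character()), n))
  all_blocks <- do.call(rbind, blocks_list)
  q <- blocks_to_granges(rep(chroms, nb), all_blocks)
  read_of <- rep(seq_len(n), nb)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, models$index, ignore.strand = TRUE))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  gene_strand <- as.character(GenomicRanges::strand(models$index))[si]
  rd_strand <- read_strands[read_of[qi]]
  keep <- switch(strand_mode,
                 sense = gene_strand == rd_strand,
                 antisense = gene_strand != rd_strand,
                 unstranded = rep(TRUE, length(qi)))
  qi <- qi[keep]; gid <- models$index$gene_id[si][keep]
  cand <- rep(list(character()), n)
  if (length(qi)) {
    sp <- split(gid, read_of[qi])
    cand[as.integer(names(sp))] <- lapply(sp, unique)
  }
  cand
}

#' Assign one aligned read to a gene in union mode
#'
#' Candidate genes are those whose exon union overlaps any aligned block by
#' at least one base and whose strand is compatible under `strand_mode`
#' (`sense`: gene strand equals read strand; `antisense`: opposite;
#' `unstranded`: ignored). Exactly one candidate yields `assigned`; zero
#' yields `no_feature`; two or more yield `ambiguous` — only reads
#' overlapping the exonic regions of exactly one gene are counted.
#'
#' @param aligned_blocks 0-based half-open interval matrix from the CIGAR.
#' @param chrom chromosome name (absent from the models gives `no_feature`).
#' @param read_strand `"+"` or `"-"`.
#' @param models a `gene_models` object.
#' @param strand_mode `"sense"` (default for CEL-Seq chemistry, which keeps
#'   strand orientation), `"antisense"`, or `"unstranded"`.
#' @return list with `outcome` (`"assigned"`, `"no_feature"`,
#'   `"ambiguous"`) and `gene_id` (`NA` unless assigned).
#' @export
assign_read_to_gene <- function(aligned_blocks, chrom, read_strand, models,
                                strand_mode = c("sense", "antisense",
                                                "unstranded")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(models, "gene_models"))
  cand <- assign_engine(list(aligned_blocks), chrom, read_strand, models,
                        strand_mode)[[1]]
  if (length(cand) == 1) list(outcome = "assigned", gene_id = cand)
  else if (length(cand) == 0) list(outcome = "no_feature",
                                   gene_id = NA_character_)
  else list(outcome = "ambiguous", gene_id = NA_character_)
}

#' Deduplicate a multiset of UMIs
#'
#' `raw` is the number of distinct UMI strings (`N` is a literal letter, not
#' a wildcard). `corrected` applies directional single-pass collapse:
#' distinct UMIs are visited in order of decreasing read support (ties
#' lexicographic); a UMI is absorbed when an already-kept UMI lies within
#' Hamming distance 1 and has at least twice its read support, otherwise it
#' founds a new cluster.
#'
#' @param umis character vector, one element per read (a multiset).
#' @return list with `raw` and `corrected` cluster counts
#'   (`corrected <= raw`); empty input gives `(0, 0)`.
#' @export
dedup_umis <- function(umis) {
  cl <- umi_clusters(umis)
  list(raw = cl$raw, corrected = length(cl$cluster_reads))
}

# directional collapse with cluster read totals (for reads-per-corrected-UMI
# metrics). Returns raw count and per-cluster total read support.
umi_clusters <- function(umis) {
  if (length(umis) == 0)
    return(list(raw = 0L, cluster_reads = integer(),
                per_umi_reads = integer()))
  if (any(!grepl("^[ACGTN]+$", umis)))
    stop("UMI contains characters outside A,C,G,T,N")
  tab <- table(umis)
  cnt <- as.integer(tab)
  seqs <- names(tab)
  ord <- order(-cnt, seqs)
  seqs <- seqs[ord]; cnt <- cnt[ord]
  kept <- integer(0)              # indices into seqs
  cluster_reads <- integer(0)
  split_chars <- strsplit(seqs, "", fixed = TRUE)
  for (i in seq_along(seqs)) {
    absorbed <- FALSE
    for (kpos in seq_along(kept)) {
      k <- kept[kpos]
      if (cnt[k] >= 2L * cnt[i] &&
          hamming1(split_chars[[k]], split_chars[[i]])) {
        cluster_reads[kpos] <- cluster_reads[kpos] + cnt[i]
        absorbed <- TRUE
        break
      }
    }
    if (!absorbed) {
      kept <- c(kept, i)
      cluster_reads <- c(cluster_reads, cnt[i])
    }
  }
  list(raw = length(seqs), cluster_reads = cluster_reads,
       per_umi_reads = setNames(cnt, seqs))
}

hamming1 <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  sum(a != b) <= 1L
}

#' Count UMIs per gene for one cell
#'
#' Reads the cell's alignment file, skips secondary/supplementary records,
#' assigns each primary mapped read to at most one gene in union mode,
#' parses UMIs from the `:UMI:` read-name tags (a record without the tag is
#' a fatal contract violation), and summarizes distinct UMIs per gene. The
#' reported counts are raw distinct-UMI counts; directional correction
#' feeds only the reads-per-corrected-UMI metrics.
#'
#' Metrics use non-spike-in genes for transcript totals and gene detection
#' (spike-ins are counted in the matrix but handled separately downstream).
#' Metrics with an undefined denominator report 0 and raise `qc_flag`.
#'
#' @param alignment_path SAM or BAM for one cell.
#' @param models a `gene_models` object.
#' @param strand_mode see [assign_read_to_gene()].
#' @return An object of class `cell_counts`: `per_gene_umi` and
#'   `per_gene_reads` (named integer vectors over all model genes),
#'   `metrics` (named numeric), `qc_flag` (logical).
#' @export
count_cell <- function(alignment_path, models,
                       strand_mode = c("sense", "antisense", "unstranded")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(models, "gene_models"))
  aln <- read_alignments(alignment_path)
  primary <- aln[!aln$secondary, , drop = FALSE]
  total_reads <- nrow(primary)
  mapped <- primary[!primary$unmapped, , drop = FALSE]

  gene_ids <- models$genes$gene_id
  per_gene_umi <- setNames(integer(length(gene_ids)), gene_ids)
  per_gene_reads <- per_gene_umi
  assigned_gene <- character(0)
  assigned_umi <- character(0)

  if (nrow(mapped) > 0) {
    umi <- umis_from_names(mapped$qname)
    cand <- assign_engine(mapped$blocks, mapped$chrom, mapped$strand,
                          models, strand_mode)
    one <- vapply(cand, length, integer(1)) == 1L
    assigned_gene <- unlist(cand[one], use.names = FALSE) %||% character(0)
    assigned_umi <- umi[one]
  }

  per_umi_reads <- integer(0)         # read support per (gene, raw UMI)
  per_cluster_reads <- integer(0)     # read support per (gene, corrected UMI)
  if (length(assigned_gene)) {
    byg <- split(assigned_umi, assigned_gene)
    for (g in names(byg)) {
      cl <- umi_clusters(byg[[g]])
      per_gene_umi[g] <- cl$raw
      per_gene_reads[g] <- length(byg[[g]])
      per_umi_reads <- c(per_umi_reads, unname(cl$per_umi_reads))
      per_cluster_reads <- c(per_cluster_reads, cl$cluster_reads)
    }
  }

  main <- !models$genes$is_spike_in
  coding <- main & !is.na(models$genes$biotype) &
    models$genes$biotype == "protein_coding"
  mito <- main & models$genes$is_mito
  qc_flag <- FALSE
  safe_div <- function(a, b) {
    if (b == 0) { qc_flag <<- TRUE; 0 } else a / b
  }
  assigned_reads_total <- sum(per_gene_reads)
  raw_umi_total_all <- sum(per_gene_umi)
  corrected_total <- length(per_cluster_reads)

  metrics <- c(
    total_reads = total_reads,
    reads_mapped_to_genome = nrow(mapped),
    reads_mapped_to_genes = length(assigned_gene),
    total_umis = sum(per_gene_umi[main]),
    mito_umis = sum(per_gene_umi[mito]),
    protein_coding_umis = sum(per_gene_umi[coding]),
    genes_detected = sum(per_gene_umi[main] > 0),
    protein_coding_genes_detected = sum(per_gene_umi[coding] > 0),
    reads_per_umi_mean = safe_div(assigned_reads_total, raw_umi_total_all),
    reads_per_umi_median = if (length(per_umi_reads)) median(per_umi_reads)
                           else { qc_flag <- TRUE; 0 },
    reads_per_corrected_umi_mean = safe_div(assigned_reads_total,
                                            corrected_total),
    reads_per_corrected_umi_median =
      if (length(per_cluster_reads)) median(per_cluster_reads)
      else { qc_flag <- TRUE; 0 },
    genes_per_million_reads = safe_div(sum(per_gene_umi[main] > 0),
                                       total_reads / 1e6)
  )
  structure(list(per_gene_umi = per_gene_umi,
                 per_gene_reads = per_gene_reads,
                 metrics = metrics, qc_flag = qc_flag),
            class = "cell_counts")
}

#' Count an experiment: all cells into one gene-by-cell matrix
#'
#' Column `j` of the matrix equals [count_cell()] of cell `j`; the result is
#' independent of processing order. Gene rows follow GTF encounter order,
#' cell columns the order of the cells table. A cell whose alignment file
#' fails to parse gets a zero column and a `count_failed` flag; the run
#' continues.
#'
#' @param cells cell annotation data.frame with `cell_id` and
#'   `alignment_path` columns (from [align_cells()]).
#' @param models a `gene_models` object.
#' @param strand_mode see [assign_read_to_gene()].
#' @return an [experiment_set()] whose `cells` table carries all counting
#'   metrics and whose `matrix` is the raw distinct-UMI [count_matrix()].
#' @export
count_experiment <- function(cells, models,
                             strand_mode = c("sense", "antisense",
                                             "unstranded")) {
  strand_mode <- match.arg(strand_mode)
  cells <- as.data.frame(cells)
  stopifnot(all(c("cell_id", "alignment_path") %in% names(cells)))
  gene_ids <- models$genes$gene_id
  mat <- matrix(0L, nrow = length(gene_ids), ncol = nrow(cells),
                dimnames = list(gene_ids, cells$cell_id))
  metric_rows <- vector("list", nrow(cells))
  cells$count_failed <- FALSE
  cells$qc_flag <- FALSE
  for (j in seq_len(nrow(cells))) {
    res <- tryCatch(
      count_cell(cells$alignment_path[j], models, strand_mode),
      error = function(e) e)
    if (inherits(res, "error")) {
      # a missing UMI tag is an upstream contract break, not a bad cell
      if (grepl(":UMI:", conditionMessage(res), fixed = TRUE)) stop(res)
      warning(sprintf("counting failed for cell %s: %s",
                      cells$cell_id[j], conditionMessage(res)))
      cells$count_failed[j] <- TRUE
      metric_rows[[j]] <- NULL
      next
    }
    mat[, j] <- res$per_gene_umi
    cells$qc_flag[j] <- res$qc_flag
    metric_rows[[j]] <- res$metrics
  }
  ok <- which(!vapply(metric_rows, is.null, logical(1)))
  if (length(ok)) {
    for (m in names(metric_rows[[ok[1]]])) {
      cells[[m]] <- vapply(metric_rows, function(r)
        if (is.null(r)) 0 else unname(r[[m]]), numeric(1))
    }
  }
  genes <- models$genes
  experiment_set(cells, genes, count_matrix(mat))
}
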