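#' Configuration of the synthetic-data generator
#'
#' The generator emulates a plate-based (CEL-Seq style) experiment at desk
#' scale: a miniature genome with multi-exon genes on both strands plus
#' mitochondrial and spike-in contigs, a known-truth molecule count matrix,
#' paired FASTQ reads (read 1 = barcode+UMI, read 2 = a 3'-biased transcript
#' substring) with seeded error processes, and matching per-cell SAM files.
#' Every random fate is drawn once and recorded, so downstream expectations
#' are exact bookkeeping rather than statistical claims.
#'
#' @param n_genes biological genes (including mitochondrial ones).
#' @param n_cells wells/cells on the plate.
#' @param n_transcripts_per_gene inclusive range, e.g. `c(1, 3)`.
#' @param umi_length,barcode_length bases.
#' @param read2_length transcript-read length in bases.
#' @param duplication_factor reads per molecule; a scalar or an inclusive
#'   range sampled per molecule.
#' @param barcode_error_rate,umi_error_rate,low_quality_rate per-read
#'   probabilities of the corresponding injected fate (disjoint; the rest
#'   of the reads are clean).
#' @param base_quality constant Phred score given to all simulated bases.
#' @param min_phred,max_mismatch demultiplexing parameters the truth
#'   bookkeeping assumes (injected fates are constructed to be
#'   unambiguous under them).
#' @param mito_gene_fraction fraction of `n_genes` placed on the
#'   mitochondrial contig.
#' @param spike_in_genes number of extra spike-in genes (ERCC-style ids).
#' @param mean_molecules Poisson mean of true molecules per gene per cell.
#' @param strand_mode chemistry strandedness of the simulated reads.
#' @param experiment_id run label.
#' @param seed mandatory random seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 20, n_cells = 12,
                       n_transcripts_per_gene = c(1, 3),
                       umi_length = 6, barcode_length = 8,
                       read2_length = 50, duplication_factor = 3,
                       barcode_error_rate = 0, umi_error_rate = 0,
                       low_quality_rate = 0, base_quality = 37,
                       min_phred = 10, max_mismatch = 1,
                       mito_gene_fraction = 0.1, spike_in_genes = 2,
                       mean_molecules = 2,
                       strand_mode = c("sense", "antisense"),
                       experiment_id = "sim", seed) {
  if (missing(seed)) stop("a seed is mandatory")
  strand_mode <- match.arg(strand_mode)
  rates <- c(barcode_error_rate, umi_error_rate, low_quality_rate)
  stopifnot(all(rates >= 0), all(rates <= 1), sum(rates) <= 1,
            n_genes >= 3, n_cells >= 1, mean_molecules > 0,
            max_mismatch < barcode_length)
  layout <- read_layout(0, barcode_length, barcode_length, umi_length)
  structure(list(
    n_genes = n_genes, n_cells = n_cells,
    n_transcripts_per_gene = n_transcripts_per_gene,
    umi_length = umi_length, barcode_length = barcode_length,
    read2_length = read2_length, duplication_factor = duplication_factor,
    barcode_error_rate = barcode_error_rate,
    umi_error_rate = umi_error_rate, low_quality_rate = low_quality_rate,
    base_quality = base_quality, min_phred = min_phred,
    max_mismatch = max_mismatch, mito_gene_fraction = mito_gene_fraction,
    spike_in_genes = spike_in_genes, mean_molecules = mean_molecules,
    strand_mode = strand_mode, experiment_id = experiment_id,
    layout = layout, seed = as.integer(seed)
  ), class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a miniature reference genome and annotation
#'
#' Non-overlapping multi-exon genes on both strands of a main chromosome,
#' a designated mitochondrial contig (`MT`, gene names prefixed `mt-`) and
#' spike-in contigs with `ERCC-` gene ids. The first two genes of the main
#' chromosome are forced onto the `+` strand so a same-strand adjacent gene
#' pair always exists for the ambiguous-read class of
#' [simulate_alignments()]. The GTF is written and re-parsed through
#' [load_gene_models()], guaranteeing a lossless round trip.
#'
#' @param config a [sim_config()].
#' @param out_dir directory receiving `genome.fasta` and `annotation.gtf`.
#' @return list with `fasta_path`, `gtf_path`, `models` (a `gene_models`),
#'   `seqs` (DNAStringSet), `seqlens`, and `truth_structure` (the intended
#'   per-gene interval matrices, for round-trip checks).
#' @export
simulate_reference <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  n_mito <- max(1L, round(config$mito_gene_fraction * config$n_genes))
  n_main <- config$n_genes - n_mito
  if (n_main < 2) stop("config infeasible: need at least 2 non-mito genes")

  gene_rows <- list()
  structure_truth <- list()
  make_genes <- function(n, chrom, id_prefix, name_fun, biotype_fun,
                         force_plus_first2 = FALSE) {
    cursor <- 200L
    for (k in seq_len(n)) {
      gid <- sprintf("%s%04d", id_prefix, k)
      n_ex <- sample(2:4, 1)
      ex_len <- sample(120:300, n_ex, replace = TRUE)
      in_len <- if (n_ex > 1) sample(60:200, n_ex - 1, replace = TRUE)
                else integer(0)
      starts <- integer(n_ex); ends <- integer(n_ex)
      pos <- cursor
      for (e in seq_len(n_ex)) {
        starts[e] <- pos
        ends[e] <- pos + ex_len[e]
        pos <- ends[e] + if (e < n_ex) in_len[e] else 0L
      }
      cursor <- pos + sample(200:500, 1)
      strand <- if (force_plus_first2 && k <= 2) "+"
                else sample(c("+", "-"), 1)
      exons <- cbind(start = starts, end = ends)
      ntx <- sample(config$n_transcripts_per_gene[1]:
                      config$n_transcripts_per_gene[2], 1)
      txs <- list()
      txs[[sprintf("%s-201", gid)]] <- exons  # full-structure isoform
      if (ntx > 1) {
        for (t in seq_len(ntx - 1)) {
          keep <- sort(unique(c(1L, n_ex,
                                sample(seq_len(n_ex),
                                       max(1, n_ex - 1), replace = FALSE))))
          txs[[sprintf("%s-%d", gid, 201 + t)]] <-
            exons[keep, , drop = FALSE]
        }
      }
      gene_rows[[length(gene_rows) + 1L]] <<- list(
        gene_id = gid, gene_name = name_fun(k), chrom = chrom,
        strand = strand, biotype = biotype_fun(), transcripts = txs)
      structure_truth[[gid]] <<- exon_union(exons)
    }
    cursor + 200L  # chromosome length
  }
  len_main <- make_genes(n_main, "chr1", "G",
                         function(k) sprintf("Gene%d", k),
                         function() sample(c("protein_coding", "lincRNA"),
                                           1, prob = c(0.8, 0.2)),
                         force_plus_first2 = TRUE)
  len_mt <- make_genes(n_mito, "MT", "MTG",
                       function(k) sprintf("mt-%d", k),
                       function() "protein_coding")
  len_spike <- if (config$spike_in_genes > 0)
    make_genes(config$spike_in_genes, "ERCC", "ERCC-",
               function(k) sprintf("ERCC-%04d", k),
               function() "spike_in")
  else NULL

  seqlens <- c(chr1 = len_main, MT = len_mt)
  if (!is.null(len_spike)) seqlens <- c(seqlens, ERCC = len_spike)
  seqs <- Biostrings::DNAStringSet(vapply(seqlens, random_dna, character(1)))
  names(seqs) <- names(seqlens)
  fasta_path <- file.path(out_dir, "genome.fasta")
  Biostrings::writeXStringSet(seqs, fasta_path)

  gtf_path <- file.path(out_dir, "annotation.gtf")
  lines <- character(0)
  for (g in gene_rows) {
    for (tx in names(g$transcripts)) {
      ex <- g$transcripts[[tx]]
      attr_str <- sprintf(
        paste0('gene_id "%s"; transcript_id "%s"; gene_name "%s"; ',
               'gene_biotype "%s";'),
        g$gene_id, tx, g$gene_name, g$biotype)
      lines <- c(lines, sprintf(
        "%s\tplateseq_sim\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
        g$chrom, min(ex[, 1]) + 1L, max(ex[, 2]), g$strand, attr_str))
      for (e in seq_len(nrow(ex))) {
        lines <- c(lines, sprintf(
          "%s\tplateseq_sim\texon\t%d\t%d\t.\t%s\t.\t%s",
          g$chrom, ex[e, 1] + 1L, ex[e, 2], g$strand, attr_str))
      }
    }
  }
  writeLines(lines, gtf_path)

  models <- load_gene_models(gtf_path)
  list(fasta_path = fasta_path, gtf_path = gtf_path, models = models,
       seqs = seqs, seqlens = seqlens, truth_structure = structure_truth)
}

#' Simulate a cell-barcode whitelist
#'
#' Barcodes are drawn with pairwise Hamming distance at least
#' `2 * max_mismatch + 1`, so matching within `max_mismatch` can never be
#' ambiguous between true barcodes.
#'
#' @param config a [sim_config()].
#' @return data.frame with `barcode`, `well_label`.
#' @export
simulate_whitelist <- function(config) {
  set.seed(config$seed + 1L)
  need <- 2L * config$max_mismatch + 1L
  bcs <- character(0)
  while (length(bcs) < config$n_cells) {
    cand <- random_dna(config$barcode_length)
    if (length(bcs) == 0 ||
        min(barcode_distances(cand, bcs)) >= need)
      bcs <- c(bcs, cand)
  }
  data.frame(barcode = bcs,
             well_label = sprintf("well%02d", seq_along(bcs)),
             stringsAsFactors = FALSE)
}

#' Simulate the ground-truth molecule count matrix
#'
#' Independent Poisson molecule counts per gene per cell (spike-in and
#' mitochondrial genes included).
#'
#' @param config a [sim_config()].
#' @param models the `gene_models` from [simulate_reference()].
#' @param whitelist data.frame from [simulate_whitelist()].
#' @return a [count_matrix()] (genes x cells).
#' @export
simulate_truth_counts <- function(config, models, whitelist) {
  set.seed(config$seed + 2L)
  gene_ids <- models$genes$gene_id
  cell_ids <- sprintf("%s_%s", config$experiment_id, whitelist$barcode)
  m <- matrix(rpois(length(gene_ids) * length(cell_ids),
                    config$mean_molecules),
              nrow = length(gene_ids),
              dimnames = list(gene_ids, cell_ids))
  count_matrix(m)
}

# mRNA [a,b) -> genomic blocks through the transcript's exon chain
# (exons 0-based half-open, genomic order). For '-' transcripts mRNA
# coordinates run from the genomic end, so the interval is mirrored first.
mrna_to_blocks <- function(exons, strand, a, b) {
  lens <- exons[, 2] - exons[, 1]
  L <- sum(lens)
  if (strand == "-") { tmp <- a; a <- L - b; b <- L - tmp }
  offs <- cumsum(c(0, lens))
  out <- NULL
  for (e in seq_len(nrow(exons))) {
    s <- max(a, offs[e]); t <- min(b, offs[e + 1])
    if (s < t)
      out <- rbind(out, c(exons[e, 1] + (s - offs[e]),
                          exons[e, 1] + (t - offs[e])))
  }
  colnames(out) <- c("start", "end")
  out
}

# spliced mRNA sequence of a transcript (sense strand of the gene)
mrna_seq <- function(chrom_seq, exons, strand) {
  parts <- vapply(seq_len(nrow(exons)), function(e)
    as.character(Biostrings::subseq(chrom_seq, exons[e, 1] + 1L,
                                    exons[e, 2])), character(1))
  s <- Biostrings::DNAString(paste(parts, collapse = ""))
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

mutate_base <- function(seq, pos) {
  base <- substr(seq, pos, pos)
  sub_with <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
  paste0(substr(seq, 1, pos - 1), sub_with,
         substr(seq, pos + 1, nchar(seq)))
}

#' Simulate paired FASTQ reads with exact truth bookkeeping
#'
#' Every true molecule emits `duplication_factor` read pairs. Read 1 carries
#' the cell barcode and a UMI drawn without replacement within each
#' (cell, gene); read 2 is a 3'-biased substring of the chosen transcript's
#' mRNA. Injected fates, drawn once per read and recorded in
#' `per_read_truth`, are: `bc_error` (barcode with `max_mismatch + 1` `N`
#' bases, hence deterministically unmatched), `umi_error` (one substituted
#' UMI base; still assigned), `low_quality` (one barcode/UMI base below
#' `min_phred`), otherwise `clean`. Expected demultiplexing statistics are
#' tallied analytically from the recorded fates.
#'
#' @param config a [sim_config()].
#' @param reference output of [simulate_reference()].
#' @param truth_counts output of [simulate_truth_counts()].
#' @param whitelist output of [simulate_whitelist()].
#' @param out_dir directory receiving `r1.fastq.gz` / `r2.fastq.gz`.
#' @return An object of class `truth_bundle`: `r1_path`, `r2_path`,
#'   `counts`, `per_read_truth` (data.frame: `read_id`, `cell_id`,
#'   `barcode`, `gene_id`, `true_umi`, `obs_umi`, `fate`, `chrom`,
#'   `strand`, `blocks`), `expected_stats` (`demux_stats`), `whitelist`,
#'   `seqlens`, `config`.
#' @export
simulate_reads <- function(config, reference, truth_counts, whitelist,
                           out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 3L)
  models <- reference$models
  cell_ids <- colnames(truth_counts)
  stopifnot(identical(cell_ids,
                      sprintf("%s_%s", config$experiment_id,
                              whitelist$barcode)))

  umi_pool <- function(n, taken) {
    out <- character(0)
    while (length(out) < n) {
      u <- random_dna(config$umi_length)
      if (!u %in% taken && !u %in% out) out <- c(out, u)
    }
    out
  }

  rows <- list()
  k <- 0L
  for (j in seq_along(cell_ids)) {
    for (gi in seq_len(nrow(models$genes))) {
      cnt <- truth_counts[gi, j]
      if (cnt == 0) next
      g <- models$genes[gi, ]
      txs <- models$transcripts[[g$gene_id]]
      umis <- umi_pool(cnt, character(0))
      for (mol in seq_len(cnt)) {
        tx_name <- sample(names(txs), 1)
        ex <- txs[[tx_name]]
        L <- sum(ex[, 2] - ex[, 1])
        rl <- min(config$read2_length, L)
        off <- sample(0:min(20L, L - rl), 1)
        a <- L - rl - off; b <- L - off
        blocks <- mrna_to_blocks(ex, g$strand, a, b)
        mseq <- mrna_seq(reference$seqs[[g$chrom]], ex, g$strand)
        r2 <- substr(mseq, a + 1L, b)
        read_strand <- if (config$strand_mode == "sense") g$strand
                       else if (g$strand == "+") "-" else "+"
        dup <- if (length(config$duplication_factor) == 1)
          config$duplication_factor
        else sample(config$duplication_factor[1]:
                      config$duplication_factor[2], 1)
        for (d in seq_len(dup)) {
          k <- k + 1L
          u <- runif(1)
          fate <- if (u < config$barcode_error_rate) "bc_error"
          else if (u < config$barcode_error_rate +
                     config$umi_error_rate) "umi_error"
          else if (u < config$barcode_error_rate +
                     config$umi_error_rate +
                     config$low_quality_rate) "low_quality"
          else "clean"
          obs_bc <- whitelist$barcode[j]
          obs_umi <- umis[mol]
          if (fate == "bc_error") {
            posns <- sample(config$barcode_length, config$max_mismatch + 1L)
            bcv <- strsplit(obs_bc, "")[[1]]
            bcv[posns] <- "N"
            obs_bc <- paste(bcv, collapse = "")
          } else if (fate == "umi_error") {
            obs_umi <- mutate_base(obs_umi,
                                   sample(config$umi_length, 1))
          }
          rows[[k]] <- list(
            cell_id = cell_ids[j], barcode = whitelist$barcode[j],
            gene_id = g$gene_id, true_umi = umis[mol], obs_umi = obs_umi,
            obs_bc = obs_bc, fate = fate, chrom = g$chrom,
            strand = read_strand,
            blocks = paste(sprintf("%d-%d", blocks[, 1], blocks[, 2]),
                           collapse = ";"),
            r2 = r2, transcript = tx_name)
        }
      }
    }
  }
  n <- length(rows)
  if (n == 0) stop("truth counts are all zero; nothing to simulate")
  ord <- sample(n)   # mix cells in the pooled FASTQ
  rows <- rows[ord]
  truth <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r[setdiff(names(r), "r2")], stringsAsFactors = FALSE)))
  truth$read_id <- sprintf("sim:%06d", seq_len(n))
  truth <- truth[c("read_id", setdiff(names(truth), "read_id"))]

  span <- layout_span(config$layout)
  qual_char <- function(q) intToUtf8(q + 33L)
  r1_seq <- character(n); r1_qual <- character(n); r2_seq <- character(n)
  for (i in seq_len(n)) {
    r <- rows[[i]]
    base_vec <- rep("A", span)
    bcv <- strsplit(r$obs_bc, "")[[1]]
    umv <- strsplit(r$obs_umi, "")[[1]]
    base_vec[(config$layout$barcode_start + 1):
               (config$layout$barcode_start + config$barcode_length)] <- bcv
    base_vec[(config$layout$umi_start + 1):
               (config$layout$umi_start + config$umi_length)] <- umv
    r1_seq[i] <- paste(base_vec, collapse = "")
    qv <- rep(config$base_quality, span)
    if (r$fate == "low_quality")
      qv[sample(span, 1)] <- max(0L, config$min_phred - 1L)
    r1_qual[i] <- paste(vapply(qv, qual_char, character(1)), collapse = "")
    r2_seq[i] <- r$r2
  }
  r1_path <- file.path(out_dir, "r1.fastq.gz")
  r2_path <- file.path(out_dir, "r2.fastq.gz")
  write_fq <- function(seqs, quals, ids, path) {
    sr <- ShortRead::ShortReadQ(
      sread = Biostrings::DNAStringSet(seqs),
      quality = ShortRead::FastqQuality(Biostrings::BStringSet(quals)),
      id = Biostrings::BStringSet(ids))
    if (file.exists(path)) unlink(path)
    ShortRead::writeFastq(sr, path, mode = "w", compress = TRUE)
  }
  write_fq(r1_seq, r1_qual, truth$read_id, r1_path)
  write_fq(r2_seq, vapply(nchar(r2_seq), function(w)
    paste(rep(qual_char(config$base_quality), w), collapse = ""),
    character(1)), truth$read_id, r2_path)

  assigned <- truth$fate %in% c("clean", "umi_error")
  per_cell <- vapply(whitelist$barcode, function(b)
    sum(assigned & truth$barcode == b), integer(1))
  expected_stats <- structure(list(
    total_pairs = n,
    assigned_pairs = sum(assigned),
    low_quality_pairs = sum(truth$fate == "low_quality"),
    unmatched_pairs = sum(truth$fate == "bc_error"),
    ambiguous_pairs = 0L,
    per_cell_assigned = setNames(per_cell, whitelist$barcode)
  ), class = "demux_stats")

  structure(list(r1_path = r1_path, r2_path = r2_path,
                 counts = truth_counts, per_read_truth = truth,
                 expected_stats = expected_stats, whitelist = whitelist,
                 seqlens = reference$seqlens, config = config),
            class = "truth_bundle")
}

# encode blocks matrix <-> "s-e;s-e" strings used in per_read_truth
parse_blocks <- function(s) {
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, as.integer))
  colnames(m) <- c("start", "end")
  m
}

blocks_to_cigar <- function(blocks) {
  ops <- sprintf("%dM", blocks[1, 2] - blocks[1, 1])
  if (nrow(blocks) > 1) {
    for (e in 2:nrow(blocks)) {
      gap <- blocks[e, 1] - blocks[e - 1, 2]
      ops <- paste0(ops, sprintf("%dN%dM", gap, blocks[e, 2] - blocks[e, 1]))
    }
  }
  ops
}

#' Simulate per-cell SAM alignments from the truth bundle
#'
#' Each read assigned at demultiplexing (`clean` / `umi_error` fates)
#' becomes one primary SAM record at its true transcript location, with the
#' correct strand flag, a CIGAR that includes `N` for exon-spanning reads,
#' and the `:UMI:`-tagged read name. Optional seeded fractions of records
#' are diverted to an `unmapped`, `ambiguous` (spliced across two adjacent
#' same-strand genes, hence discarded by union-mode counting) or `intronic`
#' (inside an intron, hence `no_feature`) class; every diverted read is
#' recorded in the returned truth labels. One SAM file is written per
#' whitelist cell, including empty ones.
#'
#' @param truth a `truth_bundle` from [simulate_reads()].
#' @param models the `gene_models` of the same reference.
#' @param out_dir directory receiving `<cell_id>.sam` files.
#' @param unmapped_rate,ambiguous_rate,intronic_rate per-read diversion
#'   probabilities (disjoint).
#' @return list with `cells` (data.frame `cell_id`, `alignment_path`) and
#'   `aln_truth` (data.frame `read_id`, `cell_id`, `aln_fate`).
#' @export
simulate_alignments <- function(truth, models, out_dir, unmapped_rate = 0,
                                ambiguous_rate = 0, intronic_rate = 0) {
  stopifnot(inherits(truth, "truth_bundle"),
            unmapped_rate + ambiguous_rate + intronic_rate <= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config <- truth$config
  set.seed(config$seed + 4L)

  # ambiguous locus: first two genes of chr1 are '+' by construction
  main <- models$genes[models$genes$chrom == "chr1" &
                         models$genes$strand == "+", ]
  stopifnot(nrow(main) >= 2)
  gA <- main$gene_id[1]; gB <- main$gene_id[2]
  euA <- models$exon_union[[gA]]; euB <- models$exon_union[[gB]]
  amb_blocks <- rbind(c(euA[nrow(euA), 2] - 15L, euA[nrow(euA), 2]),
                      c(euB[1, 1], euB[1, 1] + 15L))
  # an intron of some multi-exon gene, used for the intronic class
  multi <- Filter(function(g) nrow(models$exon_union[[g]]) >= 2,
                  models$genes$gene_id)
  intron_block <- if (length(multi)) {
    eu <- models$exon_union[[multi[1]]]
    gap <- c(eu[1, 2], eu[2, 1])
    mid <- floor((gap[1] + gap[2]) / 2)
    half <- max(1L, min(10L, floor((gap[2] - gap[1]) / 2) - 1L))
    matrix(c(mid - half, mid + half), ncol = 2)
  } else NULL
  intron_chrom <- if (length(multi))
    models$genes$chrom[models$genes$gene_id == multi[1]] else NA

  tr <- truth$per_read_truth
  assigned <- tr[tr$fate %in% c("clean", "umi_error"), , drop = FALSE]
  u <- runif(nrow(assigned))
  aln_fate <- rep("mapped", nrow(assigned))
  aln_fate[u < unmapped_rate] <- "unmapped"
  aln_fate[u >= unmapped_rate & u < unmapped_rate + ambiguous_rate] <-
    "ambiguous"
  aln_fate[u >= unmapped_rate + ambiguous_rate &
             u < unmapped_rate + ambiguous_rate + intronic_rate] <-
    "intronic"
  if (any(aln_fate == "intronic") && is.null(intron_block))
    stop("no multi-exon gene available for the intronic class")

  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(truth$seqlens),
                      unname(truth$seqlens)))
  cell_ids <- sprintf("%s_%s", config$experiment_id,
                      truth$whitelist$barcode)
  paths <- file.path(out_dir, paste0(cell_ids, ".sam"))
  for (j in seq_along(cell_ids)) {
    sel <- which(assigned$cell_id == cell_ids[j])
    recs <- character(0)
    for (i in sel) {
      r <- assigned[i, ]
      qname <- tag_header_with_umi(r$read_id, r$obs_umi)
      f <- aln_fate[i]
      if (f == "unmapped") {
        recs <- c(recs, paste(qname, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                              "*", "*", sep = "\t"))
        next
      }
      if (f == "mapped") {
        blocks <- parse_blocks(r$blocks); chrom <- r$chrom
        strand <- r$strand
      } else if (f == "ambiguous") {
        blocks <- amb_blocks; chrom <- "chr1"; strand <- "+"
      } else {
        blocks <- intron_block; chrom <- intron_chrom
        strand <- r$strand
      }
      flag <- if (strand == "-") 16L else 0L
      recs <- c(recs, paste(qname, flag, chrom, blocks[1, 1] + 1L, 60L,
                            blocks_to_cigar(blocks), "*", 0L, 0L, "*", "*",
                            sep = "\t"))
    }
    writeLines(c(header, recs), paths[j])
  }
  aln_truth <- data.frame(read_id = assigned$read_id,
                          cell_id = assigned$cell_id,
                          aln_fate = aln_fate, stringsAsFactors = FALSE)
  list(cells = data.frame(cell_id = cell_ids, alignment_path = paths,
                          stringsAsFactors = FALSE),
       aln_truth = aln_truth)
}

#' Run the complete synthetic-fixture generator
#'
#' Orchestrates [simulate_reference()], [simulate_whitelist()],
#' [simulate_truth_counts()], [simulate_reads()] and
#' [simulate_alignments()], and writes the truth directory
#' (`truth/counts.tsv`, `truth/per_read_truth.tsv`,
#' `truth/expected_stats.tsv`) plus `whitelist.tsv` under `out_dir`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param unmapped_rate,ambiguous_rate,intronic_rate passed to
#'   [simulate_alignments()].
#' @return list with `reference`, `whitelist`, `truth` (the
#'   `truth_bundle`), `alignments` (from [simulate_alignments()]), and
#'   `out_dir`.
#' @export
simulate_run <- function(config, out_dir, unmapped_rate = 0,
                         ambiguous_rate = 0, intronic_rate = 0) {
  reference <- simulate_reference(config, out_dir)
  whitelist <- simulate_whitelist(config)
  truth_counts <- simulate_truth_counts(config, reference$models, whitelist)
  truth <- simulate_reads(config, reference, truth_counts, whitelist,
                          out_dir)
  alignments <- simulate_alignments(truth, reference$models,
                                    file.path(out_dir, "sam"),
                                    unmapped_rate, ambiguous_rate,
                                    intronic_rate)
  write.table(whitelist, file.path(out_dir, "whitelist.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tdir <- file.path(out_dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  write_count_matrix(truth$counts, file.path(tdir, "counts.tsv"))
  write.table(truth$per_read_truth, file.path(tdir, "per_read_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_demux_stats(truth$expected_stats,
                    file.path(tdir, "expected_stats.tsv"))
  list(reference = reference, whitelist = whitelist, truth = truth,
       alignments = alignments, out_dir = out_dir)
}
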