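# fixtures are built in code at test time; nothing binary ships in the repo

write_fastq_plain <- function(path, ids, seqs, quals) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(quals))
  out <- character(4 * length(ids))
  if (length(ids)) {
    out[seq(1, by = 4, length.out = length(ids))] <- paste0("@", ids)
    out[seq(2, by = 4, length.out = length(ids))] <- seqs
    out[seq(3, by = 4, length.out = length(ids))] <- "+"
    out[seq(4, by = 4, length.out = length(ids))] <- quals
  }
  writeLines(out, path)
  path
}

qual_str <- function(phreds) {
  paste(vapply(phreds, function(q) intToUtf8(q + 33L), character(1)),
        collapse = "")
}

# minimal GTF from a list of genes:
# list(gene_id=, chrom=, strand=, biotype=, name=,
#      tx = list(txname = matrix of 0-based half-open exons))
write_tiny_gtf <- function(genes, path = tempfile(fileext = ".gtf")) {
  lines <- character(0)
  for (g in genes) {
    for (tx in names(g$tx)) {
      ex <- g$tx[[tx]]
      at <- sprintf(
        'gene_id "%s"; transcript_id "%s"; gene_name "%s"; gene_biotype "%s";',
        g$gene_id, tx, g$name %||% g$gene_id,
        g$biotype %||% "protein_coding")
      for (e in seq_len(nrow(ex)))
        lines <- c(lines, sprintf("%s\ttest\texon\t%d\t%d\t.\t%s\t.\t%s",
                                  g$chrom, ex[e, 1] + 1L, ex[e, 2],
                                  g$strand, at))
    }
  }
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# SAM writer: recs = data.frame(qname, flag, chrom, pos0, cigar) plus
# optional extra tag columns pasted verbatim
write_tiny_sam <- function(path, seqlens, qname = character(),
                           flag = integer(), chrom = character(),
                           pos0 = integer(), cigar = character(),
                           tags = NULL) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens),
                      as.integer(seqlens)))
  recs <- character(0)
  for (i in seq_along(qname)) {
    r <- paste(qname[i], flag[i],
               if (bitwAnd(flag[i], 4L) != 0L) "*" else chrom[i],
               if (bitwAnd(flag[i], 4L) != 0L) 0L else pos0[i] + 1L,
               60L,
               if (bitwAnd(flag[i], 4L) != 0L) "*" else cigar[i],
               "*", 0L, 0L, "*", "*", sep = "\t")
    if (!is.null(tags) && nzchar(tags[i])) r <- paste(r, tags[i], sep = "\t")
    recs <- c(recs, r)
  }
  writeLines(c(header, recs), path)
  path
}

# one shared clean simulation reused across test files (and a noisy one)
.sim_cache <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (is.null(.sim_cache$clean)) {
    dir <- file.path(tempdir(), "plateseq_sim_clean")
    cfg <- sim_config(seed = 42)
    .sim_cache$clean <- simulate_run(cfg, dir)
  }
  .sim_cache$clean
}

shared_noisy_sim <- function() {
  if (is.null(.sim_cache$noisy)) {
    dir <- file.path(tempdir(), "plateseq_sim_noisy")
    cfg <- sim_config(seed = 43, barcode_error_rate = 0.08,
                      umi_error_rate = 0.05, low_quality_rate = 0.07,
                      duplication_factor = c(1, 4))
    .sim_cache$noisy <- simulate_run(cfg, dir, unmapped_rate = 0.1,
                                     ambiguous_rate = 0.05,
                                     intronic_rate = 0.05)
  }
  .sim_cache$noisy
}

run_demux <- function(sim, out_dir) {
  cfg <- sim$truth$config
  demultiplex_run(sim$truth$r1_path, sim$truth$r2_path, sim$whitelist,
                  cfg$layout, out_dir, experiment_id = cfg$experiment_id,
                  min_phred = cfg$min_phred,
                  max_mismatch = cfg$max_mismatch)
}
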