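# independent brute-force oracles; deliberately written as plain nested
# loops, never sharing code with the implementation they check

hamming_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  stopifnot(length(av) == length(bv))
  sum(av != bv | av == "N")
}

# minimal-distance scan with tie rejection
match_barcode_oracle <- function(observed, whitelist, max_mismatch) {
  d <- vapply(whitelist, function(w) hamming_oracle(observed, w), numeric(1))
  dmin <- min(d)
  if (dmin > max_mismatch) return(list(status = "unmatched", index = NA))
  hits <- which(d == dmin)
  if (length(hits) > 1) return(list(status = "ambiguous", index = NA))
  list(status = "matched", index = hits)
}

# union-mode assignment by exhaustive nested loops over genes, union
# intervals and read blocks
assign_oracle <- function(blocks, chrom, read_strand, gene_defs,
                          strand_mode) {
  cands <- character(0)
  for (g in gene_defs) {
    if (g$chrom != chrom) next
    ok_strand <- switch(strand_mode,
                        sense = g$strand == read_strand,
                        antisense = g$strand != read_strand,
                        unstranded = TRUE)
    if (!ok_strand) next
    hit <- FALSE
    for (e in seq_len(nrow(g$union))) {
      for (b in seq_len(nrow(blocks))) {
        if (blocks[b, 1] < g$union[e, 2] && blocks[b, 2] > g$union[e, 1])
          hit <- TRUE
      }
    }
    if (hit) cands <- c(cands, g$gene_id)
  }
  if (length(cands) == 1) list(outcome = "assigned", gene_id = cands)
  else if (length(cands) == 0) list(outcome = "no_feature",
                                    gene_id = NA_character_)
  else list(outcome = "ambiguous", gene_id = NA_character_)
}

# directional clustering via a full pairwise Hamming matrix
dedup_oracle <- function(umis) {
  if (length(umis) == 0) return(list(raw = 0L, corrected = 0L))
  tab <- table(umis)
  seqs <- names(tab)
  cnt <- as.integer(tab)
  o <- order(-cnt, seqs)
  seqs <- seqs[o]; cnt <- cnt[o]
  m <- length(seqs)
  dm <- matrix(0L, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    av <- strsplit(seqs[i], "")[[1]]; bv <- strsplit(seqs[j], "")[[1]]
    dm[i, j] <- sum(av != bv)
  }
  kept <- integer(0)
  for (i in seq_len(m)) {
    parent <- NA
    for (k in kept) {
      if (dm[k, i] <= 1L && cnt[k] >= 2L * cnt[i]) { parent <- k; break }
    }
    if (is.na(parent)) kept <- c(kept, i)
  }
  list(raw = m, corrected = length(kept))
}

# point-sampling membership oracle for interval unions
union_member_oracle <- function(intervals, points) {
  vapply(points, function(p) {
    any(intervals[, 1] <= p & p < intervals[, 2])
  }, logical(1))
}

# region-overlap scan over a SAM text file (primary mapped records only),
# counting reads with any CIGAR reference block overlapping [start, end)
region_count_oracle <- function(sam_path, chrom, start, end) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  n <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L || bitwAnd(flag, 256L) != 0L ||
        bitwAnd(flag, 2048L) != 0L) next
    if (f[3] != chrom) next
    pos <- as.integer(f[4]) - 1L  # to 0-based
    ops <- regmatches(f[6], gregexpr("[0-9]+[MIDNSHP=X]", f[6]))[[1]]
    cur <- pos
    hit <- FALSE
    blk_start <- cur
    for (op in ops) {
      len <- as.integer(sub("[A-Z=]", "", op))
      type <- sub("[0-9]+", "", op)
      if (type %in% c("M", "=", "X", "D")) {
        cur <- cur + len
      } else if (type == "N") {
        if (blk_start < end && cur > start) hit <- TRUE
        cur <- cur + len
        blk_start <- cur
      }
    }
    if (blk_start < end && cur > start) hit <- TRUE
    if (hit) n <- n + 1L
  }
  n
}
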