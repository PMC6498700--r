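#' Read a cell-barcode whitelist
#'
#' Plain text / TSV with columns `barcode` and optional `well_label`; a
#' header row is detected and tolerated. Single-column files are accepted.
#'
#' @param path whitelist file.
#' @return data.frame with columns `barcode`, `well_label`.
#' @export
read_whitelist <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("barcode", first, ignore.case = TRUE)
  df <- read.delim(path, header = has_header, sep = "\t",
                   stringsAsFactors = FALSE)
  if (!has_header) names(df)[1] <- "barcode"
  names(df) <- tolower(names(df))
  if (!"well_label" %in% names(df))
    df$well_label <- df$barcode
  bc <- toupper(df$barcode)
  if (anyDuplicated(bc)) stop("duplicate barcodes in whitelist: ", path)
  if (length(unique(nchar(bc))) > 1)
    stop("whitelist barcodes have unequal lengths")
  data.frame(barcode = bc, well_label = as.character(df$well_label),
             stringsAsFactors = FALSE)
}

#' Extract barcode and UMI from a read-1 sequence
#'
#' The barcode and UMI are the exact substrings at the layout's offsets;
#' their per-base qualities are returned concatenated (barcode first) for
#' quality filtering.
#'
#' @param read1_seq read-1 nucleotide string.
#' @param read1_qual integer vector of per-base Phred scores for read 1.
#' @param layout a [read_layout()].
#' @return list with `barcode`, `umi`, `qual` (integer vector), or throws a
#'   condition of class `plateseq_structure_error` when the read is shorter
#'   than the layout span.
#' @export
extract_barcode_umi <- function(read1_seq, read1_qual, layout) {
  stopifnot(inherits(layout, "read_layout"))
  n <- nchar(read1_seq)
  if (n < layout_span(layout)) {
    cond <- structure(
      class = c("plateseq_structure_error", "error", "condition"),
      list(message = sprintf(
        "read of length %d shorter than layout span %d", n,
        layout_span(layout)), call = NULL))
    stop(cond)
  }
  bc <- substr(read1_seq, layout$barcode_start + 1L,
               layout$barcode_start + layout$barcode_length)
  um <- substr(read1_seq, layout$umi_start + 1L,
               layout$umi_start + layout$umi_length)
  q <- c(read1_qual[(layout$barcode_start + 1L):
                      (layout$barcode_start + layout$barcode_length)],
         read1_qual[(layout$umi_start + 1L):
                      (layout$umi_start + layout$umi_length)])
  list(barcode = bc, umi = um, qual = as.integer(q))
}

#' Test barcode/UMI base qualities against a Phred threshold
#'
#' Under the default `min_base` rule every base must reach the threshold: a
#' single unreliable UMI base corrupts deduplication, so the strictest
#' reading is the default. `mean` accepts a read whose average quality
#' reaches the threshold.
#'
#' @param quals integer vector of Phred scores (empty passes vacuously).
#' @param min_phred threshold in `[0, 93]`.
#' @param rule `"min_base"` or `"mean"`.
#' @return logical scalar.
#' @export
passes_quality <- function(quals, min_phred, rule = c("min_base", "mean")) {
  rule <- match.arg(rule)
  stopifnot(min_phred >= 0, min_phred <= 93)
  if (length(quals) == 0) return(TRUE)
  if (rule == "min_base") all(quals >= min_phred)
  else mean(quals) >= min_phred
}

# Hamming distances of observed barcodes (rows) to each whitelist barcode.
# 'N' in an observed barcode mismatches every base.
barcode_distances <- function(observed, whitelist) {
  k <- nchar(whitelist[1])
  if (any(nchar(observed) != k) || any(nchar(whitelist) != k))
    stop("barcode length inconsistent with whitelist")
  obs <- matrix(unlist(strsplit(observed, "", fixed = TRUE)),
                ncol = k, byrow = TRUE)
  d <- matrix(0L, nrow = length(observed), ncol = length(whitelist))
  for (j in seq_along(whitelist)) {
    wl <- strsplit(whitelist[j], "", fixed = TRUE)[[1]]
    mism <- obs != rep(wl, each = nrow(obs)) | obs == "N"
    d[, j] <- as.integer(rowSums(matrix(mism, ncol = k)))
  }
  d
}

#' Match observed barcodes against a whitelist
#'
#' Each observed barcode is matched to the unique whitelist entry at minimal
#' Hamming distance `d <= max_mismatch`. If no entry qualifies the read is
#' `unmatched`; if two or more tie at the minimal qualifying distance it is
#' `ambiguous` (ties are rejected rather than broken arbitrarily, since
#' misassignment contaminates cells). `N` bases in the observed barcode
#' count as mismatches against any base.
#'
#' @param observed character vector of observed barcodes.
#' @param whitelist character vector of whitelist barcodes (same length as
#'   the observed ones; unequal lengths are a configuration error).
#' @param max_mismatch maximum Hamming distance (must be `< nchar(barcode)`).
#' @return data.frame with one row per observed barcode: `status`
#'   (`"matched"`, `"unmatched"`, `"ambiguous"`) and `index` (1-based
#'   whitelist index, `NA` unless matched).
#' @export
match_barcode <- function(observed, whitelist, max_mismatch) {
  stopifnot(max_mismatch >= 0, max_mismatch < nchar(whitelist[1]))
  d <- barcode_distances(observed, whitelist)
  dmin <- apply(d, 1L, min)
  nmin <- rowSums(d == dmin)
  status <- rep("matched", length(observed))
  index <- apply(d, 1L, which.min)
  status[dmin > max_mismatch] <- "unmatched"
  status[dmin <= max_mismatch & nmin > 1] <- "ambiguous"
  index[status != "matched"] <- NA_integer_
  data.frame(status = status, index = as.integer(index),
             stringsAsFactors = FALSE)
}

#' Append a UMI to a read identifier
#'
#' Encodes the UMI into the read name as `<id>:UMI:<umi>` so it survives any
#' aligner that preserves read names; [parse_umi_tag()] inverts the
#' encoding unambiguously.
#'
#' @param read_id read identifier (the token before the first whitespace of
#'   the FASTQ header; must not itself contain whitespace).
#' @param umi UMI sequence over `A,C,G,T,N`.
#' @return tagged identifier string.
#' @export
tag_header_with_umi <- function(read_id, umi) {
  if (any(grepl("[[:space:]]", read_id)))
    stop("read id must not contain whitespace")
  if (any(!grepl("^[ACGTN]+$", umi)))
    stop("UMI contains characters outside A,C,G,T,N")
  paste0(read_id, ":UMI:", umi)
}

#' Recover the read id and UMI from a tagged identifier
#'
#' @param tagged identifier produced by [tag_header_with_umi()].
#' @return list with `read_id` and `umi`; errors if no tag is present.
#' @export
parse_umi_tag <- function(tagged) {
  m <- regmatches(tagged, regexpr(":UMI:[ACGTN]+$", tagged))
  if (length(m) != length(tagged) || any(!nzchar(m)))
    stop("read name lacks a ':UMI:' tag: ", tagged[1])
  list(read_id = sub(":UMI:[ACGTN]+$", "", tagged),
       umi = sub("^.*:UMI:", "", tagged))
}

# vectorized: umis for many tagged names at once; fatal if any untagged
umis_from_names <- function(qnames) {
  hit <- regexpr(":UMI:[ACGTN]+$", qnames)
  bad <- which(hit < 0)
  if (length(bad))
    stop("alignment record lacks a ':UMI:' read-name tag: ", qnames[bad[1]])
  substring(qnames, hit + 5L)
}

#' Demultiplex a paired-end FASTQ run into per-cell FASTQ files
#'
#' Read 1 carries barcode and UMI, read 2 the transcript. For every pair the
#' barcode/UMI base qualities are checked first (`min_phred`); surviving
#' pairs have their barcode matched against the whitelist within
#' `max_mismatch` Hamming distance. Assigned read-2 sequences are written to
#' one gzipped FASTQ per whitelist barcode (created even when empty, so
#' downstream cell accounting is complete), trimmed to `layout$read2_keep`
#' when set, with the UMI appended to the read name. Read-1 records shorter
#' than the layout span are counted in the `low_quality` bucket.
#'
#' @param fastq_r1,fastq_r2 paths to the paired FASTQ files (plain or gzip).
#' @param whitelist data.frame from [read_whitelist()] or a path to one.
#' @param layout a [read_layout()].
#' @param out_dir output directory for per-cell FASTQ files.
#' @param experiment_id label for this run; prefixes cell ids and filenames.
#' @param min_phred Phred threshold for barcode+UMI bases (default 10).
#' @param max_mismatch maximum barcode Hamming distance (default 1).
#' @param phred_offset 33 (modern default) or 64.
#' @param quality_rule `"min_base"` (default) or `"mean"`; see
#'   [passes_quality()].
#' @return list with `cells` (cell annotation data.frame: `cell_id`,
#'   `experiment_id`, `barcode`, `fastq_path`, `reads_assigned`,
#'   `fraction_of_total`) and `stats` (a `demux_stats` list: `total_pairs`,
#'   `assigned_pairs`, `low_quality_pairs`, `unmatched_pairs`,
#'   `ambiguous_pairs`, `per_cell_assigned`).
#' @export
demultiplex_run <- function(fastq_r1, fastq_r2, whitelist, layout, out_dir,
                            experiment_id = "expt1", min_phred = 10,
                            max_mismatch = 1, phred_offset = 33,
                            quality_rule = c("min_base", "mean")) {
  quality_rule <- match.arg(quality_rule)
  stopifnot(inherits(layout, "read_layout"), phred_offset %in% c(33, 64))
  if (is.character(whitelist)) whitelist <- read_whitelist(whitelist)
  if (nchar(whitelist$barcode[1]) != layout$barcode_length)
    stop("whitelist barcode length differs from layout barcode_length")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # force offset-33 decoding; offset 64 is handled by shifting below
  fq1 <- ShortRead::readFastq(fastq_r1, qualityType = "FastqQuality")
  fq2 <- ShortRead::readFastq(fastq_r2, qualityType = "FastqQuality")
  n <- length(fq1)
  if (length(fq2) != n)
    stop(sprintf("pairing error: %d read-1 records vs %d read-2 records",
                 n, length(fq2)))
  id_token <- function(x) sub("/[12]$", "", sub("[[:space:]].*$", "",
                                                as.character(ShortRead::id(x))))
  ids1 <- id_token(fq1)
  ids2 <- id_token(fq2)
  if (n > 0 && !identical(ids1, ids2)) {
    bad <- which(ids1 != ids2)[1]
    stop(sprintf("pairing error at record %d: '%s' vs '%s'",
                 bad, ids1[bad], ids2[bad]))
  }

  span <- layout_span(layout)
  w1 <- IRanges::width(fq1)
  long_enough <- w1 >= span

  # barcode/UMI substrings and min quality over both spans, vectorized
  bc <- um <- rep(NA_character_, n)
  qual_ok <- rep(FALSE, n)
  if (any(long_enough)) {
    idx <- which(long_enough)
    sr <- ShortRead::sread(fq1)[idx]
    bc[idx] <- as.character(Biostrings::subseq(
      sr, start = layout$barcode_start + 1L, width = layout$barcode_length))
    um[idx] <- as.character(Biostrings::subseq(
      sr, start = layout$umi_start + 1L, width = layout$umi_length))
    qm <- as(Biostrings::quality(fq1)[idx], "matrix")
    if (phred_offset == 64) qm <- qm - 31L  # matrix decodes at offset 33
    cols <- c((layout$barcode_start + 1L):
                (layout$barcode_start + layout$barcode_length),
              (layout$umi_start + 1L):(layout$umi_start + layout$umi_length))
    qsub <- qm[, cols, drop = FALSE]
    qual_ok[idx] <- if (quality_rule == "min_base")
      apply(qsub, 1L, min) >= min_phred
    else rowMeans(qsub) >= min_phred
  }

  fate <- rep("low_quality", n)     # short reads land here too
  cell_of <- rep(NA_integer_, n)
  pass_q <- long_enough & qual_ok
  if (any(pass_q)) {
    m <- match_barcode(bc[pass_q], whitelist$barcode, max_mismatch)
    f <- ifelse(m$status == "matched", "assigned", m$status)
    fate[pass_q] <- f
    cell_of[pass_q] <- m$index
  }

  # write one gz FASTQ per whitelist barcode, input order preserved
  paths <- file.path(out_dir, sprintf("%s_%s.fastq.gz",
                                      experiment_id, whitelist$barcode))
  assigned <- fate == "assigned"
  per_cell <- integer(nrow(whitelist))
  for (j in seq_len(nrow(whitelist))) {
    sel <- which(assigned & cell_of == j)
    reads <- fq2[sel]
    if (!is.null(layout$read2_keep) && length(reads))
      reads <- IRanges::narrow(
        reads, start = 1L,
        end = pmin(IRanges::width(reads), layout$read2_keep))
    newid <- Biostrings::BStringSet(
      if (length(sel)) tag_header_with_umi(ids2[sel], um[sel]) else character())
    out <- ShortRead::ShortReadQ(sread = ShortRead::sread(reads),
                                 quality = Biostrings::quality(reads),
                                 id = newid)
    if (file.exists(paths[j])) unlink(paths[j])
    ShortRead::writeFastq(out, paths[j], mode = "w", compress = TRUE)
    per_cell[j] <- length(sel)
  }

  stats <- structure(list(
    total_pairs = n,
    assigned_pairs = sum(assigned),
    low_quality_pairs = sum(fate == "low_quality"),
    unmatched_pairs = sum(fate == "unmatched"),
    ambiguous_pairs = sum(fate == "ambiguous"),
    per_cell_assigned = setNames(per_cell, whitelist$barcode)
  ), class = "demux_stats")

  cells <- data.frame(
    cell_id = sprintf("%s_%s", experiment_id, whitelist$barcode),
    experiment_id = experiment_id,
    barcode = whitelist$barcode,
    well_label = whitelist$well_label,
    fastq_path = paths,
    reads_assigned = per_cell,
    fraction_of_total = if (n > 0) per_cell / n else 0,
    stringsAsFactors = FALSE
  )
  list(cells = cells, stats = stats)
}

#' Write demultiplexing statistics as TSV
#'
#' One row per stats bucket followed by one row per cell.
#'
#' @param stats `demux_stats` from [demultiplex_run()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_demux_stats <- function(stats, path) {
  stopifnot(inherits(stats, "demux_stats"))
  buckets <- data.frame(
    key = c("total_pairs", "assigned_pairs", "low_quality_pairs",
            "unmatched_pairs", "ambiguous_pairs"),
    value = c(stats$total_pairs, stats$assigned_pairs,
              stats$low_quality_pairs, stats$unmatched_pairs,
              stats$ambiguous_pairs))
  cells <- data.frame(key = paste0("cell:", names(stats$per_cell_assigned)),
                      value = unname(stats$per_cell_assigned))
  write.table(rbind(buckets, cells), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @export
print.demux_stats <- function(x, ...) {
  cat(sprintf(paste0("demux: %d pairs | assigned %d, low-quality %d, ",
                     "unmatched %d, ambiguous %d\n"),
              x$total_pairs, x$assigned_pairs, x$low_quality_pairs,
              x$unmatched_pairs, x$ambiguous_pairs))
  invisible(x)
}
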