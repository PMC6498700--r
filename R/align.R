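#' Describe an external aligner command
#'
#' The pipeline never implements alignment itself: any aligner that
#' preserves read names (and therefore the `:UMI:` tags) can be plugged in
#' through a shell command template.
#'
#' @param command_template shell command containing the placeholders
#'   `{fastq}`, `{out}` and `{index}`; all three are required.
#' @param expected_output `"sam"` or `"bam"`.
#' @return An object of class `aligner_spec`.
#' @examples
#' aligner_spec("STAR --genomeDir {index} --readFilesIn {fastq} --outFileNamePrefix {out}")
#' @export
aligner_spec <- function(command_template, expected_output = c("bam", "sam")) {
  expected_output <- match.arg(expected_output)
  for (ph in c("{fastq}", "{out}", "{index}")) {
    if (!grepl(ph, command_template, fixed = TRUE))
      stop("command template lacks required placeholder ", ph)
  }
  structure(list(command_template = command_template,
                 expected_output = expected_output),
            class = "aligner_spec")
}

#' Align each cell's FASTQ, or attach pre-existing alignments
#'
#' In command mode the template is instantiated per cell and run through the
#' shell; in `pre_aligned` mode existing SAM/BAM files are matched to cells
#' by filename stem (the FASTQ basename without `.fastq[.gz]`), which is
#' also how tests bypass alignment entirely. Either way the adapter never
#' rewrites alignment records. Each cell gains `alignment_path`,
#' `reads_mapped` (primary non-unmapped records) and `fraction_mapped`
#' (relative to `reads_assigned`). Read names in the output must still
#' carry the `:UMI:` tag; a violation is fatal because downstream counting
#' would be meaningless.
#'
#' A nonzero exit status or missing output file is recorded per cell
#' (`align_failed`) and the run continues.
#'
#' @param cells cell annotation data.frame with `fastq_path` and
#'   `reads_assigned` columns.
#' @param spec an [aligner_spec()] (command mode), or `NULL`.
#' @param index_path aligner index path substituted for `{index}`.
#' @param pre_aligned directory of existing per-cell SAM/BAM files, or
#'   `NULL`.
#' @param out_dir where command-mode outputs are written.
#' @return the cells table with `alignment_path`, `reads_mapped`,
#'   `fraction_mapped`, `align_failed` columns.
#' @export
align_cells <- function(cells, spec = NULL, index_path = NULL,
                        pre_aligned = NULL, out_dir = NULL) {
  cells <- as.data.frame(cells)
  stopifnot(all(c("fastq_path", "reads_assigned") %in% names(cells)))
  if (is.null(spec) == is.null(pre_aligned))
    stop("provide exactly one of 'spec' or 'pre_aligned'")
  if (!is.null(spec)) {
    stopifnot(inherits(spec, "aligner_spec"))
    if (is.null(out_dir)) stop("command mode requires out_dir")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  stem <- sub("\\.fastq(\\.gz)?$", "", basename(cells$fastq_path))
  cells$alignment_path <- NA_character_
  cells$reads_mapped <- 0L
  cells$fraction_mapped <- 0
  cells$align_failed <- FALSE

  for (j in seq_len(nrow(cells))) {
    if (!is.null(pre_aligned)) {
      hits <- file.path(pre_aligned, paste0(stem[j], c(".bam", ".sam")))
      hit <- hits[file.exists(hits)]
      if (length(hit) == 0) {
        warning("no pre-aligned file for cell ", cells$cell_id[j])
        cells$align_failed[j] <- TRUE
        next
      }
      out <- hit[1]
    } else {
      out <- file.path(out_dir, paste0(stem[j], ".", spec$expected_output))
      cmd <- spec$command_template
      cmd <- gsub("{fastq}", shQuote(cells$fastq_path[j]), cmd, fixed = TRUE)
      cmd <- gsub("{out}", shQuote(out), cmd, fixed = TRUE)
      cmd <- gsub("{index}", shQuote(index_path %||% ""), cmd, fixed = TRUE)
      status <- system2("/bin/sh", c("-c", shQuote(cmd)))
      if (status != 0 || !file.exists(out)) {
        warning(sprintf("aligner failed for cell %s (exit %d)",
                        cells$cell_id[j], status))
        cells$align_failed[j] <- TRUE
        next
      }
    }
    aln <- read_alignments(out)
    primary <- aln[!aln$secondary, , drop = FALSE]
    if (nrow(primary) > 0) {
      has_tag <- grepl(":UMI:[ACGTN]+$", primary$qname)
      if (!all(has_tag))
        stop(sprintf(
          "aligner contract violation: read names in %s lost the :UMI: tag",
          out))
    }
    cells$alignment_path[j] <- out
    cells$reads_mapped[j] <- sum(!primary$unmapped)
    cells$fraction_mapped[j] <-
      if (cells$reads_assigned[j] > 0)
        cells$reads_mapped[j] / cells$reads_assigned[j] else 0
  }
  cells
}
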