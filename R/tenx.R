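#' Read a Cell Ranger filtered-barcode list
#'
#' One barcode per line; a trailing `-1` style GEM-group suffix is tolerated
#' and stripped.
#'
#' @param path text file of barcodes.
#' @return character vector of normalized barcodes.
#' @export
read_filtered_barcodes <- function(path) {
  if (!file.exists(path)) stop("barcode list not found: ", path)
  bc <- readLines(path)
  bc <- bc[nzchar(bc)]
  if (length(bc) == 0) stop("barcode list is empty: ", path)
  unique(sub("-[0-9]+$", "", bc))
}

#' Per-barcode alignment QC from a Cell Ranger style BAM
#'
#' Restricted to the filtered-barcode list: for every listed barcode,
#' `reads_mapped` counts primary non-unmapped records whose corrected cell
#' barcode (`CB` tag; fallback `CR` with a warning) matches, and
#' `reads_mapped_to_genes` additionally requires a gene-assignment tag
#' (`GX`; fallback `GN`). Barcodes absent from the BAM get zero rows;
#' records from unlisted barcodes are dropped, never reassigned. The result
#' feeds [build_qc_table()]-style plotting across runs.
#'
#' @param bam_path BAM file with cell-barcode tags.
#' @param filtered_barcodes character vector (or path to a file readable by
#'   [read_filtered_barcodes()]).
#' @param run_label label for this run in multi-run plots.
#' @return data.frame with `barcode`, `run_label`, `reads_mapped`,
#'   `reads_mapped_to_genes`, `fraction_gene_reads`, ordered as the input
#'   barcode list.
#' @export
tenx_bamqc <- function(bam_path, filtered_barcodes, run_label = "run1") {
  if (is.character(filtered_barcodes) && length(filtered_barcodes) == 1 &&
      file.exists(filtered_barcodes))
    filtered_barcodes <- read_filtered_barcodes(filtered_barcodes)
  filtered_barcodes <- unique(sub("-[0-9]+$", "", filtered_barcodes))
  if (length(filtered_barcodes) == 0) stop("empty filtered barcode list")

  p <- Rsamtools::ScanBamParam(what = c("flag"),
                               tag = c("CB", "CR", "GX", "GN"))
  r <- Rsamtools::scanBam(bam_path, param = p)[[1]]
  n <- length(r$flag)
  tags <- r$tag
  cb <- tags$CB
  if (is.null(cb) || all(is.na(cb))) {
    cr <- tags$CR
    if (is.null(cr) || all(is.na(cr))) {
      if (n == 0) stop("BAM has no records: ", bam_path)
      stop("BAM carries neither CB nor CR cell-barcode tags: ", bam_path)
    }
    warning("no CB tags found; falling back to raw CR barcodes")
    cb <- cr
  }
  if (length(cb) < n) length(cb) <- n   # scanBam pads missing tags with NA
  gx <- tags$GX
  if (is.null(gx) || all(is.na(gx))) gx <- tags$GN
  if (is.null(gx)) gx <- rep(NA_character_, n)
  if (length(gx) < n) length(gx) <- n

  flag <- r$flag
  primary_mapped <- bitwAnd(flag, 4L) == 0L & bitwAnd(flag, 256L) == 0L &
    bitwAnd(flag, 2048L) == 0L
  bc_norm <- sub("-[0-9]+$", "", cb)
  usable <- primary_mapped & !is.na(bc_norm)
  idx <- match(bc_norm, filtered_barcodes)
  listed <- usable & !is.na(idx)

  reads_mapped <- tabulate(idx[listed], nbins = length(filtered_barcodes))
  gene_rec <- listed & !is.na(gx)
  reads_genes <- tabulate(idx[gene_rec], nbins = length(filtered_barcodes))
  data.frame(
    barcode = filtered_barcodes,
    run_label = run_label,
    reads_mapped = reads_mapped,
    reads_mapped_to_genes = reads_genes,
    fraction_gene_reads = ifelse(reads_mapped > 0,
                                 reads_genes / reads_mapped, 0),
    stringsAsFactors = FALSE)
}
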