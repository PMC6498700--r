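#' Describe the positional layout of barcode and UMI within read 1
#'
#' Plate-based protocols place a cell barcode and a unique molecular
#' identifier (UMI) at fixed offsets of read 1, with the transcript sequence
#' on read 2. CEL-Seq puts the barcode first, CEL-Seq2 puts the UMI first;
#' both are expressed through this one structure.
#'
#' @param barcode_start 0-based offset of the first barcode base in read 1.
#' @param barcode_length number of barcode bases (>= 1).
#' @param umi_start 0-based offset of the first UMI base in read 1.
#' @param umi_length number of UMI bases (>= 1).
#' @param read2_keep optional number of leading read-2 bases to retain after
#'   demultiplexing (`NULL` keeps the whole read); useful when 3' read ends
#'   have poor quality.
#'
#' @return An object of class `read_layout`.
#' @examples
#' read_layout(0, 8, 8, 6)            # CEL-Seq style: barcode then UMI
#' read_layout(6, 6, 0, 6)            # CEL-Seq2 style: UMI then barcode
#' @export
read_layout <- function(barcode_start, barcode_length, umi_start, umi_length,
                        read2_keep = NULL) {
  stopifnot(barcode_start >= 0, umi_start >= 0,
            barcode_length >= 1, umi_length >= 1)
  if (!is.null(read2_keep) && read2_keep < 1)
    stop("read2_keep, if given, must be >= 1")
  bc <- c(barcode_start, barcode_start + barcode_length)
  um <- c(umi_start, umi_start + umi_length)
  if (max(bc[1], um[1]) < min(bc[2], um[2]))
    stop("barcode and UMI spans overlap in read 1")
  structure(list(
    barcode_start = as.integer(barcode_start),
    barcode_length = as.integer(barcode_length),
    umi_start = as.integer(umi_start),
    umi_length = as.integer(umi_length),
    read2_keep = if (is.null(read2_keep)) NULL else as.integer(read2_keep)
  ), class = "read_layout")
}

# minimum read-1 length this layout requires
layout_span <- function(layout) {
  max(layout$barcode_start + layout$barcode_length,
      layout$umi_start + layout$umi_length)
}

#' @export
print.read_layout <- function(x, ...) {
  cat(sprintf("read layout: barcode [%d,%d), UMI [%d,%d)%s\n",
              x$barcode_start, x$barcode_start + x$barcode_length,
              x$umi_start, x$umi_start + x$umi_length,
              if (is.null(x$read2_keep)) ""
              else sprintf(", keep first %d bases of read 2", x$read2_keep)))
  invisible(x)
}
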