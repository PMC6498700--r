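#' Read-track data for a genomic region
#'
#' Collects every primary mapped alignment overlapping the query region from
#' one cell's alignment file: one datum per read, spanning the leftmost to
#' rightmost aligned base (spliced reads are drawn as one arrow), with the
#' UMI parsed from the read name and a greedy first-fit display row so that
#' arrows in one row never collide.
#'
#' @param alignment_path SAM or BAM for one cell.
#' @param chrom chromosome name.
#' @param start,end region, 0-based half-open.
#' @return data.frame with `read_id`, `start`, `end` (0-based half-open),
#'   `strand`, `umi`, `row`; attributes `chrom`, `start`, `end` record the
#'   region. An unknown chromosome yields an empty track with a warning.
#' @export
rview_data <- function(alignment_path, chrom, start, end) {
  stopifnot(end > start)
  aln <- read_alignments(alignment_path)
  keep <- !aln$secondary & !aln$unmapped
  aln <- aln[keep, , drop = FALSE]
  if (nrow(aln) > 0 && !chrom %in% aln$chrom)
    warning("no alignments on chromosome ", chrom)
  dat <- data.frame(read_id = character(), start = integer(),
                    end = integer(), strand = character(),
                    umi = character(), row = integer(),
                    stringsAsFactors = FALSE)
  if (nrow(aln) > 0) {
    span_s <- vapply(aln$blocks, function(b) min(b[, 1]), numeric(1))
    span_e <- vapply(aln$blocks, function(b) max(b[, 2]), numeric(1))
    ov <- aln$chrom == chrom & span_s < end & span_e > start
    if (any(ov)) {
      umi <- umis_from_names(aln$qname[ov])
      dat <- data.frame(read_id = sub(":UMI:[ACGTN]+$", "", aln$qname[ov]),
                        start = as.integer(span_s[ov]),
                        end = as.integer(span_e[ov]),
                        strand = aln$strand[ov],
                        umi = umi, stringsAsFactors = FALSE)
      dat <- dat[order(dat$start, dat$end), , drop = FALSE]
      dat$row <- pack_rows(dat$start, dat$end)
      rownames(dat) <- NULL
    }
  }
  structure(dat, chrom = chrom, region_start = start, region_end = end)
}

# greedy first-fit interval packing: each datum goes to the lowest row whose
# rightmost end does not overlap it
pack_rows <- function(start, end) {
  row_end <- numeric(0)
  rows <- integer(length(start))
  for (i in seq_along(start)) {
    fit <- which(row_end <= start[i])
    if (length(fit)) {
      rows[i] <- fit[1]
      row_end[fit[1]] <- end[i]
    } else {
      row_end <- c(row_end, end[i])
      rows[i] <- length(row_end)
    }
  }
  rows
}

#' Isoform-track data for a genomic region
#'
#' One datum per transcript with at least one exon overlapping the region;
#' exons are clipped to the region for display.
#'
#' @param models a `gene_models` object.
#' @param chrom chromosome name.
#' @param start,end region, 0-based half-open.
#' @return data.frame with `transcript_name`, `gene_id`, `strand`, and
#'   clipped exon `start`/`end` (one row per exon); region attributes as in
#'   [rview_data()]. Empty when nothing overlaps.
#' @export
gview_data <- function(models, chrom, start, end) {
  stopifnot(inherits(models, "gene_models"), end > start)
  out <- list()
  sel <- which(models$genes$chrom == chrom)
  for (gi in sel) {
    g <- models$genes[gi, ]
    for (tx in names(models$transcripts[[g$gene_id]])) {
      ex <- models$transcripts[[g$gene_id]][[tx]]
      ov <- ex[, 1] < end & ex[, 2] > start
      if (!any(ov)) next
      ex <- ex[ov, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        transcript_name = tx, gene_id = g$gene_id, strand = g$strand,
        start = pmax(ex[, 1], start), end = pmin(ex[, 2], end),
        stringsAsFactors = FALSE)
    }
  }
  dat <- if (length(out)) do.call(rbind, out)
  else data.frame(transcript_name = character(), gene_id = character(),
                  strand = character(), start = integer(), end = integer(),
                  stringsAsFactors = FALSE)
  rownames(dat) <- NULL
  structure(dat, chrom = chrom, region_start = start, region_end = end)
}

# deterministic UMI -> palette colour so identical UMIs share colour across
# figures
umi_colour <- function(umi, palette = grDevices::hcl.colors(32, "Dark 3")) {
  h <- vapply(umi, function(u)
    sum(utf8ToInt(u) * seq_len(nchar(u)) * 131L) %% length(palette),
    numeric(1))
  palette[h + 1L]
}

#' Combined read + isoform track figure
#'
#' Reads (arrows, coloured by UMI, direction = mapping strand) are drawn
#' above the isoform track (grey exon rectangles labelled by transcript
#' name) on a shared x axis in 1-based display coordinates.
#'
#' @param read_track output of [rview_data()].
#' @param isoform_track output of [gview_data()] for the same region.
#' @param out_path output figure file (extension selects the device, e.g.
#'   `.png`, `.svg`, `.pdf`).
#' @return `out_path`, invisibly.
#' @export
combine_tracks <- function(read_track, isoform_track, out_path) {
  same <- function(a) identical(attr(read_track, a), attr(isoform_track, a))
  if (!same("chrom") || !same("region_start") || !same("region_end"))
    stop("read and isoform tracks cover different regions")
  chrom <- attr(read_track, "chrom")
  xs <- attr(read_track, "region_start") + 1L  # 1-based display
  xe <- attr(read_track, "region_end")

  n_tx <- length(unique(isoform_track$transcript_name))
  p <- ggplot2::ggplot() +
    ggplot2::coord_cartesian(xlim = c(xs, xe)) +
    ggplot2::labs(x = sprintf("%s position (1-based)", chrom), y = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank(),
                   legend.position = "none")
  if (nrow(isoform_track) > 0) {
    iso <- isoform_track
    iso$lane <- match(iso$transcript_name, unique(iso$transcript_name))
    p <- p +
      ggplot2::geom_rect(data = iso, ggplot2::aes(
        xmin = start + 1, xmax = end, ymin = -lane - 0.35,
        ymax = -lane + 0.35), fill = "grey60") +
      ggplot2::geom_text(data = iso[!duplicated(iso$transcript_name), ],
                         ggplot2::aes(x = xs, y = -lane + 0.55,
                                      label = transcript_name),
                         hjust = 0, size = 2.6)
  }
  if (nrow(read_track) > 0) {
    rt <- read_track
    rt$x0 <- ifelse(rt$strand == "+", rt$start + 1, rt$end)
    rt$x1 <- ifelse(rt$strand == "+", rt$end, rt$start + 1)
    rt$colour <- umi_colour(rt$umi)
    p <- p + ggplot2::geom_segment(
      data = rt,
      ggplot2::aes(x = x0, xend = x1, y = row, yend = row),
      colour = rt$colour,
      arrow = ggplot2::arrow(length = ggplot2::unit(1.6, "mm"),
                             type = "closed"))
  }
  ggplot2::ggsave(out_path, p, width = 7,
                  height = 2 + 0.1 * max(c(read_track$row, 4)) + 0.3 * n_tx,
                  limitsize = FALSE)
  invisible(out_path)
}
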