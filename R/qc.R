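#' Assemble the rectangular per-cell QC metrics table
#'
#' One row per cell with identifiers and every QC metric collected across
#' demultiplexing, alignment and counting: read totals and the three
#' mapped-read fraction variants, transcript (UMI) totals, mitochondrial and
#' protein-coding fractions, genes detected, reads per corrected and
#' uncorrected UMI (median and mean), and genes detected per million reads.
#' Metrics missing from the input (for example when counting failed for a
#' cell) are filled with 0 and flagged.
#'
#' @param cells cell annotation data.frame accumulated by the pipeline.
#' @return data.frame, one row per cell; identifier columns `cell_id`,
#'   `experiment_id`, `barcode` followed by numeric metric columns and a
#'   logical `qc_flag`.
#' @export
build_qc_table <- function(cells) {
  cells <- as.data.frame(cells)
  if (anyDuplicated(cells$cell_id)) stop("duplicated cell_id")
  need_id <- c("cell_id", "experiment_id", "barcode")
  stopifnot(all(need_id %in% names(cells)))
  metrics <- c(
    "reads_assigned", "fraction_of_total", "reads_mapped", "fraction_mapped",
    "total_reads", "reads_mapped_to_genome", "reads_mapped_to_genes",
    "frac_mapped_to_genome", "frac_gene_reads_in_mapped",
    "frac_gene_reads_in_total", "total_umis", "mito_umis", "frac_mito_umis",
    "genes_detected", "protein_coding_genes_detected",
    "frac_protein_coding_genes", "protein_coding_umis",
    "frac_protein_coding_umis", "reads_per_umi_median", "reads_per_umi_mean",
    "reads_per_corrected_umi_median", "reads_per_corrected_umi_mean",
    "genes_per_million_reads")
  out <- cells[need_id]
  flag <- if ("qc_flag" %in% names(cells)) as.logical(cells$qc_flag)
          else rep(FALSE, nrow(cells))
  flag[is.na(flag)] <- TRUE
  get0n <- function(nm) {
    if (nm %in% names(cells)) {
      v <- as.numeric(cells[[nm]])
      miss <- is.na(v)
      flag[miss] <<- TRUE
      v[miss] <- 0
      v
    } else NULL
  }
  # derived fractions: computed here from the component metrics so the table
  # is complete even if the caller never stored them
  base <- list(
    frac_mapped_to_genome = c("reads_mapped_to_genome", "total_reads"),
    frac_gene_reads_in_mapped = c("reads_mapped_to_genes",
                                  "reads_mapped_to_genome"),
    frac_gene_reads_in_total = c("reads_mapped_to_genes", "total_reads"),
    frac_mito_umis = c("mito_umis", "total_umis"),
    frac_protein_coding_genes = c("protein_coding_genes_detected",
                                  "genes_detected"),
    frac_protein_coding_umis = c("protein_coding_umis", "total_umis"))
  for (m in metrics) {
    v <- get0n(m)
    if (is.null(v) && m %in% names(base)) {
      num <- get0n(base[[m]][1]); den <- get0n(base[[m]][2])
      if (!is.null(num) && !is.null(den)) {
        v <- ifelse(den > 0, num / den, 0)
        flag[den == 0] <- TRUE
      }
    }
    if (is.null(v)) {
      v <- rep(0, nrow(cells))
      flag <- rep(TRUE, nrow(cells))
    }
    out[[m]] <- v
  }
  out$qc_flag <- flag
  out
}

#' Long-format plot data behind [qc_plots()]
#'
#' Pure builder (no rendering): one row per cell per metric.
#'
#' @param table output of [build_qc_table()].
#' @return data.frame with `metric`, `experiment_id`, `cell_id`, `value`.
#' @export
qc_plot_data <- function(table) {
  id_cols <- c("cell_id", "experiment_id", "barcode", "qc_flag")
  metric_cols <- setdiff(names(table), id_cols)
  long <- do.call(rbind, lapply(metric_cols, function(m)
    data.frame(metric = m, experiment_id = table$experiment_id,
               cell_id = table$cell_id, value = as.numeric(table[[m]]),
               stringsAsFactors = FALSE)))
  long$metric <- factor(long$metric, levels = metric_cols)
  long
}

#' Render the per-metric QC boxplot report
#'
#' One boxplot panel per metric, one box per experiment, individual cells
#' overlaid as jittered points (fixed jitter seed for reproducible output).
#' Whiskers extend to 1.5 IQR.
#'
#' @param table output of [build_qc_table()]; must be non-empty.
#' @param out_path output file; `.pdf` gives one page per metric, any other
#'   extension is treated as a directory receiving one SVG per metric.
#' @param jitter_seed seed for point jitter.
#' @return `out_path`, invisibly.
#' @export
qc_plots <- function(table, out_path, jitter_seed = 1L) {
  if (nrow(table) == 0) stop("empty QC table")
  long <- qc_plot_data(table)
  panel <- function(d) {
    ggplot2::ggplot(d, ggplot2::aes(x = experiment_id, y = value)) +
      ggplot2::geom_boxplot(outlier.shape = NA, coef = 1.5) +
      ggplot2::geom_point(position = ggplot2::position_jitter(
        width = 0.2, height = 0, seed = jitter_seed),
        size = 1, colour = "steelblue") +
      ggplot2::labs(title = unique(as.character(d$metric)),
                    x = "experiment", y = NULL) +
      ggplot2::theme_bw()
  }
  if (grepl("\\.pdf$", out_path, ignore.case = TRUE)) {
    pdf(out_path, width = 6, height = 4, onefile = TRUE)
    on.exit(dev.off())
    for (m in levels(long$metric)) print(panel(long[long$metric == m, ]))
  } else {
    dir.create(out_path, showWarnings = FALSE, recursive = TRUE)
    for (m in levels(long$metric)) {
      p <- panel(long[long$metric == m, ])
      ggplot2::ggsave(file.path(out_path, paste0(m, ".svg")), p,
                      width = 6, height = 4)
    }
  }
  invisible(out_path)
}
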