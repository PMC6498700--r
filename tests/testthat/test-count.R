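# three genes for assignment unit cases:
#  gA + strand exons [99,300); gB + strand [280,400) (overlaps gA tail);
#  gC - strand spliced [500,520)+[600,650)
unit_models <- function() {
  load_gene_models(write_tiny_gtf(list(
    list(gene_id = "gA", chrom = "chr1", strand = "+",
         tx = list(tA = rbind(c(99, 300)))),
    list(gene_id = "gB", chrom = "chr1", strand = "+",
         tx = list(tB = rbind(c(280, 400)))),
    list(gene_id = "gC", chrom = "chr1", strand = "-",
         tx = list(tC = rbind(c(500, 520), c(600, 650)))))))
}

test_that("union-mode assignment: unique, ambiguous, spliced, stranded", {
  models <- unit_models()
  # block inside gA only
  expect_equal(
    assign_read_to_gene(rbind(c(120, 170)), "chr1", "+", models, "sense"),
    list(outcome = "assigned", gene_id = "gA"))
  # block overlapping gA and gB -> ambiguous
  expect_equal(
    assign_read_to_gene(rbind(c(290, 310)), "chr1", "+", models,
                        "sense")$outcome, "ambiguous")
  # spliced read: only the second block touches gC
  expect_equal(
    assign_read_to_gene(rbind(c(450, 470), c(610, 630)), "chr1", "-",
                        models, "sense"),
    list(outcome = "assigned", gene_id = "gC"))
  # strand flip: sense read over the antisense-only gene
  expect_equal(
    assign_read_to_gene(rbind(c(610, 630)), "chr1", "+", models,
                        "sense")$outcome, "no_feature")
  expect_equal(
    assign_read_to_gene(rbind(c(610, 630)), "chr1", "+", models,
                        "antisense")$outcome, "assigned")
  # unknown chromosome
  expect_equal(
    assign_read_to_gene(rbind(c(120, 170)), "chr9", "+", models,
                        "sense")$outcome, "no_feature")
})

test_that("assignment agrees with the nested-loop oracle on random cases", {
  set.seed(21)
  n_genes <- 30
  gtf_genes <- list(); gene_defs <- list()
  for (i in seq_len(n_genes)) {
    chrom <- sample(c("c1", "c2"), 1)
    s <- sample(0:8000, 1)
    n_ex <- sample(1:3, 1)
    starts <- sort(sample(s:(s + 700), n_ex))
    ex <- cbind(starts, starts + sample(40:200, n_ex, replace = TRUE))
    gid <- sprintf("g%02d", i)
    strand <- sample(c("+", "-"), 1)
    gtf_genes[[i]] <- list(gene_id = gid, chrom = chrom, strand = strand,
                           tx = list(t1 = ex))
    gene_defs[[i]] <- list(gene_id = gid, chrom = chrom, strand = strand,
                           union = exon_union(ex))
  }
  models <- load_gene_models(write_tiny_gtf(gtf_genes))
  for (r in 1:350) {
    chrom <- sample(c("c1", "c2"), 1)
    strand <- sample(c("+", "-"), 1)
    mode <- sample(c("sense", "antisense", "unstranded"), 1)
    s1 <- sample(0:9000, 1)
    blocks <- rbind(c(s1, s1 + sample(20:120, 1)))
    if (runif(1) < 0.4) {           # spliced
      s2 <- blocks[1, 2] + sample(30:400, 1)
      blocks <- rbind(blocks, c(s2, s2 + sample(20:120, 1)))
    }
    got <- assign_read_to_gene(blocks, chrom, strand, models, mode)
    want <- assign_oracle(blocks, chrom, strand, gene_defs, mode)
    expect_identical(got$outcome, want$outcome)
    if (want$outcome == "assigned")
      expect_identical(got$gene_id, want$gene_id)
  }
})

test_that("UMI dedup: raw counts, degenerate input, directional collapse", {
  expect_equal(dedup_umis(c("AAAA", "AAAA", "CCCC"))$raw, 2L)
  expect_equal(dedup_umis(character(0)), list(raw = 0L, corrected = 0L))
  expect_error(dedup_umis("AC-G"), "outside")

  # directional: 10x AAAA absorbs 3x AAAT (10 >= 2*3)
  expect_equal(dedup_umis(c(rep("AAAA", 10), rep("AAAT", 3)))$corrected, 1L)
  # 2x vs 2x: support rule fails (2 < 2*2), two clusters
  expect_equal(dedup_umis(c(rep("AAAA", 2), rep("AAAT", 2)))$corrected, 2L)
  # distance 2 never collapses
  expect_equal(dedup_umis(c(rep("AAAA", 10), rep("AATT", 1)))$corrected, 2L)

  # idempotence on the distinct set; duplicate monotonicity
  set.seed(2)
  for (i in 1:20) {
    umis <- replicate(sample(1:30, 1), paste(
      sample(c("A", "C", "G", "T"), 5, replace = TRUE), collapse = ""))
    raw1 <- dedup_umis(umis)$raw
    expect_equal(dedup_umis(unique(umis))$raw, raw1)
    expect_equal(dedup_umis(c(umis, umis[1]))$raw, raw1)    # PCR duplicate
    novel <- "NNNNN"
    expect_equal(dedup_umis(c(umis, novel))$raw, raw1 + 1L) # novel UMI
  }
})

test_that("directional collapse matches the pairwise-Hamming oracle", {
  set.seed(13)
  for (rep in 1:25) {
    base <- replicate(sample(3:20, 1), paste(
      sample(c("A", "C", "G", "T"), 6, replace = TRUE), collapse = ""))
    reads <- sample(base, 200, replace = TRUE)
    # seed 1-edit errors on a fraction of the reads
    err <- runif(200) < 0.15
    for (i in which(err)) {
      p <- sample(6, 1)
      v <- strsplit(reads[i], "")[[1]]
      v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
      reads[i] <- paste(v, collapse = "")
    }
    got <- dedup_umis(reads)
    want <- dedup_oracle(reads)
    expect_equal(got$raw, want$raw)
    expect_equal(got$corrected, want$corrected)
    expect_lte(got$corrected, got$raw)
  }
})

test_that("count_cell on a hand-built fixture matches hand computation", {
  models <- unit_models()
  sam <- write_tiny_sam(
    tempfile(fileext = ".sam"), c(chr1 = 1000),
    qname = c("r1:UMI:AAAA", "r2:UMI:AAAA", "r3:UMI:CCCC", "r4:UMI:AAAA",
              "r5:UMI:GGGG", "r6:UMI:TTTT"),
    flag = c(0L, 0L, 0L, 16L, 4L, 256L),
    chrom = rep("chr1", 6),
    pos0 = c(120L, 130L, 140L, 610L, 0L, 120L),
    cigar = c("30M", "30M", "30M", "20M", "*", "30M"))
  # gene gA gets UMIs {AAAA, AAAA, CCCC}; gC gets {AAAA}; r5 unmapped;
  # r6 secondary (skipped)
  cc <- count_cell(sam, models, "sense")
  expect_equal(unname(cc$per_gene_umi[c("gA", "gC")]), c(2L, 1L))
  expect_equal(unname(cc$per_gene_reads[c("gA", "gC")]), c(3L, 1L))
  m <- cc$metrics
  expect_equal(unname(m["total_reads"]), 5)            # primary records
  expect_equal(unname(m["reads_mapped_to_genome"]), 4)
  expect_equal(unname(m["reads_mapped_to_genes"]), 4)
  expect_equal(unname(m["total_umis"]), 3)
  expect_equal(unname(m["reads_per_umi_mean"]), 4 / 3)
  expect_equal(unname(m["reads_per_umi_median"]), 1)
  expect_equal(unname(m["genes_detected"]), 2)
})

test_that("count_cell degenerate cases: all unmapped, missing UMI tag", {
  models <- unit_models()
  sam0 <- write_tiny_sam(tempfile(fileext = ".sam"), c(chr1 = 1000),
                         qname = c("r1:UMI:AAAA", "r2:UMI:CCCC"),
                         flag = c(4L, 4L), chrom = c("*", "*"),
                         pos0 = c(0L, 0L), cigar = c("*", "*"))
  cc <- count_cell(sam0, models)
  expect_equal(sum(cc$per_gene_umi), 0L)
  expect_equal(unname(cc$metrics["genes_detected"]), 0)
  expect_equal(unname(cc$metrics["reads_per_umi_median"]), 0)  # convention
  expect_true(cc$qc_flag)

  sam_bad <- write_tiny_sam(tempfile(fileext = ".sam"), c(chr1 = 1000),
                            qname = "r1", flag = 0L, chrom = "chr1",
                            pos0 = 120L, cigar = "30M")
  expect_error(count_cell(sam_bad, models), ":UMI:")
})

test_that("spike-in genes count in the matrix but not in the QC metrics", {
  models <- load_gene_models(write_tiny_gtf(list(
    list(gene_id = "gA", chrom = "chr1", strand = "+",
         tx = list(tA = rbind(c(0, 300)))),
    list(gene_id = "ERCC-0001", chrom = "ERCC", strand = "+",
         biotype = "spike_in", tx = list(tE = rbind(c(0, 200)))))))
  sam <- write_tiny_sam(
    tempfile(fileext = ".sam"), c(chr1 = 1000, ERCC = 500),
    qname = c("r1:UMI:AAAA", "r2:UMI:CCCC", "r3:UMI:GGGG"),
    flag = c(0L, 0L, 0L),
    chrom = c("chr1", "ERCC", "ERCC"),
    pos0 = c(10L, 10L, 50L), cigar = rep("20M", 3))
  cc <- count_cell(sam, models, "sense")
  expect_equal(unname(cc$per_gene_umi[["ERCC-0001"]]), 2L)  # in matrix
  expect_equal(unname(cc$metrics["total_umis"]), 1)         # excluded
  expect_equal(unname(cc$metrics["genes_detected"]), 1)
})

test_that("count_experiment composes per-cell results, order-invariantly", {
  sim <- shared_sim()
  dm <- run_demux(sim, file.path(tempdir(), "ce_demux"))
  cells <- align_cells(dm$cells, pre_aligned = file.path(sim$out_dir, "sam"))
  es <- count_experiment(cells, sim$reference$models)
  # column j equals count_cell of cell j
  for (j in c(1, 5, 12)) {
    cc <- count_cell(cells$alignment_path[j], sim$reference$models)
    expect_equal(es$matrix[, j], cc$per_gene_umi)
  }
  # permuted cell order: identical matrix up to column order
  perm <- sample(nrow(cells))
  es2 <- count_experiment(cells[perm, ], sim$reference$models)
  expect_equal(unclass(es2$matrix)[, colnames(es$matrix)],
               unclass(es$matrix)[, ])
  # a broken alignment file yields a zero column and a flag, not an abort
  cells_bad <- cells
  cells_bad$alignment_path[3] <- tempfile(fileext = ".sam")  # missing
  expect_warning(es3 <- count_experiment(cells_bad, sim$reference$models),
                 "counting failed")
  expect_true(es3$cells$count_failed[3])
  expect_equal(sum(es3$matrix[, 3]), 0L)
  expect_equal(unclass(es3$matrix)[, -3], unclass(es$matrix)[, -3])
})

test_that("per-cell count/read inequalities hold on noisy data", {
  sim <- shared_noisy_sim()
  dm <- run_demux(sim, file.path(tempdir(), "ineq_demux"))
  cells <- align_cells(dm$cells, pre_aligned = file.path(sim$out_dir, "sam"))
  es <- count_experiment(cells, sim$reference$models)
  cc <- es$cells
  expect_true(all(colSums(es$matrix) <= cc$reads_mapped_to_genes))
  expect_true(all(cc$reads_mapped_to_genes <= cc$reads_mapped_to_genome))
  expect_true(all(cc$reads_mapped_to_genome <= cc$reads_assigned))
  expect_true(all(es$matrix >= 0))
})
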