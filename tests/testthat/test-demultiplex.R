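test_that("barcode and UMI are cut at the layout offsets", {
  layout <- read_layout(0, 8, 8, 4)
  r <- extract_barcode_umi("ACGTACGTTTAACC", rep(30L, 14), layout)
  expect_equal(r$barcode, "ACGTACGT")
  expect_equal(r$umi, "TTAA")
  expect_equal(r$qual, rep(30L, 12))

  # CEL-Seq2 style: UMI first
  layout2 <- read_layout(6, 6, 0, 6)
  r2 <- extract_barcode_umi("AAAAAACGCGCGTT", rep(30L, 14), layout2)
  expect_equal(r2$barcode, "CGCGCG")
  expect_equal(r2$umi, "AAAAAA")

  expect_error(extract_barcode_umi("ACGTA", rep(30L, 5),
                                   read_layout(0, 8, 8, 4)),
               class = "plateseq_structure_error")
})

test_that("read_layout rejects overlapping spans", {
  expect_error(read_layout(0, 8, 4, 6), "overlap")
  expect_error(read_layout(0, 8, 8, 0), NULL)
})

test_that("quality rule: every barcode/UMI base must reach the threshold", {
  expect_true(passes_quality(c(30L, 30L, 30L), 10))
  expect_false(passes_quality(c(30L, 9L, 30L), 10))
  expect_true(passes_quality(integer(0), 93))      # vacuous
  expect_true(passes_quality(c(30L, 9L, 30L), 10, rule = "mean"))
})

test_that("barcode matching handles exact, near and ambiguous cases", {
  wl <- c("AAAA", "CCCC")
  expect_equal(match_barcode("AAAT", wl, 1),
               data.frame(status = "matched", index = 1L))
  expect_equal(match_barcode("AATT", wl, 1)$status, "unmatched")
  expect_equal(match_barcode("AAAC", c("AAAA", "AAAT"), 1)$status,
               "ambiguous")
  # max_mismatch 0 reduces to exact membership
  obs <- c("AAAA", "CCCC", "AAAC")
  m0 <- match_barcode(obs, wl, 0)
  expect_equal(m0$status == "matched", obs %in% wl)
  # N counts as a mismatch everywhere
  expect_equal(match_barcode("AAAN", wl, 1)$index, 1L)
  expect_equal(match_barcode("AANN", wl, 1)$status, "unmatched")
  expect_error(match_barcode("AAAAA", wl, 1), "length")
})

test_that("barcode matching agrees with the brute-force oracle", {
  set.seed(7)
  bases <- c("A", "C", "G", "T", "N")
  for (rep in 1:40) {
    k <- sample(4:10, 1)
    wl <- unique(replicate(sample(2:12, 1), paste(
      sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")))
    mm <- sample(0:(k - 1), 1)
    obs <- replicate(50, paste(sample(bases, k, replace = TRUE,
                                      prob = c(rep(0.24, 4), 0.04)),
                               collapse = ""))
    got <- match_barcode(obs, wl, mm)
    for (i in seq_along(obs)) {
      want <- match_barcode_oracle(obs[i], wl, mm)
      expect_identical(got$status[i], want$status)
      if (want$status == "matched")
        expect_identical(got$index[i], as.integer(want$index))
    }
  }
})

test_that("UMI header tagging round-trips and validates", {
  tagged <- tag_header_with_umi("NS500:7:ABC:1:101:500:900", "TTAA")
  expect_equal(tagged, "NS500:7:ABC:1:101:500:900:UMI:TTAA")
  expect_error(tag_header_with_umi("id", "TT-A"), "outside")
  expect_error(tag_header_with_umi("id with space", "TTAA"), "whitespace")
  set.seed(3)
  for (i in 1:50) {
    id <- paste0("M:", paste(sample(c(LETTERS, 0:9, ":"), 12,
                                    replace = TRUE), collapse = ""))
    umi <- paste(sample(c("A", "C", "G", "T", "N"), 8, replace = TRUE),
                 collapse = "")
    back <- parse_umi_tag(tag_header_with_umi(id, umi))
    expect_equal(back$read_id, id)
    expect_equal(back$umi, umi)
  }
})

test_that("demultiplex_run routes reads, filters and keeps order", {
  dir <- file.path(tempdir(), "dm_small")
  layout <- read_layout(0, 4, 4, 3)
  wl <- data.frame(barcode = c("AAAA", "CCCC"), well_label = c("w1", "w2"))
  ids <- c("p1", "p2", "p3", "p4", "p5")
  # p1 -> AAAA; p2 -> CCCC; p3 low quality (UMI base 5); p4 unmatched;
  # p5 -> AAAA again (order check)
  r1seq <- c("AAAAGGG", "CCCCTTT", "AAAAGGG", "GGTTAAA", "AAAACCC")
  r1q <- c(qual_str(rep(30, 7)), qual_str(rep(30, 7)),
           qual_str(c(30, 30, 30, 30, 5, 30, 30)),
           qual_str(rep(30, 7)), qual_str(rep(30, 7)))
  r1 <- write_fastq_plain(tempfile(fileext = ".fastq"), ids, r1seq, r1q)
  r2 <- write_fastq_plain(tempfile(fileext = ".fastq"), ids,
                          c("ACGTACGTAC", "TGCATGCATG", "ACACACACAC",
                            "GTGTGTGTGT", "CACACACACA"),
                          rep(qual_str(rep(35, 10)), 5))
  res <- demultiplex_run(r1, r2, wl, layout, dir, experiment_id = "e1",
                         min_phred = 10, max_mismatch = 1)
  s <- res$stats
  expect_equal(s$total_pairs, 5L)
  expect_equal(s$assigned_pairs, 3L)
  expect_equal(s$low_quality_pairs, 1L)
  expect_equal(s$unmatched_pairs, 1L)
  expect_equal(unname(s$per_cell_assigned), c(2L, 1L))

  fqA <- ShortRead::readFastq(file.path(dir, "e1_AAAA.fastq.gz"))
  expect_equal(as.character(ShortRead::id(fqA)),
               c("p1:UMI:GGG", "p5:UMI:CCC"))       # input order kept
  expect_equal(as.character(ShortRead::sread(fqA)),
               c("ACGTACGTAC", "CACACACACA"))
  # empty per-cell file still created for unused barcodes
  expect_true(file.exists(file.path(dir, "e1_CCCC.fastq.gz")))

  # read2_keep trims the transcript read
  layout_k <- read_layout(0, 4, 4, 3, read2_keep = 6)
  res_k <- demultiplex_run(r1, r2, wl, layout_k,
                           file.path(tempdir(), "dm_keep"),
                           experiment_id = "e1")
  fqk <- ShortRead::readFastq(file.path(tempdir(), "dm_keep",
                                        "e1_AAAA.fastq.gz"))
  expect_equal(unique(IRanges::width(fqk)), 6L)
})

test_that("a pair failing both filters is counted low-quality (filter order)", {
  dir <- file.path(tempdir(), "dm_order")
  layout <- read_layout(0, 4, 4, 3)
  wl <- data.frame(barcode = "AAAA", well_label = "w1")
  # barcode GGGG (unmatched) AND bad quality -> must land in low_quality
  r1 <- write_fastq_plain(tempfile(fileext = ".fastq"), "p1", "GGGGTTT",
                          qual_str(c(5, 30, 30, 30, 30, 30, 30)))
  r2 <- write_fastq_plain(tempfile(fileext = ".fastq"), "p1", "ACGT",
                          qual_str(rep(30, 4)))
  res <- demultiplex_run(r1, r2, wl, layout, dir)
  expect_equal(res$stats$low_quality_pairs, 1L)
  expect_equal(res$stats$unmatched_pairs, 0L)
})

test_that("pairing errors are fatal", {
  layout <- read_layout(0, 4, 4, 3)
  wl <- data.frame(barcode = "AAAA", well_label = "w1")
  r1 <- write_fastq_plain(tempfile(fileext = ".fastq"), c("a", "b"),
                          c("AAAATTT", "AAAATTT"),
                          rep(qual_str(rep(30, 7)), 2))
  r2_short <- write_fastq_plain(tempfile(fileext = ".fastq"), "a", "ACGT",
                                qual_str(rep(30, 4)))
  expect_error(demultiplex_run(r1, r2_short, wl, layout, tempdir()),
               "pairing error")
  r2_misnamed <- write_fastq_plain(tempfile(fileext = ".fastq"),
                                   c("a", "x"), c("ACGT", "ACGT"),
                                   rep(qual_str(rep(30, 4)), 2))
  expect_error(demultiplex_run(r1, r2_misnamed, wl, layout, tempdir()),
               "pairing error at record 2")
})

test_that("demultiplexing a synthetic run reproduces the truth tally", {
  sim <- shared_noisy_sim()
  dm <- run_demux(sim, file.path(tempdir(), "dm_noisy"))
  exp <- sim$truth$expected_stats
  expect_equal(dm$stats$total_pairs, exp$total_pairs)
  expect_equal(dm$stats$assigned_pairs, exp$assigned_pairs)
  expect_equal(dm$stats$low_quality_pairs, exp$low_quality_pairs)
  expect_equal(dm$stats$unmatched_pairs, exp$unmatched_pairs)
  expect_equal(dm$stats$ambiguous_pairs, exp$ambiguous_pairs)
  expect_equal(dm$stats$per_cell_assigned, exp$per_cell_assigned)
  # conservation
  expect_equal(dm$stats$assigned_pairs + dm$stats$low_quality_pairs +
                 dm$stats$unmatched_pairs + dm$stats$ambiguous_pairs,
               dm$stats$total_pairs)
  # cell annotation mirrors the per-cell tallies
  expect_equal(dm$cells$reads_assigned,
               unname(exp$per_cell_assigned))
  expect_equal(dm$cells$fraction_of_total,
               unname(exp$per_cell_assigned) / exp$total_pairs)
})

test_that("re-demultiplexing is byte-identical (idempotence)", {
  sim <- shared_sim()
  d1 <- file.path(tempdir(), "dm_rep1")
  d2 <- file.path(tempdir(), "dm_rep2")
  run_demux(sim, d1)
  run_demux(sim, d2)
  f1 <- sort(list.files(d1, full.names = TRUE))
  f2 <- sort(list.files(d2, full.names = TRUE))
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
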