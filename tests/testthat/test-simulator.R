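test_that("regime transcripts have the expected structure", {
  m <- met_model()
  wt <- build_transcript_specs(m, "WT")[[1]]
  expect_equal(wt$sequence, spliced_sequence(m))
  d14 <- build_transcript_specs(m, "delta14")[[1]]
  expect_equal(d14$sequence, skipped_transcript(m, 14))
  # the novel exon13-exon15 junction context is present in the skipped
  # transcript with enough flank for any read to span it
  expect_true(grepl(skip_junction_sequence(m, 14, flank = 149),
                    d14$sequence, fixed = TRUE))
  expect_error(build_transcript_specs(m, "bogus"), "unknown regime")
})

test_that("chimera truth map covers the intron-2 window", {
  m <- met_model()
  ch <- build_transcript_specs(m, "chimera")[[1]]
  tm <- ch$truth_map
  i2 <- m$introns[2]
  on_chr7 <- tm[tm$chrom == "chr7", ]
  hit <- GenomicRanges::GRanges(on_chr7$chrom,
                                IRanges::IRanges(on_chr7$g_start,
                                                 on_chr7$g_end))
  expect_true(any(IRanges::overlapsAny(hit, i2)))
  # intronic segment sits inside intron 2, not in any exon interval
  ex <- GenomicRanges::GRanges(m$exons$chrom,
                               IRanges::IRanges(m$exons$start, m$exons$end))
  intr <- hit[IRanges::overlapsAny(hit, i2)]
  expect_false(any(IRanges::overlapsAny(intr, ex)))
  # and the 5' segment lives on the repeat contig
  expect_true("LINE1_like_synthetic" %in% tm$chrom)
})

test_that("simulation is deterministic for a fixed seed", {
  m <- met_model()
  specs <- build_transcript_specs(m, "delta14")
  cfg <- sim_config(n_read_pairs = 300L, seed = 77L, error_rate = 0.01)
  a <- simulate_reads(specs, cfg)
  b <- simulate_reads(specs, cfg)
  expect_identical(a$reads, b$reads)
  expect_identical(as.list(a$aln), as.list(b$aln))
})

test_that("error-free reads are exact transcript substrings", {
  m <- met_model()
  wt <- build_transcript_specs(m, "WT")[[1]]
  rs <- simulate_reads(list(wt), sim_config(n_read_pairs = 200L, seed = 5L,
                                            error_rate = 0))
  tx <- wt$sequence
  hits <- vapply(rs$reads$sequence, function(s)
    grepl(s, tx, fixed = TRUE) ||
      grepl(skipnet:::revcomp(s), tx, fixed = TRUE), TRUE,
    USE.NAMES = FALSE)
  expect_true(all(hits))
})

test_that("exon-14 interior has zero truth coverage in delta14 reads", {
  m <- met_model()
  rs <- simulate_reads(build_transcript_specs(m, "delta14"),
                       sim_config(n_read_pairs = 2000L, seed = 13L,
                                  error_rate = 0))
  e14 <- m$exons[m$exons$ordinal == 14, ]
  flat <- unlist(rs$aln)
  expect_false(any(IRanges::overlapsAny(
    flat, GenomicRanges::GRanges(e14$chrom,
                                 IRanges::IRanges(e14$start, e14$end)),
    ignore.strand = TRUE)))
  # and no read carries a 16-mer from the exon-14 interior of the WT splice
  wt_tx <- spliced_sequence(m)
  widths <- m$exons$width
  e14_tx_start <- sum(widths[1:13]) + 1L
  interior <- substring(wt_tx, e14_tx_start + 1L, e14_tx_start + 139L)
  interior_kmers <- unique(c(skipnet:::kmer_windows(interior, 16L),
                             skipnet:::kmer_windows(skipnet:::revcomp(interior), 16L)))
  read_kmers <- unique(unlist(lapply(rs$reads$sequence[1:400],
                                     skipnet:::kmer_windows, k = 16L)))
  expect_length(intersect(read_kmers, interior_kmers), 0L)
})

test_that("coverage depth matches the sampling expectation", {
  m <- met_model()
  wt <- build_transcript_specs(m, "WT")[[1]]
  n_pairs <- 3000L
  rs <- simulate_reads(list(wt), sim_config(n_read_pairs = n_pairs, seed = 2L,
                                            error_rate = 0))
  tx_len <- nchar(wt$sequence)
  cov <- coverage_features(rs, m)   # whole-exon scope = whole transcript
  expected <- n_pairs * 2 * 150 / tx_len
  expect_lt(abs(mean(cov) - expected), 3 * sqrt(expected))
})

test_that("mixture proportions are recovered from truth labels", {
  m <- met_model()
  specs <- build_transcript_specs(m, "mixture",
                                  proportions = c(WT = 0.7, delta14 = 0.3))
  n <- 4000L
  rs <- simulate_reads(specs, sim_config(n_read_pairs = n, seed = 21L))
  p_hat <- mean(rs$reads$label == "delta14")
  expect_lt(abs(p_hat - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  expect_equal(rs$label, "mixed")
})

test_that("degenerate simulator inputs error out", {
  m <- toy3_model()   # 24 nt transcript, far below one read length
  expect_error(simulate_reads(build_transcript_specs(m, "WT"),
                              sim_config(n_read_pairs = 10L)),
               "shorter than a read")
  expect_error(build_transcript_specs(met_model(), "mixture",
                                      proportions = c(WT = 0, delta14 = 0)),
               "not all be zero")
})
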