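# Featurization against brute-force oracles built in helper-fixtures.R.

one_exon_model <- function(seq) {
  gene_model("mini", "mchr", "+", 1L, nchar(seq), seq, locus_seq = seq)
}

test_that("vocabulary is the ordered, deduplicated k-window set", {
  v <- build_vocabulary(one_exon_model("ACGTAC"), k = 3L,
                        include_skip_junction = FALSE)
  expect_equal(v$kmers, c("ACG", "CGT", "GTA", "TAC"))
  v2 <- build_vocabulary(one_exon_model("AAAA"), k = 3L,
                         include_skip_junction = FALSE)
  expect_equal(v2$kmers, "AAA")
  expect_error(build_vocabulary(one_exon_model("ACG"), k = 4L), "shorter")
})

test_that("skip-junction k-mers extend the canonical vocabulary exactly", {
  m <- met_model()
  with_j <- build_vocabulary(m, k = 16L, scope = 13:15,
                             include_skip_junction = TRUE)
  without <- build_vocabulary(m, k = 16L, scope = 13:15,
                              include_skip_junction = FALSE)
  expect_equal(head(with_j$kmers, length(without$kmers)), without$kmers)
  # brute-force oracle: windows of the junction context absent from the
  # canonical splice windows
  jseq <- skip_junction_sequence(m, 14L, flank = 15L)
  novel <- setdiff(unique(skipnet:::kmer_windows(jseq, 16L)), without$kmers)
  expect_setequal(setdiff(with_j$kmers, without$kmers), novel)
  expect_equal(with_j$n_canonical, length(without$kmers))
})

test_that("k-mer counting credits each window once, orientation-blind", {
  v <- build_vocabulary(one_exon_model("ACGTAC"), k = 3L,
                        include_skip_junction = FALSE)
  grp <- list(reads = data.frame(name = "r1", sequence = "ACGTAC",
                                 first = TRUE), group_id = "g")
  expect_equal(as.numeric(kmer_features(grp, v)), c(1, 1, 1, 1))
  # the reverse-complement read gives the identical vector
  grp_rc <- list(reads = data.frame(name = "r1",
                                    sequence = skipnet:::revcomp("ACGTAC"),
                                    first = TRUE), group_id = "g")
  expect_equal(as.numeric(kmer_features(grp_rc, v)),
               as.numeric(kmer_features(grp, v)))
})

test_that("k-mer counts equal the brute-force dictionary oracle", {
  m <- met_model()
  v <- build_vocabulary(m, k = 16L, scope = 13:15)
  grp <- sim_groups("WT", n_pairs = 50L, seed = 31L, size = 100L,
                    error_rate = 0)[[1]]
  got <- as.numeric(kmer_features(grp, v))
  expect_equal(got, oracle_kmer_counts(grp$reads$sequence, v$kmers, 16L))
  # conservation bound: at most one credit per window per orientation rule
  expect_lte(sum(got), sum(pmax(nchar(grp$reads$sequence) - 16L + 1L, 0L)))
})

test_that("reads shorter than k are ignored with a message", {
  v <- build_vocabulary(one_exon_model("ACGTACGTAC"), k = 8L,
                        include_skip_junction = FALSE)
  grp <- list(reads = data.frame(name = c("a", "b"),
                                 sequence = c("ACGTACGT", "ACG"),
                                 first = TRUE), group_id = "g")
  expect_message(fv <- kmer_features(grp, v), "shorter than k")
  expect_equal(sum(fv), 1)
})

test_that("frequency conversion normalizes to unit sum", {
  v <- build_vocabulary(one_exon_model("AACCGGTT"), k = 2L,
                        include_skip_junction = FALSE)
  fv <- skipnet:::new_feature_vector(c(2, 2, 4), "kmer_count",
                                     list(kind = "kmer_count", dim = 3),
                                     "g")
  fr <- to_frequency(fv)
  expect_equal(as.numeric(fr), c(0.25, 0.25, 0.5))
  expect_equal(attr(fr, "kind"), "kmer_count_freq")
  zero <- skipnet:::new_feature_vector(c(0, 0, 0), "coverage",
                                       list(kind = "coverage", dim = 3), "g")
  expect_warning(fz <- to_frequency(zero), "all-zero")
  expect_equal(as.numeric(fz), c(0, 0, 0))
  set.seed(1)
  rand <- skipnet:::new_feature_vector(runif(40), "coverage",
                                       list(kind = "coverage", dim = 40), "g")
  expect_equal(sum(to_frequency(rand)), 1, tolerance = 1e-12)
})

test_that("coverage marks exactly the covered block positions", {
  m <- gene_model("cov1", "c", "+", 9L, 20L, strrep("A", 12),
                  locus = "c:1-30", locus_seq = strrep("A", 30))
  grp <- placed_read_set("s", "r1", 11L, 14L, chrom = "c")
  fv <- coverage_features(grp, m, scope = 1L)
  expect_equal(as.numeric(fv), c(0, 0, 1, 1, 1, 1, rep(0, 6)))
})

test_that("coverage sums are conserved and order-invariant", {
  m <- met_model()
  grp <- sim_groups("WT", n_pairs = 300L, seed = 8L, size = 500L)[[1]]
  scope <- 13:15
  fv <- coverage_features(grp, m, scope)
  ex <- m$exons[match(scope, m$exons$ordinal), ]
  scope_gr <- GenomicRanges::GRanges(ex$chrom,
                                     IRanges::IRanges(ex$start, ex$end))
  flat <- unlist(grp$aln)
  hits <- GenomicRanges::findOverlaps(flat, scope_gr, ignore.strand = TRUE)
  overlap <- sum(IRanges::width(IRanges::pintersect(
    IRanges::ranges(flat)[S4Vectors::queryHits(hits)],
    IRanges::ranges(scope_gr)[S4Vectors::subjectHits(hits)])))
  expect_equal(sum(fv), overlap)
  # permuting reads leaves the features unchanged
  perm <- sample(n_reads(grp))
  grp2 <- grp; grp2$reads <- grp$reads[perm, ]; grp2$aln <- grp$aln[perm]
  expect_equal(as.numeric(coverage_features(grp2, m, scope)),
               as.numeric(fv))
  v <- build_vocabulary(m, 16L, scope)
  expect_equal(as.numeric(kmer_features(grp2, v)),
               as.numeric(kmer_features(grp, v)))
})

test_that("unaligned groups give zero coverage with a warning", {
  m <- met_model()
  grp <- list(reads = data.frame(name = "r", sequence = "ACGT", first = TRUE),
              aln = NULL, group_id = "g")
  expect_warning(fv <- coverage_features(grp, m, 13:15), "all-zero")
  expect_true(all(fv == 0))
})

test_that("WT and delta14 groups separate on the exon-14 coverage block", {
  m <- met_model()
  gw <- sim_groups("WT", 1500L, seed = 61L, size = 500L, error_rate = 0)
  gd <- sim_groups("delta14", 1500L, seed = 62L, size = 500L, error_rate = 0)
  mat <- featurize_groups(c(gw, gd), "coverage_freq", m, 13:15)
  block14 <- attr(mat, "schema")$exon_of == 14
  m14 <- rowSums(mat[, block14])
  labs <- attr(mat, "labels")
  expect_true(all(m14[labs == "delta14"] == 0))
  expect_true(all(m14[labs == "WT"] > 0))
})

test_that("feature matrices round-trip through TSV + schema sidecar", {
  m <- met_model()
  groups <- sim_groups("WT", 600L, seed = 15L, size = 400L)
  v <- build_vocabulary(m, 16L, 13:15)
  mat <- featurize_groups(groups, "kmer_freq", vocab = v)
  path <- tempfile(fileext = ".tsv")
  write_features(mat, path)
  back <- read_features(path)
  expect_equal(as.vector(back), as.vector(mat), tolerance = 1e-12)
  expect_equal(attr(back, "labels"), attr(mat, "labels"))
  expect_equal(attr(back, "schema")$fingerprint,
               attr(mat, "schema")$fingerprint)
  # tampering with the sidecar is caught
  sj <- paste0(path, ".schema.json")
  s <- jsonlite::read_json(sj, simplifyVector = TRUE)
  s$k <- 31
  jsonlite::write_json(s, sj, auto_unbox = TRUE)
  expect_error(read_features(path), "fingerprint mismatch")
})
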