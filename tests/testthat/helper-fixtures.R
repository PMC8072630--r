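# Shared fixtures, all built in code. The toy models are tiny enough to
# check by hand; the MET-like model reuses the package's synthetic
# reference, memoised so the 126 kb locus sequence is generated once per
# test run.

extdata <- function(f) system.file("extdata", f, package = "skipnet")

# two-exon toy: exons 1-4 and 7-10 (1-based) on ACGTTTACGTAA, plus strand
toy2_model <- function() {
  gene_model("toy2", "toychr", "+", c(1L, 7L), c(4L, 10L),
             c("ACGT", "ACGT"), locus_seq = "ACGTTTACGTAA",
             locus = "toychr:1-12")
}

# three-exon toy with distinct, non-palindromic exon sequences
toy3_model <- function() {
  g <- "TTGACCTAGGTTTTCAGGATCCAATTTTTGGCCAAGTCAA"
  gene_model("toy3", "toychr3", "+", c(3L, 15L, 29L), c(10L, 22L, 36L),
             substring(g, c(3, 15, 29), c(10, 22, 36)),
             locus_seq = g, locus = "toychr3:1-40")
}

.met_cache <- new.env()
met_model <- function() {
  if (is.null(.met_cache$model)) .met_cache$model <- synthetic_met_gene_model()
  .met_cache$model
}

# simulate one class and partition into groups of `size` reads
sim_groups <- function(regime, n_pairs, seed, size = 1000L,
                       error_rate = 0.001, model = met_model(), ...) {
  specs <- build_transcript_specs(model, regime, ...)
  rs <- simulate_reads(specs, sim_config(n_read_pairs = n_pairs, seed = seed,
                                         error_rate = error_rate),
                       sample_id = paste0("sim_", regime, "_", seed))
  partition_reads(rs, size, seed = seed)
}

# read set with hand-placed single-block alignments on one contig
placed_read_set <- function(sample_id, names, starts, ends, chrom = "chr7",
                            strand = "+", first = TRUE, label = "unknown",
                            seqs = NULL) {
  n <- length(names)
  if (is.null(seqs))
    seqs <- vapply(ends - starts + 1L, function(w)
      paste(rep("A", w), collapse = ""), "")
  aln <- GenomicRanges::split(
    GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends), strand),
    factor(seq_len(n), seq_len(n)))
  read_set(sample_id,
           data.frame(name = names, sequence = seqs,
                      first = rep_len(first, n), stringsAsFactors = FALSE),
           aln = aln, label = label)
}

# plain-R k-mer counting oracle: per window, the forward slot is credited
# when present, otherwise the reverse-complement slot
oracle_kmer_counts <- function(seqs, vocab_kmers, k) {
  counts <- setNames(numeric(length(vocab_kmers)), vocab_kmers)
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  for (s in seqs) {
    if (nchar(s) < k) next
    for (i in 1:(nchar(s) - k + 1)) {
      w <- substring(s, i, i + k - 1)
      if (w %in% vocab_kmers) counts[w] <- counts[w] + 1
      else {
        wr <- rc(w)
        if (wr %in% vocab_kmers) counts[wr] <- counts[wr] + 1
      }
    }
  }
  unname(counts)
}
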