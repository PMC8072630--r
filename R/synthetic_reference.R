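# Synthetic MET-like reference. Real hg38 sequence is deliberately not
# shipped: the model below reproduces the *structure* relevant to exon-14
# skip detection — the published locus bounds chr7:116672196-116798377, a
# 21-exon transcript on the plus strand, a 141-nt exon 14, and an intron 2
# containing the chr7:116715690-116717329 window where LINE1-MET chimeras
# pile up reads — over seeded random sequence. Everything downstream is
# gene-model-agnostic, so swapping in a real annotation + genome works
# unchanged.

MET_LOCUS_CHROM <- "chr7"
MET_LOCUS_START <- 116672196
MET_LOCUS_END <- 116798377
MET_INTRON2_PEAK_START <- 116715690
MET_INTRON2_PEAK_END <- 116717329

met_exon_table <- function() {
  starts <- c(116672196, 116708000, 116720000, 116724500, 116729000,
              116734800, 116739500, 116744200, 116748900, 116753600,
              116758300, 116763000, 116767700, 116771800, 116775900,
              116780000, 116783700, 116787400, 116790100, 116792800,
              116796700)
  widths <- c(192L, 123L, 143L, 130L, 154L, 162L, 112L, 134L, 141L, 152L,
              118L, 137L, 150L, 141L, 198L, 128L, 146L, 122L, 138L, 157L,
              1678L)
  data.frame(ordinal = seq_along(starts), start = starts,
             end = starts + widths - 1L, width = widths)
}

#' Synthetic MET-like gene model
#'
#' A 21-exon plus-strand gene whose locus matches the MET locus bounds
#' chr7:116672196-116798377 (hg38, 1-based inclusive) and whose intron 2
#' contains the chr7:116715690-116717329 window; exon 14 is 141 nt. The
#' nucleotide sequence is seeded-random, i.e. SYNTHETIC — structure, not
#' biology, is reproduced. The locus sequence is kept on the model so
#' intron-derived chimeric transcripts can be simulated.
#'
#' @param seed integer seed for the locus sequence.
#' @return a [gene_model()] with `locus_seq` populated.
#' @export
synthetic_met_gene_model <- function(seed = 208L) {
  set.seed(seed)
  locus_len <- MET_LOCUS_END - MET_LOCUS_START + 1L
  locus_seq <- random_dna(locus_len)
  tab <- met_exon_table()
  seqs <- substring(locus_seq, tab$start - MET_LOCUS_START + 1L,
                    tab$end - MET_LOCUS_START + 1L)
  gene_model("MET_synthetic", MET_LOCUS_CHROM, "+", tab$start, tab$end, seqs,
             locus = sprintf("%s:%d-%d", MET_LOCUS_CHROM, MET_LOCUS_START,
                             MET_LOCUS_END),
             locus_seq = locus_seq)
}

#' Write the synthetic MET-like reference to disk
#'
#' Emits a FASTA holding the locus slice (contig named
#' `"chr7:116672196-116798377"`, the `samtools faidx` region convention,
#' recognised by [load_gene_model()]) and a GFF3 with the 21 exon features in
#' genomic coordinates.
#'
#' @param dir output directory (created if needed).
#' @param seed seed forwarded to [synthetic_met_gene_model()].
#' @return named list of paths (`fasta`, `gff3`) plus the `gene_model`.
#' @export
synthetic_met_reference <- function(dir = tempfile("metref"), seed = 208L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  model <- synthetic_met_gene_model(seed)
  fasta <- file.path(dir, "met_synthetic.fa")
  gff3 <- file.path(dir, "met_synthetic.gff3")
  slice <- Biostrings::DNAStringSet(model$locus_seq)
  names(slice) <- sprintf("%s:%d-%d", MET_LOCUS_CHROM, MET_LOCUS_START,
                          MET_LOCUS_END)
  Biostrings::writeXStringSet(slice, fasta)
  write_gene_model(model, gff3, transcript_id = "MET_synthetic.t1")
  list(fasta = fasta, gff3 = gff3, model = model)
}

#' Genomic sequence of an intron window of a gene model
#'
#' @param model a `gene_model` carrying `locus_seq`.
#' @param start,end 1-based inclusive genomic coordinates inside the locus.
#' @return plus-strand nucleotide string of the window.
#' @export
locus_window_sequence <- function(model, start, end) {
  if (is.null(model$locus_seq))
    stopf("gene model has no locus sequence; rebuild with locus_seq")
  ls <- GenomicRanges::start(model$locus)
  le <- GenomicRanges::end(model$locus)
  if (start < ls || end > le) stopf("coordinate error: window outside locus")
  substring(model$locus_seq, start - ls + 1L, end - ls + 1L)
}

#' Shipped LINE1-like repeat fixture
#'
#' A 2 kb SYNTHETIC stand-in for the LINE-1 retrotransposon consensus, used
#' as the default repeat reference of the chimera simulator and the
#' discordant-mate screen. Any real repeat sequence can be passed instead.
#'
#' @return nucleotide string of length 2000.
#' @export
line1_like_sequence <- function() {
  path <- system.file("extdata", "line1_like_synthetic.fa",
                      package = "skipnet", mustWork = TRUE)
  as.character(Biostrings::readDNAStringSet(path)[[1]])
}
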