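# Gene model: the target gene's locus, ordered exon structure and sequences.
# All intervals are Bioconductor-style 1-based closed (GRanges); region
# strings accepted from users follow the same convention.

#' Construct a gene model from exon coordinates and sequences
#'
#' The gene model is the single source of truth for the locus under study:
#' an ordered set of exons (transcript order, so exon 1 is the 5' exon on
#' either strand) with their genomic intervals and transcript-oriented
#' sequences, plus the derived introns. All downstream stages — the read
#' simulator, featurization and the autoencoder connectivity mask — take a
#' gene model as input, so any gene/annotation can be used, not only MET.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends 1-based inclusive genomic exon coordinates,
#'   in genomic order.
#' @param sequences transcript-oriented exon sequences (reverse-complemented
#'   already for minus-strand genes), in transcript order.
#' @param locus optional `GRanges` (or `"chrom:start-end"` string) overriding
#'   the default locus, which is the transcript span.
#' @param locus_seq optional plus-strand genomic sequence of the locus
#'   (character); required for simulating intron-derived transcripts.
#' @return an object of class `gene_model` with elements `gene_id`, `locus`,
#'   `exons` (data.frame: ordinal, chrom, start, end, strand, width,
#'   sequence) and `introns` (`GRanges`).
#' @export
gene_model <- function(gene_id, chrom, strand, exon_starts, exon_ends,
                       sequences, locus = NULL, locus_seq = NULL) {
  stopifnot(length(exon_starts) == length(exon_ends),
            length(sequences) == length(exon_starts),
            strand %in% c("+", "-"), nzchar(chrom))
  if (any(exon_ends < exon_starts)) stopf("coordinate error: exon end < start")
  o <- order(exon_starts)
  exon_starts <- exon_starts[o]; exon_ends <- exon_ends[o]
  if (any(exon_starts[-1] <= exon_ends[-length(exon_ends)]))
    stopf("coordinate error: overlapping exons")
  n <- length(exon_starts)
  # transcript order: ascending coordinates on +, descending on -
  tx_order <- if (strand == "+") seq_len(n) else rev(seq_len(n))
  widths <- exon_ends - exon_starts + 1L
  if (any(nchar(sequences) != widths[tx_order]))
    stopf("exon sequence lengths do not match interval widths")
  exons <- data.frame(
    ordinal = seq_len(n),
    chrom = chrom,
    start = exon_starts[tx_order],
    end = exon_ends[tx_order],
    strand = strand,
    width = widths[tx_order],
    sequence = as.character(sequences),
    stringsAsFactors = FALSE
  )
  if (is.null(locus)) {
    locus <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(min(exon_starts), max(exon_ends)), strand)
  } else {
    if (is.character(locus)) locus <- parse_region(locus)
    GenomicRanges::strand(locus) <- strand
  }
  if (min(exon_starts) < GenomicRanges::start(locus) ||
      max(exon_ends) > GenomicRanges::end(locus))
    stopf("coordinate error: exons extend outside the locus")
  # introns, in transcript order between consecutive exons
  introns <- GenomicRanges::GRanges()
  if (n > 1L) {
    gs <- sort(exon_starts); ge <- sort(exon_ends)
    istart <- ge[-n] + 1L
    iend <- gs[-1] - 1L
    introns <- GenomicRanges::GRanges(chrom, IRanges::IRanges(istart, iend), strand)
    if (strand == "-") introns <- rev(introns)
  }
  structure(list(gene_id = gene_id, locus = locus, exons = exons,
                 introns = introns, locus_seq = locus_seq),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model '%s': %d exons, locus %s (%s)\n",
              x$gene_id, nrow(x$exons), format_region(x$locus),
              as.character(GenomicRanges::strand(x$locus))))
  cat(sprintf("  transcript length %d nt; exon widths: %s\n",
              sum(x$exons$width),
              paste(x$exons$width, collapse = " ")))
  invisible(x)
}

#' Number of exons of a gene model
#' @param model a `gene_model`.
#' @export
n_exons <- function(model) nrow(model$exons)

#' Load a gene model from annotation and genome files
#'
#' Reads exon features of one transcript from a GFF3 or GTF annotation and
#' extracts their sequences from a FASTA genome, reverse-complementing for
#' minus-strand transcripts. The genome may either contain the full
#' chromosome, or a region slice named `"chrom:start-end"` in the
#' `samtools faidx` convention, in which case coordinates are offset
#' internally.
#'
#' @param annotation_path GFF3 (`.gff`/`.gff3`) or GTF (`.gtf`) file.
#' @param genome_path FASTA file.
#' @param gene_id gene identifier (stored on the model).
#' @param transcript_id transcript whose exons define the model.
#' @param locus optional locus override, 1-based inclusive
#'   `"chrom:start-end"` string or `GRanges`.
#' @return a [gene_model()].
#' @export
load_gene_model <- function(annotation_path, genome_path, gene_id,
                            transcript_id, locus = NULL) {
  fmt <- if (grepl("\\.gtf(\\.gz)?$", annotation_path, ignore.case = TRUE))
    "gtf" else "gff3"
  ann <- rtracklayer::import(annotation_path, format = fmt)
  ex <- ann[ann$type == "exon"]
  keep <- if (fmt == "gtf") {
    !is.na(ex$transcript_id) & ex$transcript_id == transcript_id
  } else {
    vapply(as.list(ex$Parent), function(p)
      any(sub("^transcript:", "", p) == transcript_id), logical(1))
  }
  ex <- ex[keep]
  if (length(ex) == 0L)
    stopf("annotation not found: no exons for transcript '%s' in %s",
          transcript_id, annotation_path)
  chrom <- as.character(GenomicRanges::seqnames(ex))[1]
  strand <- as.character(GenomicRanges::strand(ex))[1]
  if (strand == "*") strand <- "+"

  genome <- Biostrings::readDNAStringSet(genome_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  offset <- 0L
  if (chrom %in% names(genome)) {
    chrom_seq <- genome[[chrom]]
  } else {
    # region-slice contig: "chrom:start-end" (samtools faidx naming)
    slice <- grep(paste0("^", chrom, ":[0-9]+-[0-9]+$"), names(genome), value = TRUE)
    if (length(slice) != 1L)
      stopf("annotation not found: chromosome '%s' absent from %s",
            chrom, genome_path)
    bounds <- parse_region(slice)
    offset <- GenomicRanges::start(bounds) - 1L
    chrom_seq <- genome[[slice]]
  }
  starts <- GenomicRanges::start(ex) - offset
  ends <- GenomicRanges::end(ex) - offset
  if (any(starts < 1L) || any(ends > length(chrom_seq)))
    stopf("coordinate error: exon outside chromosome bounds")
  o <- order(starts)
  seqs <- as.character(Biostrings::extractAt(
    chrom_seq, IRanges::IRanges(starts[o], ends[o])))
  if (strand == "-") seqs <- rev(revcomp(seqs))
  locus_seq <- NULL
  if (!is.null(locus)) {
    lg <- if (is.character(locus)) parse_region(locus) else locus
    ls <- GenomicRanges::start(lg) - offset; le <- GenomicRanges::end(lg) - offset
    if (ls >= 1L && le <= length(chrom_seq))
      locus_seq <- as.character(chrom_seq[ls:le])
  }
  gene_model(gene_id, chrom, strand,
             GenomicRanges::start(ex)[o], GenomicRanges::end(ex)[o],
             seqs, locus = locus, locus_seq = locus_seq)
}

#' Write a gene model as GFF3 (gene/mRNA/exon features)
#'
#' Together with the genome FASTA used to build the model this round-trips
#' through [load_gene_model()].
#'
#' @param model a `gene_model`.
#' @param path output GFF3 path.
#' @param transcript_id transcript identifier to write (default
#'   `<gene_id>.t1`).
#' @export
write_gene_model <- function(model, path, transcript_id = NULL) {
  if (is.null(transcript_id)) transcript_id <- paste0(model$gene_id, ".t1")
  ex <- model$exons
  chrom <- ex$chrom[1]; strand <- ex$strand[1]
  gr <- GenomicRanges::GRanges(
    chrom,
    IRanges::IRanges(c(min(ex$start), min(ex$start), ex$start),
                     c(max(ex$end), max(ex$end), ex$end)),
    strand)
  gr$type <- c("gene", "mRNA", rep("exon", nrow(ex)))
  gr$ID <- c(model$gene_id, transcript_id,
             paste0(transcript_id, ".exon", ex$ordinal))
  gr$Parent <- c(NA, model$gene_id, rep(transcript_id, nrow(ex)))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Spliced sequence over a set of exon ordinals
#'
#' @param model a `gene_model`.
#' @param exon_ordinals ascending 1-based exon ordinals (transcript order);
#'   default all exons, giving the full mature transcript.
#' @return nucleotide string: the named exons' sequences concatenated in
#'   transcript order.
#' @export
spliced_sequence <- function(model, exon_ordinals = NULL) {
  if (is.null(exon_ordinals)) exon_ordinals <- model$exons$ordinal
  if (any(!exon_ordinals %in% model$exons$ordinal))
    stopf("unknown exon ordinal(s): %s",
          paste(setdiff(exon_ordinals, model$exons$ordinal), collapse = ","))
  if (is.unsorted(exon_ordinals, strictly = TRUE))
    stopf("exon ordinals must be strictly ascending")
  paste(model$exons$sequence[match(exon_ordinals, model$exons$ordinal)],
        collapse = "")
}

#' Transcript sequence with one internal exon skipped
#'
#' Models an exon-skipping splicing aberration: the full spliced transcript
#' minus one internal exon (the 5' and 3' terminal exons cannot be skipped).
#'
#' @param model a `gene_model`.
#' @param skipped_ordinal ordinal of the internal exon to drop (default 14,
#'   the MET juxtamembrane-domain exon).
#' @return nucleotide string of length
#'   `sum(exon widths) - width(skipped exon)`.
#' @export
skipped_transcript <- function(model, skipped_ordinal = 14L) {
  ords <- model$exons$ordinal
  if (!skipped_ordinal %in% ords)
    stopf("unknown exon ordinal: %d", skipped_ordinal)
  if (skipped_ordinal == min(ords) || skipped_ordinal == max(ords))
    stopf("exon %d is terminal; only internal exons can be skipped",
          skipped_ordinal)
  spliced_sequence(model, setdiff(ords, skipped_ordinal))
}

#' Exon-junction sequence context created by skipping an exon
#'
#' Returns the novel junction formed when `skipped_ordinal` is excised:
#' the last `flank` bases of the upstream exon joined to the first `flank`
#' bases of the downstream exon. Used to extend k-mer vocabularies with
#' skip-junction k-mers absent from the canonical splice.
#'
#' @inheritParams skipped_transcript
#' @param flank bases of context on each side of the junction.
#' @export
skip_junction_sequence <- function(model, skipped_ordinal = 14L, flank = 15L) {
  ords <- model$exons$ordinal
  i <- match(skipped_ordinal, ords)
  if (is.na(i) || i == 1L || i == length(ords))
    stopf("exon %d is not an internal exon", skipped_ordinal)
  up <- model$exons$sequence[i - 1L]
  down <- model$exons$sequence[i + 1L]
  paste0(substring(up, max(1L, nchar(up) - flank + 1L), nchar(up)),
         substring(down, 1L, min(flank, nchar(down))))
}
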