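# Locus read extraction from coordinate-sorted indexed BAM, the minimum
# coverage sample filter, and discordant half-mapped mate collection.

primary_flags <- function(mapped = TRUE) {
  Rsamtools::scanBamFlag(isUnmappedQuery = !mapped,
                         isSecondaryAlignment = FALSE,
                         isSupplementaryAlignment = FALSE)
}

check_bam <- function(alignment_path) {
  if (!file.exists(alignment_path)) stopf("no such file: %s", alignment_path)
  if (grepl("\\.sam$", alignment_path, ignore.case = TRUE)) {
    alignment_path <- sam_to_bam(alignment_path,
                                 tempfile("skipnet_aln"))
  }
  idx <- c(paste0(alignment_path, ".bai"),
           sub("\\.bam$", ".bai", alignment_path))
  if (!any(file.exists(idx)))
    stopf("missing index for %s (coordinate-sorted, indexed BAM required)",
          alignment_path)
  alignment_path
}

gal_to_read_set <- function(gal, sample_id, source, label) {
  qname <- S4Vectors::mcols(gal)$qname
  flag <- S4Vectors::mcols(gal)$flag
  seqs <- as.character(S4Vectors::mcols(gal)$seq)
  minus <- as.character(GenomicAlignments::strand(gal)) == "-"
  seqs[minus] <- revcomp(seqs[minus])  # back to read orientation
  first <- bitwAnd(flag, 64L) > 0L
  blocks <- GenomicAlignments::grglist(gal)
  flat <- unlist(blocks, use.names = FALSE)
  GenomicRanges::strand(flat) <-
    ifelse(rep(minus, S4Vectors::elementNROWS(blocks)), "-", "+")
  blocks <- IRanges::relist(flat, blocks)
  read_set(sample_id,
           data.frame(name = qname, sequence = seqs, first = first,
                      stringsAsFactors = FALSE),
           aln = blocks, source = source, label = label)
}

#' Extract reads overlapping a locus from an alignment file
#'
#' Returns every primary-alignment read whose alignment overlaps the locus
#' by at least one base; secondary and supplementary records are excluded,
#' duplicates retained. SAM input is converted to sorted/indexed BAM on the
#' fly.
#'
#' @param alignment_path coordinate-sorted, indexed BAM (or SAM) file.
#' @param locus `GRanges` of length 1 or `"chrom:start-end"` string
#'   (1-based inclusive).
#' @param sample_id sample identifier (default: file base name).
#' @param label truth label to attach, if known.
#' @return a [read_set()] with alignment blocks.
#' @export
extract_locus_reads <- function(alignment_path, locus,
                                sample_id = NULL, label = "unknown") {
  if (is.character(locus)) locus <- parse_region(locus)
  GenomicRanges::strand(locus) <- "*"
  bam <- check_bam(alignment_path)
  if (is.null(sample_id))
    sample_id <- sub("\\.(bam|sam)$", "", basename(alignment_path))
  param <- Rsamtools::ScanBamParam(flag = primary_flags(),
                                   what = c("qname", "flag", "seq"),
                                   which = locus)
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  gal_to_read_set(gal, sample_id, source = alignment_path, label = label)
}

#' Minimum-coverage sample filter
#'
#' A sample enters the analysis only when the target locus is covered by at
#' least `threshold` reads (default 5000); below that depth the exon-14
#' coverage gap that identifies skipping becomes too blurry to call.
#'
#' @param readset a `read_set`.
#' @param threshold minimum read count, > 0.
#' @return `TRUE` iff the read set holds at least `threshold` reads.
#' @export
passes_min_reads <- function(readset, threshold = 5000L) {
  stopifnot(threshold > 0L)
  n_reads(readset) >= threshold
}

#' Extract half-mapped mate pairs around a locus
#'
#' Collects read pairs where exactly one mate aligns to the locus; the other
#' mate may be unaligned or aligned elsewhere. These discordant pairs are
#' the raw material of the repeat (LINE1) fusion screen: the locus-anchored
#' mate gives the putative fusion point, the free mate is matched against a
#' repeat reference. Pairs missing a mate record are skipped and counted.
#'
#' @inheritParams extract_locus_reads
#' @return data.frame of class `half_mapped_pairs` with one row per pair:
#'   `name`, locus-mate coordinates and sequence, mate sequence/coordinates
#'   and mapping status. Attribute `n_orphans` counts skipped singletons.
#' @export
extract_half_mapped_pairs <- function(alignment_path, locus) {
  if (is.character(locus)) locus <- parse_region(locus)
  GenomicRanges::strand(locus) <- "*"
  bam <- check_bam(alignment_path)

  pm <- Rsamtools::ScanBamParam(flag = primary_flags(TRUE),
                                what = c("qname", "flag", "seq"))
  gal <- GenomicAlignments::readGAlignments(bam, param = pm)
  minus <- as.character(GenomicAlignments::strand(gal)) == "-"
  mseq <- as.character(S4Vectors::mcols(gal)$seq)
  mseq[minus] <- revcomp(mseq[minus])
  mapped <- data.frame(
    name = S4Vectors::mcols(gal)$qname,
    first = bitwAnd(S4Vectors::mcols(gal)$flag, 64L) > 0L,
    sequence = mseq,
    chrom = as.character(GenomicAlignments::seqnames(gal)),
    start = GenomicAlignments::start(gal),
    end = GenomicAlignments::end(gal),
    mapped = TRUE, stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(mapped$chrom,
                               IRanges::IRanges(mapped$start, mapped$end))
  mapped$in_locus <- IRanges::overlapsAny(gr, locus)

  pu <- Rsamtools::ScanBamParam(flag = primary_flags(FALSE),
                                what = c("qname", "flag", "seq"))
  um <- Rsamtools::scanBam(bam, param = pu)[[1]]
  n_um <- length(um$qname)
  unmapped <- data.frame(
    name = um$qname, first = bitwAnd(um$flag, 64L) > 0L,
    sequence = as.character(um$seq), chrom = rep(NA_character_, n_um),
    start = rep(NA_integer_, n_um), end = rep(NA_integer_, n_um),
    mapped = rep(FALSE, n_um), in_locus = rep(FALSE, n_um),
    stringsAsFactors = FALSE)
  all <- rbind(mapped, unmapped)

  mate_row <- match(paste(all$name, !all$first), paste(all$name, all$first))
  n_orphans <- sum(is.na(mate_row) & all$first) +
    sum(is.na(mate_row) & !all$first)
  ok <- !is.na(mate_row)
  # keep the locus-anchored side of pairs with exactly one mate in the locus
  keep <- ok & all$in_locus & !all$in_locus[mate_row]
  out <- data.frame(
    name = all$name[keep],
    locus_chrom = all$chrom[keep],
    locus_start = all$start[keep],
    locus_end = all$end[keep],
    locus_seq = all$sequence[keep],
    mate_seq = all$sequence[mate_row[keep]],
    mate_mapped = all$mapped[mate_row[keep]],
    mate_chrom = all$chrom[mate_row[keep]],
    mate_start = all$start[mate_row[keep]],
    stringsAsFactors = FALSE)
  if (n_orphans > 0L)
    message(n_orphans, " orphaned mate record(s) skipped")
  attr(out, "n_orphans") <- n_orphans
  class(out) <- c("half_mapped_pairs", class(out))
  out
}
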