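# ReadSet: the sample-level unit — reads overlapping the target locus plus
# their alignments (real, from a BAM, or simulator truth). Sequences are
# stored in read orientation; SAM emission and BAM ingestion convert to and
# from the reference-strand convention so a written subset re-extracts
# identically.

#' Construct a read set
#'
#' @param sample_id sample identifier.
#' @param reads data.frame with columns `name` (read identifier), `sequence`
#'   (read-orientation nucleotides), `first` (logical, first in pair) and
#'   optionally `label` (`WT`, `delta14`, `chimera`, `unknown`).
#' @param aln `GRangesList` parallel to `reads`: alignment blocks of each
#'   read (zero-length element = unaligned).
#' @param source provenance string.
#' @param label sample-level truth label, inherited by read groups.
#' @export
read_set <- function(sample_id, reads, aln = NULL, source = "unknown",
                     label = "unknown") {
  stopifnot(is.data.frame(reads),
            all(c("name", "sequence", "first") %in% names(reads)))
  if (any(!nzchar(reads$sequence))) stopf("empty read sequence")
  key <- paste(reads$name, reads$first)
  if (anyDuplicated(key)) stopf("duplicate (name, mate) identity in read set")
  if (!is.null(aln)) stopifnot(length(aln) == nrow(reads))
  structure(list(sample_id = sample_id, reads = reads, aln = aln,
                 source = source, label = label),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  n_aln <- if (is.null(x$aln)) 0L else sum(S4Vectors::elementNROWS(x$aln) > 0L)
  cat(sprintf("read_set '%s': %d reads (%d aligned), label=%s, source=%s\n",
              x$sample_id, nrow(x$reads), n_aln, x$label, x$source))
  invisible(x)
}

#' Number of reads in a read set or read group
#' @param x a `read_set` or `read_group`.
#' @export
n_reads <- function(x) nrow(x$reads)

subset_read_set <- function(rs, idx) {
  read_set(rs$sample_id, rs$reads[idx, , drop = FALSE],
           if (is.null(rs$aln)) NULL else rs$aln[idx],
           source = rs$source, label = rs$label)
}

#' @export
print.half_mapped_pairs <- function(x, ...) {
  cat(sprintf("half_mapped_pairs: %d pairs (%d with unmapped mate)\n",
              nrow(x), sum(!x$mate_mapped)))
  invisible(x)
}

sam_flag <- function(paired, first, mapped, minus, mate_mapped, mate_minus) {
  f <- 0L
  if (paired) f <- f + 1L + if (first) 64L else 128L
  if (!mapped) f <- f + 4L
  if (mapped && minus) f <- f + 16L
  if (paired && !mate_mapped) f <- f + 8L
  if (paired && mate_mapped && mate_minus) f <- f + 32L
  f
}

#' Write a read set as SAM (truth or subset alignments)
#'
#' Alignment blocks become `M` segments joined by `N` gaps, so spliced reads
#' carry standard skip CIGARs. Mates are located by shared read name.
#'
#' @param rs a `read_set`.
#' @param path output SAM path.
#' @param ref_lengths named integer vector of reference contig lengths; by
#'   default inferred from the alignment block maxima.
#' @return `path`, invisibly.
#' @export
write_readset_sam <- function(rs, path, ref_lengths = NULL) {
  if (is.null(rs$aln)) stopf("read set carries no alignments")
  blocks <- rs$aln
  nb <- S4Vectors::elementNROWS(blocks)
  flat <- unlist(blocks, use.names = FALSE)
  if (is.null(ref_lengths)) {
    if (length(flat) == 0L) stopf("no alignments and no ref_lengths given")
    ref_lengths <- tapply(GenomicRanges::end(flat),
                          as.character(GenomicRanges::seqnames(flat)), max)
    ref_lengths <- setNames(as.integer(ref_lengths), names(ref_lengths))
  }
  chrom <- character(length(blocks)); pos <- integer(length(blocks))
  cigar <- character(length(blocks)); minus <- logical(length(blocks))
  grp <- factor(rep.int(seq_along(blocks), nb), seq_along(blocks))
  starts <- split(GenomicRanges::start(flat), grp)
  widths <- split(GenomicRanges::width(flat), grp)
  chroms <- split(as.character(GenomicRanges::seqnames(flat)), grp)
  strands <- split(as.character(GenomicRanges::strand(flat)), grp)
  readlen <- nchar(rs$reads$sequence)
  for (i in which(nb > 0L)) {
    ch <- chroms[[i]]
    keep <- rep(TRUE, length(ch))
    if (length(unique(ch)) > 1L) {
      # a read straddling a fusion breakpoint spans two contigs; one SAM
      # record cannot express that, so keep the majority contig and
      # soft-clip the rest
      per <- tapply(widths[[i]], ch, sum)
      keep <- ch == names(per)[which.max(per)]
    }
    s0 <- starts[[i]][keep]; w0 <- widths[[i]][keep]
    o <- order(s0); s <- s0[o]; w <- w0[o]
    gaps <- if (length(s) > 1L) s[-1] - (s[-length(s)] + w[-length(w)]) else integer(0)
    cig <- paste0(w[1], "M")
    if (length(gaps)) cig <- paste0(cig, paste0(gaps, "N", w[-1], "M", collapse = ""))
    clip <- readlen[i] - sum(w)
    if (clip > 0L) cig <- paste0(clip, "S", cig)
    cigar[i] <- cig
    pos[i] <- s[1]
    chrom[i] <- ch[keep][1]
    minus[i] <- strands[[i]][keep][1] == "-"
  }

  rd <- rs$reads
  mapped <- nb > 0L
  mate_row <- match(paste(rd$name, !rd$first), paste(rd$name, rd$first))
  paired <- !is.na(mate_row)
  mate_mapped <- ifelse(paired, mapped[mate_row], FALSE)
  mate_minus <- ifelse(paired & mate_mapped, minus[mate_row], FALSE)
  flags <- mapply(sam_flag, paired, rd$first, mapped, minus,
                  mate_mapped, mate_minus)
  seqs <- rd$sequence
  seqs[mapped & minus] <- revcomp(seqs[mapped & minus])
  rname <- ifelse(mapped, chrom, ifelse(mate_mapped, chrom[mate_row], "*"))
  posn <- ifelse(mapped, pos, ifelse(mate_mapped, pos[mate_row], 0L))
  rnext <- ifelse(!paired | !mate_mapped, "*",
                  ifelse(chrom[mate_row] == rname & mapped, "=", chrom[mate_row]))
  pnext <- ifelse(paired & mate_mapped, pos[mate_row], 0L)
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t%s",
                   rd$name, flags, rname, posn, ifelse(mapped, 60L, 0L),
                   ifelse(mapped, cigar, "*"), rnext, pnext, seqs,
                   strrep("I", nchar(seqs)))
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Convert SAM to a coordinate-sorted, indexed BAM
#'
#' @param sam_path input SAM.
#' @param bam_prefix output path without the `.bam` extension.
#' @return path of the BAM file.
#' @export
sam_to_bam <- function(sam_path, bam_prefix = sub("\\.sam$", "", sam_path)) {
  Rsamtools::asBam(sam_path, bam_prefix, overwrite = TRUE,
                   indexDestination = TRUE)
}

#' Write a read set as paired FASTQ (R1/R2)
#'
#' @param rs a `read_set`.
#' @param prefix output prefix; files `<prefix>_R1.fastq`, `<prefix>_R2.fastq`.
#' @return character vector of the two paths.
#' @export
write_readset_fastq <- function(rs, prefix) {
  paths <- paste0(prefix, c("_R1.fastq", "_R2.fastq"))
  for (m in 1:2) {
    sel <- if (m == 1L) rs$reads$first else !rs$reads$first
    dna <- Biostrings::DNAStringSet(rs$reads$sequence[sel])
    names(dna) <- rs$reads$name[sel]
    qual <- Biostrings::BStringSet(strrep("I", nchar(rs$reads$sequence[sel])))
    Biostrings::writeXStringSet(dna, paths[m], format = "fastq",
                                qualities = qual)
  }
  paths
}
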