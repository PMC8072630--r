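# Paired-end read simulator. Emulates the four training/test regimes the
# classifiers are built for — wild-type MET, exon-14-skipped MET (each at
# arbitrary depth), their mixtures — plus the chimeric false-positive class:
# a LINE1-like 5' segment fused to the intron-2 window, exon 6 and the last
# exon, reproducing the coverage signature (intron-2 peak, exon-6 and
# last-exon accumulation) that LINE1-MET fusion transcripts leave in tumour
# RNA-seq. Fragments start uniformly along the transcript; errors are
# independent per-base substitutions.

#' Transcript specification for the simulator
#'
#' @param name transcript name.
#' @param sequence transcript nucleotide string.
#' @param label truth class: `"WT"`, `"delta14"` or `"chimera"`.
#' @param weight relative abundance (>= 0).
#' @param truth_map data.frame mapping transcript to genomic coordinates,
#'   one row per contiguous segment: `tx_start`, `tx_end`, `chrom`,
#'   `g_start`, `g_end`, `strand`.
#' @export
transcript_spec <- function(name, sequence, label, weight = 1,
                            truth_map = NULL) {
  stopifnot(label %in% c("WT", "delta14", "chimera"), weight >= 0)
  if (!is.null(truth_map)) {
    stopifnot(all(c("tx_start", "tx_end", "chrom", "g_start", "g_end",
                    "strand") %in% names(truth_map)))
    if (sum(truth_map$tx_end - truth_map$tx_start + 1L) != nchar(sequence))
      stopf("truth_map does not tile the transcript")
  }
  structure(list(name = name, sequence = sequence, label = label,
                 weight = weight, truth_map = truth_map),
            class = "transcript_spec")
}

# truth map whose segments are the given genomic intervals, in the order
# they appear along the transcript
segments_truth_map <- function(chrom, g_start, g_end, strand) {
  w <- g_end - g_start + 1L
  tx_end <- cumsum(w)
  data.frame(tx_start = tx_end - w + 1L, tx_end = tx_end, chrom = chrom,
             g_start = g_start, g_end = g_end, strand = strand,
             stringsAsFactors = FALSE)
}

exon_truth_map <- function(model, ordinals) {
  ex <- model$exons[match(ordinals, model$exons$ordinal), ]
  segments_truth_map(ex$chrom, ex$start, ex$end, ex$strand)
}

#' Build simulator transcript specs for a regime
#'
#' Regimes mirror the data the classifiers are trained and tested on:
#' `"WT"` — the full spliced transcript; `"delta14"` — the transcript with
#' the skip exon excised; `"chimera"` — a synthetic fusion transcript
#' (LINE1-like 5' segment + intron-2 window + exon 6 + last exon) whose
#' truth coverage reproduces the intron-2-peak signature of LINE1 fusions;
#' `"mixture"` — any combination with stated proportions.
#'
#' @param gene_model a [gene_model()] (`locus_seq` required for chimera).
#' @param regime `"WT"`, `"delta14"`, `"chimera"` or `"mixture"`.
#' @param proportions for `"mixture"`: named numeric vector of weights over
#'   the other three regimes, e.g. `c(WT = 0.8, delta14 = 0.2)`.
#' @param skip_ordinal exon excised in the `delta14` regime (default 14).
#' @param repeat_seq 5' repeat sequence of the chimera (default the shipped
#'   synthetic LINE1-like fixture).
#' @param repeat_span how many 5' bases of `repeat_seq` the chimera carries.
#' @param intron_window 1-based genomic `c(start, end)` of the intronic
#'   segment (the fusion breakpoint is its start; default the intron-2 peak
#'   window chr7:116715690-116717329).
#' @param chimera_exons exon ordinals appended after the intronic segment
#'   (default exon 6 and the last exon).
#' @return list of [transcript_spec()].
#' @export
build_transcript_specs <- function(gene_model, regime,
                                   proportions = NULL,
                                   skip_ordinal = 14L,
                                   repeat_seq = NULL,
                                   repeat_span = 800L,
                                   intron_window = c(MET_INTRON2_PEAK_START,
                                                     MET_INTRON2_PEAK_END),
                                   chimera_exons = NULL) {
  ords <- gene_model$exons$ordinal
  if (regime == "WT") {
    return(list(transcript_spec(
      "WT", spliced_sequence(gene_model), "WT",
      truth_map = exon_truth_map(gene_model, ords))))
  }
  if (regime == "delta14") {
    keep <- setdiff(ords, skip_ordinal)
    seq <- skipped_transcript(gene_model, skip_ordinal)
    return(list(transcript_spec(
      paste0("delta", skip_ordinal), seq, "delta14",
      truth_map = exon_truth_map(gene_model, keep))))
  }
  if (regime == "chimera") {
    if (is.null(repeat_seq)) repeat_seq <- line1_like_sequence()
    if (is.null(chimera_exons)) chimera_exons <- c(6L, max(ords))
    repeat_span <- min(repeat_span, nchar(repeat_seq))
    intron_seq <- locus_window_sequence(gene_model, intron_window[1],
                                        intron_window[2])
    ex <- gene_model$exons[match(chimera_exons, gene_model$exons$ordinal), ]
    seq <- paste0(substring(repeat_seq, 1L, repeat_span), intron_seq,
                  paste(ex$sequence, collapse = ""))
    tm <- segments_truth_map(
      chrom = c("LINE1_like_synthetic", ex$chrom[1], ex$chrom),
      g_start = c(1L, intron_window[1], ex$start),
      g_end = c(repeat_span, intron_window[2], ex$end),
      strand = c("+", ex$strand[1], ex$strand))
    return(list(transcript_spec("chimera", seq, "chimera",
                                truth_map = tm)))
  }
  if (regime == "mixture") {
    if (is.null(proportions) || is.null(names(proportions)))
      stopf("mixture regime needs a named 'proportions' vector")
    specs <- list()
    for (r in names(proportions)) {
      s <- build_transcript_specs(gene_model, r, skip_ordinal = skip_ordinal,
                                  repeat_seq = repeat_seq,
                                  repeat_span = repeat_span,
                                  intron_window = intron_window,
                                  chimera_exons = chimera_exons)[[1]]
      s$weight <- unname(proportions[r])
      specs[[r]] <- s
    }
    if (all(vapply(specs, function(s) s$weight, 0) == 0))
      stopf("mixture weights must not all be zero")
    return(unname(specs))
  }
  stopf("unknown regime '%s'", regime)
}

#' Simulator configuration
#'
#' @param read_length read length in bases (paired 2 x `read_length`).
#' @param fragment_mean,fragment_sd fragment length distribution (normal,
#'   truncated to `[read_length, transcript length]`).
#' @param error_rate per-base substitution probability, in `[0, 0.1)`.
#' @param n_read_pairs number of fragments to draw.
#' @param seed RNG seed; fixed seed gives identical output.
#' @export
sim_config <- function(read_length = 150L, fragment_mean = 350,
                       fragment_sd = 50, error_rate = 0.001,
                       n_read_pairs = 1000L, seed = 1L) {
  stopifnot(read_length <= fragment_mean, error_rate >= 0, error_rate < 0.1,
            n_read_pairs >= 1L)
  structure(list(read_length = as.integer(read_length),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 error_rate = error_rate,
                 n_read_pairs = as.integer(n_read_pairs),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# map transcript intervals [s, e] (rows) through a truth map; returns a
# data.frame of genomic blocks with a `read` index column
map_tx_intervals <- function(truth_map, s, e, read_idx, read_strand) {
  q <- IRanges::IRanges(s, e)
  subj <- IRanges::IRanges(truth_map$tx_start, truth_map$tx_end)
  hits <- IRanges::findOverlaps(q, subj)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  os <- pmax(s[qi], truth_map$tx_start[si])
  oe <- pmin(e[qi], truth_map$tx_end[si])
  seg_minus <- truth_map$strand[si] == "-"
  gs <- ifelse(seg_minus,
               truth_map$g_end[si] - (oe - truth_map$tx_start[si]),
               truth_map$g_start[si] + (os - truth_map$tx_start[si]))
  ge <- ifelse(seg_minus,
               truth_map$g_end[si] - (os - truth_map$tx_start[si]),
               truth_map$g_start[si] + (oe - truth_map$tx_start[si]))
  # genomic strand of the block: read orientation on the transcript,
  # flipped where the segment itself is on the minus strand
  blk_minus <- xor(read_strand[qi] == "-", seg_minus)
  data.frame(read = read_idx[qi], chrom = truth_map$chrom[si],
             start = gs, end = ge,
             strand = ifelse(blk_minus, "-", "+"),
             stringsAsFactors = FALSE)
}

#' Simulate labelled paired-end reads from transcript specs
#'
#' Fragments are drawn across specs proportionally to their weights, start
#' positions uniform over valid positions, and each read carries its truth
#' genomic alignment (spliced across segment boundaries) derived from the
#' spec's transcript-to-genome map. Substitution errors are applied after
#' the truth alignment is recorded, as in real sequencing. Deterministic for
#' a fixed seed.
#'
#' @param specs list of [transcript_spec()].
#' @param config a [sim_config()].
#' @param sample_id identifier of the resulting read set.
#' @return a [read_set()]; `reads$label` holds per-read truth labels and the
#'   set-level label is the single spec label or `"mixed"`.
#' @export
simulate_reads <- function(specs, config, sample_id = "sim") {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(specs, "transcript_spec")) specs <- list(specs)
  w <- vapply(specs, function(s) s$weight, 0)
  if (all(w == 0)) stopf("spec weights must not all be zero")
  txlen <- vapply(specs, function(s) nchar(s$sequence), 0L)
  if (any(txlen < config$read_length))
    stopf("transcript shorter than a read (%d nt needed)", config$read_length)

  set.seed(config$seed)
  n <- config$n_read_pairs
  rl <- config$read_length
  spec_of <- sample.int(length(specs), n, replace = TRUE, prob = w)

  name <- sprintf("sim%07d", seq_len(n))
  r1 <- character(n); r2 <- character(n)
  blocks <- vector("list", 2L)
  label <- character(n)
  for (j in seq_along(specs)) {
    idx <- which(spec_of == j)
    if (!length(idx)) next
    sp <- specs[[j]]
    L <- txlen[j]
    frag <- pmin(pmax(round(rnorm(length(idx), config$fragment_mean,
                                  config$fragment_sd)), rl), L)
    start <- 1L + floor(runif(length(idx)) * (L - frag + 1))
    r1s <- start; r1e <- start + rl - 1L
    r2e <- start + frag - 1L; r2s <- r2e - rl + 1L
    r1[idx] <- substring(sp$sequence, r1s, r1e)
    r2[idx] <- revcomp(substring(sp$sequence, r2s, r2e))
    label[idx] <- sp$label
    if (!is.null(sp$truth_map)) {
      blocks[[1]] <- rbind(blocks[[1]],
        map_tx_intervals(sp$truth_map, r1s, r1e, idx, rep("+", length(idx))))
      blocks[[2]] <- rbind(blocks[[2]],
        map_tx_intervals(sp$truth_map, r2s, r2e, idx, rep("-", length(idx))))
    }
  }
  r1 <- mutate_bases(r1, config$error_rate)
  r2 <- mutate_bases(r2, config$error_rate)

  reads <- data.frame(name = rep(name, 2L),
                      sequence = c(r1, r2),
                      first = rep(c(TRUE, FALSE), each = n),
                      label = rep(label, 2L),
                      stringsAsFactors = FALSE)
  # row index in `reads` for R1_i is i, for R2_i is n + i; one split() call
  # builds the whole list (per-element assignment does not scale)
  b <- rbind(blocks[[1]], blocks[[2]])
  sel <- c(blocks[[1]]$read, if (!is.null(blocks[[2]])) blocks[[2]]$read + n)
  gr <- if (is.null(b)) GenomicRanges::GRanges() else
    GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start, b$end), b$strand)
  aln <- GenomicRanges::split(gr, factor(sel, levels = seq_len(2L * n)))
  lab <- unique(label)
  read_set(sample_id, reads, aln = aln, source = "simulator",
           label = if (length(lab) == 1L) lab else "mixed")
}

#' Reference contig lengths implied by a gene model (+ repeat fixture)
#'
#' Convenience for [write_readset_sam()] on simulated read sets.
#' @param model a `gene_model`.
#' @param repeat_name,repeat_length optional extra contig (default the
#'   shipped LINE1-like fixture).
#' @export
simulator_ref_lengths <- function(model, repeat_name = "LINE1_like_synthetic",
                                  repeat_length = 2000L) {
  out <- setNames(GenomicRanges::end(model$locus),
                  as.character(GenomicRanges::seqnames(model$locus)))
  out[repeat_name] <- repeat_length
  out
}
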