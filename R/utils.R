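# Small shared helpers. Sequence utilities lean on Biostrings; anything that
# touches randomness takes an explicit seed at the caller.

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' All length-k windows of a sequence, in order
#' @noRd
kmer_windows <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Parse a 1-based inclusive "chrom:start-end" region string
#' @noRd
parse_region <- function(region) {
  m <- regmatches(region, regexec("^(.+):([0-9,]+)-([0-9,]+)$", region))[[1]]
  if (length(m) != 4L)
    stop("cannot parse region string '", region, "' (expected chrom:start-end)")
  start <- as.numeric(gsub(",", "", m[3]))
  end <- as.numeric(gsub(",", "", m[4]))
  if (start > end) stop("region start exceeds end in '", region, "'")
  GenomicRanges::GRanges(m[2], IRanges::IRanges(start, end))
}

format_region <- function(gr) {
  sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)),
          GenomicRanges::start(gr), GenomicRanges::end(gr))
}

# Deterministic fingerprint of a feature schema; cheap stand-in for a
# cryptographic digest, sufficient to catch train/predict schema mismatches.
schema_fingerprint <- function(schema) {
  vocab_part <- if (is.null(schema$vocab)) "" else
    paste(length(schema$vocab), schema$vocab[1L],
          schema$vocab[length(schema$vocab)], sep = "|")
  paste(schema$kind, schema$k %||% "", paste(schema$scope, collapse = ","),
        schema$dim, vocab_part, sep = ";")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Introduce independent per-base substitution errors into read sequences
#' @noRd
mutate_bases <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  nmut <- rbinom(length(seqs), nchar(seqs), rate)
  idx <- which(nmut > 0L)
  for (i in idx) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(length(chars), nmut[i])
    for (p in pos) {
      chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
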