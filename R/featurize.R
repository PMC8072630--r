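# Featurization: fixed-length representations of a read group. Four kinds —
# k-mer counts over a reference-derived vocabulary, their frequencies,
# per-base coverage over an exon scope, and coverage frequencies. The
# vocabulary is derived from the spliced reference (optionally extended with
# skip-junction k-mers), which fixes the input dimension of the networks.

#' Build a k-mer vocabulary over an exon scope
#'
#' Slides a k-window over the spliced sequence of the scope exons (canonical
#' splice) and keeps distinct k-mers in first-occurrence order. With
#' `include_skip_junction`, the novel k-mers spanning the junction created
#' by excising the skip exon are appended, so presence (not just absence)
#' evidence of the skip is representable in k-mer space.
#'
#' @param gene_model a [gene_model()].
#' @param k k-mer length (>= 2; 16 by default, 31 also used in practice).
#' @param scope exon ordinals; default all exons.
#' @param include_skip_junction append skip-junction k-mers (default TRUE).
#' @param skip_ordinal exon whose excision defines the junction (default 14;
#'   ignored when it is not an internal exon of the scope).
#' @return object of class `kmer_vocabulary`: `k`, `scope`, `kmers`,
#'   `n_canonical` (count of canonical-splice k-mers preceding any junction
#'   k-mers), `skip_ordinal`.
#' @export
build_vocabulary <- function(gene_model, k = 16L, scope = NULL,
                             include_skip_junction = TRUE,
                             skip_ordinal = 14L) {
  stopifnot(k >= 2L)
  if (is.null(scope)) scope <- gene_model$exons$ordinal
  if (!length(scope)) stopf("empty exon scope")
  ref <- spliced_sequence(gene_model, scope)
  if (nchar(ref) < k)
    stopf("scope sequence (%d nt) shorter than k = %d", nchar(ref), k)
  kmers <- unique(kmer_windows(ref, k))
  n_canonical <- length(kmers)
  junction_ok <- include_skip_junction && skip_ordinal %in% scope &&
    skip_ordinal > min(gene_model$exons$ordinal) &&
    skip_ordinal < max(gene_model$exons$ordinal)
  if (junction_ok) {
    jseq <- skip_junction_sequence(gene_model, skip_ordinal, flank = k - 1L)
    jk <- setdiff(unique(kmer_windows(jseq, k)), kmers)
    kmers <- c(kmers, jk)
  }
  structure(list(k = as.integer(k), scope = as.integer(scope), kmers = kmers,
                 n_canonical = n_canonical,
                 skip_ordinal = if (junction_ok) as.integer(skip_ordinal)
                                else NA_integer_),
            class = "kmer_vocabulary")
}

#' @export
print.kmer_vocabulary <- function(x, ...) {
  cat(sprintf(
    "kmer_vocabulary: %d %d-mers over exons %s (%d canonical + %d junction)\n",
    length(x$kmers), x$k, paste(x$scope, collapse = ","), x$n_canonical,
    length(x$kmers) - x$n_canonical))
  invisible(x)
}

new_feature_vector <- function(values, kind, schema, group_id) {
  structure(as.numeric(values), kind = kind, schema = schema,
            group_id = group_id, class = "feature_vector")
}

kmer_schema <- function(vocab) {
  s <- list(kind = "kmer_count", k = vocab$k, scope = vocab$scope,
            dim = length(vocab$kmers), vocab = vocab$kmers,
            exon_of = NULL)
  s$fingerprint <- schema_fingerprint(s)
  s
}

#' k-mer count features of a read group
#'
#' Every length-k window of every read is tested against the vocabulary in
#' both the read orientation and its reverse complement; each match
#' increments that vocabulary slot. Counting is alignment-free; windows not
#' in the vocabulary are ignored, and reads shorter than k contribute
#' nothing.
#'
#' @param group a `read_group` (or `read_set`).
#' @param vocab a [build_vocabulary()] result.
#' @return `feature_vector` of kind `kmer_count`, length `length(vocab$kmers)`.
#' @export
kmer_features <- function(group, vocab, .pd = NULL) {
  if (n_reads(group) == 0L) stopf("empty read group")
  short <- nchar(group$reads$sequence) < vocab$k
  seqs <- group$reads$sequence[!short]
  if (any(short))
    message(sum(short), " read(s) shorter than k = ", vocab$k, " ignored")
  pd <- .pd %||% Biostrings::PDict(vocab$kmers)
  counts <- numeric(length(vocab$kmers))
  if (length(seqs)) {
    dna <- Biostrings::DNAStringSet(seqs)
    counts <- rowSums(Biostrings::vcountPDict(pd, dna)) +
      rowSums(Biostrings::vcountPDict(pd, Biostrings::reverseComplement(dna)))
    # a window whose forward form is already in the vocabulary must not also
    # credit the slot of its reverse complement: subtract those occurrences
    both <- which(revcomp(vocab$kmers) %in% vocab$kmers)
    if (length(both)) {
      c2 <- rowSums(Biostrings::vcountPDict(
        Biostrings::PDict(vocab$kmers[both]), dna))
      rc_slot <- match(revcomp(vocab$kmers[both]), vocab$kmers)
      counts[rc_slot] <- counts[rc_slot] - c2
    }
  }
  new_feature_vector(counts, "kmer_count", kmer_schema(vocab),
                     group$group_id %||% group$sample_id)
}

coverage_schema <- function(gene_model, scope) {
  ex <- gene_model$exons[match(scope, gene_model$exons$ordinal), ]
  s <- list(kind = "coverage", k = NULL, scope = as.integer(scope),
            dim = sum(ex$width), vocab = NULL,
            exon_of = rep(ex$ordinal, ex$width))
  s$fingerprint <- schema_fingerprint(s)
  s
}

#' Per-base coverage features over an exon scope
#'
#' Depth at each base of the scope exons, concatenated in transcript order
#' (each exon's positions run 5' to 3' on the transcript strand). A read
#' increments every scope base covered by one of its alignment blocks —
#' standard depth semantics over match-consuming positions.
#'
#' @param group a `read_group` (or `read_set`) with alignments.
#' @param gene_model a [gene_model()].
#' @param scope exon ordinals; default all exons.
#' @return `feature_vector` of kind `coverage`, length = total scope width.
#' @export
coverage_features <- function(group, gene_model, scope = NULL) {
  if (is.null(scope)) scope <- gene_model$exons$ordinal
  ex <- gene_model$exons[match(scope, gene_model$exons$ordinal), ]
  if (anyNA(ex$ordinal)) stopf("unknown exon ordinal in scope")
  flat <- if (is.null(group$aln)) GenomicRanges::GRanges() else
    unlist(group$aln, use.names = FALSE)
  flat <- flat[as.character(GenomicRanges::seqnames(flat)) == ex$chrom[1]]
  schema <- coverage_schema(gene_model, scope)
  if (length(flat) == 0L) {
    warning("read group has no aligned reads on ", ex$chrom[1],
            "; all-zero coverage")
    return(new_feature_vector(numeric(schema$dim), "coverage", schema,
                              group$group_id %||% group$sample_id))
  }
  maxend <- max(GenomicRanges::end(flat), ex$end)
  cov <- IRanges::coverage(IRanges::ranges(flat), width = maxend)
  vals <- lapply(seq_len(nrow(ex)), function(i) {
    v <- as.integer(IRanges::Views(cov, ex$start[i], ex$end[i])[[1]])
    if (ex$strand[i] == "-") rev(v) else v
  })
  new_feature_vector(unlist(vals), "coverage", schema,
                     group$group_id %||% group$sample_id)
}

#' Convert a count feature vector to a frequency vector
#'
#' Values are divided by their sum, giving a composition summing to 1; an
#' all-zero vector is returned unchanged with a warning.
#'
#' @param fv `feature_vector` of kind `kmer_count` or `coverage`, or a
#'   matrix of such rows.
#' @export
to_frequency <- function(fv) {
  if (is.matrix(fv)) {
    s <- rowSums(fv)
    if (any(s == 0)) warning(sum(s == 0), " all-zero row(s) left as zero")
    s[s == 0] <- 1
    out <- fv / s
    schema <- attr(fv, "schema")
    if (!is.null(schema)) {
      schema$kind <- paste0(schema$kind, "_freq")
      schema$fingerprint <- schema_fingerprint(schema)
      attr(out, "schema") <- schema
    }
    return(out)
  }
  stopifnot(inherits(fv, "feature_vector"))
  kind <- attr(fv, "kind")
  if (!kind %in% c("kmer_count", "coverage"))
    stopf("to_frequency expects a count/coverage vector, got %s", kind)
  s <- sum(fv)
  vals <- if (s == 0) {
    warning("all-zero feature vector; frequencies left at zero")
    as.numeric(fv)
  } else as.numeric(fv) / s
  schema <- attr(fv, "schema")
  schema$kind <- paste0(kind, "_freq")
  schema$fingerprint <- schema_fingerprint(schema)
  new_feature_vector(vals, schema$kind, schema, attr(fv, "group_id"))
}

#' Feature matrix for a list of read groups
#'
#' @param groups list of `read_group`s.
#' @param kind one of `kmer_count`, `kmer_freq`, `coverage`, `coverage_freq`.
#' @param gene_model needed for the coverage kinds.
#' @param scope exon ordinals (coverage kinds).
#' @param vocab [build_vocabulary()] result (k-mer kinds).
#' @return numeric matrix, rows = groups (named by group id), with a
#'   `schema` attribute and a `labels` attribute of per-group truth labels.
#' @export
featurize_groups <- function(groups, kind, gene_model = NULL, scope = NULL,
                             vocab = NULL) {
  kind <- match.arg(kind, c("kmer_count", "kmer_freq", "coverage",
                            "coverage_freq"))
  base_kind <- sub("_freq$", "", kind)
  base_kind <- ifelse(base_kind == "kmer", "kmer_count", base_kind)
  pd <- if (base_kind == "kmer_count") Biostrings::PDict(vocab$kmers)
  fvs <- lapply(groups, function(g) {
    if (base_kind == "kmer_count") kmer_features(g, vocab, .pd = pd)
    else coverage_features(g, gene_model, scope)
  })
  mat <- do.call(rbind, lapply(fvs, as.numeric))
  rownames(mat) <- vapply(groups, function(g) g$group_id, "")
  attr(mat, "schema") <- attr(fvs[[1]], "schema")
  if (grepl("_freq$", kind)) mat <- to_frequency(mat)
  attr(mat, "labels") <- vapply(groups, function(g) g$label, "")
  mat
}

#' Write a feature matrix as TSV with a sidecar JSON schema
#'
#' @param features matrix from [featurize_groups()].
#' @param path TSV path; the schema goes to `<path>.schema.json`.
#' @export
write_features <- function(features, path) {
  df <- data.frame(group_id = rownames(features),
                   label = attr(features, "labels") %||%
                     rep("unknown", nrow(features)),
                   features, check.names = FALSE)
  colnames(df)[-(1:2)] <- paste0("f", seq_len(ncol(features)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  schema <- attr(features, "schema")
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a feature matrix written by [write_features()]
#'
#' Validates the stored schema fingerprint before returning; a corrupted or
#' mismatched sidecar is an error.
#' @param path TSV path.
#' @export
read_features <- function(path) {
  schema <- jsonlite::read_json(paste0(path, ".schema.json"),
                                simplifyVector = TRUE)
  if (!identical(schema_fingerprint(schema), schema$fingerprint))
    stopf("schema fingerprint mismatch for %s", path)
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -(1:2), drop = FALSE])
  dimnames(mat) <- list(df$group_id, NULL)
  attr(mat, "schema") <- schema
  attr(mat, "labels") <- df$label
  mat
}
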