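# Random, non-overlapping, fixed-size read groups — the unit on which
# features are computed and the networks are trained and tested.

#' Partition a read set into fixed-size random read groups
#'
#' Reads are shuffled with a seeded generator and chunked into
#' `floor(N / group_size)` pairwise-disjoint groups of exactly `group_size`
#' reads; the remainder is discarded. Sampling is without replacement within
#' one partition; independent partitions (different seeds) may be used for
#' augmentation and are distinguishable by their group ids.
#'
#' @param readset a [read_set()].
#' @param group_size reads per group (>= 1); training uses 1000, test sweeps
#'   typically use 500/1000/5000.
#' @param seed partition seed.
#' @return list of `read_group` objects (possibly empty); each inherits the
#'   read set's label and records its parent sample and seed.
#' @export
partition_reads <- function(readset, group_size, seed = 1L) {
  stopifnot(group_size >= 1L)
  n <- n_reads(readset)
  n_groups <- n %/% group_size
  if (n_groups == 0L) {
    message("read set has ", n, " reads < group size ", group_size,
            "; no groups formed")
    return(list())
  }
  set.seed(seed)
  perm <- sample.int(n)
  lapply(seq_len(n_groups), function(g) {
    idx <- perm[((g - 1L) * group_size + 1L):(g * group_size)]
    structure(list(
      group_id = sprintf("%s.s%d.g%04d", readset$sample_id, seed, g),
      reads = readset$reads[idx, , drop = FALSE],
      aln = if (is.null(readset$aln)) NULL else readset$aln[idx],
      size = as.integer(group_size),
      parent_sample = readset$sample_id,
      label = readset$label,
      seed = as.integer(seed)), class = "read_group")
  })
}

#' @export
print.read_group <- function(x, ...) {
  cat(sprintf("read_group %s: %d reads, label=%s\n",
              x$group_id, x$size, x$label))
  invisible(x)
}

#' Group manifest: group id to read names
#'
#' Serializable record of a partition (one row per read).
#' @param groups list of `read_group`s.
#' @export
group_manifest <- function(groups) {
  do.call(rbind, lapply(groups, function(g)
    data.frame(group_id = g$group_id, read = g$reads$name,
               first = g$reads$first, label = g$label,
               stringsAsFactors = FALSE)))
}
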