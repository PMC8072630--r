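# Discovery utilities: input normalization for the autoencoder, seeded
# k-means clustering of the latent space with silhouette-selected k, a
# pairwise-Jaccard cluster stability score, and the exact-k-mer repeat
# screen over discordant mate pairs.

#' Normalize feature matrices for the autoencoder
#'
#' Per-sample frequency normalization, scaling to counts-per-10k followed
#' by `log1p`, then per-feature z-scoring (zero-variance features are set to
#' zero). A simple, fully documented chain standing where single-cell-style
#' expression-recovery normalization would be used on real cohorts.
#'
#' @param features non-negative matrix, rows = samples.
#' @return matrix of the same shape; column means ~0, sd ~1 for
#'   non-degenerate features; row order preserved.
#' @export
normalize_latent_input <- function(features) {
  X <- as.matrix(features)
  if (any(X < 0)) stopf("normalize_latent_input expects non-negative input")
  rs <- rowSums(X)
  rs[rs == 0] <- 1
  X <- log1p(X / rs * 1e4)
  mu <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  X <- sweep(X, 2L, mu, "-")
  nz <- sdv > 0
  X[, nz] <- sweep(X[, nz, drop = FALSE], 2L, sdv[nz], "/")
  X[, !nz] <- 0
  attr(X, "schema") <- attr(features, "schema")
  attr(X, "labels") <- attr(features, "labels")
  X
}

mean_silhouette <- function(d, cl) {
  mean(cluster::silhouette(cl, d)[, "sil_width"])
}

#' Cluster a latent space repeatedly with silhouette-selected k
#'
#' Each of the `n_runs` sub-seeded runs fits k-means to a random subsample
#' of the rows for every candidate k, keeps the k with the best mean
#' silhouette width on that subsample, and extends the fitted clusters to
#' every sample by nearest centroid. The subsampling gives each run an
#' independent perturbation, so run-to-run agreement — measured by
#' [cluster_stability()] over identical samples — reflects how well the
#' cluster organization is supported by the data rather than by the
#' optimizer's restarts.
#'
#' @param latent numeric matrix, rows = samples (e.g. from [encode()]).
#' @param k_candidates candidate cluster counts.
#' @param n_runs number of independent runs (>= 2 for stability).
#' @param seed base seed; run r uses `seed + r`.
#' @param subsample_fraction fraction of samples each run is fitted on.
#' @return list of `cluster_result` objects (`assignments` over all
#'   samples, `k`, `seed`, `silhouette`).
#' @export
cluster_latent <- function(latent, k_candidates = 2:6, n_runs = 10L,
                           seed = 1L, subsample_fraction = 0.8) {
  stopifnot(n_runs >= 2L, subsample_fraction > 0, subsample_fraction <= 1)
  latent <- as.matrix(latent)
  n <- nrow(latent)
  n_fit <- max(round(subsample_fraction * n), max(k_candidates) + 1L)
  if (n <= max(k_candidates))
    stopf("fewer samples (%d) than clusters requested (%d)",
          n, max(k_candidates))
  lapply(seq_len(n_runs), function(r) {
    set.seed(seed + r)
    idx <- sample.int(n, min(n_fit, n))
    sub <- latent[idx, , drop = FALSE]
    d <- dist(sub)
    fits <- lapply(k_candidates, function(k)
      kmeans(sub, centers = k, nstart = 5L))
    sil <- vapply(seq_along(k_candidates), function(i)
      mean_silhouette(d, fits[[i]]$cluster), 0)
    best <- fits[[which.max(sil)]]
    # nearest-centroid extension to the full sample set
    k <- nrow(best$centers)
    d2 <- outer(rowSums(latent^2), rowSums(best$centers^2), "+") -
      2 * latent %*% t(best$centers)
    structure(list(assignments = max.col(-d2),
                   k = k, seed = seed + r,
                   silhouette = max(sil)),
              class = "cluster_result")
  })
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

#' Stability of repeated latent-space clusterings
#'
#' Draws random pairs of runs and, for every cluster of the first run,
#' records the best Jaccard overlap with any cluster of the second. A
#' conserved cluster organization scores near 1 across the many pairings;
#' clustering noise degrades it.
#'
#' @param results list of `cluster_result`s over identical samples.
#' @param n_pairs number of random run pairs to compare (capped by the
#'   number of distinct pairs).
#' @param seed seed for the pair draw.
#' @return object of class `stability_score`: `per_cluster` (mean best-match
#'   Jaccard per cluster label of the reference run), `overall` (their
#'   mean), `n_pairs`.
#' @export
cluster_stability <- function(results, n_pairs = 1000L, seed = 1L) {
  stopifnot(length(results) >= 2L)
  sizes <- vapply(results, function(r) length(r$assignments), 0L)
  if (length(unique(sizes)) != 1L)
    stopf("cluster results cover different sample sets")
  set.seed(seed)
  combos <- utils::combn(length(results), 2L)
  take <- sample.int(ncol(combos), min(n_pairs, ncol(combos)),
                     replace = n_pairs > ncol(combos))
  scores <- list()
  for (idx in take) {
    a <- results[[combos[1L, idx]]]$assignments
    b <- results[[combos[2L, idx]]]$assignments
    mem_a <- split(seq_along(a), a)
    mem_b <- split(seq_along(b), b)
    for (cl in names(mem_a)) {
      best <- max(vapply(mem_b, jaccard, 0, a = mem_a[[cl]]))
      scores[[cl]] <- c(scores[[cl]], best)
    }
  }
  per_cluster <- vapply(scores, mean, 0)
  structure(list(per_cluster = per_cluster,
                 overall = mean(per_cluster),
                 n_pairs = length(take)),
            class = "stability_score")
}

#' @export
print.stability_score <- function(x, ...) {
  cat(sprintf("stability_score: overall %.3f over %d run pairs (%d clusters)\n",
              x$overall, x$n_pairs, length(x$per_cluster)))
  invisible(x)
}

#' Screen discordant mates against a repeat reference by exact k-mer seeds
#'
#' A non-locus mate "matches" the repeat when it shares at least one exact
#' k-mer with the repeat sequence in either orientation. For each hit the
#' putative fusion point is reported from the locus-anchored mate's
#' alignment start — the deterministic stand-in for a full repeat
#' alignment.
#'
#' @param pairs `half_mapped_pairs` from [extract_half_mapped_pairs()] (any
#'   data.frame with `name`, `mate_seq`, `locus_chrom`, `locus_start`
#'   columns works).
#' @param repeat_sequence repeat reference (default the shipped synthetic
#'   LINE1-like fixture).
#' @param k exact seed length (default 31; must not exceed read length).
#' @return data.frame of hits: `name`, `matched` (shared k-mer count),
#'   `putative_fusion_chrom`, `putative_fusion_point`.
#' @export
repeat_screen <- function(pairs, repeat_sequence = NULL, k = 31L) {
  if (is.null(repeat_sequence)) repeat_sequence <- line1_like_sequence()
  empty <- data.frame(name = character(0), matched = integer(0),
                      putative_fusion_chrom = character(0),
                      putative_fusion_point = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) return(empty)
  if (any(nchar(pairs$mate_seq) < k))
    message("mate(s) shorter than k = ", k, " cannot match")
  ref_kmers <- unique(c(kmer_windows(repeat_sequence, k),
                        kmer_windows(revcomp(repeat_sequence), k)))
  matched <- vapply(pairs$mate_seq, function(s)
    sum(unique(kmer_windows(s, k)) %in% ref_kmers), 0L, USE.NAMES = FALSE)
  hit <- matched > 0L
  data.frame(name = pairs$name[hit], matched = matched[hit],
             putative_fusion_chrom = pairs$locus_chrom[hit],
             putative_fusion_point = pairs$locus_start[hit],
             stringsAsFactors = FALSE)
}
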