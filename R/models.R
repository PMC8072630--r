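# Training, prediction, connectivity masks, hyperparameter grid search and
# model persistence on top of the network engine in nn_core.R.

feature_hash <- function(features) {
  s <- attr(features, "schema")
  if (is.null(s)) "unspecified" else s$fingerprint
}

encode_labels <- function(labels) {
  if (is.numeric(labels)) {
    y <- as.numeric(labels)
    if (!all(y %in% c(0, 1))) stopf("numeric labels must be 0 (WT) / 1 (skip)")
  } else {
    lv <- as.character(labels)
    if (!all(lv %in% c("WT", "delta14")))
      stopf("labels must be WT/delta14 or 0/1")
    y <- as.numeric(lv == "delta14")
  }
  if (length(unique(y)) < 2L)
    stopf("training labels contain a single class")
  y
}

train_net <- function(spec, X, target, opt, epochs, batch_size, val_fraction,
                      seed, patience, verbose = FALSE) {
  stopifnot(ncol(X) == spec$input_dim)
  set.seed(seed)
  params <- init_params(spec)
  state <- adam_init(params, opt)
  n <- nrow(X)
  n_val <- if (val_fraction > 0) max(1L, round(val_fraction * n)) else 0L
  val_idx <- if (n_val > 0L) sample.int(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  tgt <- function(i) if (spec$arch == "sca") X[i, , drop = FALSE]
                     else matrix(target[i], ncol = 1L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(loss = Inf, params = params, epoch = 0L)
  stale <- 0L
  for (ep in seq_len(epochs)) {
    ord <- tr_idx[sample.int(length(tr_idx))]
    batch_losses <- numeric(0)
    for (b in seq_len(ceiling(length(ord) / batch_size))) {
      bi <- ord[((b - 1L) * batch_size + 1L):min(b * batch_size, length(ord))]
      fw <- forward_net(spec, params, X[bi, , drop = FALSE], training = TRUE)
      lo <- net_loss(spec, fw$pred, tgt(bi), opt$loss)
      if (!is.finite(lo$loss))
        stopf("non-finite loss at epoch %d batch %d; try a lower lr", ep, b)
      grads <- backward_net(spec, params, fw$cache, lo$dout)
      st <- adam_step(state, params, grads)
      state <- st$state; params <- st$params
      if (spec$arch == "sca") {   # hard sparsity: re-mask after every step
        params$We <- params$We * spec$mask
        params$Wd <- params$Wd * t(spec$mask)
      }
      batch_losses <- c(batch_losses, lo$loss)
    }
    val_loss <- NA_real_
    if (n_val > 0L) {
      fw <- forward_net(spec, params, X[val_idx, , drop = FALSE])
      val_loss <- net_loss(spec, fw$pred, tgt(val_idx), opt$loss)$loss
    }
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = mean(batch_losses),
                                         val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %3d train %.6f val %.6f", ep,
                      mean(batch_losses), val_loss))
    monitor <- if (n_val > 0L) val_loss else mean(batch_losses)
    if (monitor < best$loss - 1e-9) {
      best <- list(loss = monitor, params = params, epoch = ep)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) break
    }
  }
  list(params = best$params, history = history, best_epoch = best$epoch,
       best_loss = best$loss)
}

new_skipnet_model <- function(spec, fit, opt, schema_hash, seed, task) {
  structure(list(spec = spec, params = fit$params, opt = opt,
                 feature_schema_hash = schema_hash,
                 history = fit$history, best_epoch = fit$best_epoch,
                 val_loss = fit$best_loss, seed = seed, task = task,
                 version = 1L),
            class = "skipnet_model")
}

#' @export
print.skipnet_model <- function(x, ...) {
  cat(sprintf(
    "skipnet_model (%s, %s): %d params, best epoch %d (monitored loss %.3g)\n",
    x$spec$arch, x$task, n_params(x), x$best_epoch, x$val_loss))
  invisible(x)
}

#' Train a binary read-group classifier (dense or convolutional)
#'
#' Trains with Adam on mean-squared error (the historical default for these
#' models; cross-entropy available through `opt`), recording per-epoch
#' train/validation loss and keeping the parameters of the best validation
#' epoch (early stopping with the given patience). Deterministic for a fixed
#' seed.
#'
#' @param spec a [dense_net_spec()] or [conv_net_spec()].
#' @param features numeric matrix, rows = read groups (e.g. from
#'   [featurize_groups()]).
#' @param labels per-row labels: `"WT"`/`"delta14"` or 0/1 (1 = skipped).
#'   Both classes must be present.
#' @param opt an [optimizer_config()].
#' @param epochs,batch_size,val_fraction,patience training loop controls.
#' @param seed RNG seed covering initialization, dropout and shuffling.
#' @param verbose print per-epoch losses.
#' @return a `skipnet_model`.
#' @export
train_classifier <- function(spec, features, labels,
                             opt = optimizer_config(), epochs = 50L,
                             batch_size = 32L, val_fraction = 0.2,
                             seed = 1L, patience = 10L, verbose = FALSE) {
  stopifnot(inherits(spec, "net_spec"), spec$arch %in% c("dense", "conv"))
  y <- encode_labels(labels)
  fit <- train_net(spec, unname(as.matrix(features)), y, opt, epochs,
                   batch_size, val_fraction, seed, patience, verbose)
  new_skipnet_model(spec, fit, opt, feature_hash(features), seed, "classify")
}

#' Predict skip scores for read groups
#'
#' @param object a trained `skipnet_model`.
#' @param newdata feature matrix or single feature vector with the same
#'   schema the model was trained on.
#' @param ... unused.
#' @return numeric scores in `[0, 1]` (classifiers) or the reconstruction
#'   matrix (autoencoder).
#' @export
predict.skipnet_model <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- matrix(as.numeric(newdata), nrow = 1L)
  if (ncol(newdata) != object$spec$input_dim)
    stopf("feature dimension %d does not match model input %d",
          ncol(newdata), object$spec$input_dim)
  h <- feature_hash(newdata)
  if (h != "unspecified" && object$feature_schema_hash != "unspecified" &&
      h != object$feature_schema_hash)
    stopf("feature schema mismatch: model %s vs data %s",
          object$feature_schema_hash, h)
  pred <- forward_net(object$spec, object$params,
                      unname(as.matrix(newdata)))$pred
  if (object$task == "classify") as.numeric(pred) else pred
}

#' Binary class call from skip scores
#'
#' @param model a trained classifier.
#' @param features feature matrix or vector.
#' @param threshold decision threshold; a group is called skipped only when
#'   its score strictly exceeds it (a score of exactly `threshold` is WT).
#' @return character vector of `"WT"` / `"delta14"` calls.
#' @export
classify <- function(model, features, threshold = 0.5) {
  ifelse(predict(model, features) > threshold, "delta14", "WT")
}

#' Connectivity mask linking features to exons
#'
#' For coverage features each position belongs to exactly one exon. For
#' k-mer features a k-mer is attributed to the exon(s) its first occurrence
#' in the spliced scope sequence overlaps; skip-junction k-mers (absent from
#' the canonical splice) connect to both exons flanking the skipped exon.
#'
#' @param feature_schema the `schema` attribute of a feature matrix.
#' @param gene_model the [gene_model()] the features were computed on.
#' @param skip_ordinal skipped exon used for junction attribution.
#' @return binary `input_dim x length(scope)` matrix, columns named by exon
#'   ordinal.
#' @export
build_connectivity_mask <- function(feature_schema, gene_model,
                                    skip_ordinal = 14L) {
  scope <- feature_schema$scope
  kind <- sub("_freq$", "", feature_schema$kind)
  mask <- matrix(0, feature_schema$dim, length(scope),
                 dimnames = list(NULL, scope))
  if (kind == "coverage") {
    mask[cbind(seq_len(feature_schema$dim),
               match(feature_schema$exon_of, scope))] <- 1
    return(mask)
  }
  k <- feature_schema$k
  ref <- spliced_sequence(gene_model, scope)
  windows <- kmer_windows(ref, k)
  pos <- match(feature_schema$vocab, windows)
  widths <- gene_model$exons$width[match(scope, gene_model$exons$ordinal)]
  bounds <- cumsum(widths)
  exon_at <- function(p) findInterval(p - 1L, bounds) + 1L  # scope index
  flank_lo <- scope[scope < skip_ordinal]
  flank_hi <- scope[scope > skip_ordinal]
  junction_cols <- match(c(if (length(flank_lo)) max(flank_lo),
                           if (length(flank_hi)) min(flank_hi)), scope)
  bad <- character(0)
  for (i in seq_along(pos)) {
    if (is.na(pos[i])) {
      if (length(junction_cols) == 2L && !anyNA(junction_cols)) {
        mask[i, junction_cols] <- 1
      } else {
        bad <- c(bad, feature_schema$vocab[i])
      }
    } else {
      mask[i, exon_at(pos[i]):exon_at(pos[i] + k - 1L)] <- 1
    }
  }
  if (length(bad))
    stopf("unattributable k-mer feature(s): %s",
          paste(head(bad, 5L), collapse = ", "))
  mask
}

#' Train the sparsely connected autoencoder
#'
#' Minimizes mean squared reconstruction error with Adam; the connectivity
#' mask is re-applied to both encoder and decoder weights after every
#' optimizer step, so masked weights are exactly zero throughout training.
#' Input should be normalized (see [normalize_latent_input()]).
#'
#' @param spec an [sca_spec()].
#' @param features normalized feature matrix, rows = samples/groups.
#' @inheritParams train_classifier
#' @return a `skipnet_model` with task `"autoencode"`.
#' @export
train_sca <- function(spec, features, opt = optimizer_config(),
                      epochs = 50L, batch_size = 32L, val_fraction = 0.2,
                      seed = 1L, patience = 10L, verbose = FALSE) {
  stopifnot(inherits(spec, "sca_spec"))
  fit <- train_net(spec, unname(as.matrix(features)), NULL, opt, epochs,
                   batch_size, val_fraction, seed, patience, verbose)
  new_skipnet_model(spec, fit, opt, feature_hash(features), seed,
                    "autoencode")
}

#' Project samples into the exon-structured latent space
#'
#' @param model a trained SCA model.
#' @param features feature matrix (same schema as training).
#' @return `n x latent_dim` matrix, columns named by exon ordinal where the
#'   mask carried names.
#' @export
encode <- function(model, features) {
  stopifnot(model$spec$arch == "sca")
  X <- unname(as.matrix(features))
  if (ncol(X) != model$spec$input_dim) stopf("feature dimension mismatch")
  H <- relu(add_bias(X %*% params_of(model)$We, params_of(model)$be))
  colnames(H) <- colnames(model$spec$mask)
  rownames(H) <- rownames(features)
  H
}

params_of <- function(model) model$params

#' Exhaustive hyperparameter grid search
#'
#' Evaluates every combination of the grid (Cartesian product), training one
#' model per configuration with a shared seed, and returns the full table
#' ranked by monitored validation loss.
#'
#' @param spec_family constructor taking `input_dim` plus grid parameters,
#'   e.g. [conv_net_spec()].
#' @param grid named list of candidate values, e.g.
#'   `list(kernel_size = c(2, 5, 100))`.
#' @param features,labels training data as in [train_classifier()].
#' @param seed seed shared across configurations.
#' @param ... forwarded to [train_classifier()].
#' @return data.frame of configurations with `val_loss`, `best_epoch` and
#'   `rank` (1 = best); the winning model is attached as attribute
#'   `best_model`.
#' @export
grid_search <- function(spec_family, grid, features, labels, seed = 1L, ...) {
  if (!length(grid) || any(!vapply(grid, length, 0L)))
    stopf("empty hyperparameter grid")
  configs <- expand.grid(grid, stringsAsFactors = FALSE)
  res <- configs
  res$val_loss <- NA_real_
  res$best_epoch <- NA_integer_
  best <- NULL
  for (i in seq_len(nrow(configs))) {
    spec <- do.call(spec_family,
                    c(list(input_dim = ncol(features)),
                      as.list(configs[i, , drop = FALSE])))
    m <- train_classifier(spec, features, labels, seed = seed, ...)
    res$val_loss[i] <- m$val_loss
    res$best_epoch[i] <- m$best_epoch
    if (is.null(best) || m$val_loss < best$val_loss) best <- m
  }
  res$rank <- rank(res$val_loss, ties.method = "first")
  res <- res[order(res$rank), , drop = FALSE]
  attr(res, "best_model") <- best
  res
}

# --- persistence -----------------------------------------------------------

#' Save a trained model as a versioned JSON archive
#'
#' The archive holds the architecture spec, full-precision weight arrays,
#' the feature schema fingerprint and training metadata; [load_model()]
#' restores a model that predicts identically.
#'
#' @param model a `skipnet_model`.
#' @param path output `.json` path.
#' @export
save_model <- function(model, path) {
  spec <- unclass(model$spec)
  payload <- list(
    format = "skipnet_model", version = model$version,
    spec = spec, spec_class = class(model$spec),
    params = lapply(model$params, function(p)
      list(dim = dim(p) %||% length(p), data = as.numeric(p))),
    opt = unclass(model$opt),
    feature_schema_hash = model$feature_schema_hash,
    history = model$history, best_epoch = model$best_epoch,
    val_loss = model$val_loss, seed = model$seed, task = model$task)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a model archive written by [save_model()]
#' @param path archive path.
#' @export
load_model <- function(path) {
  p <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) NULL)
  if (!identical(p$format, "skipnet_model"))
    stopf("%s is not a skipnet model archive", path)
  spec <- p$spec
  if (!is.null(spec$mask)) spec$mask <- as.matrix(spec$mask)
  class(spec) <- p$spec_class
  params <- lapply(p$params, function(q) {
    if (length(q$dim) == 2L) matrix(q$data, q$dim[1], q$dim[2])
    else as.numeric(q$data)
  })
  structure(list(spec = spec, params = params,
                 opt = structure(as.list(p$opt), class = "optimizer_config"),
                 feature_schema_hash = p$feature_schema_hash,
                 history = p$history, best_epoch = p$best_epoch,
                 val_loss = p$val_loss, seed = p$seed, task = p$task,
                 version = p$version),
            class = "skipnet_model")
}
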