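# One-shot orchestration: simulate (or extract) -> subsample -> featurize ->
# train -> evaluate, with the configuration and per-stage seeds serialized
# into the run directory and stage results reused when the configuration
# has not changed.

#' Pipeline run configuration
#'
#' Validated container for an end-to-end run on simulated data. Every field
#' is written to `config.json` in the run directory, making runs
#' self-describing and resumable.
#'
#' @param out_dir run directory.
#' @param arch `"dense"` or `"conv"`.
#' @param feature_kind one of `kmer_count`, `kmer_freq`, `coverage`,
#'   `coverage_freq`.
#' @param scope exon ordinals featurized (default 13-15).
#' @param k k-mer length for k-mer kinds.
#' @param kernel_size CNN kernel size.
#' @param group_size reads per group.
#' @param n_train_groups,n_test_groups groups per class for training and
#'   held-out evaluation.
#' @param skip_ordinal skipped exon (default 14).
#' @param error_rate simulator substitution rate.
#' @param epochs,batch_size training controls.
#' @param threshold decision threshold for calls.
#' @param seed master seed; stage seeds are derived from it.
#' @param gene_seed seed of the synthetic reference sequence.
#' @export
run_config <- function(out_dir,
                       arch = c("dense", "conv"),
                       feature_kind = "coverage_freq",
                       scope = 13:15, k = 16L, kernel_size = 100L,
                       group_size = 1000L,
                       n_train_groups = 100L, n_test_groups = 30L,
                       skip_ordinal = 14L, error_rate = 0.001,
                       epochs = 50L, batch_size = 32L, threshold = 0.5,
                       seed = 1L, gene_seed = 208L) {
  arch <- match.arg(arch)
  feature_kind <- match.arg(feature_kind,
                            c("kmer_count", "kmer_freq", "coverage",
                              "coverage_freq"))
  stopifnot(group_size >= 1L, n_train_groups >= 2L, n_test_groups >= 1L,
            threshold > 0, threshold < 1)
  structure(list(out_dir = out_dir, arch = arch,
                 feature_kind = feature_kind, scope = as.integer(scope),
                 k = as.integer(k), kernel_size = as.integer(kernel_size),
                 group_size = as.integer(group_size),
                 n_train_groups = as.integer(n_train_groups),
                 n_test_groups = as.integer(n_test_groups),
                 skip_ordinal = as.integer(skip_ordinal),
                 error_rate = error_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), threshold = threshold,
                 seed = as.integer(seed), gene_seed = as.integer(gene_seed)),
            class = "run_config")
}

config_fingerprint <- function(config, fields) {
  paste(vapply(fields, function(f)
    paste(format(config[[f]], digits = 15), collapse = ","), ""),
    collapse = ";")
}

stage_fresh <- function(dir, stage, fp, outputs) {
  done <- file.path(dir, paste0(stage, ".done.json"))
  if (!file.exists(done) || !all(file.exists(file.path(dir, outputs))))
    return(FALSE)
  rec <- jsonlite::read_json(done)
  identical(rec$fingerprint, fp)
}

stage_done <- function(dir, stage, fp) {
  jsonlite::write_json(list(stage = stage, fingerprint = fp,
                            time = format(Sys.time(), tz = "UTC")),
                       file.path(dir, paste0(stage, ".done.json")),
                       auto_unbox = TRUE)
}

simulate_class_groups <- function(model, regime, config, n_groups, seed) {
  n_pairs <- ceiling(n_groups * config$group_size / 2L)
  specs <- build_transcript_specs(model, regime,
                                  skip_ordinal = config$skip_ordinal)
  rs <- simulate_reads(specs, sim_config(error_rate = config$error_rate,
                                         n_read_pairs = n_pairs,
                                         seed = seed),
                       sample_id = paste0("sim_", regime, "_s", seed))
  partition_reads(rs, config$group_size, seed = seed)
}

pipeline_features <- function(groups, config, model, vocab) {
  featurize_groups(groups, config$feature_kind, gene_model = model,
                   scope = config$scope, vocab = vocab)
}

#' Run the simulate -> subsample -> featurize -> train -> evaluate pipeline
#'
#' Each stage writes its outputs plus a fingerprint of the configuration
#' slice it depends on; rerunning with an unchanged configuration reuses
#' finished stages (deleting a stage's outputs forces it, and everything
#' downstream, to re-execute).
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return invisibly, a list with the run directory, the trained model and
#'   the evaluation report.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[skipnet] ", ...)
  jsonlite::write_json(unclass(config), file.path(config$out_dir,
                                                  "config.json"),
                       auto_unbox = TRUE, digits = NA)

  model <- synthetic_met_gene_model(config$gene_seed)
  vocab <- NULL
  if (grepl("^kmer", config$feature_kind))
    vocab <- build_vocabulary(model, k = config$k, scope = config$scope,
                              skip_ordinal = config$skip_ordinal)

  feat_fp <- config_fingerprint(config,
    c("feature_kind", "scope", "k", "group_size", "n_train_groups",
      "n_test_groups", "skip_ordinal", "error_rate", "seed", "gene_seed"))
  feat_files <- c("features_train.tsv", "features_test.tsv")
  if (stage_fresh(config$out_dir, "featurize", feat_fp, feat_files)) {
    say("featurize: up to date")
    train_mat <- read_features(file.path(config$out_dir, feat_files[1]))
    test_mat <- read_features(file.path(config$out_dir, feat_files[2]))
  } else {
    say("simulate + subsample + featurize")
    groups <- list(train = list(), test = list())
    for (i in seq_along(regimes <- c("WT", "delta14"))) {
      groups$train[[i]] <- simulate_class_groups(
        model, regimes[i], config, config$n_train_groups, config$seed + i)
      groups$test[[i]] <- simulate_class_groups(
        model, regimes[i], config, config$n_test_groups,
        config$seed + 100L + i)
    }
    train_mat <- pipeline_features(c(groups$train[[1]], groups$train[[2]]),
                                   config, model, vocab)
    test_mat <- pipeline_features(c(groups$test[[1]], groups$test[[2]]),
                                  config, model, vocab)
    write_features(train_mat, file.path(config$out_dir, feat_files[1]))
    write_features(test_mat, file.path(config$out_dir, feat_files[2]))
    stage_done(config$out_dir, "featurize", feat_fp)
  }

  train_fp <- paste(feat_fp, config_fingerprint(config,
    c("arch", "kernel_size", "epochs", "batch_size")), sep = "|")
  model_file <- "model.json"
  if (stage_fresh(config$out_dir, "train", train_fp, model_file)) {
    say("train: up to date")
    net <- load_model(file.path(config$out_dir, model_file))
  } else {
    say("train (", config$arch, ")")
    spec <- if (config$arch == "dense") dense_net_spec(ncol(train_mat))
            else conv_net_spec(ncol(train_mat),
                               kernel_size = config$kernel_size)
    net <- train_classifier(spec, train_mat, attr(train_mat, "labels"),
                            epochs = config$epochs,
                            batch_size = config$batch_size,
                            seed = config$seed)
    save_model(net, file.path(config$out_dir, model_file))
    stage_done(config$out_dir, "train", train_fp)
  }

  say("evaluate")
  scores <- predict(net, test_mat)
  truth <- attr(test_mat, "labels")
  rr <- roc(scores, truth)
  calls <- ifelse(scores > config$threshold, "delta14", "WT")
  cs <- confusion_from_calls(calls, truth)
  report <- list(
    n_test_groups = length(truth), auc = rr$auc,
    sensitivity_pct = sensitivity_pct(cs),
    specificity_overall_pct = specificity_overall_pct(cs),
    specificity_classical_pct = specificity_classical_pct(cs),
    confusion = unclass(cs), threshold = config$threshold,
    best_epoch = net$best_epoch, val_loss = net$val_loss)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  say(sprintf("done: AUC %.4f, sensitivity %.1f%%, specificity %.1f%%",
              rr$auc, report$sensitivity_pct, report$specificity_overall_pct))
  invisible(list(run_dir = config$out_dir, model = net, report = report))
}
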