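# Classifier/autoencoder training against constructed data; the feature
# stack is exercised elsewhere, so these run on small synthetic matrices.

# two bounded features, as in practice: a discriminative exon-14-style
# coverage frequency and an uninformative one
separable_data <- function(n, seed, flip = FALSE) {
  set.seed(seed)
  y <- rep(c(0, 1), each = n / 2)
  x1 <- ifelse(y == 1, 0, 1) + rnorm(n, sd = 0.05)
  X <- cbind(x1, runif(n))
  if (flip) y <- sample(y)
  list(X = X, y = y)
}

untrained_model <- function(spec, seed = 1L) {
  set.seed(seed)
  structure(list(spec = spec, params = skipnet:::init_params(spec),
                 task = "classify", feature_schema_hash = "unspecified"),
            class = "skipnet_model")
}

test_that("dense parameter count matches the layer-sum formula", {
  spec <- dense_net_spec(40L)
  dims <- c(40L, 256L, 256L, 128L, 128L, 1L)
  expected <- sum(dims[-length(dims)] * dims[-1] + dims[-1])
  expect_equal(n_params(spec), expected)
})

test_that("training is deterministic for a fixed seed", {
  d <- separable_data(80L, 7L)
  m1 <- train_classifier(dense_net_spec(2L), d$X, d$y, epochs = 5L, seed = 3L)
  m2 <- train_classifier(dense_net_spec(2L), d$X, d$y, epochs = 5L, seed = 3L)
  expect_equal(tail(m1$history$train_loss, 1), tail(m2$history$train_loss, 1),
               tolerance = 1e-6)
  expect_identical(m1$params, m2$params)
})

test_that("a linearly separable toy is learned within 20 epochs", {
  d <- separable_data(200L, 11L)
  m <- train_classifier(dense_net_spec(2L), d$X, d$y, epochs = 20L, seed = 5L)
  hold <- separable_data(200L, 99L)
  acc <- mean((predict(m, hold$X) > 0.5) == (hold$y == 1))
  expect_equal(acc, 1.0)
})

test_that("shuffled labels give chance-level accuracy", {
  d <- separable_data(400L, 13L, flip = TRUE)
  m <- train_classifier(dense_net_spec(2L), d$X, d$y, epochs = 15L, seed = 5L)
  hold <- separable_data(500L, 131L, flip = TRUE)
  acc <- mean((predict(m, hold$X) > 0.5) == (hold$y == 1))
  expect_lt(abs(acc - 0.5), 0.1)
})

test_that("single-class labels and NaN-prone input are rejected", {
  X <- matrix(rnorm(40), 10)
  expect_error(train_classifier(dense_net_spec(4L), X, rep(1, 10)),
               "single class")
  expect_error(train_classifier(dense_net_spec(4L), X, rep("delta14", 10)),
               "single class")
  expect_error(train_classifier(dense_net_spec(4L), X,
                                c("WT", "weird", rep("delta14", 8))),
               "labels")
})

test_that("an untrained zero-bias model scores 0.5 and ties go to WT", {
  m <- untrained_model(dense_net_spec(6L))
  sc <- predict(m, rep(0, 6))
  expect_equal(sc, 0.5)
  expect_equal(classify(m, rep(0, 6)), "WT")  # strict > threshold
})

test_that("dimension and schema mismatches are errors at predict time", {
  d <- separable_data(60L, 17L)
  X <- d$X
  attr(X, "schema") <- list(fingerprint = "schemaA")
  m <- train_classifier(dense_net_spec(2L), X, d$y, epochs = 3L, seed = 1L)
  expect_error(predict(m, rep(0, 7)), "dimension")
  bad <- d$X
  attr(bad, "schema") <- list(fingerprint = "schemaB")
  expect_error(predict(m, bad), "schema mismatch")
  expect_equal(length(predict(m, d$X)), 60L)  # unspecified schema passes
})

bump_data <- function(n, seed, dim = 30L) {
  set.seed(seed)
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * dim, sd = 0.1), n)
  X[y == 1, 12:15] <- X[y == 1, 12:15] + 1
  list(X = X, y = y)
}

test_that("models round-trip through the JSON archive", {
  d <- bump_data(80L, 23L)
  m <- train_classifier(conv_net_spec(30L, kernel_size = 5L), d$X, d$y,
                        epochs = 4L, seed = 9L)
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(predict(m2, d$X), predict(m, d$X), tolerance = 1e-12)
  expect_equal(m2$feature_schema_hash, m$feature_schema_hash)
  expect_error(load_model(extdata("toy_gene.gff3")), "not a skipnet model")
})

test_that("convolutional spec validates kernel size and learns", {
  expect_error(conv_net_spec(10L, kernel_size = 11L))
  expect_error(conv_net_spec(10L, kernel_size = 10L), "pooling window")
  # class difference is a local bump, the kind a small kernel detects
  d <- bump_data(120L, 31L)
  m <- train_classifier(conv_net_spec(30L, kernel_size = 5L), d$X, d$y,
                        epochs = 30L, seed = 2L)
  h <- bump_data(120L, 32L)
  expect_gte(roc(predict(m, h$X), h$y)$auc, 0.99)
})

test_that("training loss does not regress with more epochs on average", {
  losses <- vapply(1:5, function(s) {
    d <- separable_data(100L, 200L + s)
    m <- train_classifier(dense_net_spec(2L), d$X, d$y, epochs = 8L,
                          val_fraction = 0, patience = 100L, seed = s)
    c(first = m$history$train_loss[1], last = tail(m$history$train_loss, 1))
  }, c(first = 0, last = 0))
  expect_lt(mean(losses["last", ]), mean(losses["first", ]))
})

test_that("grid search is exhaustive, ranked and reproducible", {
  d <- separable_data(80L, 41L)
  g1 <- grid_search(dense_net_spec, list(dropout = 0.1), d$X, d$y,
                    seed = 1L, epochs = 3L)
  expect_equal(nrow(g1), 1L)
  expect_equal(g1$rank, 1L)
  d <- bump_data(80L, 42L)
  g2 <- grid_search(conv_net_spec, list(kernel_size = c(5L, 5L, 7L)),
                    d$X, d$y, seed = 1L, epochs = 3L)
  expect_equal(nrow(g2), 3L)
  # identical configurations under the shared seed score identically
  dup <- g2[g2$kernel_size == 5L, ]
  expect_equal(dup$val_loss[1], dup$val_loss[2], tolerance = 1e-12)
  expect_equal(g2$rank, seq_len(3L))
  expect_s3_class(attr(g2, "best_model"), "skipnet_model")
  expect_error(grid_search(dense_net_spec, list(), d$X, d$y), "empty")
})

test_that("connectivity masks attribute features to their exons", {
  m <- met_model()
  scope <- 13:15
  cov_schema <- skipnet:::coverage_schema(m, scope)
  mask <- build_connectivity_mask(cov_schema, m)
  widths <- m$exons$width[match(scope, m$exons$ordinal)]
  expect_equal(unname(colSums(mask)), as.numeric(widths))
  # an exon-14 coverage position connects to latent node 14 only
  i14 <- which(cov_schema$exon_of == 14)[1]
  expect_equal(unname(mask[i14, ]), c(0, 1, 0))
  expect_true(all(rowSums(mask) >= 1))

  v <- build_vocabulary(m, k = 16L, scope = scope)
  km_schema <- skipnet:::kmer_schema(v)
  kmask <- build_connectivity_mask(km_schema, m)
  # junction k-mers connect to both flanking exons 13 and 15
  jrows <- (v$n_canonical + 1L):length(v$kmers)
  expect_true(all(kmask[jrows, "13"] == 1 & kmask[jrows, "15"] == 1 &
                    kmask[jrows, "14"] == 0))
  # a canonical k-mer straddling the exon13/14 boundary hits both
  w13 <- m$exons$width[m$exons$ordinal == 13]
  straddle <- w13 - 8L  # window covering positions w13-7 .. w13+8
  expect_equal(unname(kmask[straddle, ]), c(1, 1, 0))
  expect_true(all(rowSums(kmask) >= 1))
})

test_that("SCA enforces exact sparsity and reconstructs duplicates alike", {
  m <- met_model()
  scope <- 13:15
  schema <- skipnet:::coverage_schema(m, scope)
  mask <- build_connectivity_mask(schema, m)
  set.seed(5)
  X <- matrix(abs(rnorm(40 * nrow(mask))), 40)
  X[21:40, ] <- X[1:20, ]           # duplicated samples
  Xn <- normalize_latent_input(X)
  spec <- sca_spec(nrow(mask), mask)
  sca <- train_sca(spec, Xn, epochs = 10L, seed = 3L)
  expect_true(all(sca$params$We[mask == 0] == 0))
  expect_true(all(sca$params$Wd[t(mask) == 0] == 0))
  # non-zero encoder weights live only on mask ones (and nearly all of them)
  expect_lte(sum(sca$params$We != 0), sum(mask))
  expect_gt(sum(sca$params$We != 0), 0.9 * sum(mask))
  lat <- encode(sca, Xn)
  expect_equal(dim(lat), c(40L, 3L))
  expect_equal(lat[1:20, ], lat[21:40, ], ignore_attr = TRUE)
  # reconstruction improves over training on average
  expect_lt(tail(sca$history$train_loss, 1), sca$history$train_loss[1])
})
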