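# Network engine: forward/backward passes and the Adam optimizer, written
# against plain R matrices. Model sizes here are small (1e5-1e6 parameters)
# and BLAS matrix products carry the cost, so no compiled code is needed.
# All randomness (initialization, dropout, shuffling) flows from a single
# set.seed() in the training entry points, making runs exactly reproducible.

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Optimizer configuration (Adam)
#'
#' Defaults follow the training setup used throughout: Adam with lr 0.01,
#' beta1 0.9, beta2 0.999, epsilon 1e-8, no decay, mean-squared-error loss
#' (also for the binary classifiers; cross-entropy is available as an
#' option).
#'
#' @param algorithm only `"adam"` is implemented.
#' @param lr learning rate.
#' @param beta1,beta2,epsilon Adam moment parameters.
#' @param decay per-step learning-rate decay `lr / (1 + decay * t)`.
#' @param loss `"mean_squared_error"` or `"binary_crossentropy"`.
#' @export
optimizer_config <- function(algorithm = "adam", lr = 0.01, beta1 = 0.9,
                             beta2 = 0.999, epsilon = 1e-8, decay = 0,
                             loss = "mean_squared_error") {
  stopifnot(algorithm == "adam",
            loss %in% c("mean_squared_error", "binary_crossentropy"))
  structure(list(algorithm = algorithm, lr = lr, beta1 = beta1,
                 beta2 = beta2, epsilon = epsilon, decay = decay,
                 loss = loss), class = "optimizer_config")
}

adam_init <- function(params, cfg) {
  zero <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  list(cfg = cfg, t = 0L, m = zero, v = zero)
}

adam_step <- function(state, params, grads) {
  cfg <- state$cfg
  state$t <- state$t + 1L
  lr_t <- cfg$lr / (1 + cfg$decay * state$t)
  c1 <- 1 - cfg$beta1^state$t
  c2 <- 1 - cfg$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * g
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr_t * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + cfg$epsilon)
  }
  list(state = state, params = params)
}

# --- architecture specs ----------------------------------------------------

#' Dense classifier architecture
#'
#' Six layers in total: input, four fully connected hidden layers of
#' 256/256/128/128 ReLU units with dropout 0.1 after each activation, and a
#' single sigmoid output unit scoring a read group as exon-skipped.
#'
#' @param input_dim feature-vector length.
#' @param hidden hidden layer widths.
#' @param dropout dropout rate applied after each hidden activation.
#' @export
dense_net_spec <- function(input_dim, hidden = c(256L, 256L, 128L, 128L),
                           dropout = 0.1) {
  stopifnot(input_dim >= 1L, length(hidden) >= 1L, dropout >= 0, dropout < 1)
  structure(list(arch = "dense", input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden), dropout = dropout),
            class = c("dense_net_spec", "net_spec"))
}

#' 1-D convolutional classifier architecture
#'
#' One 1-D convolution (64 filters, kernel size a tunable among
#' 2/5/7/10/15/50/75/100/150/200), ReLU, max-pooling of size 2, one dense
#' ReLU layer of 50 units and a sigmoid output unit.
#'
#' @param input_dim feature-vector length.
#' @param filters number of convolution filters.
#' @param kernel_size convolution kernel size (<= `input_dim`).
#' @param pool max-pooling window (and stride).
#' @param dense_units width of the fully connected layer.
#' @export
conv_net_spec <- function(input_dim, filters = 64L, kernel_size = 100L,
                          pool = 2L, dense_units = 50L) {
  stopifnot(kernel_size <= input_dim, kernel_size >= 1L, filters >= 1L)
  if (input_dim - kernel_size + 1L < pool)
    stopf("conv output (%d) shorter than the pooling window (%d)",
          input_dim - kernel_size + 1L, pool)
  structure(list(arch = "conv", input_dim = as.integer(input_dim),
                 filters = as.integer(filters),
                 kernel_size = as.integer(kernel_size),
                 pool = as.integer(pool),
                 dense_units = as.integer(dense_units)),
            class = c("conv_net_spec", "net_spec"))
}

#' Sparsely connected autoencoder architecture
#'
#' The encoder maps input features to one latent node per exon, with
#' connections restricted by a binary mask: a feature feeds only the latent
#' node(s) of the exon(s) it belongs to. The decoder mirrors the encoder
#' (transposed mask, linear output); loss is mean squared reconstruction
#' error. The mask is re-applied after every optimizer step, so masked
#' weights are exactly zero at all times.
#'
#' @param input_dim feature-vector length.
#' @param mask binary `input_dim x latent_dim` connectivity matrix, e.g.
#'   from [build_connectivity_mask()].
#' @export
sca_spec <- function(input_dim, mask) {
  stopifnot(nrow(mask) == input_dim, all(mask %in% c(0, 1)))
  if (any(rowSums(mask) == 0))
    stopf("mask leaves %d input feature(s) unconnected", sum(rowSums(mask) == 0))
  structure(list(arch = "sca", input_dim = as.integer(input_dim),
                 latent_dim = ncol(mask), mask = unname(as.matrix(mask))),
            class = c("sca_spec", "net_spec"))
}

# --- initialization --------------------------------------------------------

he_init <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

init_params <- function(spec) {
  if (spec$arch == "dense") {
    dims <- c(spec$input_dim, spec$hidden, 1L)
    params <- list()
    for (l in seq_len(length(dims) - 1L)) {
      params[[paste0("W", l)]] <- he_init(dims[l], dims[l + 1L])
      params[[paste0("b", l)]] <- numeric(dims[l + 1L])
    }
    return(params)
  }
  if (spec$arch == "conv") {
    P <- spec$input_dim - spec$kernel_size + 1L
    Pp <- P %/% spec$pool
    list(Wc = he_init(spec$kernel_size, spec$filters),
         bc = numeric(spec$filters),
         W1 = he_init(Pp * spec$filters, spec$dense_units),
         b1 = numeric(spec$dense_units),
         W2 = he_init(spec$dense_units, 1L),
         b2 = numeric(1L))
  } else if (spec$arch == "sca") {
    list(We = he_init(spec$input_dim, spec$latent_dim) * spec$mask,
         be = numeric(spec$latent_dim),
         Wd = he_init(spec$latent_dim, spec$input_dim) * t(spec$mask),
         bd = numeric(spec$input_dim))
  } else stopf("unknown architecture '%s'", spec$arch)
}

add_bias <- function(Z, b) sweep(Z, 2L, b, "+")

# --- forward / backward ----------------------------------------------------

forward_net <- function(spec, params, X, training = FALSE) {
  if (spec$arch == "dense") {
    cache <- list(H = list(X), Z = list(), D = list())
    H <- X
    L <- length(spec$hidden)
    for (l in seq_len(L)) {
      Z <- add_bias(H %*% params[[paste0("W", l)]], params[[paste0("b", l)]])
      A <- relu(Z)
      D <- NULL
      if (training && spec$dropout > 0) {
        D <- (matrix(runif(length(A)), nrow(A)) >= spec$dropout) /
          (1 - spec$dropout)
        A <- A * D
      }
      cache$Z[[l]] <- Z; cache$D[[l]] <- D; cache$H[[l + 1L]] <- A
      H <- A
    }
    zout <- add_bias(H %*% params[[paste0("W", L + 1L)]],
                     params[[paste0("b", L + 1L)]])
    list(pred = sigmoid(zout), cache = cache)
  } else if (spec$arch == "conv") {
    n <- nrow(X); K <- spec$kernel_size; Fl <- spec$filters
    P <- spec$input_dim - K + 1L
    Pp <- P %/% spec$pool
    idx <- as.vector(outer(seq_len(P), 0:(K - 1L), "+"))
    Xmat <- matrix(X[, idx, drop = FALSE], n * P, K)  # row (i,p)
    Zc <- add_bias(Xmat %*% params$Wc, params$bc)     # (nP) x F
    Ac <- relu(Zc)
    Aarr <- array(Ac, c(n, P, Fl))
    odd <- seq(1L, 2L * Pp, by = 2L)
    A1 <- Aarr[, odd, , drop = FALSE]
    A2 <- Aarr[, odd + 1L, , drop = FALSE]
    take1 <- A1 >= A2
    M <- pmax(A1, A2)                                 # n x Pp x F
    flat <- matrix(M, n, Pp * Fl)
    Z1 <- add_bias(flat %*% params$W1, params$b1)
    A1d <- relu(Z1)
    zout <- add_bias(A1d %*% params$W2, params$b2)
    list(pred = sigmoid(zout),
         cache = list(Xmat = Xmat, Zc = Zc, take1 = take1, flat = flat,
                      Z1 = Z1, A1d = A1d, n = n, P = P, Pp = Pp, odd = odd))
  } else { # sca
    Ze <- add_bias(X %*% params$We, params$be)
    H <- relu(Ze)
    Xhat <- add_bias(H %*% params$Wd, params$bd)
    list(pred = Xhat, cache = list(X = X, Ze = Ze, H = H))
  }
}

# dout: gradient of the loss w.r.t. the pre-sigmoid output (classifiers) or
# the reconstruction (autoencoder)
backward_net <- function(spec, params, cache, dout) {
  if (spec$arch == "dense") {
    L <- length(spec$hidden)
    grads <- list()
    dH <- dout
    grads[[paste0("W", L + 1L)]] <- crossprod(cache$H[[L + 1L]], dH)
    grads[[paste0("b", L + 1L)]] <- colSums(dH)
    dH <- dH %*% t(params[[paste0("W", L + 1L)]])
    for (l in rev(seq_len(L))) {
      if (!is.null(cache$D[[l]])) dH <- dH * cache$D[[l]]
      dZ <- dH * (cache$Z[[l]] > 0)
      grads[[paste0("W", l)]] <- crossprod(cache$H[[l]], dZ)
      grads[[paste0("b", l)]] <- colSums(dZ)
      if (l > 1L) dH <- dZ %*% t(params[[paste0("W", l)]])
    }
    grads
  } else if (spec$arch == "conv") {
    n <- cache$n; P <- cache$P; Pp <- cache$Pp; Fl <- spec$filters
    dZ1d <- dout
    gW2 <- crossprod(cache$A1d, dZ1d); gb2 <- colSums(dZ1d)
    dA1d <- dZ1d %*% t(params$W2)
    dZ1 <- dA1d * (cache$Z1 > 0)
    gW1 <- crossprod(cache$flat, dZ1); gb1 <- colSums(dZ1)
    dflat <- dZ1 %*% t(params$W1)
    dM <- array(dflat, c(n, Pp, Fl))
    dA <- array(0, c(n, P, Fl))
    dA[, cache$odd, ] <- dM * cache$take1
    dA[, cache$odd + 1L, ] <- dM * (!cache$take1)
    dZc <- matrix(dA, n * P, Fl) * (cache$Zc > 0)
    gWc <- crossprod(cache$Xmat, dZc); gbc <- colSums(dZc)
    list(Wc = gWc, bc = gbc, W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
  } else { # sca
    dXhat <- dout
    gWd <- crossprod(cache$H, dXhat) * t(spec$mask)
    gbd <- colSums(dXhat)
    dH <- dXhat %*% t(params$Wd)
    dZe <- dH * (cache$Ze > 0)
    gWe <- crossprod(cache$X, dZe) * spec$mask
    gbe <- colSums(dZe)
    list(We = gWe, be = gbe, Wd = gWd, bd = gbd)
  }
}

# loss value and gradient at the pre-sigmoid output (classifier) or the
# reconstruction (autoencoder)
net_loss <- function(spec, pred, target, loss) {
  n <- length(pred)
  if (spec$arch == "sca") {
    d <- pred - target
    return(list(loss = mean(d * d), dout = 2 * d / length(d)))
  }
  p <- pred
  if (loss == "mean_squared_error") {
    dp <- 2 * (p - target) / n
    list(loss = mean((p - target)^2), dout = dp * p * (1 - p))
  } else {
    eps <- 1e-12
    list(loss = -mean(target * log(p + eps) + (1 - target) * log(1 - p + eps)),
         dout = (p - target) / n)
  }
}

#' Total parameter count of a network spec or trained model
#' @param x a `net_spec` or `skipnet_model`.
#' @export
n_params <- function(x) {
  params <- if (inherits(x, "skipnet_model")) x$params else init_params(x)
  sum(vapply(params, length, 0L))
}
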