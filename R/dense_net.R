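# Activation functions for the dense network. Softmax is supported as a
# hidden activation (vector softmax over the layer's units).
.ACTIVATIONS <- c("relu", "leaky_relu", "softmax", "gelu")

act_forward <- function(z, name, alpha) {
  switch(name,
    relu = pmax(z, 0),
    leaky_relu = ifelse(z > 0, z, alpha * z),
    gelu = z * stats::pnorm(z),
    softmax = {
      e <- exp(z - apply(z, 1, max))
      e / rowSums(e)
    },
    stop("unknown activation: ", name))
}

# Backward pass: returns dL/dz given dL/da and the cached (z, a).
act_backward <- function(da, z, a, name, alpha) {
  switch(name,
    relu = da * (z > 0),
    leaky_relu = da * ifelse(z > 0, 1, alpha),
    gelu = da * (stats::pnorm(z) + z * stats::dnorm(z)),
    softmax = a * (da - rowSums(da * a)),
    stop("unknown activation: ", name))
}

#' Dense network specification
#'
#' A small fully-connected binary classifier: two hidden dense layers
#' (widths 64 and 32 by default) with a selectable activation, a 1-unit
#' sigmoid output, binary cross-entropy loss and adaptive-moment (Adam)
#' updates. Defaults: batch size 32, 45 epochs.
#'
#' @param widths hidden/output layer widths (last must be 1).
#' @param activation hidden activation: `"relu"`, `"leaky_relu"`
#'   (`alpha = 0.01`), `"softmax"` or `"gelu"`.
#' @param alpha negative slope for `leaky_relu`.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param seed RNG seed for weight initialization and batch shuffling.
#' @return a `dense_net_spec`.
#' @export
dense_net_spec <- function(widths = c(64, 32, 1), activation = "leaky_relu",
                           alpha = 0.01, epochs = 45, batch_size = 32,
                           learning_rate = 0.001, seed = 1) {
  activation <- match.arg(activation, .ACTIVATIONS)
  if (any(widths <= 0)) stop("layer widths must be positive")
  if (utils::tail(widths, 1) != 1) stop("output layer width must be 1")
  structure(list(widths = widths, activation = activation, alpha = alpha,
                 epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, seed = seed),
            class = "dense_net_spec")
}

#' Train the dense network
#'
#' Glorot-uniform seeded initialization, shuffled minibatches, Adam
#' updates, binary cross-entropy loss, sigmoid output. Training is
#' single-threaded and deterministic for a fixed spec seed.
#'
#' @param X numeric matrix (samples x features); callers are expected to
#'   standardize features beforehand (see [cross_validated_extraction()]).
#' @param labels binary vector (0/1, logical, or 2-level factor).
#' @param spec a [dense_net_spec()].
#' @return a `dense_net` with per-layer `weights`/`biases`, the
#'   activation, and a training `history` (loss and accuracy per epoch).
#' @export
train_dense_net <- function(X, labels, spec = dense_net_spec()) {
  X <- as_count_matrix(X)
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stop("train_dense_net: labels are constant")
  if (any(!is.finite(X))) stop("train_dense_net: non-finite inputs")
  n <- nrow(X)
  dims <- c(ncol(X), spec$widths)
  L <- length(dims) - 1
  with_seed(spec$seed, {
    W <- lapply(seq_len(L), function(l) {
      lim <- sqrt(6 / (dims[l] + dims[l + 1]))
      matrix(stats::runif(dims[l] * dims[l + 1], -lim, lim), dims[l], dims[l + 1])
    })
    rownames(W[[1]]) <- colnames(X)
    b <- lapply(seq_len(L), function(l) numeric(dims[l + 1]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    lr <- spec$learning_rate; b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    t <- 0
    hist_loss <- numeric(spec$epochs); hist_acc <- numeric(spec$epochs)
    for (epoch in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = spec$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + spec$batch_size - 1, n)]
        a <- X[idx, , drop = FALSE]
        zs <- vector("list", L); as_ <- vector("list", L + 1)
        as_[[1]] <- a
        for (l in seq_len(L)) {
          z <- as_[[l]] %*% W[[l]] + rep(b[[l]], each = nrow(a))
          zs[[l]] <- z
          as_[[l + 1]] <- if (l < L) act_forward(z, spec$activation, spec$alpha)
                          else 1 / (1 + exp(-z))
        }
        p <- as_[[L + 1]]
        dz <- (p - y[idx]) / length(idx)       # BCE + sigmoid gradient
        t <- t + 1
        for (l in rev(seq_len(L))) {
          gW <- crossprod(as_[[l]], dz)
          gb <- colSums(dz)
          if (l > 1) {
            da <- dz %*% t(W[[l]])
            dz <- act_backward(da, zs[[l - 1]], as_[[l]], spec$activation, spec$alpha)
          }
          mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
          vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
          mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
          vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
          W[[l]] <- W[[l]] - lr * (mW[[l]] / (1 - b1^t)) /
            (sqrt(vW[[l]] / (1 - b2^t)) + eps)
          b[[l]] <- b[[l]] - lr * (mb[[l]] / (1 - b1^t)) /
            (sqrt(vb[[l]] / (1 - b2^t)) + eps)
        }
      }
      pfull <- forward_dense(list(weights = W, biases = b,
                                  activation = spec$activation,
                                  alpha = spec$alpha), X)$prob
      pc <- pmin(pmax(pfull, 1e-12), 1 - 1e-12)
      loss <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
      if (!is.finite(loss)) stop("NaN loss at epoch ", epoch)
      hist_loss[epoch] <- loss
      hist_acc[epoch] <- mean((pfull > 0.5) == (y == 1))
    }
    structure(list(weights = W, biases = b, activation = spec$activation,
                   alpha = spec$alpha, spec = spec,
                   history = data.frame(epoch = seq_len(spec$epochs),
                                        loss = hist_loss, accuracy = hist_acc)),
              class = "dense_net")
  })
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) stop("labels must be binary")
    return(as.numeric(labels == levels(labels)[2]))
  }
  u <- sort(unique(as.numeric(labels)))
  if (!all(u %in% c(0, 1))) stop("labels must be binary (0/1 or a 2-level factor)")
  as.numeric(labels)
}

# Full forward pass caching activations (used by predict and LRP).
forward_dense <- function(net, X) {
  L <- length(net$weights)
  as_ <- vector("list", L + 1); zs <- vector("list", L)
  as_[[1]] <- X
  for (l in seq_len(L)) {
    z <- as_[[l]] %*% net$weights[[l]] + rep(net$biases[[l]], each = nrow(X))
    zs[[l]] <- z
    as_[[l + 1]] <- if (l < L) act_forward(z, net$activation, net$alpha)
                    else 1 / (1 + exp(-z))
  }
  list(activations = as_, preactivations = zs,
       logit = as.numeric(zs[[L]]), prob = as.numeric(as_[[L + 1]]))
}

#' Predict from a trained dense network
#'
#' @param object a `dense_net`.
#' @param newdata feature matrix.
#' @param type `"prob"` (sigmoid output), `"logit"` or `"class"`.
#' @param ... unused.
#' @return numeric vector (or 0/1 for `"class"`).
#' @export
predict.dense_net <- function(object, newdata, type = c("prob", "logit", "class"), ...) {
  type <- match.arg(type)
  fw <- forward_dense(object, as_count_matrix(newdata))
  switch(type, prob = fw$prob, logit = fw$logit,
         class = as.integer(fw$prob > 0.5))
}
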