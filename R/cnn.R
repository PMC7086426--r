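# CNN engine: valid 2-D convolution + batch norm + ReLU + average pooling +
# softmax fully connected layer, trained with SGD (constant learning rate,
# momentum, L2 penalty) on channels-by-samples EEG matrices.
#
# Feature maps are stored column-per-example as length h*w*l vectors with the
# spatial position fastest (column-major h then w) and the filter depth
# slowest. Convolutions are evaluated as im2col gathers followed by one BLAS
# matrix product per layer per mini-batch; the backward scatter reuses the
# gather indices, accumulating per patch offset.

#' Training configuration
#'
#' Defaults are the reference training regime: constant learning rate 1e-4,
#' stochastic gradient descent with momentum 0.9, L2 regularization 5e-4,
#' mini-batch size 128, 30 epochs. The loss is 2-class cross-entropy plus
#' `l2_regularization` times the squared weight norm (convolution and fully
#' connected weights; biases and batch-norm parameters unpenalized).
#'
#' @param learning_rate Positive constant learning rate.
#' @param momentum Momentum coefficient in `[0, 1)`.
#' @param l2_regularization Nonnegative L2 penalty coefficient.
#' @param mini_batch_size Mini-batch size; the final batch of an epoch may
#'   be smaller.
#' @param epochs Number of epochs; each epoch is
#'   `iterations_per_epoch(n, mini_batch_size)` gradient steps.
#' @param seed Integer seed fixing initialization and per-epoch shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, momentum = 0.9,
                         l2_regularization = 5e-4, mini_batch_size = 128,
                         epochs = 30, seed = 1) {
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1,
            l2_regularization >= 0, mini_batch_size >= 1, epochs >= 1)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 l2_regularization = l2_regularization,
                 mini_batch_size = as.integer(mini_batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

#' Gradient steps needed to complete one epoch
#'
#' `ceiling(n_train / batch)`: e.g. 680 training segments at mini-batch size
#' 128 need six iterations per epoch.
#'
#' @param n_train Number of training examples (>= 1).
#' @param batch Mini-batch size (>= 1).
#' @return Integer iteration count.
#' @export
iterations_per_epoch <- function(n_train, batch) {
  stopifnot(n_train >= 1, batch >= 1)
  as.integer(ceiling(n_train / batch))
}

# ---- index helpers ---------------------------------------------------------

conv_indices <- function(h, w, l, f, s, h2, w2) {
  off <- as.vector(outer(outer(0:(f - 1), (0:(f - 1)) * h, "+"),
                         (seq_len(l) - 1L) * h * w, "+"))       # a,b,d order
  st <- as.vector(outer((0:(h2 - 1)) * s, (0:(w2 - 1)) * s * h, "+")) + 1L
  outer(off, st, "+")                                           # K x P
}

pool_indices <- function(h, w, l, f, s, h2, w2) {
  off <- as.vector(outer(0:(f - 1), (0:(f - 1)) * h, "+"))
  st <- as.vector(outer(as.vector(outer((0:(h2 - 1)) * s,
                                        (0:(w2 - 1)) * s * h, "+")),
                        (seq_len(l) - 1L) * h * w, "+")) + 1L
  outer(off, st, "+")                                           # f*f x P2*l
}

scatter_add <- function(dG, idx, n_in, B) {
  # generic col2im fallback: accumulate K x (P*B) patch gradients onto the
  # input volume. For a fixed patch offset k, distinct output positions map
  # to distinct input positions, so each k is a vectorized indexed addition.
  K <- nrow(idx); P <- ncol(idx)
  dX <- matrix(0, n_in, B)
  for (k in seq_len(K)) {
    v <- dG[k, ]
    dim(v) <- c(P, B)
    rows <- idx[k, ]
    dX[rows, ] <- dX[rows, , drop = FALSE] + v
  }
  dX
}

conv_bwd_indices <- function(h, w, h2, w2, lo, f, s) {
  # transposed-convolution gather: for input position (x, y) and patch
  # offset (a, b), the contributing output position is i = (x-a)/s + 1,
  # j = (y-b)/s + 1 when integral and in range; out-of-range entries point
  # at a sentinel zero row appended to the padded output.
  sent_block <- h2 * w2
  xs <- rep(seq_len(h), times = w)
  ys <- rep(seq_len(w), each = h)
  base <- matrix(NA_integer_, f * f, h * w)
  r <- 0L
  for (b in seq_len(f)) for (a in seq_len(f)) {
    # row order must be a fastest, then b
    r <- a + (b - 1L) * f
    iq <- xs - a; jq <- ys - b
    ok <- iq %% s == 0L & jq %% s == 0L
    i0 <- iq %/% s; j0 <- jq %/% s
    ok <- ok & i0 >= 0L & i0 < h2 & j0 >= 0L & j0 < w2
    pos <- ifelse(ok, i0 + j0 * h2 + 1L, NA_integer_)
    base[r, ] <- pos
  }
  sent <- sent_block * lo + 1L
  out <- matrix(sent, f * f * lo, h * w)
  for (dout in seq_len(lo)) {
    rows <- ((dout - 1L) * f * f + 1L):(dout * f * f)
    blk <- base + (dout - 1L) * sent_block
    blk[is.na(blk)] <- sent
    out[rows, ] <- blk
  }
  out
}

wt_map_indices <- function(f, l_in, lo) {
  # linear indices rearranging W (lo x f*f*l_in, patch order a,b,din) into
  # Wt (l_in x f*f*lo, patch order a,b,dout)
  map <- integer(l_in * f * f * lo)
  for (dout in seq_len(lo)) for (b in seq_len(f)) for (a in seq_len(f)) {
    k2 <- a + (b - 1L) * f + (dout - 1L) * f * f
    for (din in seq_len(l_in)) {
      k <- a + (b - 1L) * f + (din - 1L) * f * f
      map[din + l_in * (k2 - 1L)] <- dout + lo * (k - 1L)
    }
  }
  map
}

pool_bwd_index <- function(h, w, l, f, s, h2, w2) {
  # with stride >= window each input position feeds at most one window
  xs <- rep(seq_len(h), times = w)
  ys <- rep(seq_len(w), each = h)
  i0 <- (xs - 1L) %/% s; j0 <- (ys - 1L) %/% s
  ok <- (xs - 1L) %% s < f & (ys - 1L) %% s < f & i0 < h2 & j0 < w2
  pos <- ifelse(ok, i0 + j0 * h2 + 1L, NA_integer_)
  sent <- h2 * w2 * l + 1L
  out <- integer(h * w * l)
  for (d in seq_len(l)) {
    blk <- pos + (d - 1L) * h2 * w2
    blk[is.na(blk)] <- sent
    out[((d - 1L) * h * w + 1L):(d * h * w)] <- blk
  }
  out
}

# ---- network construction --------------------------------------------------

cnn_build <- function(topo) {
  tr <- trace_shapes(topo)
  shape <- topo$input_shape
  layers <- vector("list", length(topo$layers))
  for (i in seq_along(topo$layers)) {
    spec <- topo$layers[[i]]
    out <- c(h = tr$h[i], w = tr$w[i], l = tr$l[i])
    L <- list(kind = spec$kind, spec = spec, in_shape = shape, out_shape = out)
    if (spec$kind == "convolution") {
      K <- spec$f^2 * shape[["l"]]
      P <- out[["h"]] * out[["w"]]
      L$K <- K; L$P <- P
      L$idx <- conv_indices(shape[["h"]], shape[["w"]], shape[["l"]],
                            spec$f, spec$s, out[["h"]], out[["w"]])
      L$W <- matrix(stats::rnorm(spec$n_filters * K, sd = sqrt(2 / K)),
                    spec$n_filters, K)
      L$b <- numeric(spec$n_filters)
      if ("batch_norm" %in% spec$post_ops) {
        L$bn <- list(gamma = rep(1, spec$n_filters),
                     beta = numeric(spec$n_filters),
                     run_mean = numeric(spec$n_filters),
                     run_var = rep(1, spec$n_filters))
      }
      if (i > 1L) {
        L$idx_bwd <- conv_bwd_indices(shape[["h"]], shape[["w"]],
                                      out[["h"]], out[["w"]],
                                      spec$n_filters, spec$f, spec$s)
        L$wt_map <- wt_map_indices(spec$f, shape[["l"]], spec$n_filters)
      }
    } else if (spec$kind == "average_pool") {
      L$K <- spec$f^2
      L$P <- out[["h"]] * out[["w"]] * out[["l"]]
      L$idx <- pool_indices(shape[["h"]], shape[["w"]], shape[["l"]],
                            spec$f, spec$s, out[["h"]], out[["w"]])
      if (spec$s >= spec$f) {
        L$idx_bwd <- pool_bwd_index(shape[["h"]], shape[["w"]], shape[["l"]],
                                    spec$f, spec$s, out[["h"]], out[["w"]])
      }
    } else {
      nflat <- prod(shape)
      L$W <- matrix(stats::rnorm(topo$n_classes * nflat, sd = sqrt(2 / nflat)),
                    topo$n_classes, nflat)
      L$b <- numeric(topo$n_classes)
    }
    layers[[i]] <- L
    shape <- out
  }
  layers
}

BN_EPS <- 1e-5
BN_RUN_MOMENTUM <- 0.1

cnn_forward <- function(layers, X, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    L <- layers[[i]]
    B <- ncol(X)
    if (L$kind == "convolution") {
      K <- L$K; P <- L$P; lo <- L$spec$n_filters
      G <- X[as.vector(L$idx), , drop = FALSE]
      dim(G) <- c(K, P * B)
      Y <- L$W %*% G + L$b
      dim(Y) <- c(lo, P, B)
      Y <- aperm(Y, c(2, 1, 3))
      dim(Y) <- c(P * lo, B)
      cache <- list(X = X, G = G)
      if (!is.null(L$bn)) {
        xhat <- Y
        invstd <- mu <- numeric(lo)
        for (d in seq_len(lo)) {
          rows <- ((d - 1L) * P + 1L):(d * P)
          v <- Y[rows, , drop = FALSE]
          if (training) {
            m <- mean(v); va <- mean((v - m)^2)
            layers[[i]]$bn$run_mean[d] <-
              (1 - BN_RUN_MOMENTUM) * layers[[i]]$bn$run_mean[d] + BN_RUN_MOMENTUM * m
            layers[[i]]$bn$run_var[d] <-
              (1 - BN_RUN_MOMENTUM) * layers[[i]]$bn$run_var[d] + BN_RUN_MOMENTUM * va
          } else {
            m <- L$bn$run_mean[d]; va <- L$bn$run_var[d]
          }
          istd <- 1 / sqrt(va + BN_EPS)
          xhat[rows, ] <- (v - m) * istd
          Y[rows, ] <- L$bn$gamma[d] * xhat[rows, , drop = FALSE] + L$bn$beta[d]
          mu[d] <- m; invstd[d] <- istd
        }
        cache$xhat <- xhat; cache$invstd <- invstd
      }
      if ("relu" %in% L$spec$post_ops) {
        cache$pre_relu_pos <- Y > 0
        Y[!cache$pre_relu_pos] <- 0
      }
      caches[[i]] <- cache
      X <- Y
    } else if (L$kind == "average_pool") {
      G <- X[as.vector(L$idx), , drop = FALSE]
      dim(G) <- c(L$K, L$P * B)
      Y <- .colMeans(G, L$K, L$P * B)
      dim(Y) <- c(L$P, B)
      caches[[i]] <- list(X = X)
      X <- Y
    } else {
      Z <- L$W %*% X + L$b
      Z <- sweep(Z, 2, apply(Z, 2, max))
      E <- exp(Z)
      probs <- sweep(E, 2, colSums(E), "/")
      caches[[i]] <- list(X = X)
      X <- probs
    }
  }
  list(out = X, caches = caches, layers = layers)
}

cnn_backward <- function(layers, caches, probs, y_onehot, l2) {
  B <- ncol(probs)
  grads <- vector("list", length(layers))
  dY <- NULL
  for (i in rev(seq_along(layers))) {
    L <- layers[[i]]
    cache <- caches[[i]]
    if (L$kind == "fully_connected") {
      dZ <- (probs - y_onehot) / B
      grads[[i]] <- list(W = dZ %*% t(cache$X) + 2 * l2 * L$W,
                         b = rowSums(dZ))
      dY <- crossprod(L$W, dZ)
    } else if (L$kind == "average_pool") {
      dYv <- dY / L$K
      if (!is.null(L$idx_bwd)) {
        dYpad <- rbind(dYv, 0)
        dY <- dYpad[L$idx_bwd, , drop = FALSE]
      } else {
        dY <- scatter_add(dYv[rep(seq_len(L$P), each = L$K), , drop = FALSE],
                          L$idx, prod(L$in_shape), ncol(dYv))
      }
    } else {
      P <- L$P; lo <- L$spec$n_filters
      if ("relu" %in% L$spec$post_ops) dY <- dY * cache$pre_relu_pos
      if (!is.null(L$bn)) {
        dgamma <- dbeta <- numeric(lo)
        for (d in seq_len(lo)) {
          rows <- ((d - 1L) * P + 1L):(d * P)
          dv <- dY[rows, , drop = FALSE]
          xh <- cache$xhat[rows, , drop = FALSE]
          dgamma[d] <- sum(dv * xh)
          dbeta[d] <- sum(dv)
          n <- length(dv)
          dY[rows, ] <- (L$bn$gamma[d] * cache$invstd[d]) *
            (dv - sum(dv) / n - xh * (sum(dv * xh) / n))
        }
      }
      dYm <- dY
      dim(dYm) <- c(P, lo, B)
      dYm <- aperm(dYm, c(2, 1, 3))
      dim(dYm) <- c(lo, P * B)
      gW <- tcrossprod(dYm, cache$G) + 2 * l2 * L$W
      gb <- rowSums(dYm)
      g <- list(W = gW, b = gb)
      if (!is.null(L$bn)) { g$gamma <- dgamma; g$beta <- dbeta }
      grads[[i]] <- g
      if (i > 1L) {
        l_in <- L$in_shape[["l"]]
        K2 <- L$spec$f^2 * lo
        Wt <- matrix(L$W[L$wt_map], l_in, K2)
        dYpad <- rbind(dY, 0)
        Gt <- dYpad[as.vector(L$idx_bwd), , drop = FALSE]
        dim(Gt) <- c(K2, ncol(L$idx_bwd) * B)
        Z <- Wt %*% Gt
        dim(Z) <- c(l_in, ncol(L$idx_bwd), B)
        Z <- aperm(Z, c(2, 1, 3))
        dim(Z) <- c(ncol(L$idx_bwd) * l_in, B)
        dY <- Z
      }
    }
  }
  grads
}

param_names <- function(L) {
  nm <- character(0)
  if (!is.null(L$W)) nm <- c(nm, "W", "b")
  if (!is.null(L$bn)) nm <- c(nm, "gamma", "beta")
  nm
}

# ---- training --------------------------------------------------------------

segments_to_matrix <- function(segments) {
  stopifnot(length(segments) >= 1)
  dims <- dim(segments[[1]]$matrix)
  X <- vapply(segments, function(s) {
    if (!identical(dim(s$matrix), dims)) {
      stop("shape error: segment matrices differ in size", call. = FALSE)
    }
    as.vector(s$matrix)
  }, numeric(prod(dims)))
  list(X = X, h = dims[1], w = dims[2])
}

#' Train the CNN on labeled EEG segments
#'
#' Mini-batch stochastic gradient descent with momentum, constant learning
#' rate and an L2 squared-weight penalty, on 2-class cross-entropy over the
#' softmax output. Each convolution is followed by batch normalization and
#' ReLU as its layer spec dictates. Training is deterministic given the
#' segment order and `config$seed`, which drives both weight initialization
#' and the once-per-epoch shuffle.
#'
#' @param topo A `cnn_topology` whose input shape matches the segment
#'   matrices.
#' @param segments List of `eeg_segment` objects with class labels
#'   `"healthy"`/`"tbi"`; both classes must be present.
#' @param config A [train_config()].
#' @return An object of class `tbi_cnn`: the topology, learned parameters,
#'   config and a per-epoch training log (`epoch`, `loss`,
#'   `train_accuracy`).
#' @export
train_cnn <- function(topo, segments, config = train_config()) {
  stopifnot(inherits(topo, "cnn_topology"), inherits(config, "train_config"))
  y <- vapply(segments, function(s) s$class_label, "")
  if (!all(y %in% c("healthy", "tbi"))) {
    stop("training error: segments must be labeled healthy/tbi", call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("training error: both classes must be present", call. = FALSE)
  }
  dat <- segments_to_matrix(segments)
  if (dat$h != topo$input_shape[["h"]] || dat$w != topo$input_shape[["w"]]) {
    stop(sprintf("shape error: segments are %d x %d but topology expects %d x %d",
                 dat$h, dat$w, topo$input_shape[["h"]], topo$input_shape[["w"]]),
         call. = FALSE)
  }
  classes <- c("healthy", "tbi")
  y_idx <- match(y, classes)
  n <- length(segments)

  set.seed(config$seed)
  layers <- cnn_build(topo)
  vel <- lapply(layers, function(L) {
    v <- list()
    for (nm in param_names(L)) {
      src <- if (nm %in% c("gamma", "beta")) L$bn[[nm]] else L[[nm]]
      v[[nm]] <- src * 0
    }
    v
  })

  n_iter <- iterations_per_epoch(n, config$mini_batch_size)
  log_rows <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0L
    for (it in seq_len(n_iter)) {
      sel <- ord[(((it - 1L) * config$mini_batch_size + 1L):
                    min(it * config$mini_batch_size, n))]
      Xb <- dat$X[, sel, drop = FALSE]
      yb <- y_idx[sel]
      fw <- cnn_forward(layers, Xb, training = TRUE)
      layers <- fw$layers              # running BN stats updated
      probs <- fw$out
      onehot <- matrix(0, topo$n_classes, length(sel))
      onehot[cbind(yb, seq_along(sel))] <- 1
      wpen <- sum(vapply(layers, function(L)
        if (!is.null(L$W)) sum(L$W^2) else 0, 0))
      loss <- -mean(log(pmax(probs[cbind(yb, seq_along(sel))], 1e-12))) +
        config$l2_regularization * wpen
      ep_loss <- ep_loss + loss * length(sel)
      ep_correct <- ep_correct +
        sum(max.col(t(probs), ties.method = "first") == yb)
      grads <- cnn_backward(layers, fw$caches, probs, onehot,
                            config$l2_regularization)
      for (li in seq_along(layers)) {
        for (nm in param_names(layers[[li]])) {
          v <- config$momentum * vel[[li]][[nm]] -
            config$learning_rate * grads[[li]][[nm]]
          vel[[li]][[nm]] <- v
          if (nm %in% c("gamma", "beta")) {
            layers[[li]]$bn[[nm]] <- layers[[li]]$bn[[nm]] + v
          } else {
            layers[[li]][[nm]] <- layers[[li]][[nm]] + v
          }
        }
      }
    }
    log_rows[[epoch]] <- data.frame(epoch = epoch, loss = ep_loss / n,
                                    train_accuracy = 100 * ep_correct / n)
  }
  structure(
    list(topology = topo, layers = layers, classes = classes,
         config = config, training_log = do.call(rbind, log_rows)),
    class = "tbi_cnn")
}

#' @export
#' @method print tbi_cnn
print.tbi_cnn <- function(x, ...) {
  last <- x$training_log[nrow(x$training_log), ]
  cat(sprintf(
    "Trained CNN (%d layers, %d parameters): %d epochs, final loss %.4f, training accuracy %.1f%%\n",
    length(x$layers), n_parameters(x$topology), last$epoch, last$loss,
    last$train_accuracy))
  invisible(x)
}

#' @export
plot.tbi_cnn <- function(x, ...) {
  log <- x$training_log
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  graphics::plot(log$epoch, log$loss, type = "l", xlab = "epoch",
                 ylab = "loss", main = "training loss", ...)
  graphics::plot(log$epoch, log$train_accuracy, type = "l", xlab = "epoch",
                 ylab = "accuracy (%)", main = "training accuracy", ...)
  invisible(x)
}

#' Classify EEG segments with a trained CNN
#'
#' Runs the network in inference mode (batch-norm running statistics) and
#' returns per-segment softmax probabilities and the argmax label.
#'
#' @param object A `tbi_cnn` from [train_cnn()].
#' @param segments List of `eeg_segment` objects matching the model input
#'   shape.
#' @param batch Internal batch size for the forward pass.
#' @param ... Unused.
#' @return A data.frame with columns `subject_id`, `p_healthy`, `p_tbi`,
#'   `label`.
#' @export
predict.tbi_cnn <- function(object, segments, batch = 256, ...) {
  dat <- segments_to_matrix(segments)
  topo <- object$topology
  if (dat$h != topo$input_shape[["h"]] || dat$w != topo$input_shape[["w"]]) {
    stop(sprintf("shape error: segments are %d x %d but model expects %d x %d",
                 dat$h, dat$w, topo$input_shape[["h"]], topo$input_shape[["w"]]),
         call. = FALSE)
  }
  n <- ncol(dat$X)
  probs <- matrix(0, topo$n_classes, n)
  for (start in seq(1L, n, by = batch)) {
    sel <- start:min(start + batch - 1L, n)
    probs[, sel] <- cnn_forward(object$layers, dat$X[, sel, drop = FALSE],
                                training = FALSE)$out
  }
  lab <- object$classes[max.col(t(probs), ties.method = "first")]
  data.frame(subject_id = vapply(segments, function(s) s$subject_id, ""),
             p_healthy = probs[1, ], p_tbi = probs[2, ],
             label = lab, stringsAsFactors = FALSE)
}
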