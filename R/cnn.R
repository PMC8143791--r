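# ---- Spatio-temporal CNN for locus-of-attention decoding ------------------
#
# Architecture: a single convolutional layer of five independent
# channels x 17 spatio-temporal filters (17 taps = 130 ms at 128 Hz), ReLU,
# average pooling over time, a 5 -> 5 fully connected layer with sigmoid
# activation, and a 5 -> 2 output layer feeding a softmax cross-entropy
# loss.  About 5500 parameters in total.  Training is plain mini-batch SGD
# with momentum, step learning-rate decay and weight decay; the forward and
# backward passes are written directly as (BLAS) matrix products, which is
# entirely adequate at this scale.

#' Construct the locus-of-attention CNN
#'
#' Weights and biases are drawn from Normal(0, 0.5^2) under `seed`.
#'
#' @param T_len decision window length in samples.
#' @param seed integer seed for the initialization.
#' @param padding `"same"` (zero-padding; the convolution output is 1 x T per
#'   filter) or `"valid"` (unpadded; output length T - 16, requires
#'   T >= 17).
#' @param n_channels,n_filters,filter_width architecture dimensions; the
#'   defaults (64, 5, 17) are the published architecture and are the ones
#'   the rest of the package assumes.
#' @param init_sd standard deviation of the random initialization.
#' @return object of class `"cnn_model"`.
#' @export
build_cnn <- function(T_len, seed = 1, padding = c("same", "valid"),
                      n_channels = 64, n_filters = 5, filter_width = 17,
                      init_sd = 0.5) {
  padding <- match.arg(padding)
  if (padding == "valid" && T_len < filter_width) {
    stop("T must be >= ", filter_width, " for valid padding")
  }
  if (T_len < 1) stop("T must be >= 1")
  .with_seed(seed, {
    structure(list(
      conv_w = array(stats::rnorm(n_filters * n_channels * filter_width,
                                  0, init_sd),
                     dim = c(n_filters, n_channels, filter_width)),
      conv_b = stats::rnorm(n_filters, 0, init_sd),
      fc1_w = matrix(stats::rnorm(n_filters * n_filters, 0, init_sd),
                     n_filters, n_filters),
      fc1_b = stats::rnorm(n_filters, 0, init_sd),
      fc2_w = matrix(stats::rnorm(2 * n_filters, 0, init_sd), 2, n_filters),
      fc2_b = stats::rnorm(2, 0, init_sd),
      padding = padding, T_len = as.integer(T_len),
      n_channels = as.integer(n_channels),
      n_filters = as.integer(n_filters),
      filter_width = as.integer(filter_width)
    ), class = "cnn_model")
  })
}

#' Number of trainable parameters of a CNN model
#'
#' @param model a `cnn_model`.
#' @return integer parameter count (5487 for the standard architecture).
#' @export
cnn_parameter_count <- function(model) {
  length(model$conv_w) + length(model$conv_b) +
    length(model$fc1_w) + length(model$fc1_b) +
    length(model$fc2_w) + length(model$fc2_b)
}

# flatten conv weights to a (n_filters) x (n_channels * width) matrix
.conv_w_mat <- function(model) {
  matrix(model$conv_w, model$n_filters,
         model$n_channels * model$filter_width)
}

# scratch cache for shape-dependent index/pooling matrices (training reuses
# the same batch shape thousands of times)
.cnn_scratch <- new.env(parent = emptyenv())

# unfold a batch (channels x T x B) into the im2col matrix
# (channels*width) x (T_out * B); zero-padded for "same".  Implemented as a
# single gather with a cached index vector (index 0 of the padded vector is
# mapped to a trailing zero element).
.unfold <- function(x, width, padding) {
  d <- dim(x)
  nch <- d[1]; T_len <- d[2]; B <- d[3]
  pad <- if (padding == "same") (width - 1L) %/% 2L else 0L
  T_out <- if (padding == "same") T_len else T_len - width + 1L
  key <- paste("uf", nch, T_len, B, width, padding, sep = "_")
  idx <- .cnn_scratch[[key]]
  if (is.null(idx)) {
    # element (ch, k; t, b) of U maps to x[ch, t + k - 1 - pad, b], or to
    # the sentinel zero position n+1 when the time index is out of range
    n <- nch * T_len * B
    ch <- rep_len(seq_len(nch), nch * width)
    k <- rep(seq_len(width), each = nch)
    tt <- rep(seq_len(T_out), each = nch * width)
    bb <- rep(seq_len(B), each = nch * width * T_out)
    tsrc <- rep(tt, times = 1) + rep(k, times = T_out * B) - 1L - pad
    chf <- rep(ch, times = T_out * B)
    bbf <- bb
    valid <- tsrc >= 1L & tsrc <= T_len
    idx <- as.integer(ifelse(valid,
                             chf + (tsrc - 1L) * nch +
                               (bbf - 1L) * nch * T_len,
                             n + 1L))
    # bounded cache: drop old shapes if many batch geometries accumulate
    if (length(ls(.cnn_scratch)) > 24) {
      rm(list = ls(.cnn_scratch), envir = .cnn_scratch)
    }
    .cnn_scratch[[key]] <- idx
  }
  xv <- c(x, 0)
  U <- xv[idx]
  dim(U) <- c(nch * width, T_out * B)
  list(U = U, T_out = T_out, B = B)
}

# cached block indicator matrix used for average pooling
.pool_matrix <- function(T_out, B) {
  key <- paste("O", T_out, B, sep = "_")
  O <- .cnn_scratch[[key]]
  if (is.null(O)) {
    O <- matrix(0, T_out * B, B)
    O[cbind(seq_len(T_out * B), rep(seq_len(B), each = T_out))] <- 1
    .cnn_scratch[[key]] <- O
  }
  O
}

# forward pass with caches for the backward pass
.cnn_fwd <- function(model, x, keep_cache = FALSE) {
  if (length(dim(x)) == 2) x <- array(x, dim = c(dim(x), 1))
  d <- dim(x)
  if (d[1] != model$n_channels) stop("window has ", d[1], " channels; model expects ",
                                     model$n_channels)
  uf <- .unfold(x, model$filter_width, model$padding)
  W <- .conv_w_mat(model)
  # conv weights are indexed (filter, channel, tap); the unfolded rows are
  # ordered tap-major (tap block k holds all channels), matching
  # matrix(conv_w, nf, nch*width) which unrolls channel fastest
  Z <- W %*% uf$U + model$conv_b          # n_filters x (T_out*B)
  R <- Z * (Z > 0)                        # ReLU
  # average pool over time as a single matrix product with a block
  # indicator matrix (T_out*B x B)
  O <- .pool_matrix(uf$T_out, uf$B)
  P <- (R %*% O) / uf$T_out               # n_filters x B
  Z1 <- model$fc1_w %*% P + model$fc1_b
  S <- 1 / (1 + exp(-Z1))
  Z2 <- model$fc2_w %*% S + model$fc2_b   # 2 x B logits
  m <- apply(Z2, 2, max)
  E <- exp(sweep(Z2, 2, m))
  prob <- sweep(E, 2, colSums(E), "/")    # softmax: 2 x B
  out <- list(prob = prob, Z2 = Z2)
  if (keep_cache) {
    out$cache <- list(U = uf$U, T_out = uf$T_out, B = uf$B,
                      relu_mask = (Z > 0), S = S, P = P, O = O)
  }
  out
}

#' CNN forward pass: class probabilities for decision windows
#'
#' @param model a `cnn_model`.
#' @param x a single window (channels x T matrix), an array
#'   (channels x T x B), or a `decision_windows` object.
#' @return matrix B x 2 of probabilities (columns `left`, `right`), rows
#'   summing to 1.
#' @export
cnn_forward <- function(model, x) {
  if (inherits(x, "decision_windows")) x <- x$x
  p <- t(.cnn_fwd(model, x)$prob)
  colnames(p) <- c("left", "right")
  p
}

# loss and gradients for a labelled batch; y is integer 1 (left) or 2
# (right).  Cross-entropy averaged over the batch.
.cnn_loss_grad <- function(model, x, y) {
  fw <- .cnn_fwd(model, x, keep_cache = TRUE)
  ca <- fw$cache
  B <- ca$B
  eps <- 1e-12
  loss <- -mean(log(fw$prob[cbind(y, seq_len(B))] + eps))
  dZ2 <- fw$prob
  dZ2[cbind(y, seq_len(B))] <- dZ2[cbind(y, seq_len(B))] - 1
  dZ2 <- dZ2 / B                             # 2 x B
  g_fc2_w <- tcrossprod(dZ2, ca$S)
  g_fc2_b <- rowSums(dZ2)
  dS <- crossprod(model$fc2_w, dZ2)
  dZ1 <- dS * ca$S * (1 - ca$S)
  g_fc1_w <- tcrossprod(dZ1, ca$P)
  g_fc1_b <- rowSums(dZ1)
  dP <- crossprod(model$fc1_w, dZ1)          # n_filters x B
  # through average pool (broadcast over time) and ReLU
  dR <- tcrossprod(dP, ca$O) / ca$T_out      # n_filters x (T_out*B)
  dZ <- dR * ca$relu_mask
  g_conv_w <- tcrossprod(dZ, ca$U)
  g_conv_b <- rowSums(dZ)
  list(loss = loss,
       grads = list(conv_w = array(g_conv_w, dim = dim(model$conv_w)),
                    conv_b = g_conv_b,
                    fc1_w = g_fc1_w, fc1_b = g_fc1_b,
                    fc2_w = g_fc2_w, fc2_b = g_fc2_b))
}

#' Training configuration for the CNN
#'
#' Defaults are the published protocol: SGD with initial learning rate 0.09
#' and momentum 0.9, stepped to 0.045 after epoch 10 and to 0.0225 after
#' epoch 35, batch size 20, 100 epochs, weight decay 5e-4, Normal(0, 0.5^2)
#' initialization, 10 training runs.
#'
#' @param lr_initial,momentum,batch_size,epochs,weight_decay,init_std,n_runs
#'   scalars as described above.
#' @param lr_schedule named numeric vector: after the epoch named, the
#'   learning rate becomes the value.
#' @param seed integer seed controlling initialization and batch shuffling.
#' @export
train_config <- function(lr_initial = 0.09, momentum = 0.9,
                         lr_schedule = c("10" = 0.045, "35" = 0.0225),
                         batch_size = 20, epochs = 100,
                         weight_decay = 5e-4, init_std = 0.5,
                         n_runs = 10, seed = 1) {
  structure(list(lr_initial = lr_initial, momentum = momentum,
                 lr_schedule = lr_schedule, batch_size = batch_size,
                 epochs = as.integer(epochs), weight_decay = weight_decay,
                 init_std = init_std, n_runs = as.integer(n_runs),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate in effect at a given epoch
#'
#' @param config a [train_config()].
#' @param epoch epoch number (1-based).
#' @export
learning_rate_at <- function(config, epoch) {
  lr <- config$lr_initial
  if (length(config$lr_schedule)) {
    after <- as.numeric(names(config$lr_schedule))
    for (i in order(after)) {
      if (epoch > after[i]) lr <- config$lr_schedule[[i]]
    }
  }
  lr
}

#' Train the CNN with SGD, momentum, weight decay and epoch selection
#'
#' Minimizes softmax cross-entropy between outputs and attended-ear labels.
#' After every epoch the validation loss is recorded; the returned model is
#' the one from the (first) epoch with minimal validation loss.
#'
#' @param train_windows,val_windows `decision_windows`; they must not share
#'   any (subject, trial) pair unless they come from disjoint sample ranges
#'   of the same trial (as in the every-trial split); basic disjointness is
#'   asserted by the fold constructors.
#' @param config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return a `trained_cnn`: list with `model`, `selected_epoch`,
#'   `validation_loss_curve`, `training_log` (data frame: epoch,
#'   train_loss, val_loss, lr).
#' @export
train_cnn <- function(train_windows, val_windows, config = train_config(),
                      verbose = FALSE) {
  stopifnot(inherits(train_windows, "decision_windows"),
            inherits(val_windows, "decision_windows"))
  n_train <- length(train_windows$label)
  n_val <- length(val_windows$label)
  if (n_train == 0 || n_val == 0) stop("empty training or validation set")
  model <- build_cnn(train_windows$T, seed = config$seed,
                     n_channels = dim(train_windows$x)[1],
                     init_sd = config$init_std)
  vel <- lapply(model[c("conv_w", "conv_b", "fc1_w", "fc1_b",
                        "fc2_w", "fc2_b")],
                function(p) p * 0)
  y_train <- as.integer(train_windows$label)
  y_val <- as.integer(val_windows$label)
  best_val <- Inf; best_model <- model; best_epoch <- NA_integer_
  log_rows <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    lr <- learning_rate_at(config, epoch)
    ord <- .with_seed(.derive_seed(config$seed, 23, epoch),
                      sample.int(n_train))
    tl <- 0; nb <- 0
    for (s in seq(1, n_train, by = config$batch_size)) {
      idx <- ord[s:min(s + config$batch_size - 1L, n_train)]
      lg <- .cnn_loss_grad(model, train_windows$x[, , idx, drop = FALSE],
                           y_train[idx])
      if (!is.finite(lg$loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch)
      }
      tl <- tl + lg$loss; nb <- nb + 1
      for (nm in names(vel)) {
        g <- lg$grads[[nm]] + config$weight_decay * model[[nm]]
        vel[[nm]] <- config$momentum * vel[[nm]] - lr * g
        model[[nm]] <- model[[nm]] + vel[[nm]]
      }
    }
    vl <- .batched_loss(model, val_windows$x, y_val)
    if (!is.finite(vl)) {
      stop("training diverged (non-finite validation loss) at epoch ", epoch)
    }
    if (vl < best_val) {
      best_val <- vl; best_model <- model; best_epoch <- epoch
    }
    log_rows[[epoch]] <- data.frame(epoch = epoch, train_loss = tl / nb,
                                    val_loss = vl, lr = lr)
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.4f",
                      epoch, tl / nb, vl, lr))
    }
  }
  log_df <- do.call(rbind, log_rows)
  structure(list(model = best_model, selected_epoch = best_epoch,
                 validation_loss_curve = log_df$val_loss,
                 training_log = log_df),
            class = "trained_cnn")
}

.batched_loss <- function(model, x, y, batch = NULL) {
  n <- dim(x)[3]
  # keep the unfolded conv input near ~70 MB regardless of window length
  if (is.null(batch)) batch <- max(1L, 8192L %/% dim(x)[2])
  tot <- 0
  for (s in seq(1, n, by = batch)) {
    idx <- s:min(s + batch - 1L, n)
    p <- .cnn_fwd(model, x[, , idx, drop = FALSE])$prob
    tot <- tot + sum(-log(p[cbind(y[idx], seq_along(idx))] + 1e-12))
  }
  tot / n
}

#' Window-level decoding accuracy of one or more trained models
#'
#' Accuracy is the percentage of decision windows whose argmax probability
#' matches the attended-ear label.  With several models (training runs) the
#' summary is their mean; with results from several folds, fold accuracies
#' are averaged.
#'
#' @param models a `trained_cnn`/`cnn_model` or list of them.
#' @param test_windows a `decision_windows` object.
#' @return list with `per_model` (percent per model) and `accuracy` (their
#'   mean, percent).
#' @export
evaluate_cnn <- function(models, test_windows) {
  stopifnot(inherits(test_windows, "decision_windows"))
  if (length(test_windows$label) == 0) stop("empty test set")
  if (inherits(models, "trained_cnn") || inherits(models, "cnn_model")) {
    models <- list(models)
  }
  stopifnot(length(models) >= 1)
  y <- as.integer(test_windows$label)
  batch <- max(1L, 8192L %/% test_windows$T)
  acc <- vapply(models, function(m) {
    if (inherits(m, "trained_cnn")) m <- m$model
    n <- length(y); correct <- 0
    for (s in seq(1, n, by = batch)) {
      idx <- s:min(s + batch - 1L, n)
      p <- .cnn_fwd(m, test_windows$x[, , idx, drop = FALSE])$prob
      correct <- correct + sum(apply(p, 2, which.max) == y[idx])
    }
    100 * correct / n
  }, numeric(1))
  list(per_model = acc, accuracy = mean(acc))
}

#' Average accuracies over cross-validation folds
#'
#' @param fold_accuracies numeric vector of per-fold accuracies (percent).
#' @return their mean.
#' @export
fold_average <- function(fold_accuracies) mean(fold_accuracies)
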