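#' LSTM training configuration
#'
#' Defaults: one LSTM layer of 64 hidden units feeding a dense softmax
#' head, sequences of `seq_len = 5` consecutive windows, Adam with
#' learning rate 1e-3 and betas (0.9, 0.999), L2 penalty 1e-4 on all
#' weight matrices (biases excluded), batch size 64, and a fixed run of
#' 50 epochs (no early stopping).
#'
#' @param hidden hidden units per layer.
#' @param layers number of stacked LSTM layers.
#' @param seq_len windows per sequence (temporal length L).
#' @param l2_lambda L2 penalty coefficient (>= 0).
#' @param learning_rate Adam step size.
#' @param epochs training epochs (>= 1).
#' @param batch_size minibatch size.
#' @param seed RNG seed for initialization and batch shuffling.
#' @param beta1,beta2,adam_eps Adam moment decay rates and epsilon.
#' @return a list of class `lstm_config`.
#' @export
lstm_config <- function(hidden = 64, layers = 1, seq_len = 5,
                        l2_lambda = 1e-4, learning_rate = 1e-3,
                        epochs = 50, batch_size = 64, seed = 1,
                        beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8) {
  stopifnot(hidden >= 1, layers >= 1, seq_len >= 1, l2_lambda >= 0,
            learning_rate > 0, epochs >= 1, batch_size >= 1)
  structure(list(hidden = as.integer(hidden), layers = as.integer(layers),
                 seq_len = as.integer(seq_len), l2_lambda = l2_lambda,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps),
            class = "lstm_config")
}

#' Build fixed-length sequences from a feature table
#'
#' Slides a group of `L` consecutive window rows (stride `stride`)
#' within each recording — never across recordings — and labels each
#' sequence with the label of its last window.
#'
#' @param table a `feature_table` whose rows are in temporal order
#'   within each recording.
#' @param L sequence length in windows.
#' @param stride hop between sequence starts; default 1.
#' @param groups optional per-row recording identifier; default one
#'   recording. Groups shorter than `L` windows are skipped with a
#'   warning.
#' @return list with `x` (N x L x F array, feature names on the third
#'   axis), `labels`, and `feature_names`.
#' @export
make_sequences <- function(table, L, stride = 1, groups = NULL) {
  validate_feature_table(table)
  stopifnot(L >= 1, stride >= 1)
  x <- feature_matrix(table)
  n <- nrow(x)
  if (is.null(groups)) groups <- rep("r1", n)
  if (length(groups) != n) stop("`groups` must have one entry per row")
  seq_x <- list()
  seq_lab <- character(0)
  skipped <- 0L
  for (g in unique(groups)) {
    rows <- which(groups == g)
    if (length(rows) < L) {
      skipped <- skipped + 1L
      next
    }
    starts <- seq.int(1L, length(rows) - L + 1L, by = stride)
    for (s in starts) {
      idx <- rows[s:(s + L - 1L)]
      seq_x[[length(seq_x) + 1L]] <- x[idx, , drop = FALSE]
      seq_lab <- c(seq_lab, table$label[idx[L]])
    }
  }
  if (skipped > 0L)
    warning(skipped, " recording(s) shorter than L = ", L,
            " windows were skipped")
  if (length(seq_x) == 0L) stop("no sequences could be built")
  arr <- array(0, dim = c(length(seq_x), L, ncol(x)),
               dimnames = list(NULL, NULL, colnames(x)))
  for (i in seq_along(seq_x)) arr[i, , ] <- seq_x[[i]]
  list(x = arr, labels = seq_lab, feature_names = colnames(x))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Softmax cross-entropy loss with L2 weight penalty
#'
#' Mean softmax cross-entropy over the batch plus
#' `l2_lambda * sum(w^2)` summed over the supplied weight matrices
#' (biases are excluded by construction: pass only weight matrices).
#'
#' @param logits numeric matrix (batch x classes), finite.
#' @param y integer class indices in `1..C` (or a factor).
#' @param weights list of weight matrices entering the penalty; may be
#'   empty.
#' @param l2_lambda penalty coefficient.
#' @return scalar loss.
#' @export
lstm_loss <- function(logits, y, weights = list(), l2_lambda = 0) {
  if (is.factor(y)) y <- as.integer(y)
  stopifnot(all(is.finite(logits)), length(y) == nrow(logits),
            all(y >= 1), all(y <= ncol(logits)))
  m <- apply(logits, 1L, max)
  lse <- m + log(rowSums(exp(logits - m)))
  ce <- mean(lse - logits[cbind(seq_len(nrow(logits)), y)])
  pen <- if (length(weights) > 0L)
    sum(vapply(weights, function(w) sum(w^2), numeric(1))) else 0
  ce + l2_lambda * pen
}

# One forward pass through the stacked LSTM. xb: B x L x F (already
# scaled). Returns logits plus the per-layer, per-step caches needed by
# backprop.
lstm_forward <- function(params, xb, need_cache = TRUE) {
  B <- dim(xb)[1]; L <- dim(xb)[2]
  H <- nrow(params$layers[[1]]$U)
  n_layers <- length(params$layers)
  inputs <- lapply(seq_len(L), function(t) {
    xt <- xb[, t, , drop = FALSE]
    dim(xt) <- c(B, dim(xb)[3])
    xt
  })
  caches <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    lw <- params$layers[[l]]
    h <- matrix(0, B, H); cc <- matrix(0, B, H)
    cache_t <- vector("list", L)
    outs <- vector("list", L)
    for (t in seq_len(L)) {
      z <- inputs[[t]] %*% lw$W + h %*% lw$U +
        matrix(lw$b, B, 4 * H, byrow = TRUE)
      gi <- sigmoid(z[, 1:H, drop = FALSE])
      gf <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
      gg <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
      go <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
      c_prev <- cc
      h_prev <- h
      cc <- gf * c_prev + gi * gg
      tc <- tanh(cc)
      h <- go * tc
      if (need_cache)
        cache_t[[t]] <- list(x = inputs[[t]], i = gi, f = gf, g = gg,
                             o = go, c_prev = c_prev, h_prev = h_prev,
                             tanh_c = tc)
      outs[[t]] <- h
    }
    caches[[l]] <- cache_t
    inputs <- outs
  }
  logits <- inputs[[L]] %*% params$Wy +
    matrix(params$by, B, length(params$by), byrow = TRUE)
  list(logits = logits, h_last = inputs[[L]], caches = caches)
}

# Backward pass; returns gradients with the same shapes as params.
lstm_backward <- function(params, fwd, xb, y_idx, l2_lambda) {
  B <- dim(xb)[1]; L <- dim(xb)[2]
  H <- nrow(params$layers[[1]]$U)
  C <- length(params$by)
  n_layers <- length(params$layers)
  P <- softmax_rows(fwd$logits)
  dlogits <- P
  dlogits[cbind(seq_len(B), y_idx)] <- dlogits[cbind(seq_len(B), y_idx)] - 1
  dlogits <- dlogits / B
  g <- list(Wy = t(fwd$h_last) %*% dlogits + 2 * l2_lambda * params$Wy,
            by = colSums(dlogits),
            layers = vector("list", n_layers))
  # external dh per timestep for the current (top-down) layer
  dh_ext <- vector("list", L)
  for (t in seq_len(L)) dh_ext[[t]] <- matrix(0, B, H)
  dh_ext[[L]] <- dlogits %*% t(params$Wy)
  for (l in n_layers:1) {
    lw <- params$layers[[l]]
    cache <- fwd$caches[[l]]
    dW <- matrix(0, nrow(lw$W), 4 * H)
    dU <- matrix(0, H, 4 * H)
    db <- numeric(4 * H)
    dh_next <- matrix(0, B, H)
    dc_next <- matrix(0, B, H)
    dx <- vector("list", L)
    for (t in L:1) {
      ct <- cache[[t]]
      dh <- dh_ext[[t]] + dh_next
      do_ <- dh * ct$tanh_c
      dc <- dh * ct$o * (1 - ct$tanh_c^2) + dc_next
      di <- dc * ct$g
      df <- dc * ct$c_prev
      dg <- dc * ct$i
      dz <- cbind(di * ct$i * (1 - ct$i),
                  df * ct$f * (1 - ct$f),
                  dg * (1 - ct$g^2),
                  do_ * ct$o * (1 - ct$o))
      dW <- dW + t(ct$x) %*% dz
      dU <- dU + t(ct$h_prev) %*% dz
      db <- db + colSums(dz)
      dx[[t]] <- dz %*% t(lw$W)
      dh_next <- dz %*% t(lw$U)
      dc_next <- dc * ct$f
    }
    g$layers[[l]] <- list(W = dW + 2 * l2_lambda * lw$W,
                          U = dU + 2 * l2_lambda * lw$U, b = db)
    dh_ext <- dx
  }
  g
}

init_lstm_params <- function(n_features, hidden, layers, n_classes) {
  mk <- function(nr, nc, r) matrix(runif(nr * nc, -r, r), nr, nc)
  lyr <- vector("list", layers)
  f_in <- n_features
  for (l in seq_len(layers)) {
    b <- numeric(4 * hidden)
    b[(hidden + 1):(2 * hidden)] <- 1        # forget-gate bias
    lyr[[l]] <- list(W = mk(f_in, 4 * hidden, 1 / sqrt(f_in)),
                     U = mk(hidden, 4 * hidden, 1 / sqrt(hidden)),
                     b = b)
    f_in <- hidden
  }
  list(layers = lyr,
       Wy = mk(hidden, n_classes, 1 / sqrt(hidden)),
       by = numeric(n_classes))
}

weight_matrices <- function(params) {
  c(lapply(params$layers, `[[`, "W"),
    lapply(params$layers, `[[`, "U"),
    list(params$Wy))
}

# Flatten params <-> list-of-arrays helpers for Adam
params_to_list <- function(p) {
  out <- list()
  for (l in seq_along(p$layers)) {
    out[[paste0("W", l)]] <- p$layers[[l]]$W
    out[[paste0("U", l)]] <- p$layers[[l]]$U
    out[[paste0("b", l)]] <- p$layers[[l]]$b
  }
  out$Wy <- p$Wy
  out$by <- p$by
  out
}

list_to_params <- function(lst, layers) {
  p <- list(layers = vector("list", layers))
  for (l in seq_len(layers))
    p$layers[[l]] <- list(W = lst[[paste0("W", l)]],
                          U = lst[[paste0("U", l)]],
                          b = lst[[paste0("b", l)]])
  p$Wy <- lst$Wy
  p$by <- lst$by
  p
}

#' Train the LSTM activity classifier
#'
#' Seeded initialization, Adam optimization of the softmax
#' cross-entropy + L2 loss for a fixed number of epochs. Feature
#' z-scaling parameters are fitted on the training data only;
#' zero-variance features are dropped with a warning. The run is
#' reproducible given `(seed, config, data)`.
#'
#' @param x sequence array (N x L x F) from [make_sequences()].
#' @param labels per-sequence labels (>= 2 classes).
#' @param config an [lstm_config()].
#' @return object of class `har_lstm` with the weights, sorted class
#'   vocabulary, fitted scaler, config snapshot, and per-epoch mean-loss
#'   trace.
#' @export
train_lstm <- function(x, labels, config = lstm_config()) {
  stopifnot(inherits(config, "lstm_config"), length(dim(x)) == 3L)
  labels <- as.character(labels)
  N <- dim(x)[1]
  if (length(labels) != N) stop("one label per sequence required")
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes to train")
  y_idx <- match(labels, classes)
  F_all <- dim(x)[3]
  flat <- matrix(aperm(x, c(1, 2, 3)), nrow = N * dim(x)[2], ncol = F_all)
  mu <- colMeans(flat)
  sg <- apply(flat, 2L, stats::sd)
  keep <- which(is.finite(sg) & sg > 0)
  if (length(keep) < F_all)
    warning(F_all - length(keep), " zero-variance feature(s) dropped ",
            "before training")
  if (length(keep) == 0L) stop("all features have zero variance")
  scaler <- list(mean = mu, sd = sg, keep = keep, n_features = F_all)
  xs <- scale_sequences(x, scaler)
  if (!all(is.finite(xs))) stop("non-finite values after scaling")
  set.seed(config$seed)
  params <- init_lstm_params(length(keep), config$hidden, config$layers,
                             length(classes))
  flat_p <- params_to_list(params)
  mstate <- lapply(flat_p, function(w) w * 0)
  vstate <- lapply(flat_p, function(w) w * 0)
  step <- 0L
  trace <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(N)
    ep_loss <- 0
    for (bs in split(perm, ceiling(seq_along(perm) / config$batch_size))) {
      xb <- xs[bs, , , drop = FALSE]
      yb <- y_idx[bs]
      fwd <- lstm_forward(params, xb)
      loss <- lstm_loss(fwd$logits, yb, weight_matrices(params),
                        config$l2_lambda)
      if (!is.finite(loss))
        stop("training diverged: non-finite loss at epoch ", ep)
      ep_loss <- ep_loss + loss * length(bs)
      grads <- lstm_backward(params, fwd, xb, yb, config$l2_lambda)
      flat_g <- params_to_list(grads)
      flat_p <- params_to_list(params)
      step <- step + 1L
      b1 <- config$beta1; b2 <- config$beta2
      for (k in names(flat_p)) {
        mstate[[k]] <- b1 * mstate[[k]] + (1 - b1) * flat_g[[k]]
        vstate[[k]] <- b2 * vstate[[k]] + (1 - b2) * flat_g[[k]]^2
        mhat <- mstate[[k]] / (1 - b1^step)
        vhat <- vstate[[k]] / (1 - b2^step)
        flat_p[[k]] <- flat_p[[k]] -
          config$learning_rate * mhat / (sqrt(vhat) + config$adam_eps)
      }
      params <- list_to_params(flat_p, config$layers)
    }
    trace[ep] <- ep_loss / N
  }
  structure(
    list(params = params, classes = classes, scaler = scaler,
         config = config, loss_trace = trace),
    class = "har_lstm")
}

scale_sequences <- function(x, scaler) {
  if (dim(x)[3] != scaler$n_features)
    stop("feature dimension (", dim(x)[3], ") does not match training (",
         scaler$n_features, ")")
  out <- x[, , scaler$keep, drop = FALSE]
  for (j in seq_along(scaler$keep)) {
    f <- scaler$keep[j]
    out[, , j] <- (x[, , f] - scaler$mean[f]) / scaler$sd[f]
  }
  out
}

#' @export
print.har_lstm <- function(x, ...) {
  cat("<har_lstm>", x$config$layers, "layer(s) x", x$config$hidden,
      "units |", length(x$classes), "classes |",
      x$config$epochs, "epochs | final loss",
      signif(tail(x$loss_trace, 1), 4), "\n")
  invisible(x)
}

#' Class probabilities for sequences
#'
#' Softmax outputs of the trained model; each row is non-negative and
#' sums to 1. Column order is the sorted class vocabulary.
#'
#' @param model a `har_lstm`.
#' @param x sequence array (N x L x F) with the training feature
#'   dimension.
#' @return numeric matrix (N x classes) of probabilities.
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "har_lstm"), length(dim(x)) == 3L)
  xs <- scale_sequences(x, model$scaler)
  fwd <- lstm_forward(model$params, xs, need_cache = FALSE)
  p <- softmax_rows(fwd$logits)
  colnames(p) <- model$classes
  p
}

#' Predicted class labels for sequences
#'
#' Argmax of [predict_proba()]; ties resolve to the first (alphabetical)
#' class, deterministically.
#'
#' @param model a `har_lstm`.
#' @param x sequence array (N x L x F).
#' @return character vector of predicted labels.
#' @export
predict_classes <- function(model, x) {
  p <- predict_proba(model, x)
  model$classes[max.col(p, ties.method = "first")]
}
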