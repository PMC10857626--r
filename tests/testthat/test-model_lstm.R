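test_that("sequence construction slides within recordings only", {
  tab <- feature_table(matrix(seq_len(20), 10, 2), c("f1", "f2"),
                       labels = letters[1:10])
  s <- make_sequences(tab, L = 5)
  expect_equal(dim(s$x), c(6, 5, 2))
  expect_identical(s$labels, letters[5:10])    # last-window label
  s1 <- make_sequences(tab, L = 1)
  expect_equal(dim(s1$x)[1], 10)
  expect_identical(s1$labels, tab$label)
  two <- make_sequences(tab, L = 5, groups = rep(c("r1", "r2"), each = 5))
  expect_equal(dim(two$x)[1], 2)               # no cross-recording windows
  expect_warning(make_sequences(tab, L = 5,
                                groups = c(rep("r1", 8), "r2", "r3")),
                 "skipped")
})

test_that("the loss matches softmax cross-entropy plus an exact L2 term", {
  logits <- matrix(0, 4, 3)
  expect_equal(lstm_loss(logits, c(1, 2, 3, 1)), log(3), tolerance = 1e-12)
  # huge-margin correct logits drive CE to zero
  big <- matrix(c(50, 0, 0), 1, 3)
  expect_lt(lstm_loss(big, 1), 1e-12)
  w <- list(matrix(1:4 / 10, 2), matrix(-2:1 / 5, 2))
  delta <- lstm_loss(logits, c(1, 2, 3, 1), w, 0.7) -
    lstm_loss(logits, c(1, 2, 3, 1), w, 0)
  expect_equal(delta, 0.7 * (sum(w[[1]]^2) + sum(w[[2]]^2)),
               tolerance = 1e-12)
})

test_that("backpropagation matches finite-difference gradients", {
  set.seed(51)
  B <- 3; L <- 2; F_ <- 4; H <- 5; C <- 3
  lambda <- 0.01
  xb <- array(rnorm(B * L * F_), dim = c(B, L, F_))
  y <- c(1L, 3L, 2L)
  params <- harpipe:::init_lstm_params(F_, H, 1, C)
  loss_at <- function(p) {
    fwd <- harpipe:::lstm_forward(p, xb)
    lstm_loss(fwd$logits, y, harpipe:::weight_matrices(p), lambda)
  }
  fwd <- harpipe:::lstm_forward(params, xb)
  grads <- harpipe:::lstm_backward(params, fwd, xb, y, lambda)
  eps <- 1e-6
  flat_p <- harpipe:::params_to_list(params)
  flat_g <- harpipe:::params_to_list(grads)
  for (k in names(flat_p)) {
    idx <- sample(length(flat_p[[k]]), min(5, length(flat_p[[k]])))
    for (i in idx) {
      pp <- flat_p; pp[[k]][i] <- pp[[k]][i] + eps
      pm <- flat_p; pm[[k]][i] <- pm[[k]][i] - eps
      num <- (loss_at(harpipe:::list_to_params(pp, 1)) -
              loss_at(harpipe:::list_to_params(pm, 1))) / (2 * eps)
      expect_equal(flat_g[[k]][i], num, tolerance = 1e-5,
                   label = paste("grad", k, i))
    }
  }
})

test_that("stacked-layer backpropagation also matches finite differences", {
  set.seed(52)
  B <- 2; L <- 2; F_ <- 3; H <- 4; C <- 2
  xb <- array(rnorm(B * L * F_), dim = c(B, L, F_))
  y <- c(2L, 1L)
  params <- harpipe:::init_lstm_params(F_, H, 2, C)
  loss_at <- function(p) {
    fwd <- harpipe:::lstm_forward(p, xb)
    lstm_loss(fwd$logits, y, harpipe:::weight_matrices(p), 0)
  }
  fwd <- harpipe:::lstm_forward(params, xb)
  grads <- harpipe:::lstm_backward(params, fwd, xb, y, 0)
  flat_p <- harpipe:::params_to_list(params)
  flat_g <- harpipe:::params_to_list(grads)
  eps <- 1e-6
  for (k in c("W1", "U1", "b1", "W2", "U2", "b2", "Wy")) {
    i <- sample(length(flat_p[[k]]), 3)
    for (j in i) {
      pp <- flat_p; pp[[k]][j] <- pp[[k]][j] + eps
      pm <- flat_p; pm[[k]][j] <- pm[[k]][j] - eps
      num <- (loss_at(harpipe:::list_to_params(pp, 2)) -
              loss_at(harpipe:::list_to_params(pm, 2))) / (2 * eps)
      expect_equal(flat_g[[k]][j], num, tolerance = 1e-5,
                   label = paste("grad", k, j))
    }
  }
})

test_that("training separates a wide-margin synthetic problem", {
  prob <- separable_sequences(n_per_class = 30, L = 3, F_ = 4, seed = 53)
  cfg <- lstm_config(hidden = 8, seq_len = 3, epochs = 50,
                     batch_size = 16, seed = 5)
  model <- train_lstm(prob$x, prob$labels, cfg)
  acc <- mean(predict_classes(model, prob$x) == prob$labels)
  expect_gte(acc, 0.95)
  # 10-epoch moving average of the loss is non-increasing
  ma <- stats::filter(model$loss_trace, rep(1 / 10, 10), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_true(all(diff(ma) <= 1e-6))
  # strong L2 shrinks the weights
  cfg_l2 <- lstm_config(hidden = 8, seq_len = 3, epochs = 50,
                        batch_size = 16, seed = 5, l2_lambda = 10)
  model_l2 <- train_lstm(prob$x, prob$labels, cfg_l2)
  ssq <- function(m) sum(vapply(harpipe:::weight_matrices(m$params),
                                function(w) sum(w^2), numeric(1)))
  expect_lt(ssq(model_l2), ssq(model))
})

test_that("training is reproducible under a fixed seed", {
  prob <- separable_sequences(n_per_class = 15, L = 2, F_ = 3, seed = 54)
  cfg <- lstm_config(hidden = 6, seq_len = 2, epochs = 10,
                     batch_size = 8, seed = 3)
  m1 <- train_lstm(prob$x, prob$labels, cfg)
  m2 <- train_lstm(prob$x, prob$labels, cfg)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$params$Wy, m2$params$Wy)
})

test_that("probability outputs are normalized, deterministic, and guarded", {
  prob <- separable_sequences(n_per_class = 15, L = 2, F_ = 3, seed = 55)
  cfg <- lstm_config(hidden = 6, seq_len = 2, epochs = 5,
                     batch_size = 8, seed = 4)
  model <- train_lstm(prob$x, prob$labels, cfg)
  p <- predict_proba(model, prob$x)
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-6)
  expect_true(all(p >= 0))
  expect_identical(colnames(p), sort(unique(prob$labels)))
  # duplicated inputs give identical rows; permutation permutes rows
  dup <- prob$x[c(1, 1, 2), , , drop = FALSE]
  pd <- predict_proba(model, dup)
  expect_equal(pd[1, ], pd[2, ])
  perm <- c(5, 2, 9, 1)
  expect_equal(predict_proba(model, prob$x[perm, , , drop = FALSE]),
               p[perm, ])
  bad <- array(0, dim = c(2, 2, 7))
  expect_error(predict_proba(model, bad), "dimension")
  expect_error(train_lstm(prob$x, rep("p", 30), cfg), "2 classes")
})

test_that("zero-variance features are dropped with a warning", {
  prob <- separable_sequences(n_per_class = 10, L = 2, F_ = 3, seed = 56)
  prob$x[, , 2] <- 7   # constant feature
  cfg <- lstm_config(hidden = 4, seq_len = 2, epochs = 2,
                     batch_size = 8, seed = 2)
  expect_warning(model <- train_lstm(prob$x, prob$labels, cfg),
                 "zero-variance")
  expect_equal(model$scaler$keep, c(1L, 3L))
  expect_equal(ncol(predict_proba(model, prob$x)), 2)
})
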