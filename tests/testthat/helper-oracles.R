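# Independent oracles and tiny fixtures shared across tests.

# Brute-force DTW: enumerate every monotone warping path on the grid
# (moves down/right/diagonal, anchored at both corners) and take the
# minimum accumulated squared cost. Only feasible for short sequences.
bf_dtw <- function(P, R) {
  n <- length(P); m <- length(R)
  best <- Inf
  rec <- function(i, j, acc) {
    acc <- acc + (P[i] - R[j])^2
    if (i == n && j == m) {
      best <<- min(best, acc)
      return(invisible())
    }
    if (i < n) rec(i + 1, j, acc)
    if (j < m) rec(i, j + 1, acc)
    if (i < n && j < m) rec(i + 1, j + 1, acc)
  }
  rec(1, 1, 0)
  sqrt(best)
}

# Brute-force AUC: fraction of positive/negative pairs won (ties count
# half) — the normalized Mann-Whitney statistic.
bf_auc <- function(truth, scores) {
  pos <- scores[as.logical(truth)]
  neg <- scores[!as.logical(truth)]
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# A tiny labeled recording: deterministic ramp channels.
tiny_recording <- function(n = 12, fs = 10) {
  sensor_recording(
    list(acc_x = seq_len(n) / n, acc_y = rev(seq_len(n)) / n,
         acc_z = rep(1, n)),
    labels = rep(c("walk", "run"), length.out = n),
    sampling_rate_hz = fs)
}

# Feature table with n_inf informative and n_noise pure-noise features
# for two classes (selection studies).
informative_noise_table <- function(n_per_class = 40, n_inf = 5,
                                    n_noise = 5, sep = 2.5, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  labels <- rep(c("a", "b"), each = n_per_class)
  inf <- matrix(rnorm(n * n_inf), n, n_inf) +
    outer(ifelse(labels == "a", 0, sep), rep(1, n_inf))
  noise <- matrix(rnorm(n * n_noise), n, n_noise)
  feature_table(cbind(inf, noise),
                c(paste0("inf", seq_len(n_inf)),
                  paste0("noise", seq_len(n_noise))),
                labels)
}

# Linearly separable two-class sequence problem for the LSTM: class
# centers far apart, constant over the L timesteps plus small noise.
separable_sequences <- function(n_per_class = 30, L = 3, F_ = 4,
                                margin = 4, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- array(rnorm(n * L * F_, sd = 0.3), dim = c(n, L, F_))
  x[(n_per_class + 1):n, , 1] <- x[(n_per_class + 1):n, , 1] + margin
  list(x = x, labels = rep(c("p", "q"), each = n_per_class))
}
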