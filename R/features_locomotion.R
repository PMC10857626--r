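#' Biased sample autocovariance
#'
#' `r_k = (1/N) * sum_i (x_i - xbar)(x_{i-k} - xbar)` for
#' `k = 0 .. max_lag` (the estimator whose Toeplitz matrix is always
#' positive semi-definite, as required by the Yule-Walker system).
#'
#' @param x numeric vector with `length(x) >= max_lag + 1`.
#' @param max_lag largest lag.
#' @return numeric vector `r_0 .. r_max_lag`.
#' @export
autocorrelation <- function(x, max_lag) {
  stopifnot(is.numeric(x), max_lag >= 0)
  if (length(x) < max_lag + 1L)
    stop("series too short for max_lag = ", max_lag)
  as.numeric(stats::acf(x, lag.max = max_lag, type = "covariance",
                        demean = TRUE, plot = FALSE)$acf)
}

#' Linear prediction coefficients via Yule-Walker
#'
#' Solves the order-`p` Toeplitz system built from the biased
#' autocovariances `r_0 .. r_{p-1}` against the right-hand side
#' `r_1 .. r_p` by the Levinson-Durbin recursion. Sign convention: the
#' one-step prediction is `xhat_n = sum_j a_j x_{n-j}`.
#'
#' @param x non-constant numeric series, `length(x) > p`.
#' @param p prediction order (>= 1).
#' @return numeric vector `a_1 .. a_p`.
#' @export
lpc_yule_walker <- function(x, p) {
  stopifnot(p >= 1)
  if (length(x) <= p) stop("series must be longer than the LPC order")
  r <- autocorrelation(x, p)
  if (r[1] <= 0)
    stop("constant (zero-variance) series: Yule-Walker system is singular")
  a <- numeric(0)
  err <- r[1]
  for (k in seq_len(p)) {
    acc <- if (k > 1) sum(a * r[seq(k, 2)]) else 0
    if (err <= .Machine$double.eps * r[1] * 1e4)
      stop("near-singular Yule-Walker system at order ", k)
    kappa <- (r[k + 1] - acc) / err
    a <- if (k > 1) c(a - kappa * rev(a), kappa) else kappa
    err <- err * (1 - kappa^2)
  }
  a
}

#' Linear prediction cepstral coefficients
#'
#' Standard recursion from LPC coefficients `a_1 .. a_p` to cepstra
#' `c_1 .. c_d`:
#' `c_1 = a_1`;
#' `c_j = a_j + sum_{t=1}^{j-1} (t/j) c_t a_{j-t}` for `1 < j <= p`;
#' `c_j = sum_{t=j-p}^{j-1} (t/j) c_t a_{j-t}` for `p < j <= d`.
#'
#' @param a LPC coefficients `a_1 .. a_p`.
#' @param d number of cepstra to compute (`d >= p`); default `p`.
#' @return numeric vector `c_1 .. c_d`.
#' @export
lpcc <- function(a, d = length(a)) {
  p <- length(a)
  stopifnot(p >= 1)
  if (d < p) stop("`d` must be >= the LPC order p")
  cc <- numeric(d)
  cc[1] <- a[1]
  for (j in seq_len(d)[-1]) {
    t0 <- max(1L, j - p)
    t <- t0:(j - 1L)
    s <- sum((t / j) * cc[t] * a[j - t])
    cc[j] <- if (j <= p) a[j] + s else s
  }
  cc
}

#' Average reference pattern of a class
#'
#' Element-wise mean of same-length windows of one activity class; used
#' as the warping-distance reference (e.g. an "active" running pattern
#' and a "passive" walking pattern).
#'
#' @param windows matrix (windows x length) or list of equal-length
#'   numeric vectors.
#' @return numeric reference pattern.
#' @export
build_reference <- function(windows) {
  if (is.list(windows)) {
    if (length(windows) == 0L) stop("no windows to average")
    lens <- vapply(windows, length, integer(1))
    if (length(unique(lens)) != 1L) stop("windows have ragged lengths")
    windows <- do.call(rbind, windows)
  }
  windows <- as.matrix(windows)
  if (nrow(windows) == 0L) stop("no windows to average")
  colMeans(windows)
}

#' Reference bank from a window set
#'
#' Builds one per-class reference pattern (class mean) from the
#' accelerometer-magnitude segments of a window set. To keep the
#' distances amplitude-decoupled, each window is z-normalized (mean 0,
#' sd 1) before averaging when `normalize = TRUE`. Build the bank from
#' the training split only.
#'
#' @param ws a `window_set`.
#' @param acc_channels names of the three accelerometer channels.
#' @param normalize z-normalize windows before averaging; default TRUE.
#' @return named list class -> reference pattern, class `reference_bank`.
#' @export
build_reference_bank <- function(ws,
                                 acc_channels = c("acc_x", "acc_y", "acc_z"),
                                 normalize = TRUE) {
  stopifnot(inherits(ws, "window_set"))
  missing_ch <- setdiff(acc_channels, names(ws$segments))
  if (length(missing_ch) > 0L)
    stop("missing accelerometer channel(s): ",
         paste(missing_ch, collapse = ", "))
  mag <- sqrt(ws$segments[[acc_channels[1]]]^2 +
              ws$segments[[acc_channels[2]]]^2 +
              ws$segments[[acc_channels[3]]]^2)
  if (normalize) mag <- t(apply(mag, 1L, znorm))
  classes <- sort(unique(ws$labels))
  bank <- lapply(classes, function(cl)
    build_reference(mag[ws$labels == cl, , drop = FALSE]))
  names(bank) <- classes
  structure(bank, class = "reference_bank")
}

znorm <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

#' Dynamic time warping distance
#'
#' Classic dynamic program over the `|P| x |R|` grid with squared local
#' cost `(P_i - R_j)^2`, moves down/right/diagonal, anchored at both
#' boundaries; returns the square root of the optimal accumulated cost.
#'
#' @param P,R non-empty numeric sequences.
#' @return non-negative warping distance.
#' @export
dtw_distance <- function(P, R) {
  if (length(P) == 0L || length(R) == 0L)
    stop("DTW inputs must be non-empty")
  sqrt(.dtw_cost(as.numeric(P), as.numeric(R)))
}

#' Warping distances of a window to every class reference
#'
#' @param window numeric sequence (one window).
#' @param bank a `reference_bank`.
#' @param normalize z-normalize the window first (to match a normalized
#'   bank); default TRUE.
#' @return named numeric vector, one distance per class, in sorted class
#'   order (insertion-order invariant).
#' @export
dtw_features <- function(window, bank, normalize = TRUE) {
  if (length(bank) == 0L) stop("empty reference bank")
  if (normalize) window <- znorm(window)
  classes <- sort(names(bank))
  vapply(classes, function(cl) dtw_distance(window, bank[[cl]]),
         numeric(1))
}

#' Power spectrogram
#'
#' Short-time Fourier transform with Hamming-tapered frames;
#' `S(t, f) = |STFT|^2`. The frequency axis runs from 0 to Nyquist.
#'
#' @param x numeric signal, `length(x) >= frame_length`.
#' @param frame_length frame length in samples.
#' @param hop hop between frame starts in samples.
#' @param sampling_rate_hz sampling rate in Hz.
#' @return list with `S` (frames x frequency power matrix), `freq_hz`,
#'   and `time_s` (frame centers).
#' @export
power_spectrogram <- function(x, frame_length, hop, sampling_rate_hz) {
  n <- length(x)
  if (frame_length > n)
    stop("frame_length (", frame_length, ") exceeds signal length (", n, ")")
  stopifnot(hop >= 1, frame_length >= 2)
  starts <- seq.int(1L, n - frame_length + 1L, by = hop)
  w <- hamming_window(frame_length)
  frames <- vapply(starts, function(s) x[s:(s + frame_length - 1L)] * w,
                   numeric(frame_length))
  ft <- stats::mvfft(frames)                       # frame_length x n_frames
  nf <- floor(frame_length / 2) + 1L
  S <- t(Mod(ft[seq_len(nf), , drop = FALSE])^2)   # frames x freq
  list(S = S,
       freq_hz = (seq_len(nf) - 1L) * sampling_rate_hz / frame_length,
       time_s = (starts - 1L + (frame_length - 1) / 2) / sampling_rate_hz)
}

#' Mean log-power per frequency band
#'
#' Summarizes a power spectrogram into one value per band: the mean over
#' frames of `log(eps0 + band power)` with `eps0 = 1e-12`, where band
#' power is the sum of bin powers whose frequency falls in
#' `[edge_i, edge_{i+1})` (the last band includes its upper edge).
#'
#' @param spect output of [power_spectrogram()].
#' @param band_edges_hz increasing band edges within `[0, Nyquist]`;
#'   `k+1` edges define `k` bands.
#' @return numeric vector, one mean log-power per band.
#' @export
spectral_band_features <- function(spect, band_edges_hz) {
  if (is.unsorted(band_edges_hz, strictly = TRUE))
    stop("band edges must be strictly increasing")
  nb <- length(band_edges_hz) - 1L
  if (nb < 1L) stop("need at least two band edges")
  eps0 <- 1e-12
  out <- numeric(nb)
  for (b in seq_len(nb)) {
    lo <- band_edges_hz[b]; hi <- band_edges_hz[b + 1L]
    sel <- spect$freq_hz >= lo &
      (spect$freq_hz < hi | (b == nb & spect$freq_hz <= hi))
    if (!any(sel)) stop("band ", b, " [", lo, ", ", hi, ") contains no bins")
    bp <- rowSums(spect$S[, sel, drop = FALSE])
    out[b] <- mean(log(eps0 + bp))
  }
  out
}

#' Euclidean magnitude of three aligned axes
#'
#' `sqrt(x^2 + y^2 + z^2)`, elementwise.
#'
#' @param x,y,z equal-length numeric vectors.
#' @return numeric magnitude sequence.
#' @export
magnitude3 <- function(x, y, z) {
  if (length(x) != length(y) || length(y) != length(z))
    stop("x, y, z must have equal lengths")
  sqrt(x^2 + y^2 + z^2)
}

#' Delay embedding of a scalar series
#'
#' Row `i` of the embedding is `(x_i, x_{i+tau}, ..., x_{i+(m-1)tau})`;
#' there are `N - (m-1)*tau` rows. Requires enough samples for at least
#' `m` rows so the embedded covariance can be full rank.
#'
#' @param x numeric series.
#' @param m embedding dimension; default 5.
#' @param tau delay in samples; default 1.
#' @return list of class `embedded_series` with the `vectors` matrix,
#'   `m`, and `tau`.
#' @export
embed_series <- function(x, m = 5, tau = 1) {
  stopifnot(m >= 1, tau >= 1)
  n_rows <- length(x) - (m - 1L) * tau
  if (n_rows < m)
    stop("series too short to embed: need length >= ", (m - 1) * tau + m)
  v <- vapply(0:(m - 1L), function(k) x[(1:n_rows) + k * tau],
              numeric(n_rows))
  v <- matrix(v, nrow = n_rows, ncol = m)
  structure(list(vectors = v, m = as.integer(m), tau = as.integer(tau)),
            class = "embedded_series")
}

#' State-space correlation entropy
#'
#' Shannon entropy of the per-dimension variances of a delay-embedded
#' series, normalized to a probability distribution: with `v_i` the
#' variance of embedding dimension `i`, `p_i = v_i / sum_j v_j` and
#' `SSCE = -sum_i p_i log(p_i)` (natural log, `0 log 0 = 0`). Bounded in
#' `[0, log m]`; invariant to rescaling the input series.
#'
#' @param e an `embedded_series` (or a numeric matrix of embedded
#'   vectors).
#' @return non-negative entropy value.
#' @export
ssce <- function(e) {
  v <- if (inherits(e, "embedded_series")) e$vectors else as.matrix(e)
  vars <- apply(v, 2L, stats::var)
  tot <- sum(vars)
  if (!is.finite(tot) || tot <= 0)
    stop("constant series: all embedded variances are zero")
  p <- vars / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Phase angle series in degrees
#'
#' Quadrant-aware arctangent of paired axis readings,
#' `theta(t) = atan2(y(t), x(t)) * 180 / pi`, in `(-180, 180]`. Samples
#' with both components zero yield 0 with a warning.
#'
#' @param x,y equal-length numeric vectors.
#' @return numeric vector of angles in degrees.
#' @export
phase_angle_series <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal lengths")
  if (any(x == 0 & y == 0))
    warning("phase angle undefined where x = y = 0; returning 0 there")
  atan2(y, x) * 180 / pi
}

#' Sample skewness (adjusted Fisher-Pearson)
#'
#' `(n / ((n-1)(n-2))) * sum(((x - xbar)/s)^3)` with `s` the sample
#' standard deviation (n-1 denominator).
#'
#' @param x numeric vector, `n >= 3`, non-constant.
#' @return skewness value.
#' @export
skewness <- function(x) {
  n <- length(x)
  if (n < 3L) stop("skewness requires n >= 3")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("skewness undefined for constant sample")
  (n / ((n - 1) * (n - 2))) * sum(((x - mean(x)) / s)^3)
}

#' Sample excess kurtosis
#'
#' `(n(n+1) / ((n-1)(n-2)(n-3))) * sum(((x - xbar)/s)^4)
#'  - 3 (n-1)^2 / ((n-2)(n-3))`, i.e. the unbiased-style sample excess
#' kurtosis (0 for a normal population).
#'
#' @param x numeric vector, `n >= 4`, non-constant.
#' @return excess kurtosis value.
#' @export
kurtosis <- function(x) {
  n <- length(x)
  if (n < 4L) stop("kurtosis requires n >= 4")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("kurtosis undefined for constant sample")
  (n * (n + 1) / ((n - 1) * (n - 2) * (n - 3))) *
    sum(((x - mean(x)) / s)^4) - 3 * (n - 1)^2 / ((n - 2) * (n - 3))
}

#' Circular mean of angles in degrees
#' @param deg angles in degrees.
#' @return mean direction in `(-180, 180]` degrees.
#' @export
circular_mean <- function(deg) {
  rad <- deg * pi / 180
  atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
}

#' Circular standard deviation of angles in degrees
#'
#' `sqrt(-2 log Rbar)` (radians) converted to degrees, where `Rbar` is
#' the mean resultant length; 0 for perfectly concentrated angles.
#'
#' @param deg angles in degrees.
#' @return circular standard deviation in degrees.
#' @export
circular_sd <- function(deg) {
  rad <- deg * pi / 180
  rbar <- sqrt(mean(sin(rad))^2 + mean(cos(rad))^2)
  rbar <- min(1, rbar)
  sqrt(-2 * log(max(rbar, .Machine$double.xmin))) * 180 / pi
}

#' Locomotion feature bank
#'
#' Per window, computed on the accelerometer magnitude channel unless
#' noted: LPCC cepstra (`lpc_order`/`n_cepstra`), warping distances to
#' every class reference in `bank`, state-space correlation entropy of
#' the magnitude, circular mean and sd of the x/y phase-angle series,
#' skewness and kurtosis, and (when an audio channel is present and
#' bands are configured) spectrogram band summaries. Windows where a
#' sub-feature fails (e.g. a constant segment) are dropped with a
#' warning stating the count.
#'
#' Columns are named `<channel>__<feature>__<index>`.
#'
#' @param ws a `window_set` (untapered segments).
#' @param bank a `reference_bank` built from the training split.
#' @param config list of options: `lpc_order` (default 12), `n_cepstra`
#'   (default 12), `ssce_m` (5), `ssce_tau` (1), `dtw_normalize` (TRUE),
#'   `acc_channels`, `phase_channels`, `audio_channel`, `spect_frame`
#'   (64), `spect_hop` (32), `spect_bands_hz` (NULL disables audio
#'   features).
#' @return a `feature_table` with one row per surviving window.
#' @export
extract_locomotion_features <- function(ws, bank, config = list()) {
  stopifnot(inherits(ws, "window_set"))
  if (n_windows(ws) == 0L) stop("window set is empty")
  cfg <- modifyList(list(
    lpc_order = 12L, n_cepstra = 12L, ssce_m = 5L, ssce_tau = 1L,
    dtw_normalize = TRUE, acc_channels = c("acc_x", "acc_y", "acc_z"),
    phase_channels = c("acc_x", "acc_y"), audio_channel = "audio",
    spect_frame = 64L, spect_hop = 32L, spect_bands_hz = NULL),
    config)
  missing_ch <- setdiff(cfg$acc_channels, names(ws$segments))
  if (length(missing_ch) > 0L)
    stop("missing accelerometer channel(s): ",
         paste(missing_ch, collapse = ", "))
  acc <- lapply(cfg$acc_channels, function(ch) ws$segments[[ch]])
  px <- ws$segments[[cfg$phase_channels[1]]]
  py <- ws$segments[[cfg$phase_channels[2]]]
  has_audio <- !is.null(cfg$spect_bands_hz) &&
    cfg$audio_channel %in% names(ws$segments)
  classes <- sort(names(bank))
  nm <- c(paste0("acc_mag__lpcc__", seq_len(cfg$n_cepstra)),
          paste0("acc_mag__dtw__", classes),
          "acc_mag__ssce__1",
          "acc_xy__phase_cmean__1", "acc_xy__phase_csd__1",
          "acc_mag__skewness__1", "acc_mag__kurtosis__1")
  if (has_audio)
    nm <- c(nm, paste0(cfg$audio_channel, "__band_logpower__",
                       seq_len(length(cfg$spect_bands_hz) - 1L)))
  rows <- vector("list", n_windows(ws))
  ok <- logical(n_windows(ws))
  for (i in seq_len(n_windows(ws))) {
    res <- tryCatch({
      m <- magnitude3(acc[[1]][i, ], acc[[2]][i, ], acc[[3]][i, ])
      a <- lpc_yule_walker(m, cfg$lpc_order)
      cep <- lpcc(a, cfg$n_cepstra)
      dtw <- dtw_features(m, bank, normalize = cfg$dtw_normalize)
      ent <- ssce(embed_series(m, m = cfg$ssce_m, tau = cfg$ssce_tau))
      ph <- suppressWarnings(phase_angle_series(px[i, ], py[i, ]))
      v <- c(cep, dtw, ent, circular_mean(ph), circular_sd(ph),
             skewness(m), kurtosis(m))
      if (has_audio) {
        sp <- power_spectrogram(ws$segments[[cfg$audio_channel]][i, ],
                                cfg$spect_frame, cfg$spect_hop,
                                ws$sampling_rate_hz)
        v <- c(v, spectral_band_features(sp, cfg$spect_bands_hz))
      }
      v
    }, error = function(e) NULL)
    if (!is.null(res) && all(is.finite(res))) {
      rows[[i]] <- res
      ok[i] <- TRUE
    }
  }
  if (!any(ok)) stop("feature extraction failed for every window")
  if (any(!ok))
    warning(sum(!ok), " window(s) dropped during locomotion feature ",
            "extraction")
  values <- do.call(rbind, rows[ok])
  colnames(values) <- nm
  ft <- feature_table(values, nm, ws$labels[ok])
  attr(ft, "window_index") <- which(ok)
  ft
}
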