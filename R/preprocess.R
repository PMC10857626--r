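#' Chebyshev Type I magnitude response
#'
#' Closed-form low-pass prototype gain
#' `1 / sqrt(1 + eps^2 * T_n(omega/omega0)^2)` where `eps` is the ripple
#' factor derived from the passband ripple in dB,
#' `eps = sqrt(10^(rp/10) - 1)`, and `T_n` is the Chebyshev polynomial of
#' the first kind evaluated by the three-term recurrence (valid on the
#' whole real line).
#'
#' @param n filter order (integer >= 1).
#' @param rp_db passband ripple in dB (> 0).
#' @param omega_ratio normalized frequency `omega / omega0` (>= 0); may be
#'   a vector.
#' @return gain(s) in `[0, 1]`.
#' @export
chebyshev1_magnitude <- function(n, rp_db, omega_ratio) {
  stopifnot(n >= 1, rp_db > 0, all(omega_ratio >= 0))
  eps2 <- 10^(rp_db / 10) - 1
  tn <- chebyshev_T(n, omega_ratio)
  1 / sqrt(1 + eps2 * tn^2)
}

# T_n(u) by the recurrence T_{k+1} = 2 u T_k - T_{k-1}; vectorized in u.
chebyshev_T <- function(n, u) {
  tkm1 <- rep(1, length(u))
  if (n == 0) return(tkm1)
  tk <- u
  if (n == 1) return(tk)
  for (k in 2:n) {
    tkp1 <- 2 * u * tk - tkm1
    tkm1 <- tk
    tk <- tkp1
  }
  tk
}

#' Design a digital Chebyshev Type I low-pass filter
#'
#' Realizes the analog prototype as a digital IIR filter via the bilinear
#' transform (through [signal::cheby1()]). The digital passband ripple is
#' at most `rp_db` and the gain at `cutoff_hz` equals the analog
#' band-edge gain `10^(-rp_db/20)`.
#'
#' @param n filter order; default 4.
#' @param rp_db passband ripple in dB; default 0.5.
#' @param cutoff_hz cutoff frequency in Hz, must be below Nyquist.
#' @param sampling_rate_hz sampling rate in Hz.
#' @return an object of class `filter_spec` with numerator `b`,
#'   denominator `a` (leading coefficient 1) and the design parameters.
#' @export
design_chebyshev1 <- function(n = 4, rp_db = 0.5, cutoff_hz,
                              sampling_rate_hz) {
  stopifnot(n >= 1, rp_db > 0, sampling_rate_hz > 0)
  nyq <- sampling_rate_hz / 2
  if (!(cutoff_hz > 0 && cutoff_hz < nyq))
    stop("cutoff_hz must lie strictly between 0 and the Nyquist frequency (",
         nyq, " Hz)")
  ba <- signal::cheby1(n, rp_db, W = cutoff_hz / nyq, type = "low")
  a <- as.numeric(ba$a)
  b <- as.numeric(ba$b) / a[1]
  a <- a / a[1]
  structure(
    list(b = b, a = a, order = as.integer(n), rp_db = rp_db,
         cutoff_hz = cutoff_hz, sampling_rate_hz = sampling_rate_hz),
    class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat("<filter_spec> Chebyshev-I low-pass | order", x$order,
      "| ripple", x$rp_db, "dB | cutoff", x$cutoff_hz, "Hz @",
      x$sampling_rate_hz, "Hz\n")
  invisible(x)
}

#' Frequency response magnitude of a designed filter
#'
#' @param spec a `filter_spec`.
#' @param freq_hz frequencies (Hz) at which to evaluate the response.
#' @return magnitude gains at `freq_hz`.
#' @export
filter_response <- function(spec, freq_hz) {
  w <- 2 * pi * freq_hz / spec$sampling_rate_hz
  vapply(w, function(wi) {
    zb <- exp(-1i * wi * (seq_along(spec$b) - 1))
    za <- exp(-1i * wi * (seq_along(spec$a) - 1))
    Mod(sum(spec$b * zb) / sum(spec$a * za))
  }, numeric(1))
}

# Steady-state filter state for a unit step input (so filtering a
# constant yields that constant from the first sample).
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  if (n == 1) return(numeric(0))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  A <- if (n == 2) matrix(-a[2], 1, 1) else
    rbind(-a[2:n], cbind(diag(1, n - 2), rep(0, n - 2)))
  B <- b[2:n] - a[2:n] * b[1]
  solve(diag(n - 1) - t(A), B)
}

# Forward-backward zero-phase filtering with odd-reflection padding of
# 3*(filter order) samples and steady-state initial conditions at both
# ends, so constants pass through exactly and edge transients are
# suppressed.
filtfilt_zero_phase <- function(b, a, x) {
  nfilt <- max(length(a), length(b))
  pad <- 3L * (nfilt - 1L)
  n <- length(x)
  if (n <= pad)
    stop("signal too short for zero-phase filtering: need more than ",
         pad, " samples, got ", n)
  ext <- c(2 * x[1] - x[(pad + 1):2], x,
           2 * x[n] - x[(n - 1):(n - pad)])
  zi <- lfilter_zi(b, a)
  y <- .iir_filter(b, a, ext, zi * ext[1])
  y <- rev(.iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1):(pad + n)]
}

#' Zero-phase denoising of selected channels
#'
#' Applies the designed low-pass filter forward and backward to each
#' selected channel, so the effective magnitude response is squared and
#' no phase shift is introduced — peak timings used by step detection
#' are preserved. Edges are handled by odd-reflection padding with
#' steady-state initial filter conditions. Labels, length and
#' unselected channels are untouched.
#'
#' @param recording a `sensor_recording`.
#' @param spec a `filter_spec`.
#' @param channels character vector of channel names to filter; default
#'   all channels.
#' @return a new `sensor_recording` with filtered channels.
#' @export
denoise <- function(recording, spec, channels = names(recording$channels)) {
  stopifnot(inherits(recording, "sensor_recording"),
            inherits(spec, "filter_spec"))
  unknown <- setdiff(channels, names(recording$channels))
  if (length(unknown) > 0L)
    stop("unknown channel(s): ", paste(unknown, collapse = ", "))
  n <- n_samples(recording)
  if (n <= 3L * spec$order)
    stop("signal too short for stable zero-phase filtering: need more than ",
         3L * spec$order, " samples, got ", n)
  out <- recording
  for (ch in channels) {
    out$channels[[ch]] <-
      filtfilt_zero_phase(spec$b, spec$a, recording$channels[[ch]])
  }
  out
}

#' Hamming window coefficients
#'
#' `w(x) = 0.54 - 0.46 * cos(2*pi*x / (X - 1))` for `x = 0 .. X-1`.
#' Endpoints equal 0.08; for odd `X` the center coefficient is exactly 1.
#'
#' @param X window length in samples (>= 2).
#' @return numeric vector of `X` coefficients in `[0.08, 1]`.
#' @export
hamming_window <- function(X) {
  if (!(is.numeric(X) && length(X) == 1L && X >= 2 && X == round(X)))
    stop("`X` must be a single integer >= 2")
  x <- 0:(X - 1)
  0.54 - 0.46 * cos(2 * pi * x / (X - 1))
}

#' Segment a recording into overlapping windows
#'
#' Windows are half-open `[start, start + window_length)` with 0-based
#' starts `0, step, 2*step, ...` while the window fits; the count is
#' `floor((N - window_length)/step) + 1`. Each window receives the
#' majority label of its samples via [assign_window_label()]. With
#' `taper = TRUE` every channel segment is multiplied pointwise by the
#' Hamming window; the default keeps raw segments so temporal features
#' (step peaks, warping distances, moments) are undistorted, and
#' spectral consumers taper on their own.
#'
#' @param recording a `sensor_recording`.
#' @param window_length window length in samples; default 100.
#' @param step hop between window starts in samples; default 50
#'   (50% overlap).
#' @param taper logical; multiply segments by the Hamming window.
#' @return an object of class `window_set` with per-channel
#'   `n_windows x window_length` segment matrices, 0-based `starts`,
#'   per-window `labels` and the sampling rate. A recording shorter than
#'   one window yields an empty window set with a warning.
#' @export
segment <- function(recording, window_length = 100, step = 50,
                    taper = FALSE) {
  stopifnot(inherits(recording, "sensor_recording"))
  if (!(window_length >= 2)) stop("`window_length` must be >= 2")
  if (!(step >= 1 && step <= window_length))
    stop("`step` must satisfy 1 <= step <= window_length")
  window_length <- as.integer(window_length)
  step <- as.integer(step)
  n <- n_samples(recording)
  if (n < window_length) {
    warning("recording shorter (", n, ") than one window (", window_length,
            "); returning an empty window set")
    starts <- integer(0)
  } else {
    starts <- seq.int(0L, n - window_length, by = step)
  }
  idx <- outer(starts + 1L, 0:(window_length - 1L), `+`)  # 1-based indexing
  w <- if (taper) hamming_window(window_length) else NULL
  segments <- lapply(recording$channels, function(ch) {
    m <- matrix(ch[idx], nrow = length(starts), ncol = window_length)
    if (!is.null(w) && length(starts) > 0L)
      m <- sweep(m, 2L, w, `*`)
    m
  })
  labels <- vapply(seq_along(starts), function(i)
    assign_window_label(recording$labels[idx[i, ]]), character(1))
  structure(
    list(window_length = window_length, step = step, starts = starts,
         segments = segments, labels = labels, tapered = isTRUE(taper),
         sampling_rate_hz = recording$sampling_rate_hz,
         subject_id = recording$subject_id),
    class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat("<window_set>", length(x$starts), "windows of", x$window_length,
      "samples (step", x$step, ") |",
      length(x$segments), "channels | tapered:", x$tapered, "\n")
  invisible(x)
}

#' Number of windows in a window set
#' @param ws a `window_set`.
#' @return integer window count.
#' @export
n_windows <- function(ws) length(ws$starts)
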