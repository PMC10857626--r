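#' Step detection from tri-axial acceleration
#'
#' Consolidates the three accelerometer axes into the magnitude
#' `M = sqrt(bx^2 + by^2 + bz^2)` and detects steps as local maxima of
#' `M` that exceed a relative threshold `T = t_frac * mean(M)` and are
#' separated by at least `d_s` seconds (the expected gait cadence
#' floor). When two candidate peaks are closer than the minimum
#' separation the taller one is kept (greedy, tallest-first), which is
#' deterministic.
#'
#' The threshold is relative to the mean magnitude, so the step count is
#' invariant to uniform scaling and robust to the constant gravity
#' offset.
#'
#' @param acc_x,acc_y,acc_z equal-length accelerometer axis streams
#'   (length >= 2).
#' @param fs sampling rate in Hz.
#' @param t_frac threshold as a fraction of the mean magnitude;
#'   default 1.1.
#' @param d_s minimum peak separation in seconds; default 0.3
#'   (about a 3.3 steps/s cadence ceiling).
#' @return object of class `step_detection` with 1-based `peaks`,
#'   `step_count`, the `threshold` used, and the magnitude series.
#' @export
detect_steps <- function(acc_x, acc_y, acc_z, fs, t_frac = 1.1,
                         d_s = 0.3) {
  if (length(acc_x) < 2L) stop("need at least 2 samples")
  stopifnot(fs > 0)
  d_samp <- d_s * fs
  if (d_samp < 1) stop("degenerate separation: d_s * fs must be >= 1")
  M <- magnitude3(acc_x, acc_y, acc_z)
  thr <- t_frac * mean(M)
  n <- length(M)
  is_max <- if (n >= 3L) {
    c(FALSE, M[2:(n - 1)] > M[1:(n - 2)] & M[2:(n - 1)] > M[3:n], FALSE)
  } else rep(FALSE, n)
  cand <- which(is_max & M > thr)
  accepted <- integer(0)
  if (length(cand) > 0L) {
    for (i in cand[order(-M[cand], cand)]) {   # tallest first, then earliest
      if (all(abs(accepted - i) >= d_samp)) accepted <- c(accepted, i)
    }
    accepted <- sort(accepted)
  }
  structure(
    list(peaks = accepted, step_count = length(accepted), threshold = thr,
         t_frac = t_frac, d_s = d_s, fs = fs, magnitude = M),
    class = "step_detection")
}

#' @export
print.step_detection <- function(x, ...) {
  cat("<step_detection>", x$step_count, "steps | threshold",
      signif(x$threshold, 4), "| min separation", x$d_s, "s\n")
  invisible(x)
}

#' Magnetometer heading series in degrees
#'
#' Absolute heading from the horizontal magnetometer axes:
#' `H = atan2(mag_y, mag_x) * 180/pi mod 360`, in `[0, 360)`. Samples
#' with both components zero yield 0 with a warning. No tilt
#' compensation is applied.
#'
#' @param mag_x,mag_y equal-length magnetometer axis streams.
#' @return numeric heading sequence in `[0, 360)` degrees.
#' @export
heading_series <- function(mag_x, mag_y) {
  if (length(mag_x) != length(mag_y))
    stop("mag_x and mag_y must have equal lengths")
  if (any(mag_x == 0 & mag_y == 0))
    warning("heading undefined where both magnetometer axes are 0; ",
            "returning 0 there")
  (atan2(mag_y, mag_x) * 180 / pi) %% 360
}

# Arc length (degrees) spanned by a set of angles: 360 minus the largest
# gap between consecutive sorted angles on the circle.
heading_range <- function(deg) {
  a <- sort(deg %% 360)
  if (length(a) < 2L) return(0)
  gaps <- c(diff(a), 360 - (a[length(a)] - a[1]))
  360 - max(gaps)
}

#' Localization feature bank
#'
#' Per window: step count and mean inter-peak interval (seconds; 0 when
#' fewer than 2 peaks) from [detect_steps()], circular mean, circular sd
#' and angular range of the magnetometer heading, and skewness and
#' kurtosis of the accelerometer magnitude — 7 features named
#' `loc__<feature>__1`.
#'
#' @param ws a `window_set` containing accelerometer and magnetometer
#'   channels.
#' @param config list of options: `acc_channels`, `mag_channels`
#'   (x/y pair), `t_frac` (1.1), `d_s` (0.3).
#' @return a `feature_table` with one row per surviving window.
#' @export
extract_localization_features <- function(ws, config = list()) {
  stopifnot(inherits(ws, "window_set"))
  if (n_windows(ws) == 0L) stop("window set is empty")
  cfg <- modifyList(list(
    acc_channels = c("acc_x", "acc_y", "acc_z"),
    mag_channels = c("mag_x", "mag_y"),
    t_frac = 1.1, d_s = 0.3), config)
  need <- c(cfg$acc_channels, cfg$mag_channels)
  missing_ch <- setdiff(need, names(ws$segments))
  if (length(missing_ch) > 0L)
    stop("missing channel(s): ", paste(missing_ch, collapse = ", "))
  fs <- ws$sampling_rate_hz
  acc <- lapply(cfg$acc_channels, function(ch) ws$segments[[ch]])
  mx <- ws$segments[[cfg$mag_channels[1]]]
  my <- ws$segments[[cfg$mag_channels[2]]]
  nm <- c("loc__step_count__1", "loc__step_interval__1",
          "loc__heading_cmean__1", "loc__heading_csd__1",
          "loc__heading_range__1", "loc__skewness__1", "loc__kurtosis__1")
  rows <- vector("list", n_windows(ws))
  ok <- logical(n_windows(ws))
  for (i in seq_len(n_windows(ws))) {
    res <- tryCatch({
      sd_ <- detect_steps(acc[[1]][i, ], acc[[2]][i, ], acc[[3]][i, ],
                          fs, cfg$t_frac, cfg$d_s)
      interval <- if (sd_$step_count >= 2L) mean(diff(sd_$peaks)) / fs else 0
      h <- suppressWarnings(heading_series(mx[i, ], my[i, ]))
      m <- sd_$magnitude
      c(sd_$step_count, interval, circular_mean(h) %% 360,
        circular_sd(h), heading_range(h), skewness(m), kurtosis(m))
    }, error = function(e) NULL)
    if (!is.null(res) && all(is.finite(res))) {
      rows[[i]] <- res
      ok[i] <- TRUE
    }
  }
  if (!any(ok)) stop("feature extraction failed for every window")
  if (any(!ok))
    warning(sum(!ok), " window(s) dropped during localization feature ",
            "extraction")
  values <- do.call(rbind, rows[ok])
  colnames(values) <- nm
  ft <- feature_table(values, nm, ws$labels[ok])
  attr(ft, "window_index") <- which(ok)
  ft
}
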