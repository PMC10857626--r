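#' Specification of one synthetic activity class
#'
#' Describes the quasi-periodic accelerometer signature and magnetometer
#' heading behavior of an activity: a fundamental gait frequency (0 for
#' static classes such as standing or lying), per-axis amplitudes,
#' decaying harmonics, additive wideband Gaussian noise, and one of
#' three heading behaviors — `fixed` (constant angle), `walk` (random
#' walk with a per-sample sd), or `sweep` (linear sweep across a span).
#'
#' @param name class label.
#' @param freq_hz fundamental gait frequency in Hz (>= 0; must stay
#'   below Nyquist of the generated rate).
#' @param amplitude per-axis acceleration amplitude in g; scalar or
#'   length-3 vector.
#' @param harmonics number of harmonics (amplitude decays as 1/h).
#' @param noise_sd accelerometer noise sd in g (>= 0).
#' @param heading list: `type` in `c("fixed", "walk", "sweep")`,
#'   `value` (degrees; start angle), `sd` (walk step sd, degrees),
#'   `span` (sweep extent, degrees).
#' @param weight prevalence weight used when composing imbalanced
#'   scenarios.
#' @return list of class `activity_spec`.
#' @export
activity_spec <- function(name, freq_hz, amplitude = 0.5, harmonics = 2,
                          noise_sd = 0.05,
                          heading = list(type = "fixed", value = 90),
                          weight = 1) {
  stopifnot(freq_hz >= 0, noise_sd >= 0, harmonics >= 1, weight > 0)
  if (length(amplitude) == 1L) amplitude <- rep(amplitude, 3L)
  stopifnot(length(amplitude) == 3L)
  heading <- modifyList(list(type = "fixed", value = 90, sd = 2,
                             span = 180), heading)
  if (!heading$type %in% c("fixed", "walk", "sweep"))
    stop("heading$type must be one of fixed/walk/sweep")
  structure(list(name = name, freq_hz = freq_hz, amplitude = amplitude,
                 harmonics = as.integer(harmonics), noise_sd = noise_sd,
                 heading = heading, weight = weight),
            class = "activity_spec")
}

#' The default activity bank
#'
#' Four well-separated classes spanning the static-to-vigorous range:
#' `standing` (static, tiny noise), `walking` (2 Hz gait), `running`
#' (3.5 Hz, larger amplitude), and `climbing` (1 Hz, asymmetric axes) —
#' all fundamentals well inside the passband of the default 5 Hz cutoff
#' at 50 Hz so denoising does not erase the class signal.
#'
#' @return named list of [activity_spec()]s.
#' @export
default_activity_bank <- function() {
  specs <- list(
    activity_spec("standing", 0, amplitude = 0, noise_sd = 0.03,
                  heading = list(type = "fixed", value = 45)),
    activity_spec("walking", 2.0, amplitude = c(0.25, 0.2, 0.45),
                  noise_sd = 0.05,
                  heading = list(type = "walk", value = 90, sd = 1.5)),
    activity_spec("running", 3.5, amplitude = c(0.6, 0.5, 1.1),
                  noise_sd = 0.08,
                  heading = list(type = "walk", value = 180, sd = 3)),
    activity_spec("climbing", 1.0, amplitude = c(0.5, 0.15, 0.3),
                  noise_sd = 0.05,
                  heading = list(type = "sweep", value = 270, span = 90)))
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Scenario: an ordered sequence of activity bouts
#'
#' @param bouts data frame with columns `class` and `duration_s`.
#' @param sampling_rate_hz sampling rate; default 50 Hz.
#' @param seed seed fixing all generator randomness.
#' @param subject_id subject identifier for the output recording.
#' @return list of class `scenario_spec`.
#' @export
scenario_spec <- function(bouts, sampling_rate_hz = 50, seed = 1,
                          subject_id = "synth-1") {
  bouts <- as.data.frame(bouts)
  stopifnot(all(c("class", "duration_s") %in% names(bouts)),
            nrow(bouts) >= 1, all(bouts$duration_s > 0),
            sampling_rate_hz > 0)
  structure(list(bouts = bouts, sampling_rate_hz = sampling_rate_hz,
                 seed = as.integer(seed), subject_id = subject_id),
            class = "scenario_spec")
}

#' A balanced default scenario cycling through the activity bank
#'
#' Composes `cycles` rounds over the bank's classes, `bout_s` seconds
#' each, at 50 Hz. Used as the study condition for end-to-end runs.
#'
#' @param bank activity bank; default [default_activity_bank()].
#' @param cycles rounds through the classes; default 5.
#' @param bout_s seconds per bout; default 20.
#' @param sampling_rate_hz sampling rate; default 50.
#' @param seed generator seed.
#' @return a `scenario_spec`.
#' @export
default_scenario <- function(bank = default_activity_bank(), cycles = 5,
                             bout_s = 20, sampling_rate_hz = 50,
                             seed = 1) {
  classes <- names(bank)
  bouts <- data.frame(class = rep(classes, cycles),
                      duration_s = bout_s)
  scenario_spec(bouts, sampling_rate_hz, seed)
}

#' Generate a labeled multi-sensor recording
#'
#' Per bout, the accelerometer is a constant 1 g gravity offset on the
#' z-axis plus a sum of `1/h`-decaying harmonics at the class
#' fundamental, plus Gaussian noise; the gyroscope carries a scaled,
#' phase-shifted copy of the oscillation; the magnetometer is a unit
#' horizontal field rotated by the class's heading trajectory (plus
#' small noise) with a constant vertical component. Labels are painted
#' per bout. Fully deterministic under the scenario seed.
#'
#' @param scenario a `scenario_spec`.
#' @param bank named list of [activity_spec()]s covering every bout
#'   class.
#' @param mag_noise_sd magnetometer noise sd; default 0.02.
#' @return a [sensor_recording()] with channels `acc_x/y/z`,
#'   `gyr_x/y/z`, `mag_x/y/z`.
#' @export
generate_recording <- function(scenario, bank = default_activity_bank(),
                               mag_noise_sd = 0.02) {
  stopifnot(inherits(scenario, "scenario_spec"))
  missing_cls <- setdiff(unique(scenario$bouts$class), names(bank))
  if (length(missing_cls) > 0L)
    stop("bout class(es) missing from the bank: ",
         paste(missing_cls, collapse = ", "))
  fs <- scenario$sampling_rate_hz
  nyq <- fs / 2
  for (sp in bank)
    if (sp$freq_hz * sp$harmonics >= nyq && sp$freq_hz > 0)
      warning("class ", sp$name, ": harmonics reach Nyquist; aliasing")
  set.seed(scenario$seed)
  acc <- list(x = numeric(0), y = numeric(0), z = numeric(0))
  gyr <- list(x = numeric(0), y = numeric(0), z = numeric(0))
  mag <- list(x = numeric(0), y = numeric(0), z = numeric(0))
  labels <- character(0)
  for (bi in seq_len(nrow(scenario$bouts))) {
    cls <- scenario$bouts$class[bi]
    sp <- bank[[cls]]
    n <- round(scenario$bouts$duration_s[bi] * fs)
    t <- (seq_len(n) - 1) / fs
    phase <- runif(1, 0, 2 * pi)
    osc <- function(amp, extra_phase) {
      if (sp$freq_hz == 0 || amp == 0) return(numeric(n) * 0)
      s <- 0
      for (h in seq_len(sp$harmonics))
        s <- s + (amp / h) * sin(2 * pi * h * sp$freq_hz * t +
                                 phase + extra_phase)
      s
    }
    acc$x <- c(acc$x, osc(sp$amplitude[1], 0) + rnorm(n, 0, sp$noise_sd))
    acc$y <- c(acc$y, osc(sp$amplitude[2], pi / 2) +
                 rnorm(n, 0, sp$noise_sd))
    acc$z <- c(acc$z, 1 + osc(sp$amplitude[3], pi / 4) +
                 rnorm(n, 0, sp$noise_sd))
    gyr$x <- c(gyr$x, 0.5 * osc(sp$amplitude[1], pi / 3) +
                 rnorm(n, 0, sp$noise_sd))
    gyr$y <- c(gyr$y, 0.5 * osc(sp$amplitude[2], 2 * pi / 3) +
                 rnorm(n, 0, sp$noise_sd))
    gyr$z <- c(gyr$z, 0.3 * osc(sp$amplitude[3], pi) +
                 rnorm(n, 0, sp$noise_sd))
    hd <- sp$heading
    theta <- switch(hd$type,
      fixed = rep(hd$value, n),
      walk = hd$value + cumsum(rnorm(n, 0, hd$sd)),
      sweep = hd$value + seq(0, hd$span, length.out = n))
    th <- theta * pi / 180
    mag$x <- c(mag$x, cos(th) + rnorm(n, 0, mag_noise_sd))
    mag$y <- c(mag$y, sin(th) + rnorm(n, 0, mag_noise_sd))
    mag$z <- c(mag$z, 0.5 + rnorm(n, 0, mag_noise_sd))
    labels <- c(labels, rep(cls, n))
  }
  sensor_recording(
    list(acc_x = acc$x, acc_y = acc$y, acc_z = acc$z,
         gyr_x = gyr$x, gyr_y = gyr$y, gyr_z = gyr$z,
         mag_x = mag$x, mag_y = mag$y, mag_z = mag$z),
    labels, fs, scenario$subject_id)
}

#' Generate a stationary autoregressive series
#'
#' `x_t = sum_j coeffs_j x_{t-j} + e_t`, `e ~ N(0, sd^2)`, with burn-in
#' discarded (via [stats::arima.sim()]); used as a ground-truth
#' generator for linear-prediction recovery checks. Empty `coeffs`
#' yields white noise.
#'
#' @param coeffs AR coefficients; the AR polynomial must have all roots
#'   outside the unit circle.
#' @param n series length.
#' @param noise_sd innovation sd; default 1.
#' @param seed RNG seed.
#' @return numeric series of length `n`.
#' @export
generate_ar_series <- function(coeffs, n, noise_sd = 1, seed = 1) {
  stopifnot(n >= 1, noise_sd >= 0)
  set.seed(seed)
  if (length(coeffs) == 0L) return(rnorm(n, 0, noise_sd))
  roots <- polyroot(c(1, -coeffs))
  if (any(Mod(roots) <= 1))
    stop("non-stationary AR coefficients: roots inside the unit circle")
  as.numeric(stats::arima.sim(model = list(ar = coeffs), n = n,
                              sd = noise_sd,
                              n.start = max(10L * length(coeffs), 50L)))
}

#' Generate an imbalanced Gaussian-cluster feature table
#'
#' Each class is a unit-variance Gaussian cluster centered at
#' `separation` along its own coordinate direction (directions cycle
#' when there are more classes than features); per-class counts are
#' exact. A fixture generator for oversampling and feature-selection
#' studies mimicking heavy majority:minority skew.
#'
#' @param n_per_class named integer vector of class counts (>= 2
#'   classes).
#' @param n_features number of feature columns.
#' @param separation distance of each class center from the origin;
#'   0 makes the features class-blind.
#' @param seed RNG seed.
#' @return a `feature_table` with features `f1 .. f<n_features>`.
#' @export
generate_imbalanced_table <- function(n_per_class, n_features = 5,
                                      separation = 3, seed = 1) {
  if (is.null(names(n_per_class)) || length(n_per_class) < 2L)
    stop("`n_per_class` must be a named vector with >= 2 classes")
  stopifnot(all(n_per_class >= 1), n_features >= 1)
  set.seed(seed)
  classes <- names(n_per_class)
  rows <- list()
  labels <- character(0)
  for (k in seq_along(classes)) {
    nk <- n_per_class[[k]]
    center <- numeric(n_features)
    center[(k - 1L) %% n_features + 1L] <- separation
    rows[[k]] <- matrix(rnorm(nk * n_features), nk, n_features) +
      matrix(center, nk, n_features, byrow = TRUE)
    labels <- c(labels, rep(classes[k], nk))
  }
  feature_table(do.call(rbind, rows), paste0("f", seq_len(n_features)),
                labels)
}
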