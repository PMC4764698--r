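#' Gaussian ERP kernel
#'
#' The deflection model used by the simulator: a Gaussian bump whose peak
#' equals `amplitude` at `latency` and which decays to ~0 beyond about three
#' kernel SDs. Its time integral is `amplitude * width * sqrt(2*pi)`.
#'
#' @param param A [component_param()] (or any list with `amplitude`,
#'   `latency`, `width`).
#' @param time_ms Numeric time axis, ms.
#' @return Waveform in microvolts, same length as `time_ms`.
#' @export
erp_kernel <- function(param, time_ms) {
  if (param$width <= 0) stop("simulation error: width must be positive")
  if (param$latency < min(time_ms) || param$latency > max(time_ms))
    stop("simulation error: latency outside the time axis")
  param$amplitude * exp(-0.5 * ((time_ms - param$latency) / param$width)^2)
}

#' 1/f ("pink") background noise
#'
#' Synthesizes Gaussian noise with power spectral density proportional to
#' `f^slope` above `f_min` (flat below, to avoid a DC singularity), scaled to
#' the requested RMS. Built by spectrally shaping white noise, so the result
#' is exactly Hermitian-symmetric and reproducible under the current RNG
#' state.
#'
#' @param n Number of samples.
#' @param fs Sampling rate, Hz.
#' @param rms Target standard deviation, microvolts.
#' @param slope Spectral (power) slope; -1 gives pink noise.
#' @param f_min Corner frequency below which the spectrum is flat, Hz.
#' @export
pink_noise <- function(n, fs, rms = 1, slope = -1, f_min = 0.5) {
  pink_noise_matrix(n, 1L, fs, rms, slope, f_min)[, 1]
}

## several independent channels at once; two real channels ride in one
## complex FFT pair (a real spectral gain filters the real and imaginary
## parts independently), halving the transform count
pink_noise_matrix <- function(n, nch, fs, rms = 1, slope = -1,
                              f_min = 0.5) {
  out <- matrix(0, n, nch)
  if (rms == 0) return(out)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  g <- pmax(f, f_min)^(slope / 2)
  g[1] <- 0
  for (j in seq(1L, nch, by = 2L)) {
    z <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
    y <- stats::fft(stats::fft(z) * g, inverse = TRUE) / n
    out[, j] <- Re(y)
    if (j + 1L <= nch) out[, j + 1L] <- Im(y)
  }
  out * rep(rms / apply(out, 2, stats::sd), each = n)
}

#' Measurement-pipeline gain for a Gaussian kernel
#'
#' The standard analysis chain (zero-phase 4th-order Butterworth bandpass
#' followed by a 40-ms window mean at the filtered peak) does not return a
#' Gaussian deflection's peak amplitude: the window mean averages over the
#' flanks and the highpass removes the kernel's net area, and both losses
#' grow with kernel width. This function measures that end-to-end gain for a
#' unit-amplitude kernel of SD `width_ms` by running a clean kernel through
#' the same filter. The simulator divides injected kernel peaks by this gain
#' (amplitude calibration), so that a component's `amplitude` parameter is on
#' the scale the pipeline actually reports - the scale on which empirical
#' mean amplitudes are printed.
#'
#' @param width_ms Kernel SD, ms.
#' @param band Analysis bandpass edges, Hz.
#' @param fs Sampling rate, Hz.
#' @param window Quantification window width, ms.
#' @return Scalar gain in (0, 1].
#' @export
pipeline_gain <- function(width_ms, band = c(0.5, 25), fs = 1024,
                          window = 40) {
  key <- paste(width_ms, band[1], band[2], fs, window, sep = "|")
  hit <- .gain_cache[[key]]
  if (!is.null(hit)) return(hit)
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  pad_ms <- max(10000, 20 * width_ms)
  n <- round(2 * pad_ms / 1000 * fs)
  t <- (seq_len(n) - 1) / fs * 1000
  y <- signal::filtfilt(bf, exp(-0.5 * ((t - pad_ms) / width_ms)^2))
  pk <- which.max(y)
  g <- mean(y[abs(t - t[pk]) <= window / 2])
  .gain_cache[[key]] <- g
  g
}

.gain_cache <- new.env(parent = emptyenv())

## Joint calibration within a topography group: filter rebound from one
## kernel leaks into the others' measurement windows (e.g. the MMN's
## highpass rebound inflates the P3a window), and per-epoch baseline
## correction shifts every window by the filtered kernels' baseline mean.
## Solve G %*% peaks = targets, where G[i, j] is the baseline-corrected,
## filtered response of a unit kernel j inside component i's 40-ms window
## at its true latency.
calibration_peaks <- function(comps, band, fs, width = 40,
                              baseline = c(-100, 0)) {
  lat <- vapply(comps, `[[`, numeric(1), "latency")
  wd <- vapply(comps, `[[`, numeric(1), "width")
  amps <- vapply(comps, `[[`, numeric(1), "amplitude")
  key <- paste(c("G", round(lat, 3), round(wd, 3), band, fs, width),
               collapse = "|")
  G <- .gain_cache[[key]]
  if (is.null(G)) {
    k <- length(comps)
    pad_ms <- 5000
    t_ms <- seq(-pad_ms, max(lat + 5 * wd) + pad_ms, by = 1000 / fs)
    bf <- signal::butter(4, band / (fs / 2), type = "pass")
    ib <- t_ms >= baseline[1] & t_ms <= baseline[2]
    G <- matrix(0, k, k)
    for (j in seq_len(k)) {
      y <- signal::filtfilt(bf, exp(-0.5 * ((t_ms - lat[j]) / wd[j])^2))
      y <- y - mean(y[ib])
      for (i in seq_len(k))
        G[i, j] <- mean(y[t_ms >= lat[i] - width / 2 &
                            t_ms <= lat[i] + width / 2])
    }
    .gain_cache[[key]] <- G
  }
  as.numeric(solve(G, amps))
}

gauss_bump <- function(n, fs, t0_ms, width_ms) {
  # discrete support of a unit gaussian centred at t0 (ms), +-5 SD
  i0 <- max(1L, floor((t0_ms - 5 * width_ms) / 1000 * fs) + 1L)
  i1 <- min(n, ceiling((t0_ms + 5 * width_ms) / 1000 * fs) + 1L)
  if (i1 < i0) return(NULL)
  t <- ((i0:i1) - 1L) / fs * 1000
  list(idx = i0:i1, val = exp(-0.5 * ((t - t0_ms) / width_ms)^2))
}

#' Simulate a continuous EEG recording for one subject and schedule
#'
#' Builds a channels-by-time signal (stored as a samples x channels matrix)
#' consisting of independent 1/f background noise per channel, plus, at each
#' deviant target marker, the subject's component kernels for the given task
#' projected through their scalp topographies, plus blink artifacts (Poisson
#' events at the profile's blink rate; Gaussian waveform of SD 50 ms on the
#' EOG channels at full amplitude, attenuated on frontal scalp sites). The
#' signal is generated directly in the analysis reference, and marker sample
#' indices are attached. In the `"control"` task (deviant-only stream) no
#' components are injected: omissions are not rare there, so they elicit no
#' deviance response.
#'
#' @param profile A [subject_profile()].
#' @param schedule A `beat_schedule`.
#' @param task "ignore", "attend" or "control"; selects which of the
#'   profile's components are active (none for "control").
#' @param seed Integer seed.
#' @param fs Sampling rate, Hz.
#' @param channels Montage, as from [default_montage()].
#' @param calibrate Scale injected kernel peaks by the inverse
#'   [pipeline_gain()] so component amplitudes are on the post-pipeline
#'   measurement scale (default). Set to FALSE for noiseless arithmetic
#'   checks on unfiltered data.
#' @param band Analysis band assumed by the calibration, Hz.
#' @return An object of class `eeg_recording`: list with `signal` (samples x
#'   channels matrix, microvolts), `fs`, `channels`, `markers` (data.frame
#'   `sample`, `onset_ms`, `code`, `label`) and `duration_ms`.
#' @export
simulate_recording <- function(profile, schedule,
                               task = c("ignore", "attend", "control"),
                               seed = 1L, fs = 1024,
                               channels = default_montage(),
                               calibrate = TRUE, band = c(0.5, 25)) {
  task <- match.arg(task)
  stopifnot(inherits(profile, "subject_profile"),
            inherits(schedule, "beat_schedule"))
  if (!length(channels)) stop("configuration error: empty channel montage")
  if (schedule$n_sequences < 1L) stop("simulation error: empty schedule")
  set.seed(seed)
  n <- round(schedule$duration_ms / 1000 * fs)
  nch <- length(channels)
  sig <- pink_noise_matrix(n, nch, fs, rms = profile$noise_rms)
  dimnames(sig) <- list(NULL, channels)

  markers <- schedule$events
  markers$sample <- round(markers$onset_ms / 1000 * fs) + 1L
  markers <- markers[, c("sample", "onset_ms", "code", "label")]

  if (task != "control") {
    comps <- Filter(function(cp) cp$task == task, profile$components)
    dev_onsets <- markers$onset_ms[markers$code == MARKER_DEVIANT]
    ## calibrated peak amplitudes, solved jointly per topography group
    peaks <- vapply(comps, `[[`, numeric(1), "amplitude")
    if (calibrate && length(comps)) {
      topo <- vapply(comps, `[[`, character(1), "topography")
      for (grp in unique(topo)) {
        sel <- topo == grp
        peaks[sel] <- calibration_peaks(comps[sel], band, fs)
      }
    }
    for (ci in seq_along(comps)) {
      cp <- comps[[ci]]
      amp <- peaks[ci]
      if (amp == 0) next
      w <- topography_map(cp$topography, channels)
      act <- which(w != 0)
      for (t0 in dev_onsets) {
        b <- gauss_bump(n, fs, t0 + cp$latency, cp$width)
        if (is.null(b)) next
        sig[b$idx, act] <- sig[b$idx, act] +
          outer(amp * b$val, w[act])
      }
    }
  }

  if (profile$blink_rate > 0 && profile$blink_amplitude != 0) {
    n_blinks <- stats::rpois(1, profile$blink_rate *
                               schedule$duration_ms / 60000)
    if (n_blinks > 0) {
      wb <- topography_map("blink", channels)
      act <- which(wb != 0)
      times <- sort(stats::runif(n_blinks, 0, schedule$duration_ms))
      for (t0 in times) {
        b <- gauss_bump(n, fs, t0, 50)
        if (is.null(b)) next
        sig[b$idx, act] <- sig[b$idx, act] +
          outer(profile$blink_amplitude * b$val, wb[act])
      }
    }
  }

  structure(list(signal = sig, fs = fs, channels = channels,
                 markers = markers, duration_ms = schedule$duration_ms),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d markers\n",
              ncol(x$signal), nrow(x$signal), x$fs, x$duration_ms / 1000,
              nrow(x$markers)))
  invisible(x)
}

#' Simulate attend-task keypress responses
#'
#' One response per trial: "deviant" with probability `p_hit` on deviant
#' trials and `p_fa` on standard trials, otherwise "standard". Reaction times
#' are Gaussian (mean/SD from the profile, truncated at zero), measured from
#' trial onset.
#'
#' @param profile A [subject_profile()].
#' @param trials An attend `beat_schedule` (uses its `trials` table).
#' @param seed Integer seed.
#' @return data.frame with `trial`, `response` ("deviant"/"standard"),
#'   `rt` (seconds).
#' @export
simulate_behavior <- function(profile, trials, seed = 1L) {
  stopifnot(inherits(trials, "beat_schedule"),
            !is.null(trials$trials))
  set.seed(seed)
  tab <- trials$trials
  p <- ifelse(tab$deviant, profile$p_hit, profile$p_fa)
  resp <- ifelse(stats::runif(nrow(tab)) < p, "deviant", "standard")
  rt <- abs(stats::rnorm(nrow(tab), profile$rt_mean, profile$rt_sd))
  data.frame(trial = tab$trial, response = resp, rt = rt,
             stringsAsFactors = FALSE)
}
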