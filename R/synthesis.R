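# Rendering band specifications into calibrated audio.
#
# Bursts are Gaussian noise band-limited by a 10th-order Butterworth
# bandpass (second-order sections, causal), optionally 100%-depth
# sinusoidally amplitude modulated, shaped by 8-ms raised-cosine ramps and
# scaled to the calibration convention below.  Fresh noise is drawn for
# every burst.

#' Default sampling rate (Hz)
#' @export
STREAMSEG_FS <- 44100

# Calibration: 60 dB SPL maps to digital RMS 0.05.  Absolute SPL needs a
# measured playback chain; the constant is arbitrary but fixed, leaving
# ~26 dB of headroom for level differences and modulation peaks.
LEVEL_REF_DB <- 60
LEVEL_REF_RMS <- 0.05

#' Digital RMS corresponding to a nominal sound pressure level
#'
#' @param level_db level in dB SPL.
#' @return target RMS amplitude (full scale +/- 1).
#' @export
level_to_rms <- function(level_db) {
  LEVEL_REF_RMS * 10^((level_db - LEVEL_REF_DB) / 20)
}

#' Construct a waveform object
#'
#' @param samples numeric vector of amplitudes (full scale +/- 1).
#' @param fs sampling rate in Hz.
#' @return a `waveform` object.
#' @export
waveform <- function(samples, fs = STREAMSEG_FS) {
  stopifnot(is.numeric(samples), fs > 0)
  structure(list(samples = as.numeric(samples), fs = fs), class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %.3f s at %g Hz (peak %.3f, rms %.4f)\n",
              length(x$samples) / x$fs, x$fs,
              if (length(x$samples)) max(abs(x$samples)) else 0,
              if (length(x$samples)) sqrt(mean(x$samples^2)) else 0))
  invisible(x)
}

raised_cosine_ramps <- function(n, n_ramp) {
  env <- rep(1, n)
  if (n_ramp > 0) {
    ramp <- sin(pi / 2 * seq(0, 1, length.out = n_ramp))^2
    env[seq_len(n_ramp)] <- ramp
    env[n - n_ramp + seq_len(n_ramp)] <- rev(ramp)
  }
  env
}

#' Synthesise one narrowband-noise burst
#'
#' @param spec a [band_spec()].
#' @param duration_ms burst duration in ms (default 80, including the ramps).
#' @param ramp_ms rise/fall raised-cosine ramp duration in ms.
#' @param fs sampling rate in Hz.
#' @param seed optional integer seed for the noise draw.
#' @return a [waveform()] of `round(duration_ms / 1000 * fs)` samples whose
#'   RMS realises `spec$level` under the package calibration.  A spec with
#'   `level = -Inf` yields silence.
#' @examples
#' b <- synth_burst(band_spec(1803, 162, am_rate = 50), seed = 1)
#' @export
synth_burst <- function(spec, duration_ms = 80, ramp_ms = 8,
                        fs = STREAMSEG_FS, seed = NULL) {
  stopifnot(inherits(spec, "band_spec"), duration_ms >= 2 * ramp_ms)
  n <- round(duration_ms / 1000 * fs)
  if (!is.finite(spec$level)) return(waveform(numeric(n), fs))
  x <- with_seed(seed, stats::rnorm(n))
  sos <- butter_sos(10, spec$center_freq + c(-0.5, 0.5) * spec$bandwidth,
                    fs, "pass")
  x <- sos_filter(sos, x)
  if (spec$am_rate > 0) {
    t <- (seq_len(n) - 1) / fs
    x <- x * (1 + sin(2 * pi * spec$am_rate * t)) / 2  # 100% modulation depth
  }
  x <- x * raised_cosine_ramps(n, round(ramp_ms / 1000 * fs))
  rms <- sqrt(mean(x^2))
  if (rms == 0) return(waveform(x, fs))
  x <- x * level_to_rms(spec$level) / rms
  if (max(abs(x)) > 1) {
    stop(sprintf("burst clips at peak %.3f; lower the level", max(abs(x))))
  }
  waveform(x, fs)
}

#' Number of amplitude-modulation cycles in an observation interval
#'
#' The "multiple looks" count: an 80-ms burst carries 4 cycles of 50-Hz AM
#' and 24 cycles of 300-Hz AM.
#'
#' @param duration_s interval duration in seconds.
#' @param rate_hz AM rate in Hz.
#' @return `duration_s * rate_hz`.
#' @examples
#' am_cycles(0.08, 300)  # 24
#' @export
am_cycles <- function(duration_s, rate_hz) {
  stopifnot(duration_s >= 0, rate_hz >= 0)
  duration_s * rate_hz
}

#' Render a full stimulus sequence
#'
#' Each burst in the schedule is synthesised independently (fresh noise) and
#' placed at its onset; the remainder of the waveform is silence.
#'
#' @param timing a `seq_timing` from [make_sequence_timing()].
#' @param specs list with `A` and `B` [band_spec()]s, e.g. from
#'   [band_specs_for()].
#' @param fs sampling rate in Hz.
#' @param seed optional integer seed; per-burst noise seeds are derived from
#'   it.
#' @return a [waveform()] whose length equals [sequence_duration()] (within
#'   one sample).
#' @export
render_sequence <- function(timing, specs, fs = STREAMSEG_FS, seed = NULL) {
  stopifnot(inherits(timing, "seq_timing"), !is.null(specs$A), !is.null(specs$B))
  ev <- timing$events
  if (nrow(ev) == 0) stop("timing has no events")
  if (any(diff(ev$onset) < ev$duration[-nrow(ev)])) {
    stop("overlapping bursts in timing")
  }
  n <- round(sequence_duration(timing) * fs)
  out <- numeric(n)
  seeds <- derive_seeds(seed, nrow(ev))
  for (i in seq_len(nrow(ev))) {
    spec <- if (ev$stream[i] == "A") specs$A else specs$B
    b <- synth_burst(spec, duration_ms = ev$duration[i], fs = fs,
                     seed = seeds[[i]])
    i0 <- round(ev$onset[i] / 1000 * fs)
    idx <- i0 + seq_along(b$samples)
    idx <- idx[idx <= n]
    out[idx] <- out[idx] + b$samples[seq_along(idx)]
  }
  waveform(out, fs)
}
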