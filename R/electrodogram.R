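# ACE-style n-of-m processing: acoustic waveform -> electrode pulse pattern.
#
# The simulation follows the clinical strategy's structure: a short-time
# FFT filterbank over the default 22-channel frequency allocation
# (188-7938 Hz, 125-Hz analysis bins), per-channel envelopes at the channel
# stimulation rate, and per-frame selection of the `n_maxima` largest
# envelopes.  Current-level mapping (T/C levels) is not modelled; pulse
# magnitudes are envelope amplitudes.

# Default allocation: FFT bins per channel, apical (low) to basal (high).
DEFAULT_BAND_EDGES <- c(188, 313, 438, 563, 688, 813, 938, 1063, 1188, 1313,
                        1563, 1813, 2063, 2313, 2688, 3063, 3563, 4063, 4688,
                        5313, 6063, 6938, 7938)

#' ACE processing configuration
#'
#' Defaults follow the clinical default map: 22 channels spanning
#' 188-7938 Hz, 900 pulses per second per selected channel, and eight
#' maxima per analysis frame.  The activation floor is the level, relative
#' to the stimulus's peak channel envelope, below which a selected channel
#' is not stimulated; it stands in for the base level of the clinical
#' loudness-growth map and is calibrated so that a paradigm noise burst
#' activates the small group of neighbouring electrodes seen clinically.
#'
#' @param n_channels number of electrodes (22; electrode 1 is most basal =
#'   highest frequency band).
#' @param band_edges `n_channels + 1` ascending band-edge frequencies (Hz).
#' @param stim_rate per-channel stimulation (frame) rate in pulses/s.
#' @param n_maxima number of channels selected per frame.
#' @param floor_db activation floor in dB below the stimulus peak envelope.
#' @param window_ms analysis window length in ms.
#' @return an `ace_config` object.
#' @export
ace_config <- function(n_channels = 22L,
                       band_edges = DEFAULT_BAND_EDGES,
                       stim_rate = 900,
                       n_maxima = 8L,
                       floor_db = 50,
                       window_ms = 8) {
  stopifnot(length(band_edges) == n_channels + 1,
            all(diff(band_edges) > 0),
            n_maxima <= n_channels, stim_rate > 0, floor_db > 0)
  structure(list(n_channels = as.integer(n_channels), band_edges = band_edges,
                 stim_rate = stim_rate, n_maxima = as.integer(n_maxima),
                 floor_db = floor_db, window_ms = window_ms),
            class = "ace_config")
}

#' @export
print.ace_config <- function(x, ...) {
  cat(sprintf("<ace_config> %d channels %g-%g Hz, %g pps, %d maxima, floor %g dB\n",
              x$n_channels, min(x$band_edges), max(x$band_edges),
              x$stim_rate, x$n_maxima, x$floor_db))
  invisible(x)
}

#' Channel centre frequencies of an allocation table
#'
#' Geometric means of the band edges, ordered by electrode number (1 =
#' most basal). These reproduce the clinical map's printed channel centre
#' frequencies (e.g. electrode 12 -> 1683 Hz, electrode 2 -> 6486 Hz).
#'
#' @param config an [ace_config()].
#' @return named numeric vector of centre frequencies, electrode 1 first.
#' @export
channel_center_freqs <- function(config = ace_config()) {
  e <- config$band_edges
  cf <- sqrt(e[-length(e)] * e[-1])       # band 1 (apical) .. band n (basal)
  stats::setNames(rev(cf), paste0("e", seq_len(config$n_channels)))
}

band_of <- function(cf, config) {
  e <- config$band_edges
  if (cf < e[1] || cf > e[length(e)]) {
    stop(sprintf("centre frequency %g Hz outside the allocation span %g-%g Hz",
                 cf, e[1], e[length(e)]))
  }
  min(findInterval(cf, e, rightmost.closed = TRUE), config$n_channels)
}

#' Electrode assigned to a centre frequency
#'
#' @param cf frequency in Hz.
#' @param config an [ace_config()].
#' @return electrode number (1 = most basal / highest band; `n_channels` =
#'   most apical / lowest band).
#' @examples
#' assign_electrode(1683)  # 12
#' assign_electrode(2871)  # 8
#' @export
assign_electrode <- function(cf, config = ace_config()) {
  config$n_channels + 1L - band_of(cf, config)
}

#' Compute an electrodogram from a waveform
#'
#' Short-time FFT analysis with a Hann window of `window_ms` and one frame
#' per stimulation period; per-channel envelopes are root summed bin powers
#' over each allocation band.  Per frame, the `n_maxima` largest envelopes
#' are selected and a pulse is emitted for each selected channel whose
#' envelope lies within `floor_db` of the stimulus's peak envelope.
#'
#' @param w a [waveform()].
#' @param config an [ace_config()].
#' @return an `electrodogram` object: a data frame of pulses with columns
#'   `channel` (electrode number), `time_s` (frame time) and `magnitude`
#'   (envelope amplitude), with the configuration attached.
#' @export
compute_electrodogram <- function(w, config = ace_config()) {
  stopifnot(inherits(w, "waveform"), inherits(config, "ace_config"))
  fs <- w$fs
  x <- w$samples
  nwin <- round(config$window_ms / 1000 * fs)
  hop <- fs / config$stim_rate
  nf <- max(0L, floor((length(x) - nwin) / hop) + 1L)
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nwin) - 1) / (nwin - 1))
  freqs <- (seq_len(nwin) - 1) * fs / nwin
  bins <- lapply(seq_len(config$n_channels), function(b) {
    which(freqs >= config$band_edges[b] & freqs < config$band_edges[b + 1])
  })
  env <- matrix(0, nrow = nf, ncol = config$n_channels)
  for (k in seq_len(nf)) {
    i0 <- round((k - 1) * hop)
    seg <- x[i0 + seq_len(nwin)]
    seg[is.na(seg)] <- 0
    seg <- seg * win
    P <- Mod(stats::fft(seg))^2
    env[k, ] <- sqrt(vapply(bins, function(i) sum(P[i]), numeric(1)))
  }
  peak <- if (nf) max(env) else 0
  floor_env <- peak * 10^(-config$floor_db / 20)
  pulses <- list()
  for (k in seq_len(nf)) {
    sel <- order(env[k, ], decreasing = TRUE)[seq_len(config$n_maxima)]
    sel <- sel[env[k, sel] > floor_env & env[k, sel] > 0]
    if (length(sel)) {
      pulses[[length(pulses) + 1L]] <- data.frame(
        channel = config$n_channels + 1L - sel,
        time_s = (k - 1) / config$stim_rate,
        magnitude = env[k, sel]
      )
    }
  }
  pulses <- if (length(pulses)) do.call(rbind, pulses) else
    data.frame(channel = integer(0), time_s = numeric(0), magnitude = numeric(0))
  structure(list(pulses = pulses, config = config), class = "electrodogram")
}

#' Electrodes receiving at least one suprathreshold pulse
#'
#' @param e an `electrodogram`.
#' @return sorted integer vector of electrode numbers.
#' @export
activated_electrodes <- function(e) {
  stopifnot(inherits(e, "electrodogram"))
  sort(unique(e$pulses$channel))
}

#' @export
print.electrodogram <- function(x, ...) {
  act <- activated_electrodes(x)
  cat(sprintf("<electrodogram> %d pulses on %d electrodes%s\n",
              nrow(x$pulses), length(act),
              if (length(act)) paste0(" (#", paste(act, collapse = ", #"), ")") else ""))
  invisible(x)
}

#' Write an electrodogram to CSV
#'
#' @param e an `electrodogram`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_electrodogram_csv <- function(e, path) {
  utils::write.csv(e$pulses, path, row.names = FALSE)
  invisible(path)
}
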