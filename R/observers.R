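# Simulated listeners.
#
# Two observer families answer the yes/no question "was the final B burst
# delayed?":
#
# * the signal-detection observer draws its response from the equal-variance
#   Gaussian model at a generating sensitivity that depends on the condition
#   (spectral separation in octaves, AM-rate separation in octaves, sequence
#   duration, listener group), so the analysis pipeline's estimates can be
#   checked against known truth;
#
# * the envelope observer listens to the rendered audio: it band-passes at
#   the B band, extracts the envelope, detects burst onsets and judges the
#   final inter-onset interval against a criterion, providing a mechanistic
#   end-to-end exercise of the synthesis chain.
#
# Observers are lists with a `respond(trial)` function; `trial` carries the
# true `trial_type`, the condition, and (when `needs = "waveform"`) the
# rendered audio.  `feedback` is called once per trial after the response;
# both observers are stationary and ignore it.

#' Generating sensitivity for a condition under a linear rule
#'
#' d' = max(0, beta0 + beta_spec * octaves_spectral + beta_am * octaves_am +
#' beta_dur * 1\[9-pair\] + beta_group * 1\[NH\]), with the spectral octaves
#' taken from the listener profile's band table and the AM octaves from the
#' condition's AM pair (0, 2 or 2.59 octaves).
#'
#' @param condition a row of [build_condition_grid()] or a list with
#'   `n_pairs`, `spectral_sep`, `am_sep`.
#' @param params observer parameters, see [sdt_observer()].
#' @param profile a `listener_profile`.
#' @return generating d' (non-negative scalar).
#' @export
generating_dprime <- function(condition, params, profile = nh_profile()) {
  if (!is.null(params$dprime_map)) {
    m <- params$dprime_map
    hit <- m$n_pairs == condition$n_pairs &
      as.character(m$spectral_sep) == as.character(condition$spectral_sep) &
      as.character(m$am_sep) == as.character(condition$am_sep)
    if (sum(hit) != 1) stop("condition not found (or duplicated) in dprime_map")
    return(max(0, m$dprime[hit]))
  }
  row <- profile$band_table[
    profile$band_table$spectral_sep == as.character(condition$spectral_sep), ]
  oct_spec <- octave_separation(row$a_cf, row$b_cf)
  am <- switch(as.character(condition$am_sep),
               "AM0-0" = c(0, 0), "AM200-50" = c(200, 50), "AM300-50" = c(300, 50))
  oct_am <- if (am[1] == 0) 0 else octave_separation(am[1], am[2])
  d <- params$beta0 +
    params$beta_spec * oct_spec +
    params$beta_am * oct_am +
    params$beta_dur * (condition$n_pairs == 9) +
    params$beta_group * (profile$group == "NH")
  max(0, d)
}

#' Signal-detection-theory observer
#'
#' Responds from the equal-variance Gaussian yes/no model: on signal
#' (delayed) trials P(respond delayed) = Phi(d'/2 - c), on reference trials
#' Phi(-d'/2 - c), where d' is the generating sensitivity for the trial's
#' condition and c the response criterion.
#'
#' The sensitivity comes either from an explicit per-condition `dprime_map`
#' (data frame with `n_pairs`, `spectral_sep`, `am_sep`, `dprime`) or from
#' the linear rule of [generating_dprime()].  The default coefficients are
#' illustrative, chosen to mimic the qualitative pattern of interest
#' (graded spectral effect, a penalty for the largest AM separation, and a
#' build-up advantage for 9-pair sequences); they are not fitted to any
#' behavioural data set.
#'
#' @param dprime either a single number (used for every condition), a
#'   `dprime_map` data frame, or `NULL` to use the linear rule.
#' @param criterion response bias c (0 = unbiased).
#' @param beta0,beta_spec,beta_am,beta_dur,beta_group linear-rule
#'   coefficients (intercept; per octave of spectral separation; per octave
#'   of AM-rate separation; 9-pair indicator; NH-group indicator).
#' @param profile listener profile used to resolve spectral octaves.
#' @param loudness_bias_db,loudness_sd_db loudness-comparison bias and
#'   judgment noise (dB) used by [loudness_balance()]: the observer judges
#'   a comparison louder than the reference with probability
#'   Phi((level + bias - ref) / sd).
#' @return an `observer` object.
#' @examples
#' obs <- sdt_observer(dprime = 1.5)
#' obs$respond(list(trial_type = "delayed"))
#' @export
sdt_observer <- function(dprime = NULL, criterion = 0,
                         beta0 = 0.3, beta_spec = 0.9, beta_am = -0.1,
                         beta_dur = 0.45, beta_group = 0.25,
                         profile = nh_profile(),
                         loudness_bias_db = 0, loudness_sd_db = 2) {
  params <- list(criterion = criterion, beta0 = beta0, beta_spec = beta_spec,
                 beta_am = beta_am, beta_dur = beta_dur, beta_group = beta_group)
  if (is.data.frame(dprime)) {
    params$dprime_map <- dprime
  } else if (is.numeric(dprime)) {
    stopifnot(length(dprime) == 1, dprime >= 0, is.finite(dprime))
    params$fixed_dprime <- dprime
  }
  respond <- function(trial) {
    d <- if (!is.null(params$fixed_dprime)) params$fixed_dprime else
      generating_dprime(trial$condition, params, profile)
    p_delayed <- if (trial$trial_type == "delayed") {
      stats::pnorm(d / 2 - params$criterion)
    } else {
      stats::pnorm(-d / 2 - params$criterion)
    }
    if (stats::runif(1) < p_delayed) "delayed" else "no_delay"
  }
  structure(list(kind = "sdt", needs = "timing", params = params,
                 profile = profile,
                 respond = respond,
                 feedback = function(trial, correct) invisible(NULL),
                 louder = function(level_db, ref_db, freq) {
                   stats::runif(1) <
                     stats::pnorm((level_db + loudness_bias_db - ref_db) /
                                    loudness_sd_db)
                 }),
            class = "observer")
}

#' Yes/no response from the equal-variance Gaussian model
#'
#' Functional form of the signal-detection observer for a single trial.
#'
#' @param trial_type `"delayed"` or `"no_delay"` (the truth).
#' @param dprime generating sensitivity.
#' @param criterion response bias c.
#' @param seed optional integer seed.
#' @return `"delayed"` or `"no_delay"`.
#' @export
sdt_respond <- function(trial_type, dprime, criterion = 0, seed = NULL) {
  stopifnot(trial_type %in% c("delayed", "no_delay"), dprime >= 0)
  p <- if (trial_type == "delayed") stats::pnorm(dprime / 2 - criterion)
       else stats::pnorm(-dprime / 2 - criterion)
  with_seed(seed, if (stats::runif(1) < p) "delayed" else "no_delay")
}

#' Envelope-based mechanistic observer
#'
#' Listens to the rendered waveform knowing only the attended B band's
#' centre frequency: band-pass at the B band (10th-order Butterworth),
#' full-wave rectification, 4th-order low-pass envelope smoothing, onset
#' detection by upward threshold crossings, then a decision on the final
#' inter-onset interval corrupted by Gaussian internal temporal noise.
#' "Delayed" is reported when the noisy final interval exceeds the
#' criterion (halfway between the nominal 260-ms rhythm and the 295-ms
#' delayed interval by default).  When the distractor A bursts share the B
#' band (no spectral separation) they corrupt onset detection; when they
#' are spectrally remote the filter removes them and performance is limited
#' only by the internal noise.
#'
#' @param b_center_freq attended band centre frequency (Hz).
#' @param b_bandwidth listening-band bandwidth (Hz).
#' @param sigma_ms SD of internal temporal noise added to the interval
#'   estimate (ms).
#' @param lp_cutoff_hz envelope low-pass cutoff (Hz).
#' @param onset_threshold onset threshold as a fraction of the peak
#'   envelope.
#' @param refractory_ms dead time after a detected onset during which
#'   further threshold crossings are ignored; narrowband noise has intrinsic
#'   envelope fluctuations that re-cross the threshold within a burst, so
#'   the default (120 ms) spans a burst plus its envelope decay while
#'   staying well below the 260-ms rhythm of the attended stream.
#' @param criterion_ms decision criterion on the final interval (ms).
#' @return an `observer` object with `needs = "waveform"`.
#' @export
envelope_observer <- function(b_center_freq, b_bandwidth = paradigm_bandwidth(b_center_freq),
                              sigma_ms = 10, lp_cutoff_hz = 150,
                              onset_threshold = 0.25, refractory_ms = 120,
                              criterion_ms = 260 + 17.5) {
  stopifnot(sigma_ms > 0, criterion_ms > 260, criterion_ms < 295)
  params <- list(b_center_freq = b_center_freq, b_bandwidth = b_bandwidth,
                 sigma_ms = sigma_ms, lp_cutoff_hz = lp_cutoff_hz,
                 onset_threshold = onset_threshold,
                 refractory_ms = refractory_ms, criterion_ms = criterion_ms)
  respond <- function(trial) {
    envelope_respond(trial$waveform, params)
  }
  structure(list(kind = "envelope", needs = "waveform", params = params,
                 respond = respond,
                 feedback = function(trial, correct) invisible(NULL),
                 louder = function(level_db, ref_db, freq) {
                   stats::runif(1) < stats::pnorm((level_db - ref_db) / 2)
                 }),
            class = "observer")
}

#' Envelope observer's decision for one waveform
#'
#' @param w a [waveform()] of a full stimulus sequence.
#' @param params parameter list as stored by [envelope_observer()].
#' @param seed optional integer seed for the internal-noise draw (and the
#'   guess when fewer than two onsets are detected).
#' @return `"delayed"` or `"no_delay"`.
#' @export
envelope_respond <- function(w, params, seed = NULL) {
  stopifnot(inherits(w, "waveform"))
  band <- params$b_center_freq + c(-0.5, 0.5) * params$b_bandwidth
  x <- sos_filter(butter_sos(10, band, w$fs, "pass"), w$samples)
  env <- sos_filter(butter_sos(4, params$lp_cutoff_hz, w$fs, "low"), abs(x))
  thr <- params$onset_threshold * max(env)
  with_seed(seed, {
    if (thr <= 0) return(if (stats::runif(1) < 0.5) "delayed" else "no_delay")
    up <- which(env[-1] >= thr & env[-length(env)] < thr)
    if (length(up) >= 2) {  # refractory dead time after each accepted onset
      refr <- (params$refractory_ms %||% 0) / 1000 * w$fs
      keep <- up[1]
      for (u in up[-1]) if (u - keep[length(keep)] >= refr) keep <- c(keep, u)
      up <- keep
    }
    if (length(up) < 2) return(if (stats::runif(1) < 0.5) "delayed" else "no_delay")
    interval_ms <- diff(utils::tail(up, 2)) / w$fs * 1000 +
      stats::rnorm(1, 0, params$sigma_ms)
    if (interval_ms > params$criterion_ms) "delayed" else "no_delay"
  })
}

#' Guessing observer
#'
#' Responds "delayed" with fixed probability regardless of the stimulus;
#' useful as a chance-level control.
#'
#' @param p_delayed probability of responding "delayed".
#' @return an `observer` object.
#' @export
guessing_observer <- function(p_delayed = 0.5) {
  structure(list(kind = "guess", needs = "timing",
                 respond = function(trial) {
                   if (stats::runif(1) < p_delayed) "delayed" else "no_delay"
                 },
                 feedback = function(trial, correct) invisible(NULL),
                 louder = function(level_db, ref_db, freq) stats::runif(1) < 0.5),
            class = "observer")
}

#' Oracle observer
#'
#' Always answers correctly (it reads the true trial type); useful for
#' engine bookkeeping checks.
#'
#' @return an `observer` object.
#' @export
oracle_observer <- function() {
  structure(list(kind = "oracle", needs = "timing",
                 respond = function(trial) trial$trial_type,
                 feedback = function(trial, correct) invisible(NULL),
                 louder = function(level_db, ref_db, freq) {
                   stats::runif(1) < stats::pnorm((level_db - ref_db) / 2)
                 }),
            class = "observer")
}
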