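# Listener profiles: the frequency (and, for implant users, electrode)
# placement of the A and B noise bands at each spectral-separation level.
#
# Normal-hearing listeners share one profile (B fixed at 1803 Hz; A at
# 1803 / 3022 / 6665 Hz).  Each implant user has a customised table: the B
# band sits at the centre frequency of the clinical-map channel containing
# 1803 Hz, and the A bands at channels roughly 3-4 or 9-10 electrodes more
# basal.  The implant tables ship as a plain-text fixture
# (`extdata/ci_band_table.csv`) transcribed from the study population.

NH_A_CF <- c(none = 1803, moderate = 3022, large = 6665)
NH_B_CF <- 1803

#' Bandwidth convention for the paradigm's noise bands
#'
#' 162 Hz for bands centred below 5 kHz and 216 Hz above, the narrowest
#' bandwidths that keep the presentation level steady in the sound field.
#'
#' @param cf centre frequency in Hz.
#' @return bandwidth in Hz.
#' @export
paradigm_bandwidth <- function(cf) ifelse(cf < 5000, 162, 216)

#' The normal-hearing listener profile
#'
#' @param id profile label.
#' @return a `listener_profile` object with a `band_table` mapping each
#'   spectral-separation level to A and B centre frequencies.
#' @examples
#' nh_profile()
#' @export
nh_profile <- function(id = "NH") {
  band_table <- data.frame(
    spectral_sep = factor(SPECTRAL_LEVELS, levels = SPECTRAL_LEVELS),
    a_cf = unname(NH_A_CF),
    b_cf = NH_B_CF
  )
  structure(list(group = "NH", id = id, band_table = band_table),
            class = "listener_profile")
}

#' Cochlear-implant listener profiles
#'
#' One profile per implant user, from the packaged band table: the B band's
#' assigned electrode and centre frequency, and the A band's at the moderate
#' and large spectral separations.  In the no-separation condition A and B
#' are identical.
#'
#' @return a named list of `listener_profile` objects (`CI1` ... `CI6`).
#' @examples
#' ci_profiles()[["CI2"]]$band_table
#' @export
ci_profiles <- function() {
  path <- system.file("extdata", "ci_band_table.csv", package = "streamseg",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    band_table <- data.frame(
      spectral_sep = factor(SPECTRAL_LEVELS, levels = SPECTRAL_LEVELS),
      a_cf = c(r$b_cf, r$moderate_cf, r$large_cf),
      b_cf = r$b_cf,
      a_electrode = c(r$b_electrode, r$moderate_electrode, r$large_electrode),
      b_electrode = r$b_electrode
    )
    structure(list(group = "CI", id = r$id, age = r$age, brand = r$brand,
                   band_table = band_table),
              class = "listener_profile")
  })
  names(out) <- tab$id
  out
}

#' Look up a listener profile by id
#'
#' @param id `"NH"` or one of `"CI1"` ... `"CI6"`.
#' @return a `listener_profile`.
#' @export
listener_profile <- function(id) {
  if (identical(id, "NH")) return(nh_profile())
  cis <- ci_profiles()
  if (!id %in% names(cis)) {
    stop("unknown listener profile '", id, "'; available: NH, ",
         paste(names(cis), collapse = ", "))
  }
  cis[[id]]
}

#' @export
print.listener_profile <- function(x, ...) {
  cat(sprintf("<listener_profile> %s (%s)\n", x$id, x$group))
  print(x$band_table, row.names = FALSE)
  invisible(x)
}

#' Acoustic band specifications for one condition
#'
#' Resolves a listener profile and condition levels into the A and B burst
#' specifications: centre frequency, bandwidth (162 Hz below 5 kHz centre,
#' 216 Hz above), AM rate (AM0-0: both unmodulated; AM200-50: A at 200 Hz,
#' B at 50 Hz; AM300-50: A at 300 Hz, B at 50 Hz) and level.  B is presented
#' at 60 dB SPL; A defaults to 60 dB SPL until a loudness-balanced level is
#' supplied.
#'
#' @param profile a `listener_profile`.
#' @param spectral_sep `"none"`, `"moderate"` or `"large"`.
#' @param am_sep `"AM0-0"`, `"AM200-50"` or `"AM300-50"`.
#' @param a_level A-burst level in dB SPL (from [loudness_balance()]).
#' @param b_level B-burst level in dB SPL.
#' @return a list with elements `A` and `B`, each a [band_spec()].
#' @examples
#' band_specs_for(nh_profile(), "large", "AM300-50")
#' @export
band_specs_for <- function(profile, spectral_sep, am_sep,
                           a_level = 60, b_level = 60) {
  stopifnot(inherits(profile, "listener_profile"))
  spectral_sep <- as.character(spectral_sep)
  am_sep <- as.character(am_sep)
  if (!spectral_sep %in% SPECTRAL_LEVELS) {
    stop("unknown spectral separation level '", spectral_sep, "'")
  }
  if (!am_sep %in% AM_LEVELS) stop("unknown AM separation level '", am_sep, "'")
  row <- profile$band_table[profile$band_table$spectral_sep == spectral_sep, ]
  stopifnot(nrow(row) == 1)
  am <- switch(am_sep,
               "AM0-0" = c(A = 0, B = 0),
               "AM200-50" = c(A = 200, B = 50),
               "AM300-50" = c(A = 300, B = 50))
  list(
    A = band_spec(row$a_cf, paradigm_bandwidth(row$a_cf), am[["A"]], a_level),
    B = band_spec(row$b_cf, paradigm_bandwidth(row$b_cf), am[["B"]], b_level)
  )
}

#' One noise band's acoustic definition
#'
#' @param center_freq centre frequency in Hz.
#' @param bandwidth bandwidth in Hz (passband `center_freq` +/- half the
#'   bandwidth).
#' @param am_rate sinusoidal amplitude-modulation rate in Hz (0 for an
#'   unmodulated band).
#' @param level presentation level in dB SPL (`-Inf` for silence).
#' @return a `band_spec` object.
#' @export
band_spec <- function(center_freq, bandwidth, am_rate = 0, level = 60) {
  stopifnot(center_freq > 0, bandwidth > 0, bandwidth < center_freq,
            am_rate >= 0)
  structure(list(center_freq = center_freq, bandwidth = bandwidth,
                 am_rate = am_rate, level = level),
            class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %g Hz +/- %g Hz, AM %g Hz, %g dB SPL\n",
              x$center_freq, x$bandwidth / 2, x$am_rate, x$level))
  invisible(x)
}
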