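# Butterworth filters realised as cascaded second-order sections.
#
# High-order narrow bandpass filters (10th order at a relative bandwidth of
# ~1/10 of the centre frequency) are unstable in direct transfer-function
# form in double precision, so the design keeps pole pairs separated:
# analog lowpass prototype -> lowpass/bandpass transform -> bilinear
# transform -> one biquad per conjugate pole pair.

#' Design a Butterworth filter as second-order sections
#'
#' @param n filter order of the analog lowpass prototype. A bandpass design
#'   of order `n` has `2 n` poles (this matches the usual "nth-order
#'   Butterworth bandpass" naming in the psychoacoustics literature).
#' @param fc cutoff frequency in Hz; a length-2 vector `c(lo, hi)` for
#'   `type = "pass"`.
#' @param fs sampling rate in Hz.
#' @param type `"low"` or `"pass"`.
#' @return an object of class `sos_filter`: a list of sections, each with
#'   numerator `b` and denominator `a` (length-3 numeric vectors, `a[1] = 1`),
#'   to be applied in cascade.
#' @examples
#' sos <- butter_sos(10, c(1722, 1884), 44100, "pass")
#' round(20 * log10(Mod(sos_freqz(sos, c(1803, 1722, 1884), 44100))), 2)
#' @export
butter_sos <- function(n, fc, fs, type = c("low", "pass")) {
  type <- match.arg(type)
  stopifnot(n >= 1, fs > 0, all(fc > 0), all(fc < fs / 2))
  k <- seq_len(n)
  p_proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n)) # analog prototype poles
  warp <- function(f) 2 * fs * tan(pi * f / fs)       # bilinear pre-warp
  if (type == "low") {
    stopifnot(length(fc) == 1)
    p <- p_proto * warp(fc)
    ref <- 1 + 0i                                     # normalise at DC
  } else {
    stopifnot(length(fc) == 2, fc[1] < fc[2])
    wl <- warp(fc[1]); wh <- warp(fc[2])
    w0 <- sqrt(wl * wh); bw <- wh - wl
    a <- p_proto * bw / 2
    p <- c(a + sqrt(a^2 - w0^2), a - sqrt(a^2 - w0^2))
    f0d <- fs / pi * atan(w0 / (2 * fs))              # digital centre frequency
    ref <- exp(2i * pi * f0d / fs)                    # normalise at band centre
  }
  pd <- (2 * fs + p) / (2 * fs - p)
  if (any(Mod(pd) >= 1)) {
    stop("unstable filter design (pole on or outside the unit circle); ",
         "check cutoff frequencies against the sampling rate")
  }
  pos <- pd[Im(pd) > 0]
  sections <- lapply(pos, function(pp) {
    ap <- Re(c(1, -2 * Re(pp), Mod(pp)^2))
    bp <- if (type == "low") c(1, 2, 1) else c(1, 0, -1)
    num <- bp[1] * ref^2 + bp[2] * ref + bp[3]
    den <- ap[1] * ref^2 + ap[2] * ref + ap[3]
    list(b = bp * Mod(den / num), a = ap)
  })
  structure(sections, class = "sos_filter")
}

#' Apply a second-order-section filter cascade
#'
#' Causal (forward-only) filtering with zero initial conditions, matching a
#' real-time presentation chain.
#'
#' @param sos an [sos_filter] object from [butter_sos()].
#' @param x numeric signal.
#' @return filtered signal, same length as `x`.
#' @export
sos_filter <- function(sos, x) {
  stopifnot(inherits(sos, "sos_filter"), is.numeric(x))
  nx <- length(x)
  if (nx == 0) return(numeric(0))
  for (s in sos) {
    ma <- s$b[1] * x +
      s$b[2] * c(0, x[-nx]) +
      s$b[3] * c(0, 0, if (nx > 2) x[seq_len(nx - 2)] else numeric(0))[seq_len(nx)]
    x <- as.numeric(stats::filter(ma, -s$a[-1], method = "recursive"))
  }
  x
}

#' Frequency response of a second-order-section cascade
#'
#' @param sos an [sos_filter] object.
#' @param f frequencies in Hz at which to evaluate the response.
#' @param fs sampling rate in Hz.
#' @return complex response at each frequency.
#' @export
sos_freqz <- function(sos, f, fs) {
  stopifnot(inherits(sos, "sos_filter"))
  z <- exp(2i * pi * f / fs)
  H <- rep(1 + 0i, length(f))
  for (s in sos) {
    H <- H * (s$b[1] * z^2 + s$b[2] * z + s$b[3]) / (z^2 + s$a[2] * z + s$a[3])
  }
  H
}
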