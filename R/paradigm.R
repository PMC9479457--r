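# Condition grid, stimulus timing rules and bookkeeping for the rhythm-delay
# stream-segregation paradigm.
#
# A trial presents an alternating ABAB... sequence of 80-ms narrowband noise
# bursts.  The attended B subsequence is isochronous (260-ms onset-to-onset)
# except for its final burst, which is either delayed by 35 ms (signal
# trials) or advanced by 0-10 ms (reference trials).  The distracting A
# bursts are temporally jittered so that only listeners who segregate the B
# stream can track its rhythm.

SPECTRAL_LEVELS <- c("none", "moderate", "large")
AM_LEVELS <- c("AM0-0", "AM200-50", "AM300-50")

# Nominal timing constants (ms)
BURST_MS <- 80
FIRST_AB_ONSET_MS <- 130   # onset-to-onset between first A and first B
BB_ONSET_MS <- 260         # B-B onset-to-onset
DELAY_MS <- 35             # final-B delay on signal trials
ADVANCE_MAX_MS <- 10       # maximal final-B advance on reference trials
JITTER_MAX_MS <- 40        # maximal |jitter| of a distractor A burst

#' The 18-condition experimental grid
#'
#' Two sequence durations (3 or 9 AB pairs), three A-B spectral separations
#' and three AM-rate separations, fully crossed.
#'
#' @return a data frame with 18 rows and columns `n_pairs` (integer, 3 or 9),
#'   `spectral_sep` (factor: none, moderate, large) and `am_sep` (factor:
#'   AM0-0, AM200-50, AM300-50), in canonical order (`n_pairs`, then
#'   `spectral_sep`, then `am_sep`).
#' @examples
#' build_condition_grid()
#' @export
build_condition_grid <- function() {
  grid <- expand.grid(
    am_sep = factor(AM_LEVELS, levels = AM_LEVELS),
    spectral_sep = factor(SPECTRAL_LEVELS, levels = SPECTRAL_LEVELS),
    n_pairs = c(3L, 9L),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("n_pairs", "spectral_sep", "am_sep")]
  grid <- grid[order(grid$n_pairs,
                     as.integer(grid$spectral_sep),
                     as.integer(grid$am_sep)), ]
  rownames(grid) <- NULL
  grid
}

as_condition <- function(n_pairs, spectral_sep, am_sep) {
  spectral_sep <- match.arg(as.character(spectral_sep), SPECTRAL_LEVELS)
  am_sep <- match.arg(as.character(am_sep), AM_LEVELS)
  stopifnot(n_pairs %in% c(3L, 9L))
  list(n_pairs = as.integer(n_pairs),
       spectral_sep = spectral_sep,
       am_sep = am_sep)
}

#' Build the burst schedule for one stimulus sequence
#'
#' Implements the paradigm's timing rules: bursts of 80 ms; the first A at
#' time zero; B onsets on the rigid 130 + 260 k ms grid; every A after the
#' first jittered by a signed amount of magnitude at most 40 ms (uniform
#' magnitude, random sign), so each offset-to-onset gap between an A and an
#' adjacent nominal B position lies in 10-90 ms; and the final B shifted
#' from its nominal position by +35 ms (`"delayed"` trials) or by a uniform
#' 0-10 ms advance (`"no_delay"` trials).
#'
#' @param n_pairs number of AB pairs (3 or 9). A condition row from
#'   [build_condition_grid()] (or any list with an `n_pairs` field) is also
#'   accepted.
#' @param trial_type `"delayed"` or `"no_delay"`.
#' @param seed optional integer seed for the jitter and advance draws.
#' @return an object of class `seq_timing`: a list with `events` (data frame
#'   of `stream`, `onset` ms, `duration` ms in chronological order),
#'   `trial_type`, `jitters` (signed ms, one per A burst, first always 0),
#'   `final_shift` (ms) and `n_pairs`.
#' @examples
#' t9 <- make_sequence_timing(9, "delayed", seed = 1)
#' sequence_duration(t9)  # 2.325
#' @export
make_sequence_timing <- function(n_pairs, trial_type = c("delayed", "no_delay"),
                                 seed = NULL) {
  if (is.list(n_pairs)) n_pairs <- n_pairs$n_pairs
  stopifnot(n_pairs %in% c(3L, 9L))
  trial_type <- match.arg(trial_type)
  n_pairs <- as.integer(n_pairs)
  with_seed(seed, {
    jitters <- c(0, stats::runif(n_pairs - 1, 0, JITTER_MAX_MS) *
                   sample(c(-1, 1), n_pairs - 1, replace = TRUE))
    final_shift <- if (trial_type == "delayed") DELAY_MS else
      -stats::runif(1, 0, ADVANCE_MAX_MS)
    a_onsets <- (seq_len(n_pairs) - 1) * BB_ONSET_MS + jitters
    b_onsets <- FIRST_AB_ONSET_MS + (seq_len(n_pairs) - 1) * BB_ONSET_MS
    b_onsets[n_pairs] <- b_onsets[n_pairs] + final_shift
    events <- data.frame(
      stream = rep(c("A", "B"), n_pairs),
      onset = as.numeric(rbind(a_onsets, b_onsets)),
      duration = BURST_MS
    )
    structure(list(events = events, trial_type = trial_type,
                   jitters = jitters, final_shift = final_shift,
                   n_pairs = n_pairs),
              class = "seq_timing")
  })
}

#' Total duration of a stimulus sequence
#'
#' @param timing a `seq_timing` object.
#' @return duration in seconds: offset of the last burst (onset + 80 ms)
#'   relative to the first A onset.
#' @examples
#' sequence_duration(make_sequence_timing(9, "delayed"))  # 2.325
#' @export
sequence_duration <- function(timing) {
  stopifnot(inherits(timing, "seq_timing"))
  if (nrow(timing$events) == 0) stop("timing has no events")
  max(timing$events$onset + timing$events$duration) / 1000
}

#' Offset-to-onset gaps between jittered A bursts and adjacent B positions
#'
#' For each A burst after the first, the silent gap from the preceding B
#' offset to the A onset and from the A offset to the following B onset.
#' Gaps are measured against the nominal (unshifted) position of the final
#' B burst: the paradigm's 10-90 ms gap rule constrains the jitter relative
#' to the steady rhythm, while the final-B shift is the target the listener
#' must detect.
#'
#' @param timing a `seq_timing` object.
#' @return numeric vector of gaps in ms (two per jittered A burst).
#' @export
burst_gaps <- function(timing) {
  stopifnot(inherits(timing, "seq_timing"))
  n <- timing$n_pairs
  if (n < 2) return(numeric(0))
  k <- 2:n
  a_on <- (k - 1) * BB_ONSET_MS + timing$jitters[k]
  prev_b_off <- FIRST_AB_ONSET_MS + (k - 2) * BB_ONSET_MS + BURST_MS
  next_b_on <- FIRST_AB_ONSET_MS + (k - 1) * BB_ONSET_MS # nominal final B
  as.numeric(rbind(a_on - prev_b_off, next_b_on - (a_on + BURST_MS)))
}

#' Octave separation between two frequencies
#'
#' @param f1,f2 positive frequencies (Hz), or AM rates for AM-separation
#'   bookkeeping.
#' @param digits if non-`NULL`, round (half-up) to this many decimals, the
#'   convention used when quoting separations.
#' @return `|log2(f1 / f2)|` in octaves.
#' @examples
#' octave_separation(3022, 1803, digits = 2)  # 0.75
#' octave_separation(300, 50, digits = 2)     # 2.59
#' @export
octave_separation <- function(f1, f2, digits = NULL) {
  if (any(c(f1, f2) <= 0)) stop("frequencies must be positive")
  oct <- abs(log2(f1 / f2))
  if (is.null(digits)) oct else round_half_up(oct, digits)
}

round_half_up <- function(x, digits) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Pseudorandomised block order for a session
#'
#' Randomises the six duration-by-spectral-separation cells first, then the
#' three AM-rate separations nested within each cell, and schedules the two
#' repetitions of every condition in consecutive block slots.
#'
#' @param seed optional integer seed.
#' @return a data frame of 36 block slots with columns `slot`, `n_pairs`,
#'   `spectral_sep`, `am_sep` and `repetition` (1 or 2).
#' @export
pseudorandom_condition_order <- function(seed = NULL) {
  with_seed(seed, {
    cells <- expand.grid(n_pairs = c(3L, 9L),
                         spectral_sep = factor(SPECTRAL_LEVELS, levels = SPECTRAL_LEVELS),
                         KEEP.OUT.ATTRS = FALSE)
    cells <- cells[sample.int(nrow(cells)), , drop = FALSE]
    rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      ams <- sample(AM_LEVELS)
      data.frame(n_pairs = cells$n_pairs[i],
                 spectral_sep = cells$spectral_sep[i],
                 am_sep = factor(rep(ams, each = 2), levels = AM_LEVELS),
                 repetition = rep(1:2, times = 3))
    }))
    rows$slot <- seq_len(nrow(rows))
    rownames(rows) <- NULL
    rows[, c("slot", "n_pairs", "spectral_sep", "am_sep", "repetition")]
  })
}

#' @export
print.seq_timing <- function(x, ...) {
  cat(sprintf("<seq_timing> %d-pair %s sequence, %.3f s\n",
              x$n_pairs, x$trial_type, sequence_duration(x)))
  cat(sprintf("  final-B shift %+.2f ms; |jitter| max %.1f ms\n",
              x$final_shift, max(abs(x$jitters))))
  invisible(x)
}

#' @export
as.data.frame.seq_timing <- function(x, ...) {
  data.frame(x$events, trial_type = x$trial_type)
}

#' Write a burst schedule to CSV
#'
#' @param timing a `seq_timing` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timing_csv <- function(timing, path) {
  utils::write.csv(as.data.frame(timing), path, row.names = FALSE)
  invisible(path)
}
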