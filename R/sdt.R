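# Signal-detection scoring: hit/false-alarm counting, d' = Z(h) - Z(f),
# session summaries and the build-up (duration) contrast.

#' Score a block into hit and false-alarm counts
#'
#' Familiarization trials are excluded.  A hit is a "delayed" response on a
#' delayed trial; a false alarm is a "delayed" response on a no-delay
#' trial.
#'
#' @param block a `trial_block`.
#' @return list with `hits`, `false_alarms`, `n_signal`, `n_noise`,
#'   `hit_rate`, `fa_rate` (raw, uncorrected rates).
#' @export
score_block <- function(block) {
  stopifnot(inherits(block, "trial_block"))
  tr <- block$trials
  if (nrow(tr) < block$n_trials) {
    stop(sprintf("incomplete block: %d of %d trials", nrow(tr), block$n_trials))
  }
  tr <- tr[!tr$familiarization, ]
  sig <- tr$trial_type == "delayed"
  hits <- sum(sig & tr$response == "delayed")
  fas <- sum(!sig & tr$response == "delayed")
  list(hits = hits, false_alarms = fas,
       n_signal = sum(sig), n_noise = sum(!sig),
       hit_rate = hits / sum(sig), fa_rate = fas / sum(!sig))
}

#' Sensitivity d' from yes/no counts
#'
#' d' = Z(hit rate) - Z(false-alarm rate) under the equal-variance Gaussian
#' model.  Perfect or zero rates make the Z transform infinite, so rates
#' are corrected first:
#'
#' * `"loglinear"` (default): add 0.5 to each count and 1 to each trial
#'   total before forming rates (Hautus' correction; applied to every
#'   block, it is the less biased estimator at this block size);
#' * `"clamp"`: replace rates of 0 with 1/(2N) and 1 with 1 - 1/(2N),
#'   leaving intermediate rates untouched.
#'
#' @param hits,false_alarms counts of "delayed" responses on signal and
#'   noise trials.
#' @param n_signal,n_noise numbers of scored signal and noise trials.
#' @param correction extreme-rate correction, see above.
#' @return d' (scalar).
#' @examples
#' dprime(0.8413 * 60, 0.1587 * 60, 60, 60, correction = "clamp")  # ~2.00
#' @export
dprime <- function(hits, false_alarms, n_signal, n_noise,
                   correction = c("loglinear", "clamp")) {
  correction <- match.arg(correction)
  if (n_signal <= 0 || n_noise <= 0) stop("need at least one trial of each type")
  if (hits < 0 || false_alarms < 0 || hits > n_signal || false_alarms > n_noise) {
    stop("counts must lie between 0 and the corresponding trial count")
  }
  r <- corrected_rates(hits, false_alarms, n_signal, n_noise, correction)
  stats::qnorm(r$h) - stats::qnorm(r$f)
}

corrected_rates <- function(hits, false_alarms, n_signal, n_noise, correction) {
  if (correction == "loglinear") {
    list(h = (hits + 0.5) / (n_signal + 1),
         f = (false_alarms + 0.5) / (n_noise + 1))
  } else {
    clamp <- function(p, n) pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))
    list(h = clamp(hits / n_signal, n_signal),
         f = clamp(false_alarms / n_noise, n_noise))
  }
}

#' Summarise a session into a d' table
#'
#' One row per scored block (18 conditions x 2 repetitions = 36 rows), with
#' corrected rates and d'.
#'
#' @param session a `session` from [run_session()], or a list of 36
#'   `trial_block`s.
#' @param correction extreme-rate correction passed to [dprime()].
#' @return a `dprime_table` data frame with columns `n_pairs`,
#'   `spectral_sep`, `am_sep`, `repetition`, `n_signal`, `n_noise`, `hits`,
#'   `false_alarms`, `hit_rate`, `fa_rate` (corrected rates) and `dprime`.
#' @export
summarize_session <- function(session, correction = c("loglinear", "clamp")) {
  correction <- match.arg(correction)
  blocks <- if (inherits(session, "session")) session$blocks else session
  if (inherits(session, "session") && !session$passed_training) {
    stop("session failed the training gate; no scored blocks")
  }
  grid <- build_condition_grid()
  key <- function(n, s, a, r) paste(n, s, a, r, sep = "|")
  have <- vapply(blocks, function(b)
    key(b$n_pairs, as.character(b$spectral_sep), as.character(b$am_sep),
        b$repetition), character(1))
  want <- c(key(grid$n_pairs, as.character(grid$spectral_sep),
                as.character(grid$am_sep), 1),
            key(grid$n_pairs, as.character(grid$spectral_sep),
                as.character(grid$am_sep), 2))
  missing <- setdiff(want, have)
  if (length(missing)) {
    stop("missing blocks: ", paste(missing, collapse = "; "))
  }
  rows <- lapply(blocks, function(b) {
    s <- score_block(b)
    r <- corrected_rates(s$hits, s$false_alarms, s$n_signal, s$n_noise,
                         correction)
    data.frame(n_pairs = b$n_pairs,
               spectral_sep = as.character(b$spectral_sep),
               am_sep = as.character(b$am_sep),
               repetition = b$repetition,
               n_signal = s$n_signal, n_noise = s$n_noise,
               hits = s$hits, false_alarms = s$false_alarms,
               hit_rate = r$h, fa_rate = r$f,
               dprime = stats::qnorm(r$h) - stats::qnorm(r$f))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$n_pairs,
                   match(out$spectral_sep, SPECTRAL_LEVELS),
                   match(out$am_sep, AM_LEVELS),
                   out$repetition), ]
  rownames(out) <- NULL
  class(out) <- c("dprime_table", "data.frame")
  out
}

#' Per-condition mean d'
#'
#' @param table a `dprime_table`.
#' @return data frame of 18 condition means.
#' @export
condition_means <- function(table) {
  stopifnot(inherits(table, "dprime_table") || is.data.frame(table))
  agg <- stats::aggregate(dprime ~ n_pairs + spectral_sep + am_sep,
                          data = table, FUN = mean)
  agg <- agg[order(agg$n_pairs,
                   match(agg$spectral_sep, SPECTRAL_LEVELS),
                   match(agg$am_sep, AM_LEVELS)), ]
  rownames(agg) <- NULL
  agg
}

#' Build-up contrast between sequence durations
#'
#' The build-up of stream segregation appears as higher sensitivity for
#' 9-pair than for 3-pair sequences.  Returns the overall mean d'
#' difference (9-pair minus 3-pair) and the same contrast within each
#' spectral-separation level.
#'
#' @param table a `dprime_table`.
#' @return list with `overall` (scalar delta d') and `by_separation` (data
#'   frame with `spectral_sep` and `delta_dprime`).
#' @export
buildup_effect <- function(table) {
  stopifnot(is.data.frame(table))
  if (!all(c(3, 9) %in% table$n_pairs)) {
    stop("table must contain both 3-pair and 9-pair rows")
  }
  overall <- mean(table$dprime[table$n_pairs == 9]) -
    mean(table$dprime[table$n_pairs == 3])
  by_sep <- do.call(rbind, lapply(SPECTRAL_LEVELS, function(s) {
    sub <- table[table$spectral_sep == s, ]
    data.frame(spectral_sep = s,
               delta_dprime = mean(sub$dprime[sub$n_pairs == 9]) -
                 mean(sub$dprime[sub$n_pairs == 3]))
  }))
  list(overall = overall, by_separation = by_sep)
}

#' Write a d' table to CSV
#'
#' @param table a `dprime_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dprime_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
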