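# Session engine: the single-interval yes/no procedure, adaptive loudness
# balancing, the training gate, and full-session bookkeeping.

#' Run one yes/no block
#'
#' Each trial draws the trial type with probability 0.5, builds the burst
#' schedule (and the audio, for waveform-based observers), collects the
#' observer's response and delivers feedback.  The first
#' `n_familiarization` trials are flagged and later excluded from scoring.
#'
#' @param condition a row of [build_condition_grid()] (or list with
#'   `n_pairs`, `spectral_sep`, `am_sep`).
#' @param observer an `observer` object.
#' @param profile a `listener_profile` (used to resolve band specs for
#'   waveform-based observers).
#' @param seed optional integer seed; per-trial seeds are derived from it.
#' @param n_trials number of trials (65 for experimental blocks, 40 for
#'   training blocks).
#' @param n_familiarization number of initial familiarization trials
#'   (excluded from scoring; 5 for experimental blocks, 0 for training).
#' @param a_level A-burst presentation level in dB SPL (from loudness
#'   balancing).
#' @param block_index,repetition,phase bookkeeping labels stored with the
#'   block.
#' @return a `trial_block`: a list with `trials` (one row per trial:
#'   `block_index`, `trial_index`, `trial_type`, `response`, `correct`,
#'   `familiarization`, `seed`), the condition fields, `repetition`,
#'   `phase` and `n_trials`.
#' @export
run_block <- function(condition, observer, profile = nh_profile(), seed = NULL,
                      n_trials = 65L, n_familiarization = 5L,
                      a_level = 60, block_index = 1L, repetition = 1L,
                      phase = "main") {
  stopifnot(inherits(observer, "observer"))
  condition <- as_condition(condition$n_pairs, condition$spectral_sep,
                            condition$am_sep)
  seeds <- derive_seeds(seed, n_trials + 1L)
  types <- with_seed(seeds[[n_trials + 1L]],
                     sample(c("delayed", "no_delay"), n_trials, replace = TRUE))
  specs <- if (identical(observer$needs, "waveform")) {
    band_specs_for(profile, condition$spectral_sep, condition$am_sep,
                   a_level = a_level)
  } else NULL
  responses <- character(n_trials)
  for (i in seq_len(n_trials)) {
    trial_seed <- seeds[[i]]
    trial <- list(trial_type = types[i], condition = condition,
                  trial_index = i, seed = trial_seed)
    resp <- with_seed(trial_seed, {
      if (identical(observer$needs, "waveform")) {
        sub <- derive_seeds(trial_seed, 2L)
        timing <- make_sequence_timing(condition$n_pairs, types[i],
                                       seed = sub[[1]])
        trial$waveform <- render_sequence(timing, specs, seed = sub[[2]])
      }
      observer$respond(trial)
    })
    if (!resp %in% c("delayed", "no_delay")) {
      stop(sprintf("observer returned invalid response '%s' on trial %d of block %d",
                   resp, i, block_index))
    }
    responses[i] <- resp
    observer$feedback(trial, resp == types[i])
  }
  trials <- data.frame(
    block_index = block_index, trial_index = seq_len(n_trials),
    trial_type = types, response = responses, correct = responses == types,
    familiarization = seq_len(n_trials) <= n_familiarization,
    seed = vapply(seeds[seq_len(n_trials)],
                  function(s) if (is.null(s)) NA_integer_ else as.integer(s),
                  integer(1))
  )
  structure(list(trials = trials,
                 n_pairs = condition$n_pairs,
                 spectral_sep = condition$spectral_sep,
                 am_sep = condition$am_sep,
                 repetition = as.integer(repetition),
                 phase = phase,
                 n_trials = as.integer(n_trials)),
            class = "trial_block")
}

#' @export
print.trial_block <- function(x, ...) {
  cat(sprintf("<trial_block> %s %d-pair %s/%s rep %d: %d trials, %.1f%% correct\n",
              x$phase, x$n_pairs, x$spectral_sep, x$am_sep, x$repetition,
              nrow(x$trials), 100 * mean(x$trials$correct)))
  invisible(x)
}

#' Training gate
#'
#' Training continues until at least one training block of the
#' gate condition (large spectral separation, no AM-rate separation)
#' reaches d' of 1.5 or higher.
#'
#' @param training_blocks list of `trial_block`s from the training phase.
#' @param threshold gate d' threshold.
#' @param correction extreme-rate correction passed to [dprime()].
#' @return `TRUE` if any eligible block passes the gate.
#' @export
training_gate <- function(training_blocks, threshold = 1.5,
                          correction = c("loglinear", "clamp")) {
  correction <- match.arg(correction)
  any(vapply(training_blocks, function(b) {
    if (!(as.character(b$spectral_sep) == "large" &&
          as.character(b$am_sep) == "AM0-0")) return(FALSE)
    s <- score_block(b)
    dprime(s$hits, s$false_alarms, s$n_signal, s$n_noise,
           correction = correction) >= threshold
  }, logical(1)))
}

#' Adaptive loudness balancing
#'
#' Finds the A-burst level judged equally loud as the 60-dB-SPL B burst by
#' two interleaved adaptive tracks converging from above and below: a
#' 1-up/2-down track (two consecutive "louder" judgments lower the level)
#' and a 2-up/1-down track, with 4-dB steps reduced to 2 dB after two
#' reversals and 10 reversals per track.  The point of subjective equality
#' is the mean of the last six reversal levels of each track.
#'
#' @param observer an `observer` exposing a `louder(level, ref, freq)`
#'   judgment.
#' @param a_spec the A-burst [band_spec()] being balanced.
#' @param b_ref_level reference B level in dB SPL.
#' @param seed optional integer seed.
#' @param step_db,small_step_db initial and reduced step sizes (dB).
#' @param n_reversals reversals per track before stopping.
#' @param max_trials abort limit across both tracks.
#' @return matched A level in dB SPL.
#' @export
loudness_balance <- function(observer, a_spec, b_ref_level = 60, seed = NULL,
                             step_db = 4, small_step_db = 2,
                             n_reversals = 10, max_trials = 400) {
  stopifnot(inherits(observer, "observer"))
  with_seed(seed, {
    run_track <- function(down_rule, start) {
      level <- start
      consec <- 0L
      dir <- 0L
      reversals <- numeric(0)
      step <- step_db
      trials <- 0L
      while (length(reversals) < n_reversals) {
        trials <- trials + 1L
        if (trials > max_trials) {
          stop("loudness balancing did not converge within ", max_trials,
               " trials")
        }
        louder <- observer$louder(level, b_ref_level, a_spec$center_freq)
        # down_rule consecutive "louder" judgments -> step down; otherwise a
        # single "softer" judgment -> step up (and vice versa for the
        # mirrored track, where down_rule applies to "softer").
        if (down_rule == 2) {
          if (louder) consec <- consec + 1L else consec <- 0L
          move <- if (consec >= 2L) { consec <- 0L; -1L } else if (!louder) 1L else 0L
        } else {
          if (!louder) consec <- consec + 1L else consec <- 0L
          move <- if (consec >= 2L) { consec <- 0L; +1L } else if (louder) -1L else 0L
        }
        if (move != 0L) {
          if (dir != 0L && move != dir) {
            reversals <- c(reversals, level)
            if (length(reversals) == 2) step <- small_step_db
          }
          dir <- move
          level <- level + move * step
        }
      }
      mean(utils::tail(reversals, 6))
    }
    t1 <- run_track(down_rule = 2, start = b_ref_level + 2 * step_db)
    t2 <- run_track(down_rule = 1, start = b_ref_level - 2 * step_db)
    (t1 + t2) / 2
  })
}

#' Run a complete simulated session
#'
#' Training blocks (40 trials, cycling through the 18 conditions in random
#' order) run until the training gate passes or `training_cap` blocks have
#' been spent; loudness balancing derives the A level for the moderate and
#' large separations; then the 18 conditions are run in pseudorandom order,
#' two consecutive 65-trial blocks each.
#'
#' @param profile a `listener_profile`.
#' @param observer an `observer`.
#' @param master_seed integer seed governing the whole session.
#' @param n_trials trials per experimental block.
#' @param training_cap maximum number of training blocks.
#' @param balance_loudness run the loudness-balancing procedure (skipped by
#'   default for timing-only observers, whose responses do not depend on
#'   level).
#' @return a `session` object: list with `blocks` (36 scored
#'   `trial_block`s), `training` (training blocks), `order` (the block
#'   schedule), `a_levels`, `passed_training`, `profile` and `master_seed`.
#' @export
run_session <- function(profile, observer, master_seed = NULL,
                        n_trials = 65L, training_cap = 20L,
                        balance_loudness = identical(observer$needs, "waveform")) {
  stopifnot(inherits(profile, "listener_profile"), inherits(observer, "observer"))
  seeds <- derive_seeds(master_seed, 4L)
  grid <- build_condition_grid()

  # training phase
  training <- list()
  passed <- FALSE
  cycle <- integer(0)
  tseeds <- derive_seeds(seeds[[1]], training_cap + 1L)
  for (b in seq_len(training_cap)) {
    if (length(cycle) == 0) {
      cycle <- with_seed(tseeds[[training_cap + 1L]],
                         sample.int(nrow(grid)))
    }
    cond <- grid[cycle[1], ]
    cycle <- cycle[-1]
    blk <- run_block(cond, observer, profile, seed = tseeds[[b]],
                     n_trials = 40L, n_familiarization = 0L,
                     block_index = b, phase = "training")
    training[[b]] <- blk
    if (training_gate(training)) { passed <- TRUE; break }
  }

  # loudness balancing (moderate and large separations)
  a_levels <- c(none = 60, moderate = 60, large = 60)
  if (balance_loudness) {
    bseeds <- derive_seeds(seeds[[2]], 2L)
    for (i in c("moderate", "large")) {
      spec <- band_specs_for(profile, i, "AM0-0")$A
      a_levels[[i]] <- loudness_balance(observer, spec,
                                        seed = bseeds[[match(i, c("moderate", "large"))]])
    }
  }

  blocks <- list()
  order <- pseudorandom_condition_order(seed = seeds[[3]])
  if (passed) {
    oseeds <- derive_seeds(seeds[[4]], nrow(order))
    blocks <- lapply(seq_len(nrow(order)), function(s) {
      run_block(order[s, ], observer, profile, seed = oseeds[[s]],
                n_trials = n_trials,
                a_level = a_levels[[as.character(order$spectral_sep[s])]],
                block_index = s, repetition = order$repetition[s],
                phase = "main")
    })
  }
  structure(list(profile = profile, blocks = blocks, training = training,
                 order = order, a_levels = a_levels,
                 passed_training = passed, master_seed = master_seed),
            class = "session")
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("<session> %s: %d training block(s) (gate %s), %d scored block(s)\n",
              x$profile$id, length(x$training),
              if (x$passed_training) "passed" else "FAILED",
              length(x$blocks)))
  invisible(x)
}

#' Session trial log as a data frame
#'
#' One row per trial across training and main phases.
#'
#' @param x a `session`.
#' @param ... unused.
#' @return a data frame.
#' @export
as.data.frame.session <- function(x, ...) {
  one <- function(b) {
    data.frame(phase = b$phase, n_pairs = b$n_pairs,
               spectral_sep = as.character(b$spectral_sep),
               am_sep = as.character(b$am_sep),
               repetition = b$repetition, b$trials)
  }
  do.call(rbind, c(lapply(x$training, one), lapply(x$blocks, one)))
}

#' Write a session trial log to CSV
#'
#' @param session a `session`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_session_csv <- function(session, path) {
  utils::write.csv(as.data.frame(session), path, row.names = FALSE)
  invisible(path)
}
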