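# Independent oracles used across tests.

# Standard-normal quantile by bisection on pnorm (independent of qnorm).
oracle_qnorm <- function(p, tol = 1e-12) {
  stopifnot(p > 0, p < 1)
  lo <- -12; hi <- 12
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (stats::pnorm(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# d' recomputed from raw response vectors by brute-force counting plus the
# bisection quantile; mirrors the scoring definitions, not the implementation.
oracle_dprime_from_responses <- function(trial_type, response, correction) {
  ns <- sum(trial_type == "delayed")
  nn <- sum(trial_type == "no_delay")
  hits <- sum(trial_type == "delayed" & response == "delayed")
  fas <- sum(trial_type == "no_delay" & response == "delayed")
  if (correction == "loglinear") {
    h <- (hits + 0.5) / (ns + 1); f <- (fas + 0.5) / (nn + 1)
  } else {
    h <- min(max(hits / ns, 1 / (2 * ns)), 1 - 1 / (2 * ns))
    f <- min(max(fas / nn, 1 / (2 * nn)), 1 - 1 / (2 * nn))
  }
  oracle_qnorm(h) - oracle_qnorm(f)
}

# Mean power spectrum of repeated bursts (periodogram average).
mean_burst_spectrum <- function(spec, n_bursts, fs = 44100, seed = 1) {
  n <- round(0.08 * fs)
  acc <- numeric(n)
  for (i in seq_len(n_bursts)) {
    b <- synth_burst(spec, fs = fs, seed = seed + i)
    acc <- acc + Mod(stats::fft(b$samples))^2
  }
  list(freq = (seq_len(n) - 1) * fs / n, power = acc / n_bursts)
}

# An observer that counts feedback calls and records their order.
counting_observer <- function() {
  env <- new.env()
  env$feedback_count <- 0L
  env$responded <- 0L
  obs <- structure(list(
    kind = "counter", needs = "timing",
    respond = function(trial) {
      env$responded <- env$responded + 1L
      "delayed"
    },
    feedback = function(trial, correct) {
      env$feedback_count <- env$feedback_count + 1L
      # feedback must arrive only after the trial's response
      stopifnot(env$feedback_count == env$responded)
    },
    louder = function(level_db, ref_db, freq) stats::runif(1) < 0.5
  ), class = "observer")
  list(observer = obs, env = env)
}
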