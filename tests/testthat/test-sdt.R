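test_that("block scoring counts hits and false alarms from the last 60 trials", {
  mk <- function(types, resps, n_fam = 5) {
    n <- length(types)
    trials <- data.frame(block_index = 1L, trial_index = seq_len(n),
                         trial_type = types, response = resps,
                         correct = types == resps,
                         familiarization = seq_len(n) <= n_fam,
                         seed = NA_integer_)
    structure(list(trials = trials, n_pairs = 9L, spectral_sep = "large",
                   am_sep = "AM0-0", repetition = 1L, phase = "main",
                   n_trials = n), class = "trial_block")
  }
  types <- c(rep("delayed", 5), rep("delayed", 30), rep("no_delay", 30))
  resps <- c(rep("no_delay", 5),                       # familiarization, ignored
             rep("delayed", 24), rep("no_delay", 6),   # 24 hits
             rep("delayed", 6), rep("no_delay", 24))   # 6 false alarms
  s <- score_block(mk(types, resps))
  expect_equal(s[c("hits", "false_alarms", "n_signal", "n_noise")],
               list(hits = 24, false_alarms = 6, n_signal = 30, n_noise = 30))
  expect_equal(s$hit_rate, 0.8)
  expect_equal(s$fa_rate, 0.2)
  # flipping familiarization responses does not change the score
  resps2 <- resps; resps2[1:5] <- "delayed"
  expect_equal(score_block(mk(types, resps2)), s)
  # degenerate all-"delayed" responder: raw rates both 1
  s1 <- score_block(mk(types, rep("delayed", 65)))
  expect_equal(s1$hit_rate, 1)
  expect_equal(s1$fa_rate, 1)
  # incomplete blocks error
  short <- mk(types, resps); short$trials <- short$trials[1:50, ]
  expect_error(score_block(short), "incomplete")
})

test_that("d' equals Z(h) - Z(f) with both extreme-rate corrections", {
  # Phi(1) and Phi(-1) rates give d' of 2 exactly (clamp leaves them alone)
  expect_equal(dprime(pnorm(1) * 60, pnorm(-1) * 60, 60, 60,
                      correction = "clamp"), 2)
  # equal rates: chance
  expect_equal(dprime(15, 15, 30, 30, correction = "clamp"), 0)
  expect_equal(dprime(15, 15, 30, 30, correction = "loglinear"), 0)
  # perfect hits clamp to 1 - 1/(2N): 59/60 scored against f = 0.5
  expect_equal(dprime(30, 15, 30, 30, correction = "clamp"),
               qnorm(1 - 1 / 60), tolerance = 1e-12)
  expect_equal(round(dprime(30, 15, 30, 30, correction = "clamp"), 3), 2.128)
  # antisymmetry under swapping hits and false alarms
  for (co in c("loglinear", "clamp")) {
    expect_equal(dprime(24, 6, 30, 30, correction = co),
                 -dprime(6, 24, 30, 30, correction = co))
  }
  expect_error(dprime(1, 0, 0, 10), "at least one trial")
  expect_error(dprime(31, 0, 30, 30), "between 0")
})

test_that("d' agrees with the brute-force oracle to 1e-10", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(20:200, 1)
    types <- sample(c("delayed", "no_delay"), n, replace = TRUE,
                    prob = c(0.5, 0.5))
    if (length(unique(types)) < 2) next
    d_true <- runif(1, 0, 3)
    resp <- ifelse(runif(n) < ifelse(types == "delayed",
                                     pnorm(d_true / 2), pnorm(-d_true / 2)),
                   "delayed", "no_delay")
    ns <- sum(types == "delayed"); nn <- n - ns
    h <- sum(types == "delayed" & resp == "delayed")
    f <- sum(types == "no_delay" & resp == "delayed")
    co <- if (i %% 2) "loglinear" else "clamp"
    expect_lt(abs(dprime(h, f, ns, nn, correction = co) -
                    oracle_dprime_from_responses(types, resp, co)), 1e-10)
  }
})

test_that("d' estimates are consistent at large trial counts", {
  set.seed(9)
  for (d in c(0.5, 1.5, 2.5)) {
    est <- replicate(20, {
      ns <- 50000; nn <- 50000
      dprime(rbinom(1, ns, pnorm(d / 2)), rbinom(1, nn, pnorm(-d / 2)),
             ns, nn)
    })
    expect_lt(abs(mean(est) - d), 0.02)
  }
})

test_that("session summaries carry 36 corrected rows and condition means", {
  sess <- run_session(nh_profile(), sdt_observer(dprime = 2), master_seed = 21)
  tab <- summarize_session(sess)
  expect_s3_class(tab, "dprime_table")
  expect_equal(nrow(tab), 36)
  expect_true(all(tab$hit_rate > 0 & tab$hit_rate < 1))
  expect_true(all(tab$fa_rate > 0 & tab$fa_rate < 1))
  expect_equal(tab$dprime, qnorm(tab$hit_rate) - qnorm(tab$fa_rate))
  expect_true(all(table(paste(tab$n_pairs, tab$spectral_sep, tab$am_sep)) == 2))
  cm <- condition_means(tab)
  expect_equal(nrow(cm), 18)
  one <- tab[tab$n_pairs == 9 & tab$spectral_sep == "large" &
               tab$am_sep == "AM0-0", ]
  expect_equal(cm$dprime[cm$n_pairs == 9 & cm$spectral_sep == "large" &
                           cm$am_sep == "AM0-0"],
               mean(one$dprime))
  # deterministic given the session
  expect_identical(tab, summarize_session(sess))
  # missing blocks are reported
  broken <- sess; broken$blocks <- sess$blocks[-5]
  expect_error(summarize_session(broken), "missing blocks")
})

test_that("the build-up contrast isolates the duration coefficient", {
  # null build-up: same generating sensitivity at both durations (kept well
  # above the training gate so every simulated session completes)
  obs0 <- sdt_observer(beta0 = 2.5, beta_spec = 0, beta_am = 0, beta_dur = 0,
                       beta_group = 0)
  obs1 <- sdt_observer(beta0 = 2, beta_spec = 0.3, beta_am = 0,
                       beta_dur = 0.6, beta_group = 0)
  d0 <- d1 <- numeric(8)
  for (i in seq_len(8)) {
    t0 <- summarize_session(run_session(nh_profile(), obs0, master_seed = 100 + i))
    t1 <- summarize_session(run_session(nh_profile(), obs1, master_seed = 200 + i))
    d0[i] <- buildup_effect(t0)$overall
    d1[i] <- buildup_effect(t1)$overall
  }
  expect_lt(abs(mean(d0)), 0.15)   # ~3 SE around the true null
  expect_gt(mean(d1), 0.4)         # true contrast is 0.6
  be <- buildup_effect(summarize_session(run_session(nh_profile(), obs1,
                                                     master_seed = 300)))
  expect_equal(as.character(be$by_separation$spectral_sep),
               c("none", "moderate", "large"))
  # a table without 3-pair rows errors
  tab <- summarize_session(run_session(nh_profile(), obs0, master_seed = 400))
  expect_error(buildup_effect(tab[tab$n_pairs == 9, ]), "3-pair")
})
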