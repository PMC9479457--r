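test_that("condition grid has the full 2 x 3 x 3 design in canonical order", {
  grid <- build_condition_grid()
  expect_equal(nrow(grid), 18)
  expect_equal(nrow(unique(grid)), 18)
  expect_equal(sum(grid$n_pairs == 9 & grid$spectral_sep == "large" &
                     grid$am_sep == "AM0-0"), 1)
  # one AM0-0 cell per spectral level within each duration
  expect_equal(sum(grid$n_pairs == 3 & grid$am_sep == "AM0-0"), 3)
  expect_equal(grid$n_pairs, rep(c(3L, 9L), each = 9))
  expect_equal(as.character(grid$spectral_sep),
               rep(rep(c("none", "moderate", "large"), each = 3), 2))
})

test_that("band specs resolve profiles, bandwidths, AM pairs and levels", {
  nh <- band_specs_for(nh_profile(), "large", "AM300-50")
  expect_equal(nh$A$center_freq, 6665)
  expect_equal(nh$A$bandwidth, 216)
  expect_equal(nh$A$am_rate, 300)
  expect_equal(nh$B$center_freq, 1803)
  expect_equal(nh$B$bandwidth, 162)
  expect_equal(nh$B$am_rate, 50)
  expect_equal(nh$B$level, 60)

  none <- band_specs_for(nh_profile(), "none", "AM0-0")
  expect_equal(none$A$center_freq, none$B$center_freq)
  expect_equal(none$A$am_rate, 0)
  expect_equal(none$B$am_rate, 0)

  ci2 <- band_specs_for(ci_profiles()[["CI2"]], "moderate", "AM200-50")
  expect_equal(ci2$A$center_freq, 2871)
  expect_equal(ci2$B$center_freq, 1683)
  expect_equal(ci2$A$am_rate, 200)

  expect_error(band_specs_for(nh_profile(), "huge", "AM0-0"), "spectral")
})

test_that("implant profiles reproduce the transcribed band table", {
  cis <- ci_profiles()
  expect_named(cis, paste0("CI", 1:6))
  t2 <- cis[["CI2"]]$band_table
  expect_equal(t2$b_electrode, rep(12, 3))
  expect_equal(t2$a_cf[t2$spectral_sep == "moderate"], 2871)
  expect_equal(t2$a_electrode[t2$spectral_sep == "large"], 2)
  expect_equal(cis[["CI3"]]$brand, "MED-EL")
  # B band always at the channel holding ~1.8 kHz; all moderate separations
  # lie in the 0.70-0.91 octave range, large in 1.83-2.17
  # (ranges quoted at the 2-decimal reporting convention)
  for (p in cis) {
    tb <- p$band_table
    mod <- octave_separation(tb$a_cf[2], tb$b_cf[2], digits = 2)
    lar <- octave_separation(tb$a_cf[3], tb$b_cf[3], digits = 2)
    expect_gte(mod, 0.70); expect_lte(mod, 0.91)
    expect_gte(lar, 1.83); expect_lte(lar, 2.17)
  }
})

test_that("sequence timing follows the nominal grid, delay and advance rules", {
  t9 <- make_sequence_timing(9, "delayed", seed = 1)
  expect_equal(sequence_duration(t9), 2.325)
  b_on <- t9$events$onset[t9$events$stream == "B"]
  expect_equal(b_on[-9], 130 + 260 * (0:7))
  expect_equal(b_on[9], 130 + 260 * 8 + 35)

  # zero-advance reference trial sits exactly on the nominal grid
  t3 <- make_sequence_timing(3, "no_delay", seed = 1)
  t3$final_shift <- 0
  t3$events$onset[6] <- 130 + 260 * 2
  expect_equal(t3$events$onset[t3$events$stream == "B"][3], 650)

  # the rules yield 765 ms for the 3-pair delayed sequence
  expect_equal(sequence_duration(make_sequence_timing(3, "delayed", seed = 2)),
               0.765)
})

test_that("timing invariants hold over many random draws", {
  gaps_all <- numeric(0)
  durations <- numeric(0)
  for (i in 1:2000) {
    tt <- if (i %% 2) "delayed" else "no_delay"
    np <- if (i %% 4 < 2) 9 else 3
    tm <- make_sequence_timing(np, tt, seed = i)
    ev <- tm$events
    expect_equal(nrow(ev), 2 * np)
    expect_equal(ev$stream, rep(c("A", "B"), np))
    expect_equal(ev$onset[1], 0)
    expect_equal(tm$jitters[1], 0)
    expect_true(all(abs(tm$jitters) <= 40))
    # non-final B bursts exactly on the rigid grid
    b_on <- ev$onset[ev$stream == "B"]
    expect_equal(b_on[-np], 130 + 260 * (seq_len(np)[-np] - 1))
    g <- burst_gaps(tm)
    expect_true(all(g >= 10 - 1e-9 & g <= 90 + 1e-9))
    gaps_all <- c(gaps_all, g)
    if (np == 9) durations <- c(durations, sequence_duration(tm))
    if (tt == "delayed") {
      expect_equal(tm$final_shift, 35)
    } else {
      expect_gte(tm$final_shift, -10); expect_lte(tm$final_shift, 0)
    }
  }
  # gap distribution approaches its stated bounds
  expect_gt(max(gaps_all), 89.5)
  expect_lt(min(gaps_all), 10.5)
  # delayed 9-pair duration is constant; no-delay within 2.28-2.29 s
  expect_equal(unique(durations[seq(1, length(durations), 2)]), 2.325)
  nodelay <- durations[seq(2, length(durations), 2)]
  expect_true(all(nodelay >= 2.28 & nodelay <= 2.29))
})

test_that("octave separation matches quoted values and rejects bad input", {
  expect_equal(octave_separation(3022, 1803, digits = 2), 0.75)
  expect_equal(octave_separation(6665, 1803, digits = 2), 1.89)
  expect_equal(octave_separation(1803, 1803), 0)
  expect_equal(octave_separation(7352, 1632, digits = 2), 2.17)
  expect_equal(octave_separation(200, 50, digits = 2), 2)
  # symmetric in its arguments
  expect_equal(octave_separation(50, 300), octave_separation(300, 50))
  expect_error(octave_separation(-1, 100), "positive")
})

test_that("pseudorandom order nests AM within duration-by-spectral cells and pairs repetitions", {
  ord <- pseudorandom_condition_order(seed = 5)
  expect_equal(nrow(ord), 36)
  key <- paste(ord$n_pairs, ord$spectral_sep, ord$am_sep)
  expect_equal(sort(table(key), decreasing = TRUE), table(key)[order(-table(key))])
  expect_true(all(table(key) == 2))
  # repetitions of the same condition occupy consecutive slots
  for (k in unique(key)) {
    slots <- ord$slot[key == k]
    expect_equal(diff(slots), 1)
  }
  # duration x spectral cells are contiguous runs of 6 slots
  cell <- paste(ord$n_pairs, ord$spectral_sep)
  expect_equal(rle(cell)$lengths, rep(6, 6))
  # deterministic under the seed; different seeds reshuffle
  expect_identical(ord, pseudorandom_condition_order(seed = 5))
  expect_false(identical(ord, pseudorandom_condition_order(seed = 6)))
})

test_that("timing exports to a tidy CSV", {
  tm <- make_sequence_timing(3, "delayed", seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_timing_csv(tm, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 6)
  expect_equal(df$stream, rep(c("A", "B"), 3))
  expect_equal(df$duration, rep(80, 6))
  expect_equal(df$trial_type, rep("delayed", 6))
})
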