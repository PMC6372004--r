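test_that("frozen patterns have Poisson counts and uniform times", {
  cfg <- pattern_config(N = 1e4, f = 3.2, L = 0.1, seed = 11)
  pat <- generate_pattern(cfg)

  counts <- tabulate(pat$afferent + 1L, nbins = cfg$N)
  # per-afferent counts are iid Poisson(0.32): chi-square against the pmf
  obs <- c(sum(counts == 0), sum(counts == 1), sum(counts == 2),
           sum(counts >= 3))
  p_exp <- c(dpois(0:2, 0.32), ppois(2, 0.32, lower.tail = FALSE))
  chi <- suppressWarnings(chisq.test(obs, p = p_exp))
  expect_gt(chi$p.value, 0.01)

  # spike times uniform on [0, L)
  expect_true(all(pat$time >= 0 & pat$time < cfg$L))
  ks <- suppressWarnings(ks.test(pat$time, "punif", 0, cfg$L))
  expect_gt(ks$p.value, 0.01)

  # sorted by (time, afferent)
  expect_false(is.unsorted(pat$time))
})

test_that("pattern generation is deterministic given the seed", {
  cfg <- pattern_config(N = 500, f = 5, L = 0.05, seed = 3)
  expect_identical(generate_pattern(cfg), generate_pattern(cfg))
  cfg2 <- pattern_config(N = 500, f = 5, L = 0.05, seed = 4)
  expect_false(identical(generate_pattern(cfg), generate_pattern(cfg2)))
})

test_that("a vanishing pattern window contains no spikes", {
  cfg <- pattern_config(N = 1, f = 100, L = 1e-9, seed = 1)
  expect_equal(nrow(generate_pattern(cfg)), 0)
})

test_that("invalid pattern configurations are rejected", {
  expect_error(pattern_config(N = 0, f = 1, L = 0.1), "N")
  expect_error(pattern_config(N = 10, f = -1, L = 0.1), "f")
  expect_error(pattern_config(N = 10, f = 1, L = 0), "L")
  expect_error(pattern_config(N = 10, f = 1, L = 0.1, interval = 0.05,
                              n_presentations = 2), "interval")
})

test_that("sessions place unjittered patterns exactly at their onsets", {
  cfg <- pattern_config(N = 50, f = 4, L = 0.02, T = 0, interval = 0.1,
                        n_presentations = 1, seed = 9)
  pat <- generate_pattern(cfg)
  sess <- build_session(pat, cfg)
  onset <- session_onsets(sess)
  expect_length(onset, 1)
  in_win <- sess[sess$time >= onset & sess$time < onset + cfg$L, ]
  expect_equal(sort(in_win$time - onset), sort(pat$time))
  expect_setequal(in_win$afferent, pat$afferent)
})

test_that("jitter moves pattern spikes but conserves their number", {
  cfg <- pattern_config(N = 200, f = 5, L = 0.02, T = 0.004,
                        interval = 0.1, n_presentations = 20, seed = 21)
  pat <- generate_pattern(cfg)
  sess <- build_session(pat, cfg)
  onsets <- session_onsets(sess)
  # count events near each presentation attributable to pattern afferents:
  # background was excluded from [onset, onset + L], so events in
  # [onset - T, onset + L + T] from pattern spikers are >= the pattern size
  # and exactly equal in total count terms
  total_expected <- nrow(pat) * cfg$n_presentations
  in_any <- purrr::map_int(seq_along(onsets), function(k) {
    sum(sess$time >= onsets[k] - cfg$T & sess$time <= onsets[k] + cfg$L + cfg$T &
          sess$afferent %in% pat$afferent)
  })
  # background contributes only in the +/- T margins; bound its rate
  margin_spikes <- 2 * cfg$T * cfg$f * cfg$N * cfg$n_presentations
  expect_gte(sum(in_any), total_expected)
  expect_lte(sum(in_any), total_expected + 3 * margin_spikes + 30)
})

test_that("session spike totals match the Poisson expectation", {
  cfg <- pattern_config(N = 2000, f = 3.2, L = 0.1, T = 0.0032,
                        interval = 0.4, n_presentations = 50, seed = 31)
  pat <- generate_pattern(cfg)
  sess <- build_session(pat, cfg)
  duration <- train_duration(sess)
  # background covers duration - n_pres * L; pattern adds n_pres * |pattern|
  mu <- cfg$N * cfg$f * (duration - cfg$n_presentations * cfg$L) +
    cfg$n_presentations * nrow(pat)
  expect_lt(abs(nrow(sess) - mu), 3 * sqrt(mu) + 3 * sqrt(nrow(pat)))
  expect_true(all(sess$time >= 0 & sess$time < duration))
  expect_false(is.unsorted(sess$time))
})

test_that("sessions are deterministic and reject too-short intervals", {
  cfg <- pattern_config(N = 100, f = 5, L = 0.02, T = 0.002,
                        interval = 0.1, n_presentations = 5, seed = 5)
  pat <- generate_pattern(cfg)
  expect_identical(build_session(pat, cfg), build_session(pat, cfg))
  bad <- pattern_config(N = 100, f = 5, L = 0.02, T = 0.015,
                        interval = 0.03, n_presentations = 5, seed = 5)
  expect_error(build_session(pat, bad), "interval")
})

test_that("strategy selection picks exactly the >= n spikers", {
  pat <- fixture_pattern(c(0.010, 0.020, 0.030), N = 10, L = 0.1)
  sel <- select_afferents(pat, n = 1, dt_window = 0.015, t0 = 0.015)
  expect_identical(sel$selected[[1]], 1L)  # only afferent 1 spikes there

  # every afferent spikes exactly once: strategy 2 selects nobody
  sel2 <- select_afferents(pat, n = 2, dt_window = 0.1, t0 = 0)
  expect_length(sel2$selected[[1]], 0)

  expect_error(select_afferents(pat, n = 1, dt_window = 0.2), "dt_window")
  expect_error(select_afferents(pat, n = 1, dt_window = 0.05, t0 = 0.08),
               "window")
})

test_that("selection is monotone in strategy number and window length", {
  cfg <- pattern_config(N = 2000, f = 10, L = 0.05, seed = 13)
  pat <- generate_pattern(cfg)
  s1 <- select_afferents(pat, 1, 0.05)$selected[[1]]
  s2 <- select_afferents(pat, 2, 0.05)$selected[[1]]
  s3 <- select_afferents(pat, 3, 0.05)$selected[[1]]
  expect_true(all(s3 %in% s2))
  expect_true(all(s2 %in% s1))
  w_small <- select_afferents(pat, 1, 0.02, t0 = 0.01)$selected[[1]]
  w_big <- select_afferents(pat, 1, 0.04, t0 = 0.01)$selected[[1]]
  expect_true(all(w_small %in% w_big))
})

test_that("expected selection size and rate match their closed forms", {
  expect_equal(expected_M(1e4, 3.2, 0.1, 1), 1e4 * (1 - exp(-0.32)))
  expect_equal(round(expected_M(1e4, 3.2, 0.1, 1), 1), 2738.5)
  # n = 5 equals the Poisson survival function
  expect_equal(expected_M(1e4, 3.2, 0.1, 5),
               1e4 * ppois(4, 0.32, lower.tail = FALSE))
  # huge window selects everyone under strategy 1
  expect_equal(expected_M(500, 2, 1e4, 1), 500, tolerance = 1e-12)
  # strategy 1 keeps the full population rate
  expect_equal(expected_r(1e4, 3.2, 0.023, 1), 3.2e4)
  # very large n discards everything
  expect_lt(expected_r(1e4, 3.2, 0.023, 30), 1e-12)
})

test_that("Monte-Carlo selection agrees with the expectation formulas", {
  N <- 1000; f <- 3.2; dt <- 0.023
  reps <- 400
  Ms <- rs <- matrix(NA_real_, reps, 2)
  for (i in seq_len(reps)) {
    pat <- generate_pattern(pattern_config(N = N, f = f, L = dt, seed = 1e5 + i))
    for (n in 1:2) {
      sel <- select_afferents(pat, n, dt)
      Ms[i, n] <- sel$M
      rs[i, n] <- sel$r_window
    }
  }
  for (n in 1:2) {
    m_th <- expected_M(N, f, dt, n)
    se <- sd(Ms[, n]) / sqrt(reps)
    expect_lt(abs(mean(Ms[, n]) - m_th), 3 * se + 1e-9)
    r_th <- expected_r(N, f, dt, n)
    se_r <- sd(rs[, n]) / sqrt(reps)
    expect_lt(abs(mean(rs[, n]) - r_th), 3 * se_r + 1e-9)
  }
})

test_that("spike trains round-trip through delimited text bit-exactly", {
  cfg <- pattern_config(N = 300, f = 8, L = 0.05, seed = 77)
  pat <- generate_pattern(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spike_trains(pat, path)
  expect_identical(readLines(path)[1], "afferent,time_s")
  back <- read_spike_trains(path, N = 300, duration = 0.05)
  expect_identical(back$afferent, pat$afferent)
  expect_identical(back$time, pat$time)
})

test_that("pattern configurations round-trip through YAML", {
  cfg <- pattern_config(N = 100, f = 3.2, L = 0.1, T = 0.0032,
                        interval = 0.4, n_presentations = 10, seed = 2)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_pattern_config(cfg, path)
  expect_equal(read_pattern_config(path), cfg)
})
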