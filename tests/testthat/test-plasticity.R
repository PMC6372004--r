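test_that("the initial-weight rule places the noise mean 2 sd above theta", {
  w0 <- initial_weight(theta = 370, tau = 0.018, f = 3.2, N = 1e4)
  expect_equal(round(w0, 2), 0.68)
  # defining identity: w0 tau f N = theta + 2 w0 sqrt(tau f N / 2)
  mu1 <- 0.018 * 3.2 * 1e4
  expect_equal(w0 * mu1, 370 + 2 * w0 * sqrt(mu1 / 2), tolerance = 1e-12)
  # the second published operating point, to the printed precision
  expect_lt(abs(initial_weight(250, 0.018, 3.2, 1e4) - 0.47), 0.01)
  # linear in theta
  expect_equal(initial_weight(740, 0.018, 3.2, 1e4), 2 * w0)
  expect_error(initial_weight(10, 0.01, 1, 5), "too small")
})

test_that("the compiled STDP kernel matches a plain-R reference", {
  set.seed(23)
  n_aff <- 6
  times <- sort(runif(150, 0, 0.4))
  affs <- sample(0:(n_aff - 1), 150, replace = TRUE)
  w0 <- rep(0.5, n_aff)
  res <- stdplif:::stdp_sim_cpp(times, affs, n_aff, tau = 0.02,
                                theta = 1.2, dt_bin = 1e-3, duration = 0.4,
                                w_init = w0, d_apre = 0.05, tau_pre = 0.02,
                                w_out = -0.02, dead_time = 0)
  ref <- r_stdp(times, affs, n_aff, 0.02, 1.2, 1e-3, 0.4, w0,
                0.05, 0.02, -0.02)
  expect_gt(length(res$post_spikes), 3)
  expect_equal(res$post_spikes, ref$post_spikes, tolerance = 1e-12)
  expect_equal(res$weights, ref$weights, tolerance = 1e-10)
})

test_that("a single pre-post pair potentiates by the decayed trace", {
  # afferent 0 fires at t1; afferent 1 (weight 1) forces a post spike at t2
  t1 <- 0.0100005; t2 <- 0.0300005
  d_apre <- 0.01; tau_pre <- 0.02; w_out <- -0.002
  res <- stdplif:::stdp_sim_cpp(
    spike_time = c(t1, t2), spike_aff = c(0L, 1L), n_aff = 3,
    tau = 0.02, theta = 0.9, dt_bin = 1e-4, duration = 0.05,
    w_init = c(0.5, 1, 0.5), d_apre = d_apre, tau_pre = tau_pre,
    w_out = w_out, dead_time = 0)
  t_post <- res$post_spikes[1]
  expect_equal(t_post, 0.0301, tolerance = 1e-9)  # bin edge after t2
  # paired synapse: LTP decayed over the pre-post lag, plus homeostasis
  expect_equal(res$weights[1],
               0.5 + d_apre * exp(-(t_post - t1) / tau_pre) + w_out,
               tolerance = 1e-12)
  # silent synapse: homeostatic term only
  expect_equal(res$weights[3], 0.5 + w_out, tolerance = 1e-12)
})

test_that("without homeostasis steady firing saturates all weights", {
  set.seed(5)
  n_aff <- 4
  times <- sort(runif(2000, 0, 1))
  affs <- sample(0:(n_aff - 1), 2000, replace = TRUE)
  res <- stdplif:::stdp_sim_cpp(times, affs, n_aff, tau = 0.02,
                                theta = 1.0, dt_bin = 1e-4, duration = 1,
                                w_init = rep(0.5, n_aff), d_apre = 0.05,
                                tau_pre = 0.02, w_out = 0, dead_time = 0)
  expect_true(all(res$weights == 1))
})

test_that("weights stay inside [0, 1] throughout learning", {
  cfg <- pattern_config(N = 400, f = 5, L = 0.05, T = 0.002,
                        interval = 0.2, seed = 41)
  pat <- generate_pattern(cfg)
  scfg <- stdp_config(theta = 15, w_out = -0.004, tau = 0.015,
                      n_presentations = 60, interval = 0.2)
  out <- suppressWarnings(run_stdp(pat, cfg, scfg))
  expect_true(all(out$weights >= 0 & out$weights <= 1))
  expect_gt(length(out$post_spikes), 0)
  # deterministic given the seed
  out2 <- suppressWarnings(run_stdp(pat, cfg, scfg))
  expect_identical(out$weights, out2$weights)
})

test_that("a silent neuron is reported dead instead of hanging", {
  cfg <- pattern_config(N = 50, f = 5, L = 0.05, T = 0,
                        interval = 0.2, seed = 6)
  pat <- generate_pattern(cfg)
  # theta far above what 50 unit-weight afferents can depolarize
  scfg <- stdp_config(theta = 50, w_out = -0.001, n_presentations = 60,
                      interval = 0.2)
  msgs <- capture_warnings(out <- run_stdp(pat, cfg, scfg))
  expect_true(any(grepl("dead", msgs)))
  expect_true(out$dead)
  expect_false(out$converged)
  expect_equal(classify_optimal(out, pat, 0.023)$reason, "dead")
})

test_that("high-threshold strong-depression learning locks one spike per presentation", {
  cfg <- pattern_config(N = 1e4, f = 3.2, L = 0.1, T = 3.2e-3, seed = 7)
  pat <- generate_pattern(cfg)
  out <- suppressWarnings(run_stdp(pat, cfg,
                                   stdp_config(theta = 370, w_out = -3.5e-3)))
  # convergence by saturation: bimodal weights at the bounds
  expect_gte(out$frac_binarized, 0.95)
  expect_true(out$converged)
  expect_equal(out$spikes_per_presentation, 1, tolerance = 0.1)
  # selectivity precedes convergence: output spikes confined to the
  # presentation windows long before the 500-presentation session ends
  mid <- out$post_spikes[out$post_spikes > 30 & out$post_spikes < 60]
  onsets <- out$onsets
  i <- findInterval(mid, onsets - cfg$T)
  in_win <- i >= 1 & mid <= (onsets + cfg$L + cfg$T)[pmax(i, 1)]
  expect_gte(mean(in_win), 0.9)
})

test_that("constructed weight vectors classify against the window rule", {
  cfg <- pattern_config(N = 2000, f = 3.2, L = 0.1, seed = 55)
  pat <- generate_pattern(cfg)
  dt_opt <- 0.023

  # exact indicator of the afferents spiking in [0, 23 ms): optimal
  sel <- select_afferents(pat, 1, dt_opt, 0)$selected[[1]]
  w_ind <- ifelse((seq_len(cfg$N) - 1L) %in% sel, 1, 0)
  cls <- classify_optimal(w_ind, pat, dt_opt)
  expect_true(cls$optimal)
  expect_equal(cls$window_duration, dt_opt, tolerance = 0.1)

  # all weights reinforced: the only candidate window is the whole pattern
  cls_all <- classify_optimal(rep(1, cfg$N), pat, dt_opt)
  expect_false(cls_all$optimal)

  # indicator of a 40-ms window: duration outside the 10% margin
  sel40 <- select_afferents(pat, 1, 0.040, 0)$selected[[1]]
  w40 <- ifelse((seq_len(cfg$N) - 1L) %in% sel40, 1, 0)
  cls40 <- classify_optimal(w40, pat, dt_opt)
  expect_false(cls40$optimal)

  # half-binarized weights are rejected as unconverged
  w_mid <- w_ind
  w_mid[1:300] <- 0.5
  expect_equal(classify_optimal(w_mid, pat, dt_opt)$reason, "unconverged")
})

test_that("window classification agrees with a brute-force scan", {
  dt_opt <- 0.02
  set.seed(14)
  for (i in 1:6) {
    # random small pattern and a window-indicator weight vector with noise
    cfg <- pattern_config(N = 60, f = 12, L = 0.1, seed = 500 + i)
    pat <- generate_pattern(cfg)
    d_true <- sample(c(0.012, 0.02, 0.035), 1)
    t0 <- runif(1, 0, 0.1 - d_true)
    sel <- select_afferents(pat, 1, d_true, t0)$selected[[1]]
    w <- ifelse((seq_len(cfg$N) - 1L) %in% sel, 1, 0)
    cls <- classify_optimal(w, pat, dt_opt)
    brute <- brute_window_exists(pat, required = sel,
                                 forbidden = setdiff(unique(pat$afferent), sel),
                                 dt_opt = dt_opt)
    expect_equal(cls$optimal, brute,
                 info = sprintf("case %d: d_true=%g t0=%g", i, d_true, t0))
  }
})

test_that("mode analysis tabulates optimality over a small grid", {
  base <- pattern_config(N = 400, f = 5, L = 0.05, T = 0.001,
                         interval = 0.2, seed = 70)
  tb <- mode_analysis(theta_grid = c(15, 25), w_out_grid = -0.004,
                      base_config = base, dt_opt = 0.02,
                      n_replicates = 2, tau = 0.015,
                      n_presentations = 40, interval = 0.2)
  expect_equal(nrow(tb), 2)
  expect_true(all(tb$p >= 0 & tb$p <= 100))
  expect_true(all(tb$convergence_fraction >= 0 & tb$convergence_fraction <= 1))
  expect_named(tb, c("theta", "w_out", "n_replicates", "p",
                     "convergence_fraction", "mean_spikes_per_presentation",
                     "n_dead"))
})

test_that("geometric grids step by the requested ratio", {
  g <- geometric_grid(50, 1000, 1.1)
  expect_equal(g[1], 50)
  expect_true(all(abs(diff(log(g)) - log(1.1)) < 1e-12))
  expect_lte(max(g), 1000 * (1 + 1e-9))
  gn <- geometric_grid(-1e-2, -1e-4, 1.1)
  expect_true(all(gn < 0))
})
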