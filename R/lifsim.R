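#' LIF detector configuration
#'
#' @param tau Membrane time constant (s).
#' @param theta Firing threshold in unit-EPSP units, or `Inf` for
#'   threshold-free potential tracking. With unit weights the threshold
#'   reads as "number of synchronous presynaptic spikes needed to fire".
#' @param dt_bin Forward-Euler integration step (s, default 1e-4). Must
#'   be at most `tau / 10`.
#' @param weights Per-afferent synaptic weights in `[0, 1]`, or `NULL`
#'   for unit weights on every afferent.
#' @return A `lif_config` list.
#' @export
lif_config <- function(tau, theta = Inf, dt_bin = 1e-4, weights = NULL) {
  stopifnot(tau > 0, dt_bin > 0)
  if (dt_bin > tau / 10) {
    abort("`dt_bin` must be <= tau / 10 for a usable Euler discretization.")
  }
  if (!is.null(weights) && (any(weights < 0) || any(weights > 1))) {
    abort("`weights` must lie in [0, 1].")
  }
  structure(list(tau = tau, theta = theta, dt_bin = dt_bin,
                 weights = weights),
            class = "lif_config")
}

#' Simulate a LIF neuron driven by spike trains
#'
#' Clock-based forward-Euler integration with instantaneous synapses:
#' each bin the potential decays by `1 - dt_bin / tau` and jumps by the
#' summed weights of the bin's input spikes. If a threshold is set, a
#' crossing emits an output spike at the bin edge and resets the
#' potential to 0; there is no refractory period.
#'
#' @param trains A `spike_trains` tibble (columns `afferent`, `time`).
#' @param config A [lif_config()].
#' @param duration Simulated time (s); defaults to the trains' duration.
#' @param record_potential Keep the full potential trace (default TRUE).
#' @param v0 Initial potential (default 0).
#' @return A `lif_trace` tibble with columns `time` and `potential`
#'   (empty if `record_potential = FALSE`); output spike times are
#'   available via [output_spikes()].
#' @examples
#' trains <- generate_poisson_trains(N = 100, f = 5, duration = 1, seed = 1)
#' tr <- simulate_lif(trains, lif_config(tau = 0.018))
#' @export
simulate_lif <- function(trains, config, duration = NULL,
                         record_potential = TRUE, v0 = 0) {
  stopifnot(inherits(config, "lif_config"))
  duration <- duration %||% train_duration(trains)
  N <- n_afferents(trains)
  w <- config$weights %||% rep(1, N)
  if (length(w) != N) abort("`weights` must have one entry per afferent.")
  keep <- trains$time < duration
  res <- lif_sim_cpp(trains$time[keep], trains$afferent[keep], w,
                     config$tau, config$theta, config$dt_bin, duration,
                     record_potential, v0)
  out <- if (record_potential) {
    tibble(time = seq(0, by = config$dt_bin, length.out = res$n_bins + 1),
           potential = res$V)
  } else {
    tibble(time = numeric(0), potential = numeric(0))
  }
  attr(out, "out_spikes") <- res$out_spikes
  attr(out, "config") <- config
  attr(out, "duration") <- duration
  class(out) <- c("lif_trace", class(tibble()))
  out
}

#' Output spikes of a simulated LIF trace
#'
#' @param trace A `lif_trace` from [simulate_lif()].
#' @return Numeric vector of output spike times (s).
#' @export
output_spikes <- function(trace) attr(trace, "out_spikes")

#' @export
autoplot.lif_trace <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time,
                                            y = .data$potential)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "potential (unit EPSPs)")
  sp <- output_spikes(object)
  if (length(sp) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = sp, colour = "red",
                                 alpha = 0.3, linetype = "dotted")
  }
  p
}

#' Estimate the detection SNR from a potential trace
#'
#' The signal is the mean over presentations of the per-presentation
#' maximum potential, searched over `[onset - T, onset + L + T]` (jitter
#' can push the peak slightly outside the nominal window). The noise
#' statistics are taken over bins farther than `buffer` (default
#' `5 * tau`) past any presentation window, excluding the decay
#' transient. The SNR is `(Vmax_mean - noise_mean) / noise_sd`.
#'
#' @param trace A threshold-free `lif_trace`.
#' @param onsets Pattern onset times (s).
#' @param L Pattern duration (s).
#' @param T Jitter half-width (s).
#' @param buffer Post-window exclusion for the noise estimate (s);
#'   defaults to five membrane time constants.
#' @return A one-row `snr_estimate` tibble: `n_presentations`,
#'   `v_max_mean`, `v_max_sd`, `noise_mean`, `noise_sd`, `snr`.
#' @export
measure_snr <- function(trace, onsets, L, T = 0, buffer = NULL) {
  cfg <- attr(trace, "config")
  if (nrow(trace) == 0) abort("`trace` must carry a recorded potential.")
  if (length(output_spikes(trace)) > 0) {
    warn("trace has output spikes; SNR estimation assumes threshold-free dynamics.")
  }
  buffer <- buffer %||% (5 * cfg$tau)
  t <- trace$time
  V <- trace$potential

  win_lo <- onsets - T
  win_hi <- onsets + L + T
  i <- findInterval(t, win_lo)
  excl_hi <- win_hi + buffer
  in_excl <- i >= 1 & t <= excl_hi[pmax(i, 1)]

  noise <- V[!in_excl]
  if (length(noise) < 2) abort("no noise bins remain outside presentation windows.")
  noise_mean <- mean(noise)
  noise_sd <- sd(noise)
  if (noise_sd == 0) abort("degenerate noise: sd of the noise potential is 0.")

  vmax <- vapply(seq_along(onsets), function(k) {
    max(V[t >= win_lo[k] & t <= win_hi[k]])
  }, numeric(1))

  out <- tibble(
    n_presentations = length(onsets),
    v_max_mean = mean(vmax), v_max_sd = sd(vmax),
    noise_mean = noise_mean, noise_sd = noise_sd,
    snr = (mean(vmax) - noise_mean) / noise_sd
  )
  class(out) <- c("snr_estimate", class(out))
  out
}

#' Simulated versus theoretical SNR across jitter values
#'
#' For each of `n_patterns` random frozen patterns, wires a threshold-free
#' LIF to the Strategy-#n afferents (window = the whole pattern,
#' `dt_window = L`), replays the pattern `n_presentations` times in
#' Poisson background at each jitter in `T_grid`, measures the SNR with
#' [measure_snr()], and tabulates the across-pattern mean and standard
#' deviation next to the closed-form prediction.
#'
#' @param f Afferent rate (Hz).
#' @param N Afferent count.
#' @param L Pattern duration (s); also the selection window.
#' @param strategies Strategy numbers (subset of 1:2 at these rates —
#'   larger `n` selects too few afferents for the Gaussian noise
#'   approximation).
#' @param T_grid Jitter half-widths (s).
#' @param n_patterns Patterns in the ensemble.
#' @param n_presentations Presentations per pattern.
#' @param tau Membrane time constant of the detector (s).
#' @param interval Time between presentations (s).
#' @param dt_bin Euler step (s).
#' @param seed Root seed.
#' @return A `theory_validation` tibble: `strategy`, `T`,
#'   `snr_sim_mean`, `snr_sim_sd`, `snr_theory`, `n_patterns`; the
#'   per-pattern estimates are attached as attribute `per_pattern`.
#' @export
validate_theory <- function(f, N, L, strategies = c(1, 2),
                            T_grid = c(0, 1, 2, 4, 8) * 1e-3,
                            n_patterns = 20, n_presentations = 200,
                            tau = 0.018, interval = 0.4, dt_bin = 1e-4,
                            seed = 1) {
  cfg0 <- lif_config(tau = tau, theta = Inf, dt_bin = dt_bin)
  n_lo <- min(strategies)

  per_pattern <- purrr::map_dfr(seq_len(n_patterns), function(p) {
    pc <- pattern_config(N = N, f = f, L = L, T = 0, interval = interval,
                         n_presentations = n_presentations,
                         seed = child_seed(seed, paste0("vt-pat-", p)))
    pattern <- generate_pattern(pc)
    sels <- lapply(strategies, function(n) {
      select_afferents(pattern, n, dt_window = L, t0 = 0)$selected[[1]]
    })
    base_sel <- sels[[which.min(strategies)]]

    purrr::map_dfr(seq_along(T_grid), function(ti) {
      Tj <- T_grid[ti]
      pcT <- pattern_config(N = N, f = f, L = L, T = Tj,
                            interval = interval,
                            n_presentations = n_presentations,
                            seed = child_seed(seed,
                                              paste0("vt-", p, "-", ti)))
      sess <- build_session(pattern, pcT, afferents = base_sel)
      onsets <- session_onsets(sess)
      purrr::map_dfr(seq_along(strategies), function(si) {
        sel <- sels[[si]]
        ev <- sess[sess$afferent %in% sel, ]
        ev <- new_spike_trains(ev, N, train_duration(sess), onsets)
        tr <- simulate_lif(ev, cfg0)
        est <- measure_snr(tr, onsets, L, Tj)
        tibble(pattern = p, strategy = strategies[si], T = Tj,
               M = length(sel), snr = est$snr)
      })
    })
  })

  out <- per_pattern |>
    dplyr::group_by(.data$strategy, .data$T) |>
    dplyr::summarise(snr_sim_mean = mean(.data$snr),
                     snr_sim_sd = sd(.data$snr),
                     n_patterns = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(snr_theory = purrr::map2_dbl(
      .data$strategy, .data$T,
      function(n, Tj) snr_value(N, f, Tj, tau, L, n)))
  attr(out, "per_pattern") <- per_pattern
  class(out) <- c("theory_validation", class(out))
  out
}

#' @export
autoplot.theory_validation <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$T * 1e3,
                               colour = factor(.data$strategy))) +
    ggplot2::geom_line(ggplot2::aes(y = .data$snr_theory)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      y = .data$snr_sim_mean,
      ymin = .data$snr_sim_mean - .data$snr_sim_sd,
      ymax = .data$snr_sim_mean + .data$snr_sim_sd)) +
    ggplot2::labs(x = "jitter T (ms)", y = "SNR",
                  colour = "strategy n",
                  title = "Simulated (points) vs closed-form (lines) SNR")
}
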