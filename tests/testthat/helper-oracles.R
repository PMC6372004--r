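# Independent oracles used across the suite. They re-derive quantities by
# brute force or generic numerics, never through the package's own closed
# forms.

# Reduced potential under the jittered trapezoidal current, by generic ODE
# integration (deSolve); returns the peak of v(t).
ode_vmax <- function(dt_window, T, tau, n_steps = 20000) {
  i_of_t <- function(t) {
    t1 <- min(dt_window, 2 * T)
    t2 <- abs(dt_window - 2 * T)
    h <- if (T > 0) min(1, dt_window / (2 * T)) else 1
    if (T <= 0) {
      return(ifelse(t >= 0 & t < dt_window, 1, 0))
    }
    if (t < 0) 0
    else if (t < t1) h * t / t1
    else if (t < t1 + t2) h
    else if (t < t1 + t2 + t1) h * (1 - (t - t1 - t2) / t1)
    else 0
  }
  t_end <- dt_window + 2 * T + 5 * tau
  solve_on <- function(times) {
    deSolve::ode(
      y = c(v = 0), times = times,
      func = function(t, y, p) list((-y[1] + i_of_t(t)) / tau),
      parms = NULL, method = "ode45", rtol = 1e-12, atol = 1e-14
    )
  }
  # coarse pass locates the peak; dense pass around it removes the
  # grid-sampling error from the maximum
  coarse <- solve_on(seq(0, t_end, length.out = n_steps))
  i_pk <- which.max(coarse[, "v"])
  lo <- coarse[max(1, i_pk - 2), "time"]
  hi <- coarse[min(nrow(coarse), i_pk + 2), "time"]
  fine <- solve_on(c(0, seq(lo, hi, length.out = 4000)))
  max(fine[, "v"])
}

# Reference forward-Euler LIF in plain R (tiny inputs only).
r_lif <- function(times, affs, weights, tau, theta, dt_bin, duration,
                  v0 = 0) {
  n_bins <- ceiling(duration / dt_bin - 1e-9)
  V <- numeric(n_bins + 1)
  out <- numeric(0)
  v <- v0
  V[1] <- v
  for (b in seq_len(n_bins)) {
    t_end <- b * dt_bin
    v <- v * (1 - dt_bin / tau)
    in_bin <- times >= (b - 1) * dt_bin & times < t_end
    v <- v + sum(weights[affs[in_bin] + 1L])
    if (is.finite(theta) && v >= theta) {
      out <- c(out, t_end)
      V[b + 1] <- v
      v <- 0
      next
    }
    V[b + 1] <- v
  }
  list(V = V, out_spikes = out)
}

# Reference STDP simulator in plain R (tiny inputs only): same contract as
# the compiled kernel, written independently with dense trace updates.
r_stdp <- function(times, affs, n_aff, tau, theta, dt_bin, duration,
                   w_init, d_apre, tau_pre, w_out) {
  n_bins <- ceiling(duration / dt_bin - 1e-9)
  w <- w_init
  apre <- numeric(n_aff)
  apre_t <- 0
  v <- 0
  posts <- numeric(0)
  for (b in seq_len(n_bins)) {
    t_end <- b * dt_bin
    v <- v * (1 - dt_bin / tau)
    in_bin <- which(times >= (b - 1) * dt_bin & times < t_end)
    for (e in in_bin[order(times[in_bin])]) {
      a <- affs[e] + 1L
      apre <- apre * exp(-(times[e] - apre_t) / tau_pre)
      apre_t <- times[e]
      apre[a] <- apre[a] + d_apre
      v <- v + w[a]
    }
    if (v >= theta) {
      posts <- c(posts, t_end)
      tr <- apre * exp(-(t_end - apre_t) / tau_pre)
      w <- pmin(1, pmax(0, w + tr + w_out))
      v <- 0
    }
  }
  list(weights = w, post_spikes = posts)
}

# Brute-force window scan: does a window [t0, t0 + d) of the pattern exist
# whose >= n-spike afferent set covers `required` and excludes `forbidden`,
# with |d - dt_opt| <= margin * dt_opt? Scans a (t0, d) grid at `res`.
brute_window_exists <- function(pattern, required, forbidden, dt_opt,
                                margin = 0.10, res = 1e-4) {
  L <- train_duration(pattern)
  d_grid <- seq(max(res, dt_opt * (1 - margin)), dt_opt * (1 + margin),
                by = res)
  for (d in d_grid) {
    for (t0 in seq(0, L - d, by = res)) {
      inw <- pattern$time >= t0 & pattern$time < t0 + d
      spikers <- unique(pattern$afferent[inw])
      if (all(required %in% spikers) &&
          !any(forbidden %in% spikers)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Tiny deterministic pattern fixture: K afferents, one spike each at
# specified times (seconds).
fixture_pattern <- function(spike_times, N = length(spike_times), L = 0.1) {
  as_spike_trains(
    tibble::tibble(afferent = seq_along(spike_times) - 1L,
                   time = spike_times),
    N = N, duration = L
  )
}
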