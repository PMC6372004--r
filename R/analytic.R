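#' Stationary membrane statistics under Poisson bombardment
#'
#' A LIF with instantaneous unit-weight synapses driven by total Poisson
#' input rate `f * M` has stationary potential mean `tau * f * M` and
#' variance `tau * f * M / 2` (shot noise filtered by an exponential
#' kernel). The Gaussian approximation of the stationary distribution is
#' only good when `tau * f * M` is large; a warning is issued below 10.
#'
#' @param tau Membrane time constant (s).
#' @param f Per-afferent rate (Hz).
#' @param M Number of afferents.
#' @return A one-row tibble with `V_noise_mean` and `V_noise_sd`, in
#'   unit-EPSP potential units.
#' @examples
#' noise_stats(tau = 0.018, f = 3.2, M = 2739)
#' @export
noise_stats <- function(tau, f, M) {
  mu <- tau * f * M
  if (any(mu < 10)) {
    warn("tau * f * M < 10: Gaussian approximation of the noise potential is poor.")
  }
  tibble(V_noise_mean = mu, V_noise_sd = sqrt(mu / 2))
}

#' Trapezoidal input current produced by uniform jitter
#'
#' Replaying a window of `dt_window` seconds of spikes with per-spike
#' jitter uniform on `[-T, T]` smears the rectangular population rate
#' profile into a trapezoid with rise time `t1`, plateau `t2`, fall time
#' `t3` and plateau height `h` (relative to the unjittered rate):
#' `t1 = t3 = min(dt, 2T)`, `t2 = |dt - 2T|`, `h = min(1, dt / 2T)`.
#' The area is always `dt_window`: jitter moves spikes, it does not add
#' or remove them. At `T = 0` the trapezoid degenerates to the rectangle
#' (`t1 = t3 = 0`, `h = 1`).
#'
#' @param dt_window Window length (s).
#' @param T Jitter half-width (s).
#' @return A one-row tibble with `t1`, `t2`, `t3`, `h`.
#' @export
trapezoid_current <- function(dt_window, T) {
  stopifnot(all(dt_window > 0), all(T >= 0))
  k <- max(length(dt_window), length(T))
  dt_window <- rep_len(dt_window, k)
  T <- rep_len(T, k)
  t1 <- pmin(dt_window, 2 * T)
  tibble(t1 = t1,
         t2 = abs(dt_window - 2 * T),
         t3 = t1,
         h = ifelse(T > 0, pmin(1, dt_window / (2 * pmax(T, 1e-300))), 1))
}

#' Exact LIF response to a linear current ramp
#'
#' Solves `tau * dv/dt = -v + (a * t + b)` from `v(0) = v0`:
#' `v(t) = a * (t - tau) + b + (v0 - b + a * tau) * exp(-t / tau)`.
#' This is the closed form used piece by piece along the trapezoid.
#'
#' @param v0 Initial value (dimensionless).
#' @param a Current slope (1/s).
#' @param b Current intercept (dimensionless).
#' @param t Elapsed time (s); vectorized.
#' @param tau Time constant (s).
#' @return `v(t)`.
#' @examples
#' integrate_linear_piece(0, 0, 1, 0.018, 0.018)  # step response 1 - e^-1
#' @export
integrate_linear_piece <- function(v0, a, b, t, tau) {
  a * (t - tau) + b + (v0 - b + a * tau) * exp(-t / tau)
}

vmax_value <- function(dt_window, T, tau) {
  # vectorized peak of the reduced potential; T = 0 handled as exact limit
  k <- max(length(dt_window), length(T), length(tau))
  dt_window <- rep_len(dt_window, k)
  T <- rep_len(T, k)
  tau <- rep_len(tau, k)
  Tp <- pmax(T, 1e-300)  # avoid 0/0 in the unused branch
  h <- ifelse(T > 0, pmin(1, dt_window / (2 * Tp)), 1)
  rect <- 1 - exp(-dt_window / tau)
  trap <- h - tau / (2 * Tp) *
    log(1 - exp(-pmax(dt_window, 2 * T) / tau) +
          exp(-abs(dt_window - 2 * T) / tau))
  ifelse(T > 0, trap, rect)
}

#' Peak of the reduced potential for a jittered window
#'
#' Integrates the reduced LIF equation `tau * dv/dt = -v + i(t)` through
#' the trapezoidal current piece by piece: `v1` at the end of the rise,
#' `v2` at the end of the plateau, then the peak `v_max`, reached at
#' `t_max` after the plateau on the falling edge, where the closed form
#' gives `t_max = tau * log(1 + 2T(h - v2)/tau)` and
#' `v_max = h - t_max / 2T` (the maximum lies on the trapezoid edge).
#' For `T = 0` the rectangle limit `v_max = 1 - exp(-dt/tau)` applies
#' with `t_max = 0`.
#'
#' @param dt_window Window length (s).
#' @param T Jitter half-width (s).
#' @param tau Membrane time constant (s).
#' @return One-row tibble: `v_max`, `t_max` (s past the plateau end),
#'   `v1`, `v2`, `h`.
#' @examples
#' lif_vmax(0.023, 0.0032, 0.018)
#' @export
lif_vmax <- function(dt_window, T, tau) {
  stopifnot(all(dt_window > 0), all(T >= 0), all(tau > 0))
  k <- max(length(dt_window), length(T), length(tau))
  dt_window <- rep_len(dt_window, k)
  T <- rep_len(T, k)
  tau <- rep_len(tau, k)
  tz <- trapezoid_current(dt_window, T)
  T0 <- T <= 0
  Tp <- pmax(T, 1e-300)
  v1 <- ifelse(T0, 0,
               (tz$t1 + tau * (exp(-tz$t1 / tau) - 1)) / (2 * Tp))
  v2 <- tz$h + (v1 - tz$h) * exp(-tz$t2 / tau)
  t_max <- ifelse(T0, 0, tau * log(1 + 2 * T * (tz$h - v2) / tau))
  v_max <- ifelse(T0, v2, tz$h - t_max / (2 * Tp))
  tibble(v_max = v_max, t_max = t_max, v1 = v1, v2 = v2, h = tz$h)
}

#' Closed-form SNR of a Strategy-#n coincidence detector
#'
#' For a LIF (time constant `tau`, instantaneous unit-weight synapses)
#' wired to the afferents firing at least `n` spikes in a `dt_window`
#' window of a frozen Poisson pattern (`N` afferents at `f` Hz, jitter
#' half-width `T`), the signal-to-noise ratio
#' `(V_max - mean(V_noise)) / sd(V_noise)` has the closed form
#' `SNR = v_max * P(X = n - 1) * sqrt(2 * tau * N * f / P(X >= n))`
#' with `X ~ Poisson(f * dt_window)` and `v_max` from [lif_vmax()].
#'
#' @param N Afferent count.
#' @param f Per-afferent rate (Hz).
#' @param T Jitter half-width (s).
#' @param tau Membrane time constant (s).
#' @param dt_window Selection window (s).
#' @param n Strategy number (integer >= 1).
#' @param quiet Suppress the small-`tau*f*M` warning (used by sweeps).
#' @return A one-row `snr_breakdown` tibble exposing every intermediate
#'   quantity: `lambda`, `M`, `r`, `V_noise_mean`, `V_noise_sd`, `V_inf`,
#'   `h`, `v1`, `v2`, `t_max`, `v_max`, `snr`.
#' @examples
#' snr_analytic(N = 1e4, f = 3.2, T = 0.0032, tau = 0.018,
#'              dt_window = 0.023, n = 1)
#' @export
snr_analytic <- function(N, f, T, tau, dt_window, n, quiet = FALSE) {
  stopifnot(N >= 1, f > 0, T >= 0, tau > 0, dt_window > 0,
            n >= 1, n == round(n))
  lambda <- f * dt_window
  M <- expected_M(N, f, dt_window, n)
  r <- expected_r(N, f, dt_window, n)
  ns <- if (quiet) {
    suppressWarnings(noise_stats(tau, f, M))
  } else {
    noise_stats(tau, f, M)
  }
  vm <- lif_vmax(dt_window, T, tau)
  snr <- snr_value(N, f, T, tau, dt_window, n)
  out <- tibble(
    N = N, f = f, T = T, tau = tau, dt_window = dt_window, n = as.integer(n),
    lambda = lambda, M = M, r = r,
    V_noise_mean = ns$V_noise_mean, V_noise_sd = ns$V_noise_sd,
    V_inf = tau * r,
    h = vm$h, v1 = vm$v1, v2 = vm$v2, t_max = vm$t_max, v_max = vm$v_max,
    snr = snr
  )
  class(out) <- c("snr_breakdown", class(out))
  out
}

# fully vectorized SNR (Poisson terms via dpois/ppois, stable to n ~ 50+)
snr_value <- function(N, f, T, tau, dt_window, n) {
  lambda <- f * dt_window
  vmax_value(dt_window, T, tau) * dpois(n - 1, lambda) *
    sqrt(2 * tau * N * f / ppois(n - 1, lambda, lower.tail = FALSE))
}

#' @export
tidy.snr_breakdown <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), dplyr::everything(),
                      names_to = "quantity", values_to = "value")
}

#' @export
glance.snr_breakdown <- function(x, ...) {
  as_tibble(x)[, c("n", "tau", "dt_window", "M", "v_max", "snr")]
}
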