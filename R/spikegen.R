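#' Configuration for a frozen-noise pattern and its presentation session
#'
#' Bundles the parameters of the synthetic input: `N` afferents firing as
#' homogeneous Poisson processes at rate `f`, a frozen pattern of duration
#' `L` replayed every `interval` seconds with independent per-spike jitter
#' drawn uniformly from `[-T, T]` at each presentation.
#'
#' @param N Number of afferents (integer >= 1).
#' @param f Per-afferent firing rate in Hz (> 0).
#' @param L Pattern duration in seconds (> 0).
#' @param T Maximal jitter half-width in seconds (>= 0).
#' @param interval Time between consecutive pattern onsets in seconds;
#'   must be at least `L + 2 * T` so that jittered pattern spikes stay
#'   inside their presentation slot's half of the session.
#' @param n_presentations Number of pattern presentations (integer >= 0).
#' @param seed Root RNG seed (integer) or `NULL` for the current RNG state.
#'   Pattern, background and jitter use deterministic child streams of this
#'   seed, so each component is independently reproducible.
#'
#' @return A `pattern_config` list.
#' @examples
#' cfg <- pattern_config(N = 100, f = 3.2, L = 0.1, T = 0.0032,
#'                       interval = 0.4, n_presentations = 10, seed = 1)
#' @export
pattern_config <- function(N, f, L, T = 0, interval = 0.4,
                           n_presentations = 0, seed = NULL) {
  stopifnot(length(N) == 1, length(f) == 1, length(L) == 1, length(T) == 1)
  if (N < 1 || N != round(N)) abort("`N` must be a positive integer.")
  if (f <= 0) abort("`f` must be a positive rate (Hz).")
  if (L <= 0) abort("`L` must be a positive duration (s).")
  if (T < 0) abort("`T` must be non-negative (s).")
  if (n_presentations < 0 || n_presentations != round(n_presentations)) {
    abort("`n_presentations` must be a non-negative integer.")
  }
  if (n_presentations > 0 && interval < L) {
    abort("`interval` must be at least the pattern duration `L`.")
  }
  structure(
    list(N = as.integer(N), f = f, L = L, T = T, interval = interval,
         n_presentations = as.integer(n_presentations),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "pattern_config"
  )
}

#' @export
print.pattern_config <- function(x, ...) {
  cat("<pattern_config> N =", x$N, ", f =", x$f, "Hz, L =", x$L * 1e3,
      "ms, T =", x$T * 1e3, "ms, interval =", x$interval * 1e3,
      "ms,", x$n_presentations, "presentations, seed =",
      if (is.null(x$seed)) "NULL" else x$seed, "\n")
  invisible(x)
}

#' Construct a spike-train set from a data frame
#'
#' @param x A data frame with columns `afferent` (0-based integer) and
#'   `time` (seconds).
#' @param N Afferent count (indices must lie in `[0, N)`).
#' @param duration Duration (s); all times must lie in `[0, duration)`.
#' @param onsets Optional pattern onset times (s).
#' @return A sorted `spike_trains` tibble.
#' @export
as_spike_trains <- function(x, N, duration, onsets = NULL) {
  stopifnot(all(c("afferent", "time") %in% names(x)))
  if (nrow(x) > 0) {
    stopifnot(all(x$afferent >= 0), all(x$afferent < N),
              all(x$time >= 0), all(x$time < duration))
  }
  df <- tibble(afferent = as.integer(x$afferent), time = as.double(x$time))
  df <- df[order(df$time, df$afferent, method = "radix"), ]
  new_spike_trains(df, N, duration, onsets)
}

new_spike_trains <- function(df, N, duration, onsets = NULL) {
  out <- as_tibble(df)
  attr(out, "N") <- as.integer(N)
  attr(out, "duration") <- duration
  attr(out, "onsets") <- onsets
  class(out) <- c("spike_trains", class(tibble()))
  out
}

#' Accessors for spike-train metadata
#'
#' @param x A `spike_trains` tibble (columns `afferent`, `time`).
#' @return `session_onsets()` returns the pattern onset times (s) or `NULL`;
#'   `train_duration()` the session duration (s); `n_afferents()` the
#'   afferent count.
#' @export
session_onsets <- function(x) attr(x, "onsets")

#' @rdname session_onsets
#' @export
train_duration <- function(x) attr(x, "duration")

#' @rdname session_onsets
#' @export
n_afferents <- function(x) attr(x, "N")

#' Generate a frozen-noise spike pattern
#'
#' Draws one realization of `N` independent homogeneous Poisson processes
#' at rate `f` over `[0, L)`. The realization is "frozen": regenerating
#' with the same seed yields identical spikes, and the same spikes are
#' replayed (up to jitter) at every presentation.
#'
#' @param config A [pattern_config()].
#' @return A `spike_trains` tibble with columns `afferent` (0-based
#'   integer) and `time` (s in `[0, L)`), sorted by time then afferent,
#'   carrying attributes `N`, `duration = L` and `f`.
#' @examples
#' pat <- generate_pattern(pattern_config(N = 50, f = 5, L = 0.02, seed = 7))
#' @export
generate_pattern <- function(config) {
  stopifnot(inherits(config, "pattern_config"))
  pat <- with_child_seed(config$seed, "pattern", {
    counts <- rpois(config$N, config$f * config$L)
    tibble(
      afferent = rep.int(seq_len(config$N) - 1L, counts),
      time = runif(sum(counts), 0, config$L)
    )
  })
  pat <- pat[order(pat$time, pat$afferent, method = "radix"), ]
  out <- new_spike_trains(pat, config$N, config$L)
  attr(out, "f") <- config$f
  out
}

#' Generate plain Poisson spike trains (noise only)
#'
#' Homogeneous Poisson activity at rate `f` on every afferent over
#' `[0, duration)`, with no embedded pattern.
#'
#' @param N Afferent count.
#' @param f Rate (Hz).
#' @param duration Duration (s).
#' @param seed RNG seed or `NULL`.
#' @return A `spike_trains` tibble.
#' @export
generate_poisson_trains <- function(N, f, duration, seed = NULL) {
  stopifnot(N >= 1, f > 0, duration > 0)
  df <- with_child_seed(seed, "background", {
    counts <- rpois(N, f * duration)
    tibble(
      afferent = rep.int(seq_len(N) - 1L, counts),
      time = runif(sum(counts), 0, duration)
    )
  })
  df <- df[order(df$time, df$afferent, method = "radix"), ]
  new_spike_trains(df, N, duration)
}

#' Build a presentation session: jittered pattern replays in Poisson noise
#'
#' Lays out `n_presentations` slots of length `interval`; in slot `k` the
#' pattern is replayed at onset `(k-1) * interval + (interval - L) / 2`
#' (centred, so jittered spikes cannot escape the session), with every
#' spike shifted by an independent jitter uniform on `[-T, T]`. During a
#' presentation window the pattern *replaces* background activity:
#' background spikes are generated only outside `[onset, onset + L]`.
#' Jittered pattern spikes may land slightly outside the window and are
#' kept.
#'
#' @param pattern A frozen pattern from [generate_pattern()].
#' @param config The [pattern_config()] (supplies `T`, `interval`,
#'   `n_presentations` and the background rate `f`).
#' @param duration Session duration (s). Defaults to
#'   `n_presentations * interval`; required if `n_presentations = 0`.
#' @param afferents Optional 0-based indices: restrict generation to this
#'   subset of afferents (valid because afferents are independent). Used
#'   to speed up experiments whose detector is wired to a known subset.
#' @return A `spike_trains` tibble with the pattern onset times available
#'   via [session_onsets()].
#' @export
build_session <- function(pattern, config, duration = NULL,
                          afferents = NULL) {
  stopifnot(inherits(config, "pattern_config"))
  n_pres <- config$n_presentations
  if (n_pres > 0 && config$interval < config$L + 2 * config$T) {
    abort("`interval` must be >= L + 2 * T to contain jittered spikes.")
  }
  duration <- duration %||% (n_pres * config$interval)
  if (duration <= 0) {
    abort("Session duration must be positive; set `n_presentations` or `duration`.")
  }
  offset <- if (n_pres > 0) (config$interval - config$L) / 2 else 0
  onsets <- if (n_pres > 0) (seq_len(n_pres) - 1) * config$interval + offset
            else numeric(0)

  keep <- if (is.null(afferents)) seq_len(config$N) - 1L else as.integer(afferents)

  # background on the complement of the presentation windows, generated in
  # concatenated-gap coordinates then mapped back to session time
  gap_starts <- c(0, onsets + config$L)
  gap_ends <- c(onsets, duration)
  gap_len <- pmax(gap_ends - gap_starts, 0)
  G <- sum(gap_len)
  bg <- with_child_seed(config$seed, "background", {
    counts <- rpois(length(keep), config$f * G)
    u <- runif(sum(counts), 0, G)
    tibble(afferent = rep.int(keep, counts), u = u)
  })
  cum <- cumsum(c(0, gap_len))
  j <- findInterval(bg$u, cum, rightmost.closed = TRUE)
  bg_time <- gap_starts[j] + (bg$u - cum[j])

  # jittered pattern replays
  pat <- pattern[pattern$afferent %in% keep, ]
  S <- nrow(pat)
  rep_df <- with_child_seed(config$seed, "jitter", {
    jit <- if (config$T > 0) runif(S * n_pres, -config$T, config$T)
           else numeric(S * n_pres)
    tibble(
      afferent = rep.int(pat$afferent, n_pres),
      time = rep(onsets, each = S) + rep.int(pat$time, n_pres) + jit
    )
  })

  df <- tibble(
    afferent = c(bg$afferent, rep_df$afferent),
    time = c(bg_time, rep_df$time)
  )
  df <- df[order(df$time, df$afferent, method = "radix"), ]
  new_spike_trains(df, config$N, duration, onsets = onsets)
}

#' Select afferents by spike count in a window (Strategy #n)
#'
#' Strategy #n wires the detector to every afferent that emits at least
#' `n` spikes during the half-open window `[t0, t0 + dt_window)` of the
#' frozen pattern.
#'
#' @param pattern A frozen pattern.
#' @param n Strategy number (integer >= 1).
#' @param dt_window Window length (s), at most the pattern duration.
#' @param t0 Window start within the pattern (s), default 0.
#' @return A one-row tibble: `n`, `dt_window`, `t0`, the selected indices
#'   (list-column `selected`, 0-based), the realized count `M` and
#'   realized in-window rate `r_window` (Hz), and the ensemble expectations
#'   `M_expected`, `r_expected` from the Poisson closed forms.
#' @examples
#' pat <- generate_pattern(pattern_config(N = 1000, f = 5, L = 0.02, seed = 1))
#' select_afferents(pat, n = 1, dt_window = 0.02)
#' @export
select_afferents <- function(pattern, n, dt_window, t0 = 0) {
  L <- train_duration(pattern)
  N <- n_afferents(pattern)
  if (n < 1 || n != round(n)) abort("`n` must be a positive integer.")
  if (dt_window <= 0 || dt_window > L) {
    abort("`dt_window` must lie in (0, L].")
  }
  if (t0 < 0 || t0 + dt_window > L + 1e-12) {
    abort("window [t0, t0 + dt_window] must lie inside [0, L].")
  }
  inw <- pattern$time >= t0 & pattern$time < t0 + dt_window
  counts <- tabulate(pattern$afferent[inw] + 1L, nbins = N)
  selected <- which(counts >= n) - 1L
  f <- attr(pattern, "f")
  r_window <- sum(counts[selected + 1L]) / dt_window
  M <- length(selected)
  tibble(
    n = as.integer(n), dt_window = dt_window, t0 = t0,
    selected = list(selected),
    M = M,
    r_window = r_window,
    M_expected = if (is.null(f)) NA_real_ else expected_M(N, f, dt_window, n),
    r_expected = if (is.null(f)) NA_real_ else expected_r(N, f, dt_window, n)
  )
}

#' Expected number of selected afferents under Strategy #n
#'
#' The probability that a Poisson afferent with rate `f` fires at least
#' `n` times in a window of length `dt_window` is the Poisson survival
#' function at `n - 1` with mean `lambda = f * dt_window`, so the expected
#' selection size is `N * P(X >= n)`.
#'
#' @param N Afferent count.
#' @param f Rate (Hz).
#' @param dt_window Window (s).
#' @param n Strategy number (integer >= 1). Vectorized over all arguments.
#' @return Expected count (real).
#' @export
expected_M <- function(N, f, dt_window, n) {
  stopifnot(all(n >= 1))
  N * ppois(n - 1, f * dt_window, lower.tail = FALSE)
}

#' Expected total in-window rate of the selected afferents
#'
#' Discarding afferents with fewer than `n` window spikes removes, on
#' average, `N * lambda * P(X <= n - 2)` spikes, leaving a total rate
#' `N * f * P(X >= n - 1)` over the selected population.
#'
#' @inheritParams expected_M
#' @return Total rate in Hz.
#' @export
expected_r <- function(N, f, dt_window, n) {
  stopifnot(all(n >= 1))
  N * f * ppois(n - 2, f * dt_window, lower.tail = FALSE)
}

#' Expected census of per-afferent spike counts in the pattern
#'
#' How many of the `N` afferents are expected to fire exactly
#' `0, 1, 2, ...` spikes during the pattern, i.e. `N` times the Poisson
#' pmf at mean `f * L`.
#'
#' @param N Afferent count.
#' @param f Rate (Hz).
#' @param L Pattern duration (s).
#' @param max_spikes Largest count tabulated.
#' @return A tibble with columns `spikes` and `afferents` (expected,
#'   real-valued).
#' @examples
#' pattern_census(N = 1e4, f = 3.2, L = 0.1)
#' @export
pattern_census <- function(N, f, L, max_spikes = 6) {
  k <- 0:max_spikes
  tibble(spikes = k, afferents = N * dpois(k, f * L))
}

#' Read and write spike trains as delimited text
#'
#' Two-column CSV with header `afferent,time_s`: 0-based afferent index
#' and spike time in seconds at full double precision (round-trips
#' bit-exactly).
#'
#' @param x A `spike_trains` tibble.
#' @param path File path.
#' @export
write_spike_trains <- function(x, path) {
  # 17 significant digits: doubles survive the round trip bit-exactly
  writeLines(c("afferent,time_s",
               sprintf("%d,%.17g", x$afferent, x$time)),
             path)
  invisible(path)
}

#' @rdname write_spike_trains
#' @param N,duration Metadata not stored in the file; `N` defaults to
#'   `max(afferent) + 1` and `duration` to the latest spike time.
#' @export
read_spike_trains <- function(path, N = NULL, duration = NULL) {
  # base parser: correctly rounded doubles, so the round trip is bit-exact
  df <- utils::read.csv(path, colClasses = c(afferent = "integer",
                                             time_s = "numeric"))
  df <- tibble(afferent = df$afferent, time = df$time_s)
  df <- df[order(df$time, df$afferent, method = "radix"), ]
  new_spike_trains(df,
                   N %||% (max(df$afferent) + 1L),
                   duration %||% max(df$time))
}

#' Read and write a pattern configuration as YAML
#'
#' @param config A [pattern_config()].
#' @param path File path.
#' @export
write_pattern_config <- function(config, path) {
  stopifnot(inherits(config, "pattern_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pattern_config
#' @export
read_pattern_config <- function(path) {
  x <- yaml::read_yaml(path)
  pattern_config(N = x$N, f = x$f, L = x$L, T = x$T %||% 0,
                 interval = x$interval %||% 0.4,
                 n_presentations = x$n_presentations %||% 0,
                 seed = x$seed)
}
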