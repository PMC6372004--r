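#' STDP learning-rule configuration
#'
#' Additive, all-to-all STDP with LTP only: every synapse keeps a
#' presynaptic trace that decays exponentially with time constant
#' `tau_pre` and is incremented by `d_apre` at each presynaptic spike.
#' At each postsynaptic spike every weight receives its trace value plus
#' a fixed homeostatic depression `w_out < 0`, then is clipped to
#' `[0, 1]`.
#'
#' @param theta LIF firing threshold (unit-EPSP units).
#' @param w_out Homeostatic depression per postsynaptic spike (< 0).
#' @param d_apre Trace increment per presynaptic spike (default 0.01).
#' @param tau_pre Trace time constant (s, default 0.02).
#' @param tau Membrane time constant (s, default 0.018).
#' @param n_presentations Pattern presentations in the session
#'   (default 500).
#' @param interval Time between pattern onsets (s, default 0.4).
#' @param dt_bin Euler step (s, default 1e-4).
#' @return An `stdp_config` list.
#' @export
stdp_config <- function(theta, w_out, d_apre = 0.01, tau_pre = 0.02,
                        tau = 0.018, n_presentations = 500,
                        interval = 0.4, dt_bin = 1e-4) {
  stopifnot(theta > 0, tau > 0, tau_pre > 0)
  if (d_apre <= 0) abort("`d_apre` must be positive.")
  if (w_out >= 0) abort("`w_out` must be negative (homeostatic depression).")
  if (dt_bin > tau / 10) abort("`dt_bin` must be <= tau / 10.")
  structure(list(theta = theta, w_out = w_out, d_apre = d_apre,
                 tau_pre = tau_pre, tau = tau,
                 n_presentations = as.integer(n_presentations),
                 interval = interval, dt_bin = dt_bin),
            class = "stdp_config")
}

#' Uniform initial weight placing the noise potential 2 SD above threshold
#'
#' With all `N` synapses at weight `w0`, the noise potential has mean
#' `w0 * tau * f * N` and standard deviation `w0 * sqrt(tau * f * N / 2)`.
#' Solving `mean = theta + 2 * sd` for `w0` gives
#' `w0 = theta / (tau * f * N - 2 * sqrt(tau * f * N / 2))`, which puts
#' the neuron a little above threshold on average before learning (an
#' initial firing rate around 20 Hz for the parameters studied here), so
#' that postsynaptic spikes — the engine of STDP — occur from the start.
#'
#' @param theta Threshold.
#' @param tau Membrane time constant (s).
#' @param f Afferent rate (Hz).
#' @param N Afferent count.
#' @return The uniform initial weight (scalar).
#' @examples
#' initial_weight(theta = 370, tau = 0.018, f = 3.2, N = 1e4)
#' @export
initial_weight <- function(theta, tau, f, N) {
  mu1 <- tau * f * N
  denom <- mu1 - 2 * sqrt(mu1 / 2)
  if (denom <= 0) {
    abort("tau * f * N too small: no positive weight satisfies mean = theta + 2 sd.")
  }
  theta / denom
}

#' Run an STDP learning session on a frozen pattern
#'
#' Builds a presentation session for `pattern` (jittered replays every
#' `interval` seconds in Poisson background, per `config`), then
#' simulates the plastic LIF with the rule in [stdp_config()]. Initial
#' weights are uniform at [initial_weight()]. If the neuron fires no
#' spike at all during the first 50 presentations the run is aborted
#' early and flagged `dead` (weights cannot evolve without postsynaptic
#' spikes).
#'
#' @param pattern A frozen pattern from [generate_pattern()].
#' @param config The [pattern_config()] used to generate the session
#'   (supplies `f`, `T` and the session seed); its `interval` and
#'   `n_presentations` are overridden by the `stdp` configuration.
#' @param stdp An [stdp_config()].
#' @return A `learning_outcome` object: final weights, postsynaptic
#'   spike times, per-presentation spike count after learning,
#'   convergence flag (fraction of weights within 0.05 of 0 or 1 at
#'   least 95%), and session metadata. Use [tidy()] for per-afferent
#'   weights and [glance()] for the summary row.
#' @export
run_stdp <- function(pattern, config, stdp) {
  stopifnot(inherits(config, "pattern_config"), inherits(stdp, "stdp_config"))
  sess_cfg <- pattern_config(N = config$N, f = config$f, L = config$L,
                             T = config$T, interval = stdp$interval,
                             n_presentations = stdp$n_presentations,
                             seed = config$seed)
  sess <- build_session(pattern, sess_cfg)
  onsets <- session_onsets(sess)
  duration <- train_duration(sess)
  w0 <- initial_weight(stdp$theta, stdp$tau, config$f, config$N)
  if (w0 > 1) {
    warn("initial weight clipped to 1; the threshold may be unreachable.")
    w0 <- 1
  }

  res <- stdp_sim_cpp(sess$time, sess$afferent, config$N, stdp$tau,
                      stdp$theta, stdp$dt_bin, duration,
                      rep(w0, config$N), stdp$d_apre, stdp$tau_pre,
                      stdp$w_out, dead_time = 50 * stdp$interval)
  if (res$dead) {
    warn("dead neuron: no postsynaptic spike during the first 50 presentations.")
  }

  w <- res$weights
  frac_binarized <- mean(pmin(w, 1 - w) <= 0.05)

  # steady-state selectivity: spikes per presentation over the last
  # quarter of the session, counted in [onset - T, onset + L + T]
  tail_onsets <- onsets[onsets >= duration * 0.75]
  spp <- if (length(tail_onsets) > 0) {
    i <- findInterval(res$post_spikes, tail_onsets - config$T)
    hits <- i >= 1 &
      res$post_spikes <= (tail_onsets + config$L + config$T)[pmax(i, 1)]
    sum(hits) / length(tail_onsets)
  } else {
    NA_real_
  }

  structure(
    list(weights = w, initial_weight = w0,
         post_spikes = res$post_spikes, onsets = onsets,
         duration = duration, dead = res$dead,
         frac_binarized = frac_binarized,
         converged = !res$dead && frac_binarized >= 0.95,
         spikes_per_presentation = spp,
         pattern_config = config, stdp = stdp),
    class = "learning_outcome"
  )
}

#' @export
print.learning_outcome <- function(x, ...) {
  cat("<learning_outcome>", length(x$weights), "synapses,",
      length(x$post_spikes), "postsynaptic spikes\n")
  cat(sprintf("  reinforced (w > 0.5): %d; binarized: %.1f%%; converged: %s%s\n",
              sum(x$weights > 0.5), 100 * x$frac_binarized, x$converged,
              if (x$dead) "; DEAD" else ""))
  cat(sprintf("  spikes per presentation (last quarter): %.2f\n",
              x$spikes_per_presentation))
  invisible(x)
}

#' @export
tidy.learning_outcome <- function(x, ...) {
  tibble(afferent = seq_along(x$weights) - 1L, weight = x$weights)
}

#' @export
glance.learning_outcome <- function(x, ...) {
  tibble(n_reinforced = sum(x$weights > 0.5),
         frac_binarized = x$frac_binarized,
         converged = x$converged, dead = x$dead,
         n_post_spikes = length(x$post_spikes),
         spikes_per_presentation = x$spikes_per_presentation,
         initial_weight = x$initial_weight)
}

#' @export
autoplot.learning_outcome <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$weight)) +
    ggplot2::geom_histogram(bins = 50, boundary = 0) +
    ggplot2::labs(x = "synaptic weight", y = "synapses",
                  title = "Final weight distribution")
}

#' Classify a learned weight vector as an optimal Strategy-1 detector
#'
#' A converged outcome is optimal when its maximally reinforced and
#' completely depressed synapses are the two classes a Strategy-#1
#' window selection would produce: there must exist a window of the
#' frozen pattern containing at least one spike of every reinforced
#' afferent (weight within `binarize_tol` of 1) and no spike of any
#' depressed afferent (weight within `binarize_tol` of 0), with a
#' duration matching `dt_opt` within `margin` (10% by default). The
#' small fraction of synapses left at intermediate weights (bounded by
#' the convergence requirement: at least 95% binarized) is not
#' constrained — additive STDP leaves the afferents spiking right at
#' the LTP/LTD balance point of the window's leading edge unresolved,
#' so they belong to neither class. For fully binarized weights the
#' criterion is exact set equality between the reinforced set and the
#' window's spikers.
#'
#' The search is exact: windows containing a spike from a depressed
#' afferent are impossible, so candidates are confined to the gaps
#' between such spikes; within each gap the qualifying durations form
#' an interval, from the minimal span covering every reinforced
#' afferent (a sliding-window scan) up to the full gap clipped to the
#' pattern, and the window exists iff some such interval meets the
#' `dt_opt` margin band.
#'
#' @param outcome A `learning_outcome` (or any numeric weight vector).
#' @param pattern The frozen pattern learned from.
#' @param dt_opt Optimal window duration to match (s).
#' @param margin Relative duration tolerance (default 0.10).
#' @param binarize_tol Weight binarization tolerance (default 0.05).
#' @return A one-row tibble: `optimal`, `window_start`,
#'   `window_duration`, `n_reinforced`, `reason`.
#' @export
classify_optimal <- function(outcome, pattern, dt_opt, margin = 0.10,
                             binarize_tol = 0.05) {
  w <- if (inherits(outcome, "learning_outcome")) outcome$weights else outcome
  not_opt <- function(reason) {
    tibble(optimal = FALSE, window_start = NA_real_,
           window_duration = NA_real_,
           n_reinforced = sum(w >= 1 - binarize_tol),
           reason = reason)
  }
  if (inherits(outcome, "learning_outcome") && outcome$dead) {
    return(not_opt("dead"))
  }
  if (mean(pmin(w, 1 - w) <= binarize_tol) < 0.95) {
    return(not_opt("unconverged"))
  }
  reinforced <- which(w >= 1 - binarize_tol) - 1L
  depressed <- which(w <= binarize_tol) - 1L
  if (length(reinforced) == 0) return(not_opt("no reinforced synapses"))

  wins <- covering_windows(pattern, reinforced, depressed)
  if (nrow(wins) == 0) {
    return(not_opt("no window reproduces the reinforced set"))
  }
  band <- c(dt_opt - margin * dt_opt, dt_opt + margin * dt_opt)
  wins$hit <- wins$d_min <= band[2] & wins$d_max >= band[1]
  best <- wins[order(!wins$hit, pmax(wins$d_min - dt_opt,
                                     dt_opt - wins$d_max, 0)), ][1, ]
  ok <- best$hit
  tibble(optimal = ok, window_start = best$span_start,
         window_duration = min(max(dt_opt, best$d_min), best$d_max),
         n_reinforced = length(reinforced),
         reason = if (ok) "ok" else "window duration outside margin")
}

# Qualifying windows [t0, t0 + d) of the pattern containing >= 1 spike of
# every afferent in `required` and no spike of any afferent in
# `forbidden` (0-based indices). Candidate windows live in the gaps
# between forbidden spikes; per gap the achievable durations form the
# interval [d_min, d_max], where d_min is the minimal span covering all
# required afferents and d_max the gap width clipped to [0, L]. Returns a
# tibble (possibly empty) with one row per qualifying gap.
covering_windows <- function(pattern, required, forbidden = NULL) {
  L <- train_duration(pattern)
  forbidden <- forbidden %||% setdiff(unique(pattern$afferent), required)
  is_good <- pattern$afferent %in% required
  is_bad <- pattern$afferent %in% forbidden
  bad_t <- sort(pattern$time[is_bad])
  good_t <- pattern$time[is_good]
  good_a <- pattern$afferent[is_good]
  empty <- tibble(span_start = numeric(0), d_min = numeric(0),
                  d_max = numeric(0))
  if (!all(required %in% good_a)) return(empty)  # some never spike

  bounds <- c(-Inf, bad_t, Inf)
  region <- findInterval(good_t, bounds)  # spikes strictly between bad ones
  on_bad <- good_t %in% bad_t             # coincident times are unusable
  out <- empty
  for (rg in unique(region)) {
    sel <- region == rg & !on_bad
    if (!setequal(good_a[sel], required)) next
    ts <- good_t[sel]
    as <- good_a[sel]
    o <- order(ts)
    ts <- ts[o]
    as <- match(as[o], required)  # 1..K labels
    K <- length(required)
    # sliding two-pointer: minimal span containing all K labels
    count <- integer(K)
    have <- 0L
    lo <- 1L
    best_span <- Inf
    best_start <- NA_real_
    for (hi in seq_along(ts)) {
      count[as[hi]] <- count[as[hi]] + 1L
      if (count[as[hi]] == 1L) have <- have + 1L
      while (have == K) {
        span <- ts[hi] - ts[lo]
        if (span < best_span) {
          best_span <- span
          best_start <- ts[lo]
        }
        count[as[lo]] <- count[as[lo]] - 1L
        if (count[as[lo]] == 0L) have <- have - 1L
        lo <- lo + 1L
      }
    }
    d_max <- min(bounds[rg + 1], L) - max(bounds[rg], 0)
    out <- dplyr::bind_rows(out, tibble(span_start = best_start,
                                        d_min = best_span,
                                        d_max = d_max))
  }
  out
}

#' Optimality rate over the threshold x depression plane
#'
#' For each `(theta, w_out)` point, runs `n_replicates` independent STDP
#' sessions on freshly drawn frozen patterns and reports the proportion
#' `p` of runs classified optimal by [classify_optimal()], along with
#' the convergence fraction and the mean post-learning spikes per
#' presentation. Per-replicate failures are tallied, not fatal.
#'
#' @param theta_grid,w_out_grid Grids of thresholds and depression
#'   strengths; use [geometric_grid()] for the ratio-1.1 progressions
#'   typically scanned.
#' @param base_config A [pattern_config()] providing `N`, `f`, `L`, `T`;
#'   its seed seeds the replicate streams.
#' @param dt_opt Optimal window to classify against (s).
#' @param n_replicates Replicates per grid point (default 25; 100 for a
#'   full-scale scan).
#' @param d_apre,tau_pre,tau,n_presentations,interval Passed to
#'   [stdp_config()].
#' @return A tibble: `theta`, `w_out`, `n_replicates`, `p` (percent
#'   optimal), `convergence_fraction`, `mean_spikes_per_presentation`,
#'   `n_dead`.
#' @export
mode_analysis <- function(theta_grid, w_out_grid, base_config, dt_opt,
                          n_replicates = 25, d_apre = 0.01,
                          tau_pre = 0.02, tau = 0.018,
                          n_presentations = 500, interval = 0.4) {
  stopifnot(inherits(base_config, "pattern_config"))
  grid <- tidyr::expand_grid(theta = theta_grid, w_out = w_out_grid)
  purrr::pmap_dfr(grid, function(theta, w_out) {
    scfg <- stdp_config(theta = theta, w_out = w_out, d_apre = d_apre,
                        tau_pre = tau_pre, tau = tau,
                        n_presentations = n_presentations,
                        interval = interval)
    reps <- purrr::map_dfr(seq_len(n_replicates), function(rep) {
      seed_r <- child_seed(base_config$seed %||% 0,
                           paste0("mode-", theta, "-", w_out, "-", rep))
      pc <- pattern_config(N = base_config$N, f = base_config$f,
                           L = base_config$L, T = base_config$T,
                           interval = interval,
                           n_presentations = n_presentations,
                           seed = seed_r)
      pattern <- generate_pattern(pc)
      out <- tryCatch(
        suppressWarnings(run_stdp(pattern, pc, scfg)),
        error = function(e) NULL
      )
      if (is.null(out)) {
        return(tibble(optimal = FALSE, converged = FALSE, dead = TRUE,
                      spp = NA_real_))
      }
      cls <- classify_optimal(out, pattern, dt_opt)
      tibble(optimal = cls$optimal, converged = out$converged,
             dead = out$dead, spp = out$spikes_per_presentation)
    })
    tibble(theta = theta, w_out = w_out, n_replicates = n_replicates,
           p = 100 * mean(reps$optimal),
           convergence_fraction = mean(reps$converged),
           mean_spikes_per_presentation = mean(reps$spp, na.rm = TRUE),
           n_dead = sum(reps$dead))
  })
}

#' Geometric parameter grid
#'
#' Geometric progression with the given ratio covering `[from, to]`
#' (endpoints included; the grid is anchored at `from`).
#'
#' @param from,to Range endpoints (same sign).
#' @param ratio Progression ratio (default 1.1).
#' @return Numeric vector.
#' @export
geometric_grid <- function(from, to, ratio = 1.1) {
  stopifnot(ratio > 1, from != 0, sign(from) == sign(to))
  lr <- log(abs(to / from)) / log(ratio)
  k <- ceiling(abs(lr) - 1e-9)
  step <- if (lr >= 0) ratio else 1 / ratio
  out <- from * step^(0:k)
  hi <- max(abs(from), abs(to)) * (1 + 1e-12)
  lo <- min(abs(from), abs(to)) * (1 - 1e-12)
  out[abs(out) <= hi & abs(out) >= lo]
}
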