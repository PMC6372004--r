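#' Constrained maximization of the detector SNR
#'
#' Maximizes the closed-form SNR over the strategy number `n`, the
#' membrane time constant `tau` and the selection window `dt_window`, for
#' fixed external variables `f` (afferent rate) and `T` (jitter), subject
#' to `tau * f * M >= constraint` (a large number of synaptic inputs, so
#' the Gaussian noise approximation holds; default 10). For each strategy
#' the search runs Nelder-Mead refinements from an 8 x 8 log-spaced
#' multistart grid in `(tau, dt_window)`; the constraint is enforced by
#' projecting `tau` onto its feasible lower bound `constraint / (f * M)`.
#'
#' @param f Afferent rate (Hz).
#' @param T Jitter half-width (s).
#' @param N Afferent count.
#' @param n_max Largest strategy number searched (default 5).
#' @param constraint Lower bound on `tau * f * M` (default 10).
#' @param tau_range,dt_range Search bounds in seconds (log-spaced
#'   multistart grid endpoints; `dt_range[2]` also caps the window).
#' @param n_starts Multistart grid points per axis (default 8).
#' @return A `lif_optimum` object. `glance()` gives the global best
#'   (`best_n`, `best_tau`, `best_dt`, `best_snr`, `constraint_active`);
#'   `tidy()` the per-strategy optima.
#' @examples
#' \donttest{
#' opt <- optimize_snr(f = 3.2, T = 0.0032, N = 1e4)
#' glance(opt)
#' }
#' @export
optimize_snr <- function(f, T, N, n_max = 5, constraint = 10,
                         tau_range = c(5e-4, 10), dt_range = c(5e-4, 10),
                         n_starts = 8) {
  stopifnot(f > 0, T >= 0, N >= 1, n_max >= 1)

  tau_min_feasible <- function(dt, n) {
    M <- expected_M(N, f, dt, n)
    if (M <= 0) return(Inf)
    constraint / (f * M)
  }

  solve_n <- function(n) {
    obj <- function(x) {
      dt <- exp(x[2])
      if (dt > dt_range[2]) return(1e10)
      tau <- max(exp(x[1]), tau_min_feasible(dt, n))
      if (!is.finite(tau) || tau > tau_range[2] * 10) return(1e10)
      -snr_value(N, f, T, tau, dt, n)
    }
    starts <- expand.grid(
      lt = log(exp(seq(log(tau_range[1]), log(tau_range[2]),
                       length.out = n_starts))),
      ld = log(exp(seq(log(dt_range[1]), log(dt_range[2]),
                       length.out = n_starts)))
    )
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      fit <- optim(c(starts$lt[i], starts$ld[i]), obj,
                   method = "Nelder-Mead",
                   control = list(reltol = 1e-12, maxit = 5000))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    conv_ok <- best$convergence == 0
    dt_star <- exp(best$par[2])
    tau_floor <- tau_min_feasible(dt_star, n)
    tau_star <- max(exp(best$par[1]), tau_floor)
    tibble(
      n = as.integer(n),
      tau_opt = tau_star,
      dt_opt = dt_star,
      snr_opt = snr_value(N, f, T, tau_star, dt_star, n),
      constraint_active = tau_star <= tau_floor * (1 + 1e-8),
      converged = conv_ok,
      dt_at_cap = dt_star > dt_range[2] * 0.99
    )
  }

  per_strategy <- purrr::map_dfr(seq_len(n_max), solve_n)
  if (any(per_strategy$dt_at_cap)) {
    warn("Optimal window hit the search cap `dt_range[2]` for some strategy.")
  }
  # ties across n broken toward smaller n (parsimony)
  best_i <- which(per_strategy$snr_opt >=
                    max(per_strategy$snr_opt) * (1 - 1e-12))[1]
  structure(
    list(f = f, T = T, N = N, constraint = constraint,
         per_strategy = per_strategy, best = per_strategy[best_i, ]),
    class = "lif_optimum"
  )
}

#' @export
print.lif_optimum <- function(x, ...) {
  b <- x$best
  cat("<lif_optimum> f =", x$f, "Hz, T =", x$T * 1e3, "ms, N =", x$N, "\n")
  cat(sprintf("  best: n = %d, tau = %.2f ms, dt = %.2f ms, SNR = %.2f%s\n",
              b$n, b$tau_opt * 1e3, b$dt_opt * 1e3, b$snr_opt,
              if (b$constraint_active) " (constraint active)" else ""))
  invisible(x)
}

#' @export
tidy.lif_optimum <- function(x, ...) x$per_strategy

#' @export
glance.lif_optimum <- function(x, ...) {
  b <- x$best
  tibble(f = x$f, T = x$T, N = x$N,
         best_n = b$n, best_tau = b$tau_opt, best_dt = b$dt_opt,
         best_snr = b$snr_opt, constraint_active = b$constraint_active,
         converged = all(x$per_strategy$converged))
}

#' Optimal-detector map over the (f, T) plane
#'
#' Runs [optimize_snr()] at every combination of the supplied rate and
#' jitter grids (use log-spaced grids; the interesting structure spans
#' decades) and returns one row per grid point. Per-point failures are
#' returned as flagged rows rather than aborting the sweep.
#'
#' @param f_grid Rates (Hz).
#' @param T_grid Jitter half-widths (s).
#' @param N Afferent count.
#' @param ... Passed to [optimize_snr()].
#' @return A tibble with the [glance()] columns of each optimum plus a
#'   `failed` flag.
#' @export
sweep_plane <- function(f_grid, T_grid, N, ...) {
  grid <- tidyr::expand_grid(f = f_grid, T = T_grid)
  out <- purrr::pmap_dfr(grid, function(f, T) {
    res <- tryCatch(glance(optimize_snr(f = f, T = T, N = N, ...)),
                    error = function(e) NULL)
    if (is.null(res)) {
      tibble(f = f, T = T, N = N, best_n = NA_integer_,
             best_tau = NA_real_, best_dt = NA_real_, best_snr = NA_real_,
             constraint_active = NA, converged = NA, failed = TRUE)
    } else {
      dplyr::mutate(res, failed = FALSE)
    }
  })
  class(out) <- c("lif_sweep", class(out))
  out
}

#' @describeIn sweep_plane Heatmap of the optimal SNR over the plane.
#' @param object A sweep table from `sweep_plane()`.
#' @param fill Column to map to fill (default `best_snr`).
#' @export
autoplot.lif_sweep <- function(object, fill = "best_snr", ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$f, y = .data$T * 1e3,
                               fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "f (Hz)", y = "T (ms)", fill = fill)
}
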