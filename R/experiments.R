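#' Named, seeded, reproducible experiments
#'
#' One entry point for the study's experiments, each runnable at
#' `scale = "full"` (the published protocol) or `scale = "reduced"`
#' (a desk-scale version with the same structure):
#'
#' * `"table1"` — constrained SNR optimization at f = 3.2 Hz,
#'   T = 3.2 ms, N = 1e4 (same at both scales).
#' * `"fig4"` — simulated vs theoretical SNR across jitters for
#'   strategies 1-2 (full: 100 patterns x 1000 presentations;
#'   reduced: 20 x 200).
#' * `"fig5_coarse"` — optimal-detector map on a coarse log-spaced
#'   (f, T) grid (full: 7 x 7; reduced: 3 x 3).
#' * `"mode1"`, `"mode2"` — STDP optimality rate at the two operating
#'   points (theta = 370, w_out = -3.5e-3) and (theta = 250,
#'   w_out = -1.6e-3) (full: 100 replicates; reduced: 25).
#' * `"mode1_fast_lr"`, `"mode2_fast_lr"` — same with the learning rate
#'   doubled (`d_apre = 0.02`).
#' * `"mode1_sparse"`, `"mode2_sparse"` — same with presentations every
#'   800 ms instead of 400 ms.
#'
#' @param name Experiment name (see above).
#' @param scale `"reduced"` (default) or `"full"`.
#' @param seed Root seed (integer).
#' @param out_dir Optional directory; when given, the result table
#'   (`result.csv`), the resolved configuration and a provenance record
#'   (`provenance.json`: config hash, seed, package version) are written
#'   there.
#' @param overrides Named list of parameter overrides applied to the
#'   resolved configuration (unknown names are an error).
#' @return A list of class `experiment_report`: `name`, `scale`,
#'   `seed`, `config` (resolved parameters), `result` (a tibble) and
#'   `hash`.
#' @examples
#' \donttest{
#' rep <- run_experiment("table1", seed = 1)
#' rep$result
#' }
#' @export
run_experiment <- function(name, scale = c("reduced", "full"), seed = 1,
                           out_dir = NULL, overrides = list()) {
  scale <- match.arg(scale)
  spec <- experiment_specs()[[name]]
  if (is.null(spec)) {
    abort(paste0("unknown experiment `", name, "`; available: ",
                 paste(names(experiment_specs()), collapse = ", ")))
  }
  config <- spec$config(scale)
  if (length(overrides) > 0) {
    bad <- setdiff(names(overrides), names(config))
    if (length(bad) > 0) {
      abort(paste0("unknown override parameter(s): ",
                   paste(bad, collapse = ", ")))
    }
    config[names(overrides)] <- overrides
  }
  result <- spec$run(config, seed)
  report <- structure(
    list(name = name, scale = scale, seed = as.integer(seed),
         config = config, result = result,
         hash = rlang::hash(list(name, scale, seed, config)),
         package_version = as.character(utils::packageVersion("stdplif"))),
    class = "experiment_report"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(result, file.path(out_dir, "result.csv"))
    jsonlite::write_json(
      list(name = name, scale = scale, seed = report$seed,
           config = config, hash = report$hash,
           package_version = report$package_version),
      file.path(out_dir, "provenance.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>", x$name, "| scale =", x$scale,
      "| seed =", x$seed, "| hash =", x$hash, "\n")
  print(x$result)
  invisible(x)
}

mode_points <- list(
  mode1 = list(theta = 370, w_out = -3.5e-3),
  mode2 = list(theta = 250, w_out = -1.6e-3)
)

mode_experiment <- function(point, d_apre = 0.01, interval = 0.4) {
  list(
    config = function(scale) {
      list(N = 1e4, f = 3.2, L = 0.1, T = 3.2e-3,
           theta = point$theta, w_out = point$w_out, d_apre = d_apre,
           tau_pre = 0.02, tau = 0.018, interval = interval,
           n_presentations = 500, dt_opt = 0.023,
           n_replicates = if (scale == "full") 100 else 25)
    },
    run = function(cfg, seed) {
      base <- pattern_config(N = cfg$N, f = cfg$f, L = cfg$L, T = cfg$T,
                             interval = cfg$interval, seed = seed)
      mode_analysis(theta_grid = cfg$theta, w_out_grid = cfg$w_out,
                    base_config = base, dt_opt = cfg$dt_opt,
                    n_replicates = cfg$n_replicates, d_apre = cfg$d_apre,
                    tau_pre = cfg$tau_pre, tau = cfg$tau,
                    n_presentations = cfg$n_presentations,
                    interval = cfg$interval)
    }
  )
}

experiment_specs <- function() {
  list(
    table1 = list(
      config = function(scale) {
        list(f = 3.2, T = 3.2e-3, N = 1e4, n_max = 5)
      },
      run = function(cfg, seed) {
        opt <- optimize_snr(f = cfg$f, T = cfg$T, N = cfg$N,
                            n_max = cfg$n_max)
        glance(opt)
      }
    ),
    fig4 = list(
      config = function(scale) {
        list(f = 5, N = 1e4, L = 0.02, strategies = c(1, 2),
             T_grid = c(0, 1, 2, 4, 8) * 1e-3, tau = 0.018,
             interval = 0.4,
             n_patterns = if (scale == "full") 100 else 20,
             n_presentations = if (scale == "full") 1000 else 200)
      },
      run = function(cfg, seed) {
        validate_theory(f = cfg$f, N = cfg$N, L = cfg$L,
                        strategies = cfg$strategies, T_grid = cfg$T_grid,
                        n_patterns = cfg$n_patterns,
                        n_presentations = cfg$n_presentations,
                        tau = cfg$tau, interval = cfg$interval,
                        seed = seed)
      }
    ),
    fig5_coarse = list(
      config = function(scale) {
        n_pts <- if (scale == "full") 7 else 3
        list(f_grid = exp(seq(log(0.2), log(50), length.out = n_pts)),
             T_grid = exp(seq(log(2e-4), log(0.05), length.out = n_pts)),
             N = 1e4, n_max = 5)
      },
      run = function(cfg, seed) {
        sweep_plane(cfg$f_grid, cfg$T_grid, cfg$N, n_max = cfg$n_max)
      }
    ),
    mode1 = mode_experiment(mode_points$mode1),
    mode2 = mode_experiment(mode_points$mode2),
    mode1_fast_lr = mode_experiment(mode_points$mode1, d_apre = 0.02),
    mode2_fast_lr = mode_experiment(mode_points$mode2, d_apre = 0.02),
    mode1_sparse = mode_experiment(mode_points$mode1, interval = 0.8),
    mode2_sparse = mode_experiment(mode_points$mode2, interval = 0.8)
  )
}
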