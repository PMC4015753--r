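## Experiment designs and simulated time-course data sets.
##
## A design is one constant control-input vector plus an initial state and a
## uniform sampling grid; a data set is a simulated (optionally noisy)
## time-course table for one design. The defaults emulate the benchmark
## protocol: 120 samples at 1-minute intervals, several distinct constant
## (P, S) settings, multiplicative Gaussian noise.

# integrator tolerances used for data generation; "noise-free" data must sit
# far below any fitting threshold
.sim_rtol <- 1e-10
.sim_atol <- 1e-12

#' Create an experiment design
#'
#' @param controls named (or model-ordered) numeric vector of constant
#'   control-input values, strictly positive.
#' @param x0 nonnegative initial state.
#' @param t0,t_end time window (minutes), `t_end > t0`.
#' @param n_samples number of samples M (>= 2), taken uniformly at
#'   `t0 + i*(t_end-t0)/M`, i = 1..M (the initial state itself is not a
#'   sample).
#' @param design_id label.
#' @return object of class `experiment_design`.
#' @export
experiment_design <- function(controls, x0, t0 = 0, t_end = 120,
                              n_samples = 120, design_id = "design_1") {
  if (t_end <= t0) stop("'t_end' must exceed 't0'")
  if (n_samples < 2) stop("'n_samples' must be at least 2")
  if (any(controls <= 0)) stop("controls must be strictly positive")
  if (any(x0 < 0)) stop("initial states must be nonnegative")
  structure(list(design_id = design_id,
                 controls = controls, x0 = x0,
                 t0 = t0, t_end = t_end, n_samples = as.integer(n_samples)),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("<experiment_design> ", x$design_id, ": u = (",
      paste(signif(x$controls, 5), collapse = ", "), "), t in [",
      x$t0, ", ", x$t_end, "], M = ", x$n_samples, "\n", sep = "")
  invisible(x)
}

design_times <- function(design) {
  seq(design$t0, design$t_end, length.out = design$n_samples + 1L)[-1L]
}

#' Generate k experiment designs with distinct control inputs
#'
#' The first design always uses `base_controls`; further designs draw each
#' control log-uniformly in `[base/spread, base*spread]`, rejecting candidates
#' whose relative difference to any accepted design is below 10% in any
#' control. Deterministic given `seed`.
#'
#' @param model an [ode_model] (provides control names/count).
#' @param k number of designs (>= 1).
#' @param base_controls positive control vector for the first design.
#' @param x0 initial state shared by all designs.
#' @param spread log-uniform half-range factor (> 1 for k > 1).
#' @param seed integer seed.
#' @param t0,t_end,n_samples sampling grid, see [experiment_design()].
#' @return list of [experiment_design] objects.
#' @export
generate_designs <- function(model, k, base_controls, x0, spread = 3, seed = 1,
                             t0 = 0, t_end = 120, n_samples = 120) {
  if (k < 1) stop("'k' must be at least 1")
  if (length(base_controls) != length(model$control_names))
    stop("'base_controls' must have length ", length(model$control_names))
  base_controls <- stats::setNames(as.numeric(base_controls), model$control_names)
  designs <- list(experiment_design(base_controls, x0, t0, t_end, n_samples,
                                    design_id = "design_1"))
  if (k == 1L) return(designs)
  if (spread <= 1) stop("'spread' must exceed 1 when k > 1")
  m <- length(base_controls)
  with_seed(seed, {
    tries <- 0L
    while (length(designs) < k) {
      cand <- base_controls * exp(stats::runif(m, -log(spread), log(spread)))
      distinct <- all(vapply(designs, function(d) {
        all(abs(cand - d$controls) / pmax(cand, d$controls) >= 0.1)
      }, logical(1)))
      tries <- tries + 1L
      if (tries > 1000L * k)
        stop("could not draw ", k, " mutually distinct designs; increase 'spread'")
      if (!distinct) next
      designs[[length(designs) + 1L]] <-
        experiment_design(cand, x0, t0, t_end, n_samples,
                          design_id = paste0("design_", length(designs) + 1L))
    }
  })
  designs
}

#' Integrate the model trajectory for one design
#'
#' Solves the ODE from the design's initial state under its constant controls
#' and returns the states at the sampling grid (plus `t0`).
#'
#' @param model an [ode_model].
#' @param p parameter vector.
#' @param design an [experiment_design].
#' @param times optional explicit output times (defaults to the design grid
#'   including `t0`).
#' @param rtol,atol integrator tolerances.
#' @param maxsteps integrator step cap per output interval; pathological
#'   parameter regions fail fast instead of grinding at the minimum step.
#' @param method integrator method; `"adams"` tries the non-stiff solver
#'   first and falls back to lsoda.
#' @return matrix with a `time` column and one column per state.
#' @export
simulate_trajectory <- function(model, p, design, times = NULL,
                                rtol = .sim_rtol, atol = .sim_atol,
                                maxsteps = 5000, method = "lsoda") {
  check_dims(model, design$x0, design$controls, p)
  times <- times %||% c(design$t0, design_times(design))
  u <- design$controls
  deriv <- function(t, y, parms)
    list(eval(model$calls$rhs, eval_env(model, y, u, parms, t)))
  out <- ode_with_fallback(
    y = stats::setNames(as.numeric(design$x0), model$state_names),
    times = times, func = deriv, parms = as.numeric(p),
    rtol = rtol, atol = atol, maxsteps = maxsteps, method = method)
  if (is.null(out)) {
    stop("integration failed for ", design$design_id, " within [",
         times[1], ", ", times[length(times)], "]")
  }
  class(out) <- "matrix"
  out
}

#' Simulate a (possibly noisy) time-course data set
#'
#' Integrates the model under the design, samples the observed variables on
#' the design grid and applies multiplicative Gaussian noise:
#' `value = clean * (1 + noise_level * z)` with `z ~ N(0,1)`, seeded.
#' `noise_level = 0` returns exact trajectory samples. Negative noisy values
#' are kept (no clipping) so the noise stays unbiased.
#'
#' @param model an [ode_model].
#' @param p_true parameter vector used for simulation.
#' @param design an [experiment_design].
#' @param noise_level nonnegative noise fraction (0.1 = 10%).
#' @param seed integer seed for the noise draw (ignored when
#'   `noise_level = 0`).
#' @param observed names of observed states (default: all).
#' @return object of class `pc_dataset` with fields `design`, `times`,
#'   `observed_names`, `values` (M x n matrix), `weights` (all 1 by default)
#'   and `noise_level`.
#' @export
generate_dataset <- function(model, p_true, design, noise_level = 0, seed = 1,
                             observed = model$state_names) {
  if (noise_level < 0) stop("'noise_level' must be nonnegative")
  bad <- setdiff(observed, model$state_names)
  if (length(bad)) stop("unknown observed variable(s): ", paste(bad, collapse = ", "))
  traj <- simulate_trajectory(model, p_true, design)
  times <- design_times(design)
  clean <- traj[match(times, traj[, "time"]), observed, drop = FALSE]
  values <- if (noise_level > 0) {
    z <- with_seed(seed, matrix(stats::rnorm(length(clean)), nrow(clean), ncol(clean)))
    clean * (1 + noise_level * z)
  } else clean
  structure(list(design = design, times = times, observed_names = observed,
                 values = values,
                 weights = matrix(1, nrow(values), ncol(values),
                                  dimnames = dimnames(values)),
                 noise_level = noise_level,
                 seed = if (noise_level > 0) seed else NA_integer_),
            class = "pc_dataset")
}

#' @export
print.pc_dataset <- function(x, ...) {
  cat("<pc_dataset> ", x$design$design_id, ": ", length(x$times), " samples of (",
      paste(x$observed_names, collapse = ", "), "), noise ",
      x$noise_level * 100, "%\n", sep = "")
  invisible(x)
}

#' Write a data set as CSV plus a JSON metadata sidecar
#'
#' The CSV has a `time` column and one column per observed variable; the
#' sidecar `<path>.json` stores the design (controls, x0, grid), noise level
#' and seed so the data set can be reconstructed exactly.
#'
#' @param dataset a `pc_dataset`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  df <- data.frame(time = dataset$times, dataset$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(
    design_id = dataset$design$design_id,
    controls = as.list(dataset$design$controls),
    x0 = as.numeric(dataset$design$x0),
    t0 = dataset$design$t0, t_end = dataset$design$t_end,
    n_samples = dataset$design$n_samples,
    noise_level = dataset$noise_level,
    seed = if (is.na(dataset$seed)) NULL else dataset$seed
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a data set written by [write_dataset()]
#'
#' Non-uniform user-supplied grids are accepted: when the CSV times do not
#' match the sidecar's uniform grid, the actual times are kept.
#'
#' @param path CSV path (expects `<path>.json` next to it).
#' @return a `pc_dataset`.
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  controls <- unlist(meta$controls)
  design <- experiment_design(controls = controls, x0 = as.numeric(meta$x0),
                              t0 = meta$t0, t_end = meta$t_end,
                              n_samples = meta$n_samples,
                              design_id = meta$design_id %||% basename(path))
  times <- df$time
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  values <- as.matrix(df[setdiff(names(df), "time")])
  structure(list(design = design, times = times,
                 observed_names = colnames(values), values = values,
                 weights = matrix(1, nrow(values), ncol(values),
                                  dimnames = dimnames(values)),
                 noise_level = meta$noise_level %||% 0,
                 seed = meta$seed %||% NA_integer_),
            class = "pc_dataset")
}
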