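## Forward sensitivities and sampled parameter-Jacobian stacks.
##
## The correlation analysis works on two kinds of row-stacked matrices with
## one column per parameter:
##   * source "rhs_jacobian": rows of df/dp evaluated at points along the
##     trajectory (the a priori object — linear dependences here are inherited
##     by the state sensitivities through the variation-of-constants integral);
##   * source "state_sensitivity": rows of S(t) = dx/dp from integrating the
##     sensitivity ODE  S' = (df/dx) S + df/dp,  S(t0) = 0.
## Stacks across several designs realise the multi-experiment rank condition.

#' Integrate forward sensitivities along one design
#'
#' Solves the augmented system \eqn{\dot x = f}, \eqn{\dot S = (\partial
#' f/\partial x) S + \partial f/\partial p} from \eqn{S(t_0) = 0} on the
#' design's sampling grid. The zero initial condition reflects a fixed,
#' parameter-independent initial state.
#'
#' @param model an [ode_model].
#' @param design an [experiment_design].
#' @param p parameter vector at which sensitivities are evaluated.
#' @param free names (or indices) of the parameters to differentiate with
#'   respect to; default all. Restricting this shrinks the augmented system.
#' @param rtol,atol integrator tolerances.
#' @param maxsteps integrator step cap per output interval.
#' @param method integrator method; `"adams"` tries the non-stiff solver
#'   first and falls back to lsoda.
#' @return object of class `sensitivity_trajectory`: `times` (T), `states`
#'   (T x n), `sens` (T x n x NP_free array, dimnames carry parameter names).
#' @export
integrate_sensitivities <- function(model, design, p, free = model$param_names,
                                    rtol = .sim_rtol, atol = .sim_atol,
                                    maxsteps = 5000, method = "lsoda") {
  check_dims(model, design$x0, design$controls, p)
  if (is.numeric(free)) free <- model$param_names[free]
  free_idx <- match(free, model$param_names)
  if (anyNA(free_idx)) stop("unknown parameter(s) in 'free'")
  n <- n_states(model); nf <- length(free_idx)
  u <- design$controls
  times <- c(design$t0, design_times(design))
  deriv <- function(t, y, parms) {
    x <- y[seq_len(n)]
    S <- matrix(y[-seq_len(n)], n, nf)
    env <- eval_env(model, x, u, parms, t)
    f <- eval(model$calls$rhs, env)
    Jx <- matrix(eval(model$calls$jacx, env), n, n, byrow = TRUE)
    Jp <- matrix(eval(model$calls$jacp, env), n, n_params(model), byrow = TRUE)
    list(c(f, Jx %*% S + Jp[, free_idx, drop = FALSE]))
  }
  y0 <- c(as.numeric(design$x0), rep(0, n * nf))
  out <- ode_with_fallback(y = y0, times = times, func = deriv,
                           parms = as.numeric(p), rtol = rtol, atol = atol,
                           maxsteps = maxsteps, method = method)
  if (is.null(out)) {
    stop("sensitivity integration failed for ", design$design_id,
         " within [", times[1], ", ", times[length(times)], "]")
  }
  states <- out[, 1L + seq_len(n), drop = FALSE]
  colnames(states) <- model$state_names
  sens <- array(out[, -seq_len(1L + n)], dim = c(nrow(out), n, nf),
                dimnames = list(NULL, model$state_names, free))
  structure(list(times = out[, 1], states = states, sens = sens,
                 design_id = design$design_id),
            class = "sensitivity_trajectory")
}

#' @export
print.sensitivity_trajectory <- function(x, ...) {
  d <- dim(x$sens)
  cat("<sensitivity_trajectory> ", x$design_id, ": ", d[1], " times, ",
      d[2], " states, ", d[3], " parameters\n", sep = "")
  invisible(x)
}

new_derivative_stack <- function(matrix, row_info, col_labels, source) {
  colnames(matrix) <- col_labels
  structure(list(matrix = matrix, row_info = row_info,
                 col_labels = col_labels, source = source),
            class = "derivative_stack")
}

#' @export
print.derivative_stack <- function(x, ...) {
  cat("<derivative_stack> [", nrow(x$matrix), " x ", ncol(x$matrix),
      "], source = ", x$source, ", designs = ",
      length(unique(x$row_info$design)), "\n", sep = "")
  invisible(x)
}

#' Sample the parameter Jacobian df/dp along trajectories
#'
#' For each design the trajectory is integrated and \eqn{\partial f/\partial
#' p} is evaluated at `points_per_design` times spread uniformly over it; all
#' rows are stacked. Row provenance (design, time, equation) is retained so
#' analyses can be run per design or jointly.
#'
#' @param model an [ode_model].
#' @param p parameter vector.
#' @param designs list of [experiment_design] objects (>= 1).
#' @param points_per_design number of time points per design (default 40).
#' @param rtol,atol integrator tolerances for the trajectory.
#' @return a `derivative_stack` with source `"rhs_jacobian"`; the matrix has
#'   `n * points_per_design * length(designs)` rows and NP columns.
#' @export
sample_rhs_stack <- function(model, p, designs, points_per_design = 40,
                             rtol = .sim_rtol, atol = .sim_atol) {
  if (inherits(designs, "experiment_design")) designs <- list(designs)
  if (length(designs) < 1L) stop("at least one design is required")
  n <- n_states(model)
  blocks <- lapply(designs, function(d) {
    tpts <- seq(d$t0, d$t_end, length.out = points_per_design + 1L)[-1L]
    traj <- simulate_trajectory(model, p, d, times = c(d$t0, tpts),
                                rtol = rtol, atol = atol)
    rows <- do.call(rbind, lapply(seq_along(tpts), function(i) {
      jac_params(model, traj[i + 1L, model$state_names], d$controls, p, tpts[i])
    }))
    list(rows = rows,
         info = data.frame(design = d$design_id,
                           time = rep(tpts, each = n),
                           component = rep(model$state_names, points_per_design)))
  })
  new_derivative_stack(do.call(rbind, lapply(blocks, `[[`, "rows")),
                       do.call(rbind, lapply(blocks, `[[`, "info")),
                       model$param_names, "rhs_jacobian")
}

#' Stack state-sensitivity rows across designs
#'
#' Integrates forward sensitivities for each design and stacks the rows of
#' S(t) at the sample times, optionally restricted to a subset of observed
#' states. This is the matrix whose column angles drive the dendrogram and
#' whose rank decides identifiability from partial observations.
#'
#' @param model an [ode_model].
#' @param p parameter vector.
#' @param designs list of [experiment_design] objects.
#' @param observed state names whose sensitivity rows are kept (default all).
#' @param rtol,atol integrator tolerances.
#' @return a `derivative_stack` with source `"state_sensitivity"`.
#' @export
sample_sensitivity_stack <- function(model, p, designs,
                                     observed = model$state_names,
                                     rtol = .sim_rtol, atol = .sim_atol) {
  if (inherits(designs, "experiment_design")) designs <- list(designs)
  bad <- setdiff(observed, model$state_names)
  if (length(bad)) stop("unknown observed state(s): ", paste(bad, collapse = ", "))
  obs_idx <- match(observed, model$state_names)
  blocks <- lapply(designs, function(d) {
    st <- integrate_sensitivities(model, d, p, rtol = rtol, atol = atol)
    keep_t <- which(st$times > d$t0)   # S(t0) = 0 carries no information
    rows <- do.call(rbind, lapply(keep_t, function(i) {
      st$sens[i, obs_idx, , drop = TRUE]
    }))
    if (length(obs_idx) == 1L) rows <- matrix(rows, ncol = dim(st$sens)[3])
    list(rows = rows,
         info = data.frame(design = d$design_id,
                           time = rep(st$times[keep_t], each = length(obs_idx)),
                           component = rep(observed, length(keep_t))))
  })
  new_derivative_stack(do.call(rbind, lapply(blocks, `[[`, "rows")),
                       do.call(rbind, lapply(blocks, `[[`, "info")),
                       model$param_names, "state_sensitivity")
}

#' Restrict a stack to one design
#' @param stack a `derivative_stack`.
#' @param design_id design label to keep.
#' @return a `derivative_stack` with the matching rows.
#' @export
subset_stack <- function(stack, design_id) {
  keep <- stack$row_info$design %in% design_id
  if (!any(keep)) stop("no rows for design ", design_id)
  new_derivative_stack(stack$matrix[keep, , drop = FALSE],
                       stack$row_info[keep, , drop = FALSE],
                       stack$col_labels, stack$source)
}

#' Export a stack as a labelled data frame (CSV-ready)
#' @param x a `derivative_stack`.
#' @param ... unused.
#' @return data.frame with design/time/component columns then one column per
#'   parameter.
#' @export
as.data.frame.derivative_stack <- function(x, ...) {
  cbind(x$row_info, as.data.frame(x$matrix))
}
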