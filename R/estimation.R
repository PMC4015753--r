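## Multi-data-set weighted least squares with analytic sensitivities.
##
## The cost is the summed weighted squared error over all data sets fitted
## simultaneously. Internally the free parameters live on the log scale
## (kinetic constants are strictly positive and span decades), the residual
## Jacobian comes from forward sensitivities restricted to the free
## parameters, and the minimizer is Levenberg-Marquardt (minpack.lm) with
## box bounds.

#' Define a fitting problem
#'
#' @param model an [ode_model].
#' @param datasets list of `pc_dataset` objects (>= 1), possibly from
#'   different designs; fitted jointly.
#' @param free names of the parameters to estimate (default: all).
#' @param p_fixed full-length parameter vector supplying the values of the
#'   non-free parameters (ignored entries for free parameters); required when
#'   `free` is not all parameters.
#' @param bounds length-2 positive vector `c(lower, upper)` applied to every
#'   free parameter, or a 2 x NP_free matrix.
#' @param p_init optional start vector for the free parameters (full-length
#'   vectors are subset); when given, multistart is skipped.
#' @param rtol,atol integrator tolerances used inside the fit.
#' @param maxsteps integrator step cap per output interval inside the fit;
#'   parameter regions where the solver grinds at its minimum step are
#'   treated as integration failures and penalized.
#' @param method integrator method for fit internals; the default
#'   `"adams"` runs the faster non-stiff solver with automatic lsoda
#'   fallback.
#' @return object of class `fit_problem`.
#' @export
fit_problem <- function(model, datasets, free = model$param_names,
                        p_fixed = NULL, bounds = c(1e-3, 1e3), p_init = NULL,
                        rtol = 1e-7, atol = 1e-9, maxsteps = 500,
                        method = "adams") {
  if (inherits(datasets, "pc_dataset")) datasets <- list(datasets)
  if (!length(datasets)) stop("at least one data set is required")
  if (!length(free)) stop("'free' must name at least one parameter")
  bad <- setdiff(free, model$param_names)
  if (length(bad)) stop("unknown free parameter(s): ", paste(bad, collapse = ", "))
  for (ds in datasets) {
    unknown <- setdiff(ds$observed_names, model$state_names)
    if (length(unknown))
      stop("data set ", ds$design$design_id, " observes unknown variable(s): ",
           paste(unknown, collapse = ", "))
  }
  if (length(free) < n_params(model) && is.null(p_fixed))
    stop("'p_fixed' is required when some parameters are held fixed")
  p_fixed <- p_fixed %||% rep(NA_real_, n_params(model))
  if (length(p_fixed) != n_params(model))
    stop("'p_fixed' must have length ", n_params(model))
  if (is.matrix(bounds)) {
    if (!all(dim(bounds) == c(2L, length(free))))
      stop("'bounds' matrix must be 2 x ", length(free))
  } else {
    bounds <- matrix(rep(as.numeric(bounds), length(free)), nrow = 2)
  }
  if (any(bounds <= 0) || any(bounds[1, ] >= bounds[2, ]))
    stop("bounds must be positive intervals")
  if (!is.null(p_init)) {
    if (length(p_init) == n_params(model))
      p_init <- p_init[match(free, model$param_names)]
    if (length(p_init) != length(free))
      stop("'p_init' must cover the free parameters")
    if (any(p_init < bounds[1, ] | p_init > bounds[2, ]))
      stop("'p_init' must lie within the bounds")
  }
  structure(list(model = model, datasets = datasets, free = free,
                 free_idx = match(free, model$param_names),
                 p_fixed = as.numeric(p_fixed), bounds = bounds,
                 p_init = p_init, rtol = rtol, atol = atol,
                 maxsteps = maxsteps, method = method),
            class = "fit_problem")
}

#' @export
print.fit_problem <- function(x, ...) {
  cat("<fit_problem> ", length(x$datasets), " data set(s), ",
      length(x$free), "/", n_params(x$model), " parameters free\n", sep = "")
  invisible(x)
}

full_param_vector <- function(problem, p_free) {
  p <- problem$p_fixed
  p[problem$free_idx] <- p_free
  p
}

# weighted residual vector for a subset of the data sets; time-major within
# each data set (all observed variables at t_1, then t_2, ...). Returns NULL
# on integration failure.
problem_residuals <- function(problem, p_full, subset = seq_along(problem$datasets)) {
  model <- problem$model
  res <- lapply(problem$datasets[subset], function(ds) {
    traj <- try(simulate_trajectory(model, p_full, ds$design,
                                    times = c(ds$design$t0, ds$times),
                                    rtol = problem$rtol, atol = problem$atol,
                                    maxsteps = problem$maxsteps,
                                    method = problem$method),
                silent = TRUE)
    if (inherits(traj, "try-error")) return(NULL)
    pred <- traj[-1L, ds$observed_names, drop = FALSE]
    as.vector(t(sqrt(ds$weights) * (pred - ds$values)))
  })
  if (any(vapply(res, is.null, TRUE))) return(NULL)
  unlist(res, use.names = FALSE)
}

# residual Jacobian w.r.t. the log of the free parameters, same row order
problem_jacobian <- function(problem, p_full, subset = seq_along(problem$datasets)) {
  model <- problem$model
  free <- problem$free
  blocks <- lapply(problem$datasets[subset], function(ds) {
    st <- try(integrate_sensitivities(model, ds$design, p_full, free = free,
                                      rtol = problem$rtol, atol = problem$atol,
                                      maxsteps = problem$maxsteps,
                                      method = problem$method),
              silent = TRUE)
    if (inherits(st, "try-error")) return(NULL)
    ti <- match(ds$times, st$times)
    obs <- match(ds$observed_names, model$state_names)
    sw <- sqrt(ds$weights)
    do.call(rbind, lapply(seq_along(ti), function(l) {
      sw[l, ] * st$sens[ti[l], obs, , drop = TRUE]
    }))
  })
  if (any(vapply(blocks, is.null, TRUE))) return(NULL)
  J <- do.call(rbind, blocks)
  sweep(J, 2, p_full[problem$free_idx], "*")   # chain rule: d/d log p
}

#' Cost function of a fitting problem
#'
#' Summed weighted squared error over all data sets at a full parameter
#' vector, using the problem's integrator tolerances.
#'
#' @param problem a [fit_problem].
#' @param p full-length parameter vector.
#' @return nonnegative scalar.
#' @export
cost_function <- function(problem, p) {
  r <- problem_residuals(problem, p)
  if (is.null(r)) stop("integration failed at the supplied parameter point")
  sum(r^2)
}

n_residuals <- function(problem, subset = seq_along(problem$datasets)) {
  sum(vapply(problem$datasets[subset],
             function(ds) length(ds$times) * length(ds$observed_names), 1L))
}

run_lm <- function(problem, p0_free, subset, maxiter) {
  nres <- n_residuals(problem, subset)
  penalty <- sqrt(1e6 / nres)    # flat high residual when integration fails
  nfree <- length(problem$free)
  fn <- function(th) {
    r <- problem_residuals(problem, full_param_vector(problem, exp(th)), subset)
    if (is.null(r)) rep(penalty, nres) else r
  }
  jac <- function(th) {
    J <- problem_jacobian(problem, full_param_vector(problem, exp(th)), subset)
    if (is.null(J)) matrix(0, nres, nfree) else J
  }
  minpack.lm::nls.lm(par = log(p0_free), fn = fn, jac = jac,
                     lower = log(problem$bounds[1, ]),
                     upper = log(problem$bounds[2, ]),
                     control = minpack.lm::nls.lm.control(
                       maxiter = maxiter, ftol = 1e-13, ptol = 1e-13, gtol = 0))
}

# per-state residual shares of the cost at a parameter point (NULL on
# integration failure); feeds the residual-guided basin kicks
equation_shares <- function(problem, p_full, subset) {
  model <- problem$model
  shares <- numeric(n_states(model))
  names(shares) <- model$state_names
  for (ds in problem$datasets[subset]) {
    traj <- try(simulate_trajectory(model, p_full, ds$design,
                                    times = c(ds$design$t0, ds$times),
                                    rtol = problem$rtol, atol = problem$atol,
                                    maxsteps = problem$maxsteps,
                                    method = problem$method),
                silent = TRUE)
    if (inherits(traj, "try-error")) return(NULL)
    rr <- ds$weights * (traj[-1L, ds$observed_names, drop = FALSE] - ds$values)^2
    shares[ds$observed_names] <- shares[ds$observed_names] + colSums(rr)
  }
  shares
}

# full Levenberg-Marquardt descent: keep running maxiter-chunks while the
# optimizer is still moving (info == -1 means the iteration cap, not a
# stall); stop on convergence/stall, the residual threshold, or the chunk
# budget
lm_descend <- function(problem, p0_free, subset, maxiter, threshold,
                       max_chunks = 3L) {
  p <- p0_free
  iters <- 0L
  ssr_prev <- Inf
  for (chunk in seq_len(max_chunks)) {
    lm <- run_lm(problem, p, subset, maxiter)
    p <- exp(coef(lm))
    iters <- iters + lm$niter
    ssr <- sum(stats::resid(lm)^2)
    # re-chunk only while still descending (at least 10% per chunk)
    if (!all(is.finite(p)) || ssr <= threshold || lm$info != -1L ||
        ssr > 0.9 * ssr_prev) break
    ssr_prev <- ssr
  }
  list(p_free = p, ssr = ssr, info = lm$info, iters = iters)
}

# descent plus seeded basin-hopping kicks: when LM stalls in a local minimum
# above the threshold, restart it from a modified point. Odd kicks are
# residual-guided block restarts: the kick targets the single worst-fitting
# equation (cycling through the bad equations on later kicks), redraws the
# parameters structurally entering it log-uniformly in `resample_box` —
# local minima of this landscape often pin whole misfit blocks at bound
# faces, where multiplicative jitter cannot rescue them — and screens
# several such redraws by their cost before descending from the cheapest.
# Even kicks jitter every parameter at `hop_sd`. Hopping stops early after
# `patience` kicks without improvement, and respects the caller's iteration
# budget. Draws come from the ambient RNG stream (the caller seeds it).
lm_basin_hops <- function(problem, p0_free, subset, maxiter, threshold,
                          n_hops, hop_sd, resample_box, patience = 6L,
                          iter_budget = Inf, n_screen = 16L) {
  best <- lm_descend(problem, p0_free, subset, maxiter, threshold)
  if (!all(is.finite(best$p_free))) return(NULL)
  nf <- length(best$p_free)
  screen_best <- function(make_draw) {
    draws <- lapply(seq_len(n_screen), function(i) {
      pmin(pmax(make_draw(), problem$bounds[1, ]), problem$bounds[2, ])
    })
    cost <- vapply(draws, function(d) {
      r <- problem_residuals(problem, full_param_vector(problem, d), subset)
      if (is.null(r)) Inf else sum(r^2)
    }, numeric(1))
    if (all(!is.finite(cost))) NULL else draws[[which.min(cost)]]
  }
  since_improved <- 0L
  guided <- 0L
  for (hop in seq_len(n_hops)) {
    if (best$ssr <= threshold || since_improved >= patience ||
        best$iters >= iter_budget) break
    ## kick schedule: two residual-guided block restarts, one global jitter,
    ## one screened full redraw per cycle
    kind <- switch((hop - 1L) %% 4L + 1L, "block", "jitter", "block", "redraw")
    shares <- if (kind == "block")
      equation_shares(problem, full_param_vector(problem, best$p_free), subset)
    if (kind == "block" && is.null(shares)) kind <- "jitter"
    p_try <- switch(kind,
      block = {
        ## redraw the parameters of the worst equation (cycling through bad
        ## equations across kicks), screening draws by their cost
        bad <- names(sort(shares[shares >= 0.05 * max(shares)],
                          decreasing = TRUE))
        eq <- bad[(guided %% length(bad)) + 1L]
        guided <- guided + 1L
        target <- problem$free %in%
          colnames(problem$model$p_incidence)[problem$model$p_incidence[eq, ]]
        if (!any(target)) target <- rep(TRUE, nf)
        screen_best(function() {
          p <- best$p_free * exp(stats::rnorm(nf, 0, hop_sd / 4))
          p[target] <- exp(stats::runif(sum(target),
                                        log(resample_box[1, target]),
                                        log(resample_box[2, target])))
          p
        })
      },
      jitter = best$p_free * exp(stats::rnorm(nf, 0, hop_sd)),
      redraw = screen_best(function()
        exp(stats::runif(nf, log(resample_box[1, ]), log(resample_box[2, ]))))
    )
    if (is.null(p_try)) { since_improved <- since_improved + 1L; next }
    p_try <- pmin(pmax(p_try, problem$bounds[1, ]), problem$bounds[2, ])
    cand <- lm_descend(problem, p_try, subset, maxiter, threshold)
    best$iters <- best$iters + cand$iters
    if (all(is.finite(cand$p_free)) && cand$ssr < best$ssr) {
      best[c("p_free", "ssr", "info")] <- cand[c("p_free", "ssr", "info")]
      since_improved <- 0L
    } else {
      since_improved <- since_improved + 1L
    }
  }
  best
}

#' Fit parameters by multistart trust-region least squares
#'
#' Minimizes the summed weighted squared error over all data sets jointly
#' (one simultaneous fit, not averaged per-data-set fits), with the analytic
#' residual Jacobian from forward sensitivities and box bounds on the log
#' scale.
#'
#' Starts: `p_init` if the problem has one, otherwise `multistart` random
#' points drawn log-uniformly in `start_box` (intersected with the bounds)
#' and ranked by their initial cost. The optimizer then runs one
#' Levenberg-Marquardt descent from each of the `n_descents` best starts
#' and keeps the lowest stall — basins are poorly predicted by the initial
#' cost alone, so several short descents buy diversity cheaply — before
#' spending the remaining budget on *basin hops* from the incumbent: seeded
#' kicks (residual-guided block restarts on the worst-fitting equations,
#' global jitters, and screened full redraws, in a fixed cycle), each
#' followed by a fresh descent, keeping improvements. With `cascade = TRUE`
#' and three or more data sets a *data continuation* runs first: the first
#' two data sets are fitted alone and the full set is then fitted from that
#' solution — the two-data-set zero-residual manifold contains the true
#' point, so the full fit starts close to the global basin, where direct
#' all-at-once fitting from distant starts stalls.
#'
#' @param problem a [fit_problem].
#' @param multistart number of random starts to draw (ignored with `p_init`).
#' @param seed seed for the start draw and the basin hops.
#' @param cascade fit the two-data-set subproblem first (default TRUE when
#'   more than two data sets).
#' @param maxiter Levenberg-Marquardt iteration cap per descent.
#' @param residual_threshold accept the fit when the total residual falls
#'   at or below this (default `1e-9`, the noise-free acceptance scale).
#' @param start_box length-2 positive vector: log-uniform start range
#'   (default `c(0.1, 10)`).
#' @param n_hops basin-hopping kicks allowed per stage (default 10).
#' @param hop_sd log-scale standard deviation of a jitter kick (default
#'   0.3); block-restart kicks redraw the implicated parameters
#'   log-uniformly in the start box instead, which rescues minima pinned at
#'   bound faces.
#' @param max_total_iter overall Levenberg-Marquardt iteration budget across
#'   descents, stages and hops (default 900); the incumbent is returned when
#'   it is exhausted.
#' @return object of class `fit_result`: `p_hat` (full named vector),
#'   `p_free`, `total_residual`, `per_point_residuals` (list of M x n
#'   matrices of signed residuals per data set), `n_iterations`, `converged`
#'   (LM met its gradient/step tolerances), `threshold_met`, `seed`,
#'   `starts_tried`.
#' @export
fit_parameters <- function(problem, multistart = 10, seed = 1,
                           cascade = length(problem$datasets) > 2,
                           maxiter = 120, residual_threshold = 1e-9,
                           start_box = c(0.1, 10),
                           n_hops = 10, hop_sd = 0.3, max_total_iter = 900) {
  nfree <- length(problem$free)
  lo <- pmax(start_box[1], problem$bounds[1, ])
  hi <- pmin(start_box[2], problem$bounds[2, ])
  K <- length(problem$datasets)
  ## the data continuation exists to tame random starts; a user-supplied
  ## start goes straight to the full problem
  stages <- if (cascade && K > 2 && is.null(problem$p_init))
    list(1:2, seq_len(K)) else list(seq_len(K))

  best <- NULL
  tried <- 0L
  with_seed(seed, {
    if (!is.null(problem$p_init)) {
      starts <- list(problem$p_init)
    } else {
      starts <- lapply(seq_len(multistart), function(i)
        exp(stats::runif(nfree, log(lo), log(hi))))
      cost0 <- vapply(starts, function(s) {
        r <- problem_residuals(problem, full_param_vector(problem, s),
                               stages[[1]])
        if (is.null(r)) Inf else sum(r^2)
      }, numeric(1))
      if (all(!is.finite(cost0)))
        stop("integration failed at every start; widen 'start_box' or supply 'p_init'")
      starts <- starts[order(cost0)][seq_len(sum(is.finite(cost0)))]
    }

    ## phase A — the race: a short descent from every start; which basin a
    ## start leads to is poorly predicted by its initial cost, so breadth
    ## beats depth here
    spent <- 0L
    incumbent <- NULL
    race_iters <- if (length(starts) > 1L) max(30L, maxiter %/% 3L) else maxiter
    for (p0 in starts) {
      tried <- tried + 1L
      cand <- lm_descend(problem, p0, stages[[1]], race_iters,
                         residual_threshold, max_chunks = 1L)
      spent <- spent + cand$iters
      if (!all(is.finite(cand$p_free))) next
      if (is.null(incumbent) || cand$ssr < incumbent$ssr) incumbent <- cand
      if (incumbent$ssr <= residual_threshold || spent >= max_total_iter) break
    }
    if (!is.null(incumbent)) {
      ## phase B: deep descent plus basin hops from the race winner, then
      ## the remaining data-continuation stages
      best <- incumbent
      for (subset in stages) {
        cand <- lm_basin_hops(problem, best$p_free, subset, maxiter,
                              residual_threshold, n_hops, hop_sd,
                              resample_box = rbind(lo, hi),
                              iter_budget = max_total_iter - spent)
        if (is.null(cand)) break
        spent <- spent + cand$iters
        best <- cand
      }
      best$iters <- spent
    }
  })
  if (is.null(best)) stop("all fitting attempts failed to integrate")

  p_full <- full_param_vector(problem, best$p_free)
  names(p_full) <- problem$model$param_names
  per_point <- lapply(problem$datasets, function(ds) {
    traj <- simulate_trajectory(problem$model, p_full, ds$design,
                                times = c(ds$design$t0, ds$times),
                                rtol = problem$rtol, atol = problem$atol,
                                maxsteps = problem$maxsteps,
                                method = problem$method)
    traj[-1L, ds$observed_names, drop = FALSE] - ds$values
  })
  total <- sum(vapply(seq_along(per_point), function(j)
    sum(problem$datasets[[j]]$weights * per_point[[j]]^2), numeric(1)))
  structure(list(
    p_hat = p_full,
    p_free = stats::setNames(best$p_free, problem$free),
    total_residual = total,
    per_point_residuals = per_point,
    n_iterations = best$iters,
    converged = best$info %in% 1:4,
    threshold_met = total <= residual_threshold,
    seed = seed, starts_tried = tried
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> total residual ", format(x$total_residual, digits = 4),
      " after ", x$n_iterations, " iterations (",
      if (x$converged) "converged" else "not converged",
      if (x$threshold_met) ", below threshold", ")\n", sep = "")
  est <- x$p_free
  show <- utils::head(est, 6)
  cat("  estimates: ", paste(names(show), "=", signif(show, 6), collapse = ", "),
      if (length(est) > 6) ", ...", "\n", sep = "")
  invisible(x)
}

#' Rank of the stacked observation-sensitivity matrix
#'
#' Builds the sensitivity rows of the observed states across all designs'
#' sample times and returns the numerical rank. A rank equal to NP signals
#' theoretical identifiability of the state-equation parameters from those
#' observations under those designs; the rank of the full-state single-design
#' stack equals the rank of the sampled df/dp stack (the sensitivities are a
#' linear integral transform of it).
#'
#' @param model an [ode_model].
#' @param p parameter vector.
#' @param designs list of [experiment_design] objects.
#' @param observed_names names of observed states.
#' @param rank_tol relative singular-value cutoff.
#' @return integer rank.
#' @export
output_sensitivity_rank <- function(model, p, designs, observed_names,
                                    rank_tol = .rank_tol) {
  if (!length(observed_names)) stop("'observed_names' must be nonempty")
  stack <- sample_sensitivity_stack(model, p, designs, observed = observed_names)
  numerical_rank(stack$matrix, tol = rank_tol)
}
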