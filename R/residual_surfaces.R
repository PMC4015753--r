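## Residual-surface tracing: the geometric view of parameter correlations.
##
## Fixing one or two members of a correlated group at grid values and
## refitting the remaining parameters to a single data set traces the
## (zero or nonzero) residual surface of that data set in the group's
## parameter subspace. Surfaces from data sets with different control inputs
## cross at the true parameter point; surfaces of a structurally
## non-identifiable group coincide for every input.

#' Trace a residual surface in a correlated-parameter subspace
#'
#' For each grid point the named parameters are fixed and the remaining free
#' parameters are refitted to the single data set by Levenberg-Marquardt,
#' warm-starting from the neighbouring grid point for continuity. By default
#' only the other members of `group` are refitted and all parameters outside
#' the group stay at `p_ref` (isolates the group's surface); with
#' `free_all = TRUE` every non-fixed parameter is refitted.
#'
#' @param model an [ode_model].
#' @param dataset a `pc_dataset`.
#' @param group character vector: the correlated group's members (or a
#'   `correlation_group`).
#' @param fixed_params names (subset of `group`, length 1 or 2) of the
#'   parameters scanned over the grid.
#' @param grid numeric vector (one fixed parameter) or data frame/matrix with
#'   one column per fixed parameter; default 21 points log-spaced over
#'   `[0.5, 2] *` the reference value (a 7 x 7 log-grid for two).
#' @param p_ref full-length reference parameter vector (start values and the
#'   values of non-refitted parameters).
#' @param free_all refit all non-fixed parameters instead of only the group's.
#' @param multistart,seed passed to [fit_parameters()] when the warm start
#'   fails (first grid point only).
#' @param maxiter LM iteration cap per grid point.
#' @return object of class `residual_surface`: a data frame `surface` with
#'   the fixed values, the refitted free-parameter values and the residual at
#'   each grid point (failed refits are `NA`), plus metadata.
#' @export
trace_surface <- function(model, dataset, group, fixed_params, grid = NULL,
                          p_ref, free_all = FALSE, multistart = 1, seed = 1,
                          maxiter = 100) {
  if (inherits(group, "correlation_group")) group <- group$members
  if (!all(fixed_params %in% group))
    stop("'fixed_params' must be members of the group")
  if (!length(fixed_params) %in% 1:2)
    stop("1 or 2 fixed parameters are supported")
  if (length(p_ref) != n_params(model))
    stop("'p_ref' must be a full-length parameter vector")
  p_ref <- stats::setNames(as.numeric(p_ref), model$param_names)

  if (is.null(grid)) {
    gl <- lapply(fixed_params, function(pn) {
      v <- p_ref[pn]
      n <- if (length(fixed_params) == 1L) 21L else 7L
      exp(seq(log(0.5 * v), log(2 * v), length.out = n))
    })
    grid <- if (length(fixed_params) == 1L) data.frame(gl[[1]])
            else expand.grid(gl[[1]], gl[[2]], KEEP.OUT.ATTRS = FALSE)
    names(grid) <- fixed_params
  } else {
    grid <- as.data.frame(grid)
    if (ncol(grid) != length(fixed_params))
      stop("'grid' must have one column per fixed parameter")
    names(grid) <- fixed_params
  }
  if (!nrow(grid)) stop("empty grid")

  free <- if (free_all) setdiff(model$param_names, fixed_params)
          else setdiff(group, fixed_params)
  if (!length(free)) stop("no free parameters left to refit")

  refit <- matrix(NA_real_, nrow(grid), length(free),
                  dimnames = list(NULL, free))
  residuals <- rep(NA_real_, nrow(grid))
  warm <- p_ref[free]
  for (i in seq_len(nrow(grid))) {
    p_fix <- p_ref
    p_fix[fixed_params] <- as.numeric(grid[i, ])
    prob <- fit_problem(model, dataset, free = free, p_fixed = p_fix,
                        p_init = warm)
    # warm-started low-dimensional refits: plain LM, no basin hops
    res <- try(fit_parameters(prob, multistart = multistart, seed = seed,
                              maxiter = maxiter, n_hops = 0), silent = TRUE)
    if (inherits(res, "try-error")) next   # isolated failures recorded as NA
    refit[i, ] <- res$p_free
    residuals[i] <- res$total_residual
    warm <- res$p_free
  }
  structure(list(
    surface = cbind(grid, as.data.frame(refit), residual = residuals),
    fixed_params = fixed_params, free_params = free,
    dataset_id = dataset$design$design_id,
    noise_level = dataset$noise_level,
    p_ref = p_ref
  ), class = "residual_surface")
}

#' @export
print.residual_surface <- function(x, ...) {
  cat("<residual_surface> ", x$dataset_id, ": ", nrow(x$surface),
      " grid points over (", paste(x$fixed_params, collapse = ", "),
      "), refit (", paste(utils::head(x$free_params, 4), collapse = ", "),
      if (length(x$free_params) > 4) ", ...", ")\n", sep = "")
  invisible(x)
}

# spline interpolant of a minimizer locus over its own valid grid points
# (natural cubic: the loci are smooth curves, and piecewise-linear
# interpolation would bias the crossing by O(h^2) of their curvature)
locus_fun <- function(g, m) {
  ok <- is.finite(m)
  if (sum(ok) < 2) return(NULL)
  if (sum(ok) == 2) return(stats::approxfun(g[ok], m[ok], rule = 2))
  stats::splinefun(g[ok], m[ok], method = "natural")
}

# crossing of two 1-D minimizer loci on [lo, hi]; NULL when no transversal
# crossing exists there
locus_crossing <- function(f1, f2, lo, hi, degenerate_tol) {
  z <- seq(lo, hi, length.out = 201)
  h <- f1(z) - f2(z)
  scale <- max(abs(c(f1(z), f2(z))), 1e-12)
  if (max(abs(h)) <= degenerate_tol * scale)
    return(list(degenerate = TRUE))
  s <- which(h[-1] * h[-length(h)] <= 0)
  if (!length(s)) return(NULL)
  i <- s[1]
  root <- stats::uniroot(function(x) f1(x) - f2(x), c(z[i], z[i + 1]),
                         tol = 1e-12)$root
  list(degenerate = FALSE, point = c(root, (f1(root) + f2(root)) / 2))
}

#' Crossing point of residual surfaces from different data sets
#'
#' Interpolates each surface's minimizer locus and intersects them. With one
#' scanned parameter the loci are curves in the (fixed, refitted) plane:
#' every pair of surfaces contributes a crossing, and the estimate is their
#' mean with the maximal pairwise scatter as spread. With two scanned
#' parameters each surface is a (locally) planar sheet `p_free = a + b1*g1 +
#' b2*g2`; the least-squares intersection of at least three sheets is
#' returned, with the largest distance from the estimate to any sheet as
#' spread. Coinciding loci (identical inputs, or a structurally
#' non-identifiable group) are reported as degenerate: the surfaces carry no
#' transversal intersection.
#'
#' @param surfaces list of `residual_surface` objects (>= 2) sharing
#'   `fixed_params` and at least one refitted parameter.
#' @param degenerate_tol relative tolerance below which two loci count as
#'   identical.
#' @return list with `point` (named: fixed parameters then the tracked free
#'   parameter), `spread`, `degenerate` flag, and `pairwise` (the individual
#'   pair crossings, 1-D case).
#' @export
crossing_point <- function(surfaces, degenerate_tol = 1e-6) {
  if (length(surfaces) < 2) stop("at least two surfaces are required")
  fx <- surfaces[[1]]$fixed_params
  if (!all(vapply(surfaces, function(s) identical(s$fixed_params, fx), TRUE)))
    stop("surfaces must share the same fixed parameters")
  track <- Reduce(intersect, lapply(surfaces, `[[`, "free_params"))
  if (!length(track)) stop("surfaces share no refitted parameter")
  track <- track[1]

  if (length(fx) == 1L) {
    lo <- max(vapply(surfaces, function(s) min(s$surface[[fx]]), 0))
    hi <- min(vapply(surfaces, function(s) max(s$surface[[fx]]), 0))
    if (lo >= hi) stop("surface grids do not overlap")
    funs <- lapply(surfaces, function(s)
      locus_fun(s$surface[[fx]], s$surface[[track]]))
    if (any(vapply(funs, is.null, TRUE)))
      stop("a surface has too few valid refits to interpolate")
    pairs <- utils::combn(length(surfaces), 2, simplify = FALSE)
    crossings <- list(); degen <- 0L
    for (pr in pairs) {
      cr <- locus_crossing(funs[[pr[1]]], funs[[pr[2]]], lo, hi, degenerate_tol)
      if (is.null(cr)) next
      if (cr$degenerate) degen <- degen + 1L else crossings[[length(crossings) + 1L]] <- cr$point
    }
    if (!length(crossings)) {
      return(list(point = stats::setNames(rep(NA_real_, 2), c(fx, track)),
                  spread = NA_real_, degenerate = degen > 0L, pairwise = list()))
    }
    M <- do.call(rbind, crossings)
    point <- stats::setNames(colMeans(M), c(fx, track))
    spread <- if (nrow(M) == 1L) {
      0
    } else {
      max(stats::dist(M))
    }
    list(point = point, spread = spread, degenerate = FALSE,
         pairwise = lapply(crossings, stats::setNames, c(fx, track)))
  } else {
    if (length(surfaces) < 3)
      stop("two scanned parameters need at least three surfaces for a point")
    fits <- lapply(surfaces, function(s) {
      df <- s$surface[is.finite(s$surface[[track]]), , drop = FALSE]
      if (nrow(df) < 3) stop("surface ", s$dataset_id, " has too few valid points")
      stats::lm(stats::reformulate(fx, response = track), data = df)
    })
    ## sheet i:  b1*g1 + b2*g2 - track = -a   ->  rows of the linear system
    A <- do.call(rbind, lapply(fits, function(f) c(stats::coef(f)[fx], -1)))
    b <- -vapply(fits, function(f) stats::coef(f)[["(Intercept)"]], 0)
    sv <- svd(A)
    if (sv$d[length(sv$d)] < degenerate_tol * sv$d[1])
      return(list(point = stats::setNames(rep(NA_real_, 3), c(fx, track)),
                  spread = NA_real_, degenerate = TRUE, pairwise = list()))
    sol <- qr.solve(A, b)
    dists <- abs(A %*% sol - b) / sqrt(rowSums(A^2))
    list(point = stats::setNames(sol, c(fx, track)),
         spread = max(dists), degenerate = FALSE, pairwise = list())
  }
}
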