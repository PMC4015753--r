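## Model representation: nonlinear ODE systems x' = f(x, u, p) with constant
## control inputs u, optional output map y = h(x, u, q), and analytic
## Jacobians obtained by symbolic differentiation of the right-hand side.

# function whitelist for user-supplied expressions
.allowed_funs <- c("+", "-", "*", "/", "^", "(", "exp", "log", "sqrt")

parse_rhs_expr <- function(txt, equation, known, what = "expression") {
  ex <- tryCatch(parse(text = txt)[[1]],
                 error = function(e) stop("cannot parse ", what, " for '", equation,
                                          "': ", conditionMessage(e), call. = FALSE))
  nms <- all.names(ex)
  vars <- all.vars(ex)
  funs <- setdiff(nms, vars)
  bad_fun <- setdiff(funs, .allowed_funs)
  if (length(bad_fun))
    stop("disallowed function(s) in ", what, " for '", equation, "': ",
         paste(bad_fun, collapse = ", "), call. = FALSE)
  bad_sym <- setdiff(vars, known)
  if (length(bad_sym))
    stop("unknown symbol(s) in ", what, " for '", equation, "': ",
         paste(bad_sym, collapse = ", "),
         " (every symbol must be a declared state, control, parameter, or t)",
         call. = FALSE)
  ex
}

# one flat call c(e1, e2, ...) evaluates a whole expression block at once
vector_call <- function(exprs) as.call(c(quote(c), unname(exprs)))

#' Construct a nonlinear ODE model
#'
#' Builds a model object for the system \eqn{\dot x = f(x, u, p)} with an
#' optional output map \eqn{y = h(x, u, q)}. Right-hand sides are given as
#' text and parsed against a fixed function whitelist
#' (`+ - * / ^ exp log sqrt`); any symbol that is not a declared state,
#' control, parameter, output parameter or `t` is an error. Jacobians with
#' respect to states and parameters are derived symbolically at construction
#' time.
#'
#' Control inputs are treated as constants over one experiment (they are set
#' by the experimental design); time-varying inputs are not supported.
#'
#' @param states character vector of state names (length n >= 1).
#' @param params character vector of parameter names appearing in the state
#'   equations (length NP >= 1).
#' @param rhs named character vector of n expressions, names matching
#'   `states`, giving \eqn{f_i} as text.
#' @param controls character vector of control-input names (may be empty).
#' @param outputs optional named character vector of output expressions
#'   \eqn{h}; default is the identity map on the states.
#' @param output_params character vector of parameter names used only in
#'   `outputs` (may be empty).
#' @param name model label used in printing.
#' @return an object of class `ode_model`.
#' @examples
#' m <- ode_model(states = "x", params = c("p1", "p2"), controls = "u",
#'                rhs = c(x = "(p1 + u*p2)*x"))
#' eval_rhs(m, x = 1, u = 2, p = c(0.5, 0.25))
#' @export
ode_model <- function(states, params, rhs, controls = character(),
                      outputs = NULL, output_params = character(),
                      name = "ode_model") {
  states <- as.character(states); params <- as.character(params)
  controls <- as.character(controls); output_params <- as.character(output_params)
  if (length(states) < 1L) stop("at least one state is required")
  if (length(params) < 1L) stop("at least one parameter is required")
  all_names <- c(states, controls, params, output_params)
  if (anyDuplicated(all_names))
    stop("names must be unique across states, controls, parameters and output parameters: ",
         paste(unique(all_names[duplicated(all_names)]), collapse = ", "))
  if ("t" %in% all_names) stop("'t' is reserved for time")
  if (is.null(names(rhs)) || !setequal(names(rhs), states) || anyDuplicated(names(rhs)))
    stop("'rhs' must be a named vector with exactly one expression per state")
  rhs <- rhs[states]

  known <- c(states, controls, params, "t")
  rhs_exprs <- mapply(parse_rhs_expr, rhs, states,
                      MoreArgs = list(known = known), SIMPLIFY = FALSE)

  jacx <- lapply(rhs_exprs, function(e) lapply(states, function(s) stats::D(e, s)))
  jacp <- lapply(rhs_exprs, function(e) lapply(params, function(p) stats::D(e, p)))

  # structural incidence: which parameters enter which equation (D() returns
  # the constant 0 for absent symbols)
  p_incidence <- t(vapply(jacp, function(row) !vapply(row, identical, TRUE, 0),
                          logical(length(params))))
  dimnames(p_incidence) <- list(states, params)

  if (is.null(outputs)) {
    output_exprs <- lapply(states, as.name)
    names(output_exprs) <- states
  } else {
    if (is.null(names(outputs)) || anyDuplicated(names(outputs)))
      stop("'outputs' must be a uniquely named vector of expressions")
    known_h <- c(states, controls, output_params, "t")
    output_exprs <- mapply(parse_rhs_expr, outputs, names(outputs),
                           MoreArgs = list(known = known_h, what = "output expression"),
                           SIMPLIFY = FALSE)
  }
  jach_x <- lapply(output_exprs, function(e) lapply(states, function(s) stats::D(e, s)))
  jach_q <- lapply(output_exprs, function(e) lapply(output_params, function(q) stats::D(e, q)))

  model <- structure(list(
    name = name,
    state_names = states, control_names = controls,
    param_names = params, output_param_names = output_params,
    output_names = names(output_exprs),
    rhs_text = stats::setNames(as.character(rhs), states),
    rhs_exprs = rhs_exprs, output_exprs = output_exprs,
    p_incidence = p_incidence,
    calls = list(
      rhs  = vector_call(rhs_exprs),
      jacx = vector_call(unlist(jacx, recursive = FALSE)),
      jacp = vector_call(unlist(jacp, recursive = FALSE)),
      h    = vector_call(output_exprs),
      jach_x = vector_call(unlist(jach_x, recursive = FALSE)),
      jach_q = if (length(output_params)) vector_call(unlist(jach_q, recursive = FALSE))
    )
  ), class = "ode_model")
  model
}

#' @export
print.ode_model <- function(x, ...) {
  cat("<ode_model> ", x$name, "\n", sep = "")
  cat("  states     (n=",  length(x$state_names), "): ",
      paste(x$state_names, collapse = ", "), "\n", sep = "")
  if (length(x$control_names))
    cat("  controls   (m=", length(x$control_names), "): ",
        paste(x$control_names, collapse = ", "), "\n", sep = "")
  cat("  parameters (NP=", length(x$param_names), "): ",
      paste(utils::head(x$param_names, 8), collapse = ", "),
      if (length(x$param_names) > 8) ", ...", "\n", sep = "")
  if (length(x$output_param_names))
    cat("  output parameters (NQ=", length(x$output_param_names), ")\n", sep = "")
  invisible(x)
}

n_states <- function(model) length(model$state_names)
n_params <- function(model) length(model$param_names)

check_dims <- function(model, x, u, p) {
  if (length(x) != n_states(model))
    stop("state vector has length ", length(x), ", expected ", n_states(model))
  if (length(u) != length(model$control_names))
    stop("control vector has length ", length(u), ", expected ",
         length(model$control_names))
  if (length(p) != n_params(model))
    stop("parameter vector has length ", length(p), ", expected ", n_params(model))
}

eval_env <- function(model, x, u, p, t, q = NULL) {
  vals <- c(as.list(as.numeric(x)), as.list(as.numeric(u)), as.list(as.numeric(p)))
  names(vals) <- c(model$state_names, model$control_names, model$param_names)
  if (length(model$output_param_names)) {
    qv <- as.list(as.numeric(q))
    names(qv) <- model$output_param_names
    vals <- c(vals, qv)
  }
  vals$t <- t
  list2env(vals, parent = baseenv())
}

#' Evaluate the model right-hand side f(x, u, p)
#'
#' @param model an [ode_model].
#' @param x,u,p numeric state, control and parameter vectors.
#' @param t time (enters only if the RHS references `t`).
#' @return numeric vector of state derivatives, named by state.
#' @export
eval_rhs <- function(model, x, u, p, t = 0) {
  check_dims(model, x, u, p)
  v <- eval(model$calls$rhs, eval_env(model, x, u, p, t))
  if (any(!is.finite(v)))
    stop("non-finite right-hand side in equation(s): ",
         paste(model$state_names[!is.finite(v)], collapse = ", "))
  stats::setNames(v, model$state_names)
}

#' State Jacobian of the right-hand side, df/dx
#'
#' Entry (i, j) is the symbolic partial derivative of \eqn{f_i} with respect
#' to state j.
#' @inheritParams eval_rhs
#' @return n x n numeric matrix with dimnames (equation, state).
#' @export
jac_states <- function(model, x, u, p, t = 0) {
  check_dims(model, x, u, p)
  n <- n_states(model)
  v <- eval(model$calls$jacx, eval_env(model, x, u, p, t))
  J <- matrix(v, n, n, byrow = TRUE,
              dimnames = list(model$state_names, model$state_names))
  if (any(!is.finite(J)))
    stop("non-finite df/dx in equation(s): ",
         paste(model$state_names[rowSums(!is.finite(J)) > 0], collapse = ", "))
  J
}

#' Parameter Jacobian of the right-hand side, df/dp
#'
#' Entry (i, j) is the symbolic partial derivative of \eqn{f_i} with respect
#' to parameter j; columns follow the model's parameter order.
#' @inheritParams eval_rhs
#' @return n x NP numeric matrix with dimnames (equation, parameter).
#' @export
jac_params <- function(model, x, u, p, t = 0) {
  check_dims(model, x, u, p)
  v <- eval(model$calls$jacp, eval_env(model, x, u, p, t))
  J <- matrix(v, n_states(model), n_params(model), byrow = TRUE,
              dimnames = list(model$state_names, model$param_names))
  if (any(!is.finite(J)))
    stop("non-finite df/dp in equation(s): ",
         paste(model$state_names[rowSums(!is.finite(J)) > 0], collapse = ", "))
  J
}

#' Evaluate the output map h(x, u, q)
#'
#' Defaults to the identity on the states when the model declares no outputs.
#' @inheritParams eval_rhs
#' @param q output-parameter vector (length NQ; may be empty).
#' @return numeric vector of outputs.
#' @export
eval_outputs <- function(model, x, u, q = numeric(), t = 0) {
  v <- eval(model$calls$h, eval_env(model, x, u, rep(0, n_params(model)), t, q))
  stats::setNames(v, model$output_names)
}

#' Output Jacobian dh/dx
#' @inheritParams eval_outputs
#' @return r x n numeric matrix.
#' @export
jac_outputs_states <- function(model, x, u, q = numeric(), t = 0) {
  v <- eval(model$calls$jach_x, eval_env(model, x, u, rep(0, n_params(model)), t, q))
  matrix(v, length(model$output_names), n_states(model), byrow = TRUE,
         dimnames = list(model$output_names, model$state_names))
}

#' Read a model (and optional nominal point) from a YAML configuration
#'
#' The configuration has keys `states`, `controls`, `params`,
#' `output_params`, `rhs` (map state -> expression string), optional
#' `outputs`, and optional `nominal` with sub-keys `p`, `x0`, `u`.
#' Unknown top-level keys are rejected.
#'
#' @param path path to the YAML file.
#' @return list with elements `model` ([ode_model]) and `nominal` (list with
#'   `p`, `x0`, `controls`, or `NULL` when the file has no nominal block).
#' @export
read_model_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("name", "states", "controls", "params", "output_params",
               "rhs", "outputs", "nominal")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) stop("unknown key(s) in model config: ", paste(bad, collapse = ", "))
  model <- ode_model(
    states = cfg$states, params = cfg$params,
    controls = cfg$controls %||% character(),
    rhs = unlist(cfg$rhs),
    outputs = if (!is.null(cfg$outputs)) unlist(cfg$outputs),
    output_params = cfg$output_params %||% character(),
    name = cfg$name %||% basename(path)
  )
  nominal <- NULL
  if (!is.null(cfg$nominal)) {
    nominal <- nominal_point(model,
                             p = unlist(cfg$nominal$p),
                             x0 = unlist(cfg$nominal$x0),
                             controls = unlist(cfg$nominal$u))
  }
  list(model = model, nominal = nominal)
}

#' Nominal point of a model
#'
#' Bundles the true/reference parameter vector, a default initial state and
#' default constant control values, with dimension checks against the model.
#'
#' @param model an [ode_model].
#' @param p numeric parameter vector (length NP).
#' @param x0 nonnegative initial state (length n).
#' @param controls positive control values (length m).
#' @return object of class `nominal_point`.
#' @export
nominal_point <- function(model, p, x0, controls = numeric()) {
  if (length(p) != n_params(model)) stop("'p' must have length ", n_params(model))
  if (length(x0) != n_states(model)) stop("'x0' must have length ", n_states(model))
  if (length(controls) != length(model$control_names))
    stop("'controls' must have length ", length(model$control_names))
  if (any(x0 < 0)) stop("initial states must be nonnegative")
  structure(list(p = stats::setNames(as.numeric(p), model$param_names),
                 x0 = stats::setNames(as.numeric(x0), model$state_names),
                 controls = stats::setNames(as.numeric(controls), model$control_names)),
            class = "nominal_point")
}

#' @export
print.nominal_point <- function(x, ...) {
  cat("<nominal_point> NP=", length(x$p), ", n=", length(x$x0), "\n", sep = "")
  invisible(x)
}

#' The three-step metabolic pathway benchmark
#'
#' Returns the eight-state, thirty-six-parameter gene-expression /
#' enzyme-kinetics cascade with two constant control inputs `P` (product) and
#' `S` (substrate): three transcript equations with combined
#' repression/induction Hill terms, three enzyme Michaelis-Menten
#' production/degradation equations, and two metabolite equations with
#' reversible saturable kinetics. The nominal parameter point consists of the
#' literature values (0.1, 1.0 or 2.0 per parameter); the default initial
#' state is 0.667 for every concentration and the default controls are
#' P = 0.7, S = 1.4 (the analysis results do not depend on the initial
#' state, and any strictly positive controls with P, S away from 1 are
#' equivalent; see the package vignette).
#'
#' @return list with elements `model` ([ode_model]) and `nominal`
#'   ([nominal_point]).
#' @examples
#' bench <- three_step_pathway()
#' bench$model
#' eval_rhs(bench$model, x = bench$nominal$x0, u = bench$nominal$controls,
#'          p = bench$nominal$p)
#' @export
three_step_pathway <- function() {
  path <- system.file("extdata", "three_step_pathway.yaml", package = "paramcorr",
                      mustWork = TRUE)
  read_model_yaml(path)
}
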