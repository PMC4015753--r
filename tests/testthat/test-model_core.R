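test_that("model construction validates symbols, names and functions", {
  expect_error(ode_model(states = "x", params = "p", rhs = c(x = "-p*x + k")),
               "unknown symbol")
  expect_error(ode_model(states = "x", params = "p", rhs = c(x = "sin(p)*x")),
               "disallowed function")
  expect_error(ode_model(states = c("x", "x"), params = "p",
                         rhs = c(x = "-p*x", x = "-p*x")), "unique")
  expect_error(ode_model(states = "x", params = "x", rhs = c(x = "-x*x")),
               "unique")
  expect_error(ode_model(states = "t", params = "p", rhs = c(t = "-p*t")),
               "reserved")
  expect_error(ode_model(states = "x", params = "p", rhs = c(y = "-p*x")),
               "one expression per state")
})

test_that("rhs evaluation and dimension checks behave", {
  m <- toy_sum()
  expect_equal(unname(eval_rhs(m, x = 2, u = 3, p = c(0.5, 0.25))),
               -(0.5 + 3 * 0.25) * 2 + 3)
  expect_error(eval_rhs(m, x = c(1, 2), u = 1, p = c(1, 1)), "length")
  expect_error(eval_rhs(m, x = 1, u = 1, p = 1), "length")
  # division by zero state -> named evaluation error
  mm <- ode_model(states = "x", params = "p", rhs = c(x = "p/x"))
  expect_error(eval_rhs(mm, x = 0, u = numeric(), p = 1), "x")
})

test_that("benchmark model matches the hand-typed kinetics oracle", {
  b <- bench_fixture()
  m <- b$model
  expect_length(m$state_names, 8)
  expect_length(m$param_names, 36)
  expect_identical(m$control_names, c("P", "S"))
  expect_equal(unname(b$nominal$p[c(19, 20)]), c(0.1, 1.0))

  # repression/induction balance point: all Hill ratios are 1
  f <- eval_rhs(m, x = c(0, rep(0.5, 7)), u = c(P = 1, S = 1), p = rep(1, 36))
  expect_equal(unname(f[1]), 1 / 3)

  set.seed(11)
  for (i in 1:20) {
    x <- runif(8, 0.1, 2)
    u <- runif(2, 0.2, 2.5)
    p <- exp(runif(36, log(0.1), log(2)))
    expect_equal(unname(eval_rhs(m, x, u, p)), bench_rhs_oracle(x, u, p),
                 tolerance = 1e-12)
  }
})

test_that("symbolic jacobians match structure and finite differences", {
  b <- bench_fixture()
  m <- b$model
  p <- b$nominal$p
  u <- b$nominal$controls
  x <- c(2, rep(0.5, 7))

  Jx <- jac_states(m, x, u, p)
  expect_equal(unname(Jx["x1", "x1"]), -unname(p["p6"]))
  # saturable uptake slope at zero substrate
  Jx0 <- jac_states(m, c(0, rep(0.5, 7)), u, p)
  expect_equal(unname(Jx0["x4", "x1"]), unname(p["p19"] / p["p20"]))

  Jp <- jac_params(m, x, u, p)
  expect_equal(unname(Jp["x1", "p6"]), -2)           # linear decay coefficient
  expect_equal(unname(Jp["x1", paste0("p", 7:36)]), rep(0, 30))  # sparsity
  expect_equal(unname(Jp["x4", c("p1", "p22", "p35")]), rep(0, 3))

  set.seed(12)
  for (i in 1:100) {
    x <- runif(8, 0.1, 2)
    u <- runif(2, 0.3, 2)
    p <- exp(runif(36, log(0.2), log(2)))
    fd_x <- fd_jacobian(function(v) eval_rhs(m, v, u, p), x)
    expect_equal(unname(jac_states(m, x, u, p)), unname(fd_x),
                 tolerance = 1e-5)
    fd_p <- fd_jacobian(function(v) eval_rhs(m, x, u, v), p)
    expect_equal(unname(jac_params(m, x, u, p)), unname(fd_p),
                 tolerance = 1e-5)
  }
})

test_that("yaml config round-trips through the reader", {
  b <- bench_fixture()
  path <- system.file("extdata", "three_step_pathway.yaml", package = "paramcorr")
  again <- read_model_yaml(path)
  expect_identical(again$model$rhs_text, b$model$rhs_text)
  expect_equal(again$nominal$p, b$nominal$p)
  expect_error(nominal_point(b$model, p = 1:5, x0 = b$nominal$x0,
                             controls = b$nominal$controls), "length")
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c("states: [x]", "params: [p]", "rhs: {x: '-p*x'}",
               "bogus_key: 1"), tmp)
  expect_error(read_model_yaml(tmp), "unknown key")
})
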