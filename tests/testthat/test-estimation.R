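toy_fit_fixture <- function(noise = 0) {
  m <- toy_sum()
  designs <- list(toy_design(u = 0.5, id = "u_low"),
                  toy_design(u = 2, id = "u_high"))
  p_true <- c(p1 = 0.4, p2 = 0.7)
  datasets <- lapply(designs, function(d)
    generate_dataset(m, p_true, d, noise_level = noise, seed = 42))
  list(model = m, designs = designs, p_true = p_true, datasets = datasets)
}

test_that("fit problem validation catches bad inputs", {
  fx <- toy_fit_fixture()
  expect_error(fit_problem(fx$model, list()), "at least one")
  expect_error(fit_problem(fx$model, fx$datasets, free = "p9"), "unknown free")
  expect_error(fit_problem(fx$model, fx$datasets, free = "p1"), "p_fixed")
  expect_error(fit_problem(fx$model, fx$datasets, bounds = c(-1, 10)), "positive")
  expect_error(fit_problem(fx$model, fx$datasets, p_init = c(1e-9, 1)),
               "within the bounds")
})

test_that("starting at the truth returns the truth with ~zero residual", {
  fx <- toy_fit_fixture()
  prob <- fit_problem(fx$model, fx$datasets, p_init = fx$p_true)
  res <- fit_parameters(prob, maxiter = 50)
  expect_true(res$converged)
  data_scale <- sum(vapply(fx$datasets, function(d) sum(d$values^2), 1))
  expect_lt(res$total_residual, 1e-12 * data_scale)
  expect_equal(unname(res$p_hat), unname(fx$p_true), tolerance = 1e-6)
})

test_that("multistart fit recovers an input-separated pair from random starts", {
  fx <- toy_fit_fixture()
  prob <- fit_problem(fx$model, fx$datasets)
  res <- fit_parameters(prob, multistart = 5, seed = 9)
  expect_true(res$threshold_met)
  expect_equal(unname(res$p_hat), unname(fx$p_true), tolerance = 1e-5)

  # reported residual agrees with an independent recomputation
  expect_equal(res$total_residual, cost_function(prob, res$p_hat),
               tolerance = 1e-12)
  # per-point residuals reassemble into the total
  ssr <- sum(vapply(seq_along(res$per_point_residuals), function(j)
    sum(prob$datasets[[j]]$weights * res$per_point_residuals[[j]]^2), 1))
  expect_equal(ssr, res$total_residual, tolerance = 1e-12)
})

test_that("the joint fit is invariant to data-set order", {
  fx <- toy_fit_fixture(noise = 0.05)
  p0 <- c(p1 = 1, p2 = 1)
  r12 <- fit_parameters(fit_problem(fx$model, fx$datasets, p_init = p0))
  r21 <- fit_parameters(fit_problem(fx$model, rev(fx$datasets), p_init = p0))
  expect_equal(r12$p_hat, r21$p_hat, tolerance = 1e-6)
  expect_equal(r12$total_residual, r21$total_residual, tolerance = 1e-8)
})

test_that("fixed parameters stay fixed and weights enter the cost", {
  fx <- toy_fit_fixture()
  p_fix <- c(p1 = 0.9, p2 = NA)
  prob <- fit_problem(fx$model, fx$datasets, free = "p2", p_fixed = p_fix,
                      p_init = 1)
  res <- fit_parameters(prob, maxiter = 50)
  expect_equal(unname(res$p_hat["p1"]), 0.9)

  dsw <- fx$datasets
  dsw[[1]]$weights[] <- 4
  pw <- fit_problem(fx$model, dsw)
  p_probe <- c(p1 = 0.5, p2 = 0.5)
  c0 <- cost_function(fit_problem(fx$model, fx$datasets), p_probe)
  c1 <- cost_function(fit_problem(fx$model, fx$datasets[2]), p_probe)
  expect_equal(cost_function(pw, p_probe), 4 * (c0 - c1) + c1, tolerance = 1e-10)
})

test_that("observation-sensitivity rank reflects what the data can identify", {
  fx <- toy_fit_fixture()
  expect_equal(output_sensitivity_rank(fx$model, fx$p_true, fx$designs[1], "x"), 1)
  expect_equal(output_sensitivity_rank(fx$model, fx$p_true, fx$designs, "x"), 2)
  expect_error(output_sensitivity_rank(fx$model, fx$p_true, fx$designs,
                                       character()), "nonempty")
})
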