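test_that("sensitivities start at zero and match the closed form for decay", {
  m <- toy_decay()
  d <- experiment_design(controls = numeric(0), x0 = 2, t_end = 4,
                         n_samples = 40, design_id = "decay")
  st <- integrate_sensitivities(m, d, p = 0.8)
  expect_equal(st$sens[1, , ], 0)
  # x(t) = c*exp(-p t)  =>  dx/dp = -c*t*exp(-p t)
  expect_equal(unname(st$sens[, 1, 1]),
               -2 * st$times * exp(-0.8 * st$times), tolerance = 1e-8)
})

test_that("integrated sensitivities match finite differences on the benchmark", {
  b <- bench_fixture()
  m <- b$model; nom <- b$nominal
  d <- generate_designs(m, 1, nom$controls, nom$x0, t_end = 30, n_samples = 15)[[1]]
  probe <- c("p3", "p19", "p29", "p31", "p35", "p36")
  st <- integrate_sensitivities(m, d, nom$p, free = probe)
  for (j in seq_along(probe)) {
    h <- 1e-6 * nom$p[probe[j]]
    pp <- nom$p; pp[probe[j]] <- pp[probe[j]] + h
    pm <- nom$p; pm[probe[j]] <- pm[probe[j]] - h
    fd <- (simulate_trajectory(m, pp, d)[, m$state_names] -
           simulate_trajectory(m, pm, d)[, m$state_names]) / (2 * h)
    expect_equal(unname(st$sens[, , j]), unname(fd), tolerance = 1e-4)
  }
})

test_that("rhs stack has the expected shape and pairwise-parallel columns", {
  b <- bench_fixture()
  m <- b$model; nom <- b$nominal
  stack <- sample_rhs_stack(m, nom$p, bench_designs(1))
  expect_equal(dim(stack$matrix), c(8 * 40, 36))
  expect_identical(stack$col_labels, m$param_names)

  # the transcription-equation columns are mutually parallel on its rows
  f1 <- stack$matrix[stack$row_info$component == "x1", paste0("p", 1:5)]
  nn <- sweep(f1, 2, sqrt(colSums(f1^2)), "/")
  cosines <- abs(crossprod(nn))
  expect_true(all(abs(cosines - 1) < 1e-10))

  expect_error(sample_rhs_stack(m, nom$p, list()), "at least one design")
})

test_that("stacking designs never decreases rank and spans 26 to 36", {
  b <- bench_fixture()
  designs <- bench_designs(5)
  rk <- stacked_rank(b$model, b$nominal$p, designs)
  expect_equal(unname(rk$rank_by_k[1]), 26)
  expect_equal(unname(rk$rank_by_k[5]), 36)
  expect_true(all(diff(rk$rank_by_k) >= 0))
})

test_that("rhs-stack null vectors annihilate the state-sensitivity stack", {
  b <- bench_fixture()
  m <- b$model; nom <- b$nominal
  d1 <- bench_designs(1)
  rhs_stack <- sample_rhs_stack(m, nom$p, d1)
  sens_stack <- sample_sensitivity_stack(m, nom$p, d1)

  A <- rhs_stack$matrix
  An <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  sv <- svd(An)
  V <- sv$v[, sv$d <= 1e-7 * sv$d[1], drop = FALSE]
  expect_equal(ncol(V), 10)

  # dependences are inherited through the variation-of-constants integral,
  # but in the original (unscaled) column units
  Vraw <- sweep(V, 1, sqrt(colSums(A^2)), "/")
  S <- sens_stack$matrix
  resid <- S %*% Vraw
  expect_lt(max(abs(resid)) / max(abs(S)), 1e-7)
})
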