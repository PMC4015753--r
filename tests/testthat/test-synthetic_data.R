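test_that("design generation is seeded, distinct and anchored at the base", {
  b <- bench_fixture()
  m <- b$model; nom <- b$nominal
  expect_error(generate_designs(m, 0, nom$controls, nom$x0), "at least 1")

  one <- generate_designs(m, 1, nom$controls, nom$x0, seed = 3)
  expect_length(one, 1)
  expect_equal(one[[1]]$controls, nom$controls)

  d5a <- generate_designs(m, 5, nom$controls, nom$x0, seed = 3)
  d5b <- generate_designs(m, 5, nom$controls, nom$x0, seed = 3)
  expect_identical(d5a, d5b)                       # bit-identical under seed
  d5c <- generate_designs(m, 5, nom$controls, nom$x0, seed = 4)
  expect_false(identical(d5a, d5c))

  for (i in 1:4) for (j in (i + 1):5) {
    ui <- d5a[[i]]$controls; uj <- d5a[[j]]$controls
    expect_true(all(abs(ui - uj) / pmax(ui, uj) >= 0.1))
  }
})

test_that("noise-free data equal the trajectory and give zero cost at truth", {
  b <- bench_fixture()
  m <- b$model; nom <- b$nominal
  d <- bench_designs(1)[[1]]
  ds <- generate_dataset(m, nom$p, d, noise_level = 0)

  expect_length(ds$times, 120)
  expect_equal(ds$times, seq(1, 120))              # 1-minute sampling grid
  traj <- simulate_trajectory(m, nom$p, d)
  expect_identical(ds$values, traj[-1, m$state_names])
  expect_true(all(ds$weights == 1))

  # evaluating with the generation integrator reproduces the data exactly
  prob <- fit_problem(m, ds, rtol = 1e-10, atol = 1e-12, method = "lsoda")
  expect_lte(cost_function(prob, nom$p), 1e-16 * sum(ds$values^2))
})

test_that("multiplicative noise is seeded, unbiased and of the right size", {
  b <- bench_fixture()
  m <- b$model; nom <- b$nominal
  d <- bench_designs(1)[[1]]
  clean <- generate_dataset(m, nom$p, d, noise_level = 0)
  n1 <- generate_dataset(m, nom$p, d, noise_level = 0.1, seed = 7)
  n2 <- generate_dataset(m, nom$p, d, noise_level = 0.1, seed = 7)
  n3 <- generate_dataset(m, nom$p, d, noise_level = 0.1, seed = 8)
  expect_identical(n1$values, n2$values)
  expect_false(identical(n1$values, n3$values))

  z <- (n1$values - clean$values) / clean$values   # = 0.1 * standard normal
  n <- length(z)
  expect_lt(abs(mean(z)), 3 * 0.1 / sqrt(n))
  se_sd <- 0.1 / sqrt(2 * n)
  expect_lt(abs(sd(z) - 0.1), 3 * se_sd)
})

test_that("datasets round-trip through CSV + JSON sidecar", {
  b <- bench_fixture()
  m <- b$model; nom <- b$nominal
  d <- generate_designs(m, 1, nom$controls, nom$x0, t_end = 10, n_samples = 10)[[1]]
  ds <- generate_dataset(m, nom$p, d, noise_level = 0.1, seed = 5,
                         observed = c("x1", "x7"))
  path <- file.path(tempdir(), "ds1.csv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(back$values, ds$values, tolerance = 1e-12)
  expect_equal(back$times, ds$times)
  expect_identical(back$observed_names, c("x1", "x7"))
  expect_equal(back$design$controls, ds$design$controls, tolerance = 1e-12)
  expect_equal(back$noise_level, 0.1)
})
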