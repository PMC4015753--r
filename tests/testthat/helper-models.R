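## Shared fixtures: toy models and benchmark shortcuts, all built in code.

# scalar exponential decay; sensitivity has the closed form -c*t*exp(-p1*t)
toy_decay <- function() {
  ode_model(states = "x", params = "p1", rhs = c(x = "-p1*x"),
            name = "toy_decay")
}

# product non-identifiability: only p1*p2 enters the dynamics, for any input
toy_product <- function() {
  ode_model(states = "x", params = c("p1", "p2"), controls = "u",
            rhs = c(x = "-p1*p2*x + u"), name = "toy_product")
}

# input-dependent correlation: two inputs separate p1 from p2
toy_sum <- function() {
  ode_model(states = "x", params = c("p1", "p2"), controls = "u",
            rhs = c(x = "-(p1 + u*p2)*x + u"), name = "toy_sum")
}

toy_design <- function(u = 1, x0 = 1, t_end = 5, n_samples = 20,
                       id = "toy_design") {
  experiment_design(controls = c(u = u), x0 = x0, t0 = 0, t_end = t_end,
                    n_samples = n_samples, design_id = id)
}

# benchmark, built once per test run
bench_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- three_step_pathway()
    cache
  }
})

bench_designs <- local({
  cache <- NULL
  function(k = 5) {
    if (is.null(cache)) {
      b <- bench_fixture()
      cache <<- generate_designs(b$model, 5, b$nominal$controls, b$nominal$x0,
                                 seed = 101)
    }
    cache[seq_len(k)]
  }
})

# independent hand-typed transcription of the benchmark kinetics, used as the
# double-entry oracle against the parsed model
bench_rhs_oracle <- function(x, u, p) {
  P <- u[[1]]; S <- u[[2]]
  x1 <- x[[1]]; x2 <- x[[2]]; x3 <- x[[3]]; x4 <- x[[4]]
  x5 <- x[[5]]; x6 <- x[[6]]; x7 <- x[[7]]; x8 <- x[[8]]
  c(
    p[1] / (1 + (P / p[2])^p[3] + (p[4] / S)^p[5]) - p[6] * x1,
    p[7] / (1 + (P / p[8])^p[9] + (p[10] / x7)^p[11]) - p[12] * x2,
    p[13] / (1 + (P / p[14])^p[15] + (p[16] / x8)^p[17]) - p[18] * x3,
    p[19] * x1 / (p[20] + x1) - p[21] * x4,
    p[22] * x2 / (p[23] + x2) - p[24] * x5,
    p[25] * x3 / (p[26] + x3) - p[27] * x6,
    p[28] * x4 * (S - x7) / (p[29] * (1 + S / p[29] + x7 / p[30])) -
      p[31] * x5 * (x7 - x8) / (p[32] * (1 + x7 / p[32] + x8 / p[33])),
    p[31] * x5 * (x7 - x8) / (p[32] * (1 + x7 / p[32] + x8 / p[33])) -
      p[34] * x6 * (x8 - P) / (p[35] * (1 + x8 / p[35] + P / p[36]))
  )
}

# central finite differences of f along coordinates of v
fd_jacobian <- function(f, v, rel_step = 1e-6) {
  vapply(seq_along(v), function(j) {
    h <- rel_step * max(abs(v[j]), 1)
    vp <- v; vp[j] <- v[j] + h
    vm <- v; vm[j] <- v[j] - h
    (f(vp) - f(vm)) / (2 * h)
  }, f(v))
}

make_stack <- function(M, labels = colnames(M), source = "rhs_jacobian") {
  labels <- labels %||% paste0("c", seq_len(ncol(M)))
  structure(list(matrix = `colnames<-`(M, labels),
                 row_info = data.frame(design = "synthetic",
                                       time = seq_len(nrow(M)),
                                       component = "x"),
                 col_labels = labels, source = source),
            class = "derivative_stack")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
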