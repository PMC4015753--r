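test_that("angle matrix folds sign, zeroes the diagonal and flags zero columns", {
  set.seed(21)
  A <- matrix(rnorm(40), 10, 4)
  A[, 2] <- -3 * A[, 1]                 # anti-parallel pair
  A[, 4] <- 0                           # absent parameter
  ang <- angle_matrix(make_stack(A, c("a", "b", "c", "z")))
  expect_equal(diag(ang)[1:3], c(a = 0, b = 0, c = 0))
  # folded: anti-parallel reads 0 (up to acos resolution near cos = 1)
  expect_lt(ang["a", "b"], 1e-7)
  expect_true(all(is.na(ang[, "z"])) && all(is.na(ang["z", ])))
  off <- ang[1:3, 1:3]
  expect_true(all(off >= 0 & off <= pi / 2 + 1e-12))
  expect_equal(ang, t(ang))
})

test_that("benchmark angles: parallel pair at zero, jointly-correlated pair not", {
  b <- bench_fixture()
  stack <- sample_rhs_stack(b$model, b$nominal$p, bench_designs(1))
  ang <- angle_matrix(stack)
  expect_lt(ang["p35", "p36"], 1e-7)
  expect_gt(ang["p28", "p30"], 1e-2)    # correlated together but not pairwise
})

test_that("dendrogram finds the printed pairwise clusters, none with 5 designs", {
  b <- bench_fixture()
  m <- b$model; nom <- b$nominal
  ang1 <- angle_matrix(sample_sensitivity_stack(m, nom$p, bench_designs(1)))
  cl1 <- parallel_clusters(ang1)
  expect_length(cl1, 4)
  expect_setequal(vapply(cl1, paste, "", collapse = ","),
                  c("p1,p2,p3,p4,p5", "p8,p9", "p14,p15", "p35,p36"))

  ang5 <- angle_matrix(sample_rhs_stack(m, nom$p, bench_designs(5)))
  expect_length(parallel_clusters(ang5), 0)

  expect_length(parallel_clusters(angle_matrix(make_stack(diag(6)))), 0)
})

test_that("group detection recovers the printed group structure", {
  b <- bench_fixture()
  stack <- sample_rhs_stack(b$model, b$nominal$p, bench_designs(1))
  groups <- find_correlation_groups(stack)
  expect_length(groups, 5)

  members <- lapply(groups, `[[`, "members")
  expect_setequal(vapply(members, paste, "", collapse = ","),
                  c("p1,p2,p3,p4,p5", "p7,p8,p9,p10", "p13,p14,p15,p16",
                    "p28,p29,p30", "p35,p36"))
  byname <- setNames(groups, vapply(members, paste, "", collapse = ","))

  g1 <- byname[["p1,p2,p3,p4,p5"]]
  expect_equal(g1$case, "pairwise_all")
  expect_equal(g1$required_datasets, 5)

  g2 <- byname[["p7,p8,p9,p10"]]
  expect_equal(g2$case, "sets_linked")
  expect_equal(g2$d, 3L)
  sizes <- sort(lengths(g2$pairwise_sets))
  expect_equal(sizes, c(1L, 1L, 2L))
  expect_true(any(vapply(g2$pairwise_sets,
                         function(s) setequal(s, c("p8", "p9")), TRUE)))
  expect_equal(g2$required_datasets, 3)

  g3 <- byname[["p13,p14,p15,p16"]]
  expect_equal(g3$case, "sets_linked")
  expect_true(any(vapply(g3$pairwise_sets,
                         function(s) setequal(s, c("p14", "p15")), TRUE)))
  expect_equal(g3$required_datasets, 3)

  g4 <- byname[["p28,p29,p30"]]
  expect_equal(g4$case, "joint_single_relation")
  expect_equal(g4$required_datasets, 3)

  g5 <- byname[["p35,p36"]]
  expect_equal(g5$case, "pairwise_all")
  expect_equal(g5$required_datasets, 2)

  # alpha vectors annihilate the normalized group columns
  An <- stack$matrix
  An <- sweep(An, 2, sqrt(colSums(An^2)), "/")
  for (g in groups) {
    cols <- An[, g$members, drop = FALSE]
    expect_lt(max(abs(cols %*% g$alpha)), 1e-7)
  }

  # deficiency accounting: NP - rank = sum over groups of (k - rank_sub)
  expect_equal(36 - numerical_rank(stack$matrix),
               sum(vapply(groups, function(g)
                 length(g$members) - g$rank_single, 1)))
})

test_that("full-rank and constructed-deficiency stacks are handled", {
  expect_length(find_correlation_groups(make_stack(diag(5))), 0)

  set.seed(22)
  A <- matrix(rnorm(60), 20, 3)
  A[, 3] <- A[, 1] + A[, 2]
  g <- find_correlation_groups(make_stack(A, c("a", "b", "c")))
  expect_length(g, 1)
  expect_setequal(g[[1]]$members, c("a", "b", "c"))
  expect_equal(g[[1]]$case, "joint_single_relation")
  expect_equal(g[[1]]$required_datasets, 3)
  a <- g[[1]]$alpha[, 1]
  expect_equal(unname(a / a[1]),
               c(1, 1, -1) * unname(sqrt(colSums(A^2)) / sqrt(sum(A[, 1]^2))),
               tolerance = 1e-8)

  expect_error(find_correlation_groups(make_stack(matrix(1, 2, 5))),
               "more points")
})

test_that("classification separates structural from practical correlations", {
  d <- toy_design()
  p0 <- c(0.5, 0.8)

  mp <- toy_product()
  gp <- find_correlation_groups(sample_rhs_stack(mp, p0, d))
  expect_length(gp, 1)
  gp <- classify_identifiability(mp, gp, p0, d, seed = 5)
  expect_equal(gp[[1]]$classification, "structural")

  ms <- toy_sum()
  gs <- find_correlation_groups(sample_rhs_stack(ms, p0, d))
  expect_length(gs, 1)
  expect_setequal(gs[[1]]$members, c("p1", "p2"))
  gs <- classify_identifiability(ms, gs, p0, d, seed = 5)
  expect_equal(gs[[1]]$classification, "practical")

  expect_warning(
    classify_identifiability(ms, gs, p0, d, n_probe_inputs = 1, seed = 5),
    "below the largest")
})

test_that("minimum data-set rule follows the per-case arithmetic", {
  b <- bench_fixture()
  stack <- sample_rhs_stack(b$model, b$nominal$p, bench_designs(1))
  groups <- find_correlation_groups(stack)
  expect_equal(min_datasets(groups), 5L)

  g2 <- Filter(function(g) setequal(g$members, paste0("p", 7:10)), groups)
  expect_equal(min_datasets(g2), 3L)

  expect_equal(min_datasets(list()), 1L)

  gstruct <- groups[[1]]
  gstruct$classification <- "structural"
  expect_warning(md <- min_datasets(list(gstruct)), "structural")
  expect_equal(md, 1L)
})

test_that("duplicated designs add no rank", {
  b <- bench_fixture()
  d1 <- bench_designs(1)[[1]]
  d1b <- d1; d1b$design_id <- "design_1_copy"
  rk <- stacked_rank(b$model, b$nominal$p, list(d1, d1b))
  expect_equal(unname(rk$rank_by_k), c(26L, 26L))
})

test_that("group detection is invariant to x0, column scaling and grid density", {
  b <- bench_fixture()
  m <- b$model; nom <- b$nominal
  sig <- function(groups)
    sort(vapply(groups, function(g) paste(g$members, collapse = ","), ""))

  base <- bench_designs(1)[[1]]
  ref <- sig(find_correlation_groups(sample_rhs_stack(m, nom$p, base)))

  alt <- experiment_design(base$controls, x0 = rep(0.3, 8), t_end = 120,
                           n_samples = 120, design_id = "alt_x0")
  expect_identical(sig(find_correlation_groups(sample_rhs_stack(m, nom$p, alt))),
                   ref)

  stack <- sample_rhs_stack(m, nom$p, base)
  set.seed(30)
  scaled <- stack
  scaled$matrix <- sweep(stack$matrix, 2, exp(runif(36, -2, 2)), "*")
  expect_identical(sig(find_correlation_groups(scaled)), ref)

  dense <- sample_rhs_stack(m, nom$p, base, points_per_design = 120)
  expect_identical(sig(find_correlation_groups(dense)), ref)
})
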