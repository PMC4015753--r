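## End-to-end case study on the built-in benchmark and report assembly.

report_schema <- "paramcorr_report_v1"

group_to_list <- function(g) {
  list(members = g$members, case = g$case,
       sets = lapply(g$pairwise_sets, identity),
       d = if (is.na(g$d %||% NA)) NULL else g$d,
       alpha = apply(g$alpha, 2, function(a) as.numeric(a), simplify = FALSE),
       classification = g$classification,
       required_datasets = g$required_datasets)
}

#' Serialize a correlation report to the versioned JSON schema
#'
#' @param report a `correlation_report`.
#' @return list ready for [jsonlite::write_json()].
#' @export
report_to_json <- function(report) {
  list(schema = report_schema,
       groups = lapply(report$groups, group_to_list),
       unused_params = report$unused_params,
       min_datasets_overall = report$min_datasets_overall,
       rank_by_k = as.list(report$rank_by_k),
       parallel_clusters = report$parallel_clusters)
}

#' Run the benchmark case study end to end
#'
#' Builds the three-step pathway, generates `n_designs` designs and
#' noise-free data sets, runs the correlation analysis (groups,
#' classification, minimum data sets, dendrogram, rank profile), fits the
#' model simultaneously to growing numbers of data sets, and optionally
#' traces the residual surfaces of the two-parameter group. Deterministic
#' given `seed`. When `output_dir` is given, writes `summary.json` (schema
#' `paramcorr_report_v1`), the angle matrix, the data sets and the fitted
#' parameter table (one column per data-set count, mirroring how such
#' results are tabulated) as CSV.
#'
#' @param output_dir directory for JSON/CSV outputs (`NULL`: nothing
#'   written).
#' @param seed master seed for designs, noise and fits.
#' @param n_designs number of distinct-input designs to generate.
#' @param fit_sets integer vector: numbers of data sets to fit jointly
#'   (e.g. `c(1, 2, 3, 5)`); `NULL` skips fitting.
#' @param trace_surfaces also trace the p35/p36 surfaces for the first two
#'   data sets.
#' @param noise_level noise fraction for the generated data sets.
#' @param multistart forwarded to [fit_parameters()].
#' @return list with `analysis` (a `correlation_report`), `designs`,
#'   `datasets`, `fits` (list of `fit_result` by data-set count),
#'   `fitted_table` (data frame), and `surfaces`.
#' @export
run_case_study <- function(output_dir = NULL, seed = 1, n_designs = 5,
                           fit_sets = c(1, 2, 3, 5), trace_surfaces = TRUE,
                           noise_level = 0, multistart = 10) {
  bench <- three_step_pathway()
  model <- bench$model; nom <- bench$nominal

  designs <- generate_designs(model, n_designs, nom$controls, nom$x0,
                              seed = seed)
  datasets <- lapply(seq_along(designs), function(j)
    generate_dataset(model, nom$p, designs[[j]], noise_level = noise_level,
                     seed = seed + j))

  analysis <- analyze_correlations(model, nom$p, designs, seed = seed)

  fits <- list()
  if (!is.null(fit_sets)) {
    fit_sets <- fit_sets[fit_sets <= length(datasets)]
    for (k in fit_sets) {
      prob <- fit_problem(model, datasets[seq_len(k)])
      fits[[paste0("k", k)]] <- fit_parameters(prob, multistart = multistart,
                                               seed = seed)
    }
  }
  fitted_table <- data.frame(parameter = model$param_names, p_true = nom$p)
  for (nm in names(fits)) fitted_table[[nm]] <- unname(fits[[nm]]$p_hat)

  surfaces <- NULL
  if (trace_surfaces && length(datasets) >= 2) {
    g5 <- c("p35", "p36")
    surfaces <- lapply(datasets[1:2], function(ds)
      trace_surface(model, ds, g5, "p35", p_ref = nom$p, seed = seed))
    surfaces <- c(surfaces, list(crossing = crossing_point(surfaces)))
  }

  out <- list(analysis = analysis, designs = designs, datasets = datasets,
              fits = fits, fitted_table = fitted_table, surfaces = surfaces,
              seed = seed)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    summary <- report_to_json(analysis)
    summary$seed <- seed
    summary$residuals <- lapply(fits, `[[`, "total_residual")
    if (!is.null(surfaces))
      summary$surface_crossing <- list(point = as.list(surfaces$crossing$point),
                                       spread = surfaces$crossing$spread,
                                       degenerate = surfaces$crossing$degenerate)
    jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(as.data.frame(analysis$angle_matrix),
                     file.path(output_dir, "angle_matrix.csv"))
    utils::write.csv(fitted_table, file.path(output_dir, "fitted_parameters.csv"),
                     row.names = FALSE)
    for (j in seq_along(datasets))
      write_dataset(datasets[[j]], file.path(output_dir, paste0("dataset_", j, ".csv")))
  }
  invisible(out)
}
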