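## Core method: detection of correlated parameter groups from the linear
## dependences of the columns of a sampled derivative stack, classification
## of the correlations as structural or practical, and the minimum number of
## data sets with distinct control inputs needed for unique estimation.
##
## Case taxonomy for a group of k correlated parameters:
##   * pairwise_all        — every pair of columns is parallel (one functional
##                           relation per pair); k data sets are needed.
##   * sets_linked         — d disjoint sets (parallel within a set, sizes
##                           l_1..l_d, singletons allowed) tied together by a
##                           linking relation; max(l_1, ..., l_d, d) data sets.
##   * joint_single_relation — no pair is parallel but one linear relation
##                           ties all k columns; k data sets.

# defaults shared by the analysis functions
.rank_tol <- 1e-7    # singular value counts iff  s_i > tol * s_max
.angle_tol <- 1e-4   # radians; at or below this two columns count as parallel

#' Angle matrix between stack columns
#'
#' Folded angles `acos(|cos|)` between the unit-normalized columns, so
#' parallel and anti-parallel columns both read 0. All-zero columns (the
#' parameter does not enter the stack) give `NA` rows/columns.
#'
#' @param stack a `derivative_stack` (or plain matrix).
#' @return symmetric NP x NP matrix of angles in radians, zero diagonal,
#'   entries in `[0, pi/2]`.
#' @export
angle_matrix <- function(stack) {
  A <- if (inherits(stack, "derivative_stack")) stack$matrix else as.matrix(stack)
  if (nrow(A) == 0L) stop("empty stack")
  An <- normalize_columns(A)
  zero <- attr(An, "zero_cols")
  cosm <- abs(crossprod(An))
  cosm[cosm > 1] <- 1
  ang <- acos(cosm)
  diag(ang) <- 0
  if (length(zero)) { ang[zero, ] <- NA_real_; ang[, zero] <- NA_real_ }
  ang
}

#' Single-linkage dendrogram over the angle matrix
#'
#' Hierarchical clustering of the parameters with the folded column angle as
#' distance. Parameters with undefined angles (absent from the stack) are
#' placed at the maximal distance `pi/2` so the tree is complete.
#'
#' @param angles matrix from [angle_matrix()].
#' @return an object of class `hclust`.
#' @export
cluster_dendrogram <- function(angles) {
  a <- angles
  a[is.na(a)] <- pi / 2
  stats::hclust(stats::as.dist(a), method = "single")
}

#' Pairwise-parallel clusters below the angle threshold
#'
#' Cuts the single-linkage tree at `threshold` and returns the clusters with
#' at least two members: maximal sets of mutually (transitively) parallel
#' columns.
#'
#' @param angles matrix from [angle_matrix()].
#' @param threshold parallel angle threshold in radians.
#' @return named list of character vectors (cluster members).
#' @export
parallel_clusters <- function(angles, threshold = .angle_tol) {
  hc <- cluster_dendrogram(angles)
  ct <- stats::cutree(hc, h = threshold)
  cl <- split(colnames(angles) %||% as.character(seq_along(ct)), ct)
  cl <- cl[lengths(cl) >= 2]
  if (!length(cl)) return(list())
  stats::setNames(cl, paste0("cluster_", seq_along(cl)))
}

group_required_datasets <- function(case, k, set_sizes) {
  switch(case,
         pairwise_all = k,
         joint_single_relation = k,
         sets_linked = max(set_sizes, length(set_sizes)))
}

#' Detect correlated parameter groups from a derivative stack
#'
#' Computes the numerical null space of the column-normalized stack, rotates
#' the null basis into its sparsest support form (reduced row echelon with
#' partial pivoting), and takes connected components of the supports as
#' correlated groups. Inside each group, columns at mutual angle at most
#' `angle_tol` form pairwise-parallel sets, from which the case and the
#' per-group data-set requirement follow.
#'
#' @param stack a `derivative_stack` with at least NP rows.
#' @param rank_tol relative singular-value cutoff for rank/null space.
#' @param angle_tol pairwise-parallel angle threshold (radians).
#' @return list of `correlation_group` objects, each with fields `members`,
#'   `case`, `pairwise_sets`, `d`, `alpha` (k x nullity coefficient matrix
#'   whose columns annihilate the group's normalized columns),
#'   `required_datasets`, `rank_single` (rank of the group's sub-stack) and
#'   `classification` (`NA` until [classify_identifiability()] fills it).
#' @export
find_correlation_groups <- function(stack, rank_tol = .rank_tol,
                                    angle_tol = .angle_tol) {
  A <- stack$matrix
  labels <- stack$col_labels
  if (nrow(A) < ncol(A))
    stop("stack has ", nrow(A), " rows for ", ncol(A),
         " parameters; sample more points per design")
  An <- normalize_columns(A)
  zero <- attr(An, "zero_cols")
  keep <- setdiff(seq_len(ncol(An)), zero)
  An <- An[, keep, drop = FALSE]

  V <- null_space(An, tol = rank_tol, normalize = FALSE)
  if (ncol(V) == 0L) return(list())

  R <- rref(t(V), tol = 1e-8)
  supports <- apply(R, 1, function(row) {
    s <- which(abs(row) > 1e-6 * max(abs(row)))
    s
  }, simplify = FALSE)
  comps <- connected_components(supports, ncol(An))

  angles <- angle_matrix(structure(list(matrix = An, col_labels = labels[keep]),
                                   class = "derivative_stack"))
  lapply(comps, function(idx) {
    members <- labels[keep][idx]
    k <- length(idx)
    sub <- An[, idx, drop = FALSE]
    sv <- svd(sub, nu = 0)
    rank_sub <- sum(sv$d > rank_tol * sv$d[1])
    nullity <- k - rank_sub
    alpha <- sv$v[, seq.int(rank_sub + 1L, k), drop = FALSE]
    rownames(alpha) <- members

    ## transitive closure of "angle <= angle_tol" within the group
    pairs <- which(angles[idx, idx, drop = FALSE] <= angle_tol, arr.ind = TRUE)
    psets <- connected_components(
      lapply(seq_len(nrow(pairs)), function(i) sort(unname(pairs[i, ]))), k)
    in_set <- sort(unique(unlist(psets)))
    singletons <- setdiff(seq_len(k), in_set)
    sets <- c(psets, as.list(singletons))
    sets <- sets[order(vapply(sets, min, 1L))]
    set_sizes <- lengths(sets)

    case <- if (length(sets) == 1L && set_sizes[1] == k) {
      "pairwise_all"
    } else if (all(set_sizes == 1L) && nullity == 1L) {
      "joint_single_relation"
    } else {
      "sets_linked"
    }
    pairwise_sets <- lapply(sets, function(s) members[s])
    structure(list(
      members = members,
      case = case,
      pairwise_sets = if (case == "joint_single_relation") list() else pairwise_sets,
      d = if (case == "sets_linked") length(sets) else NA_integer_,
      alpha = alpha,
      rank_single = rank_sub,
      required_datasets = group_required_datasets(case, k, set_sizes),
      classification = NA_character_
    ), class = "correlation_group")
  })
}

#' @export
print.correlation_group <- function(x, ...) {
  cat("<correlation_group> {", paste(x$members, collapse = ", "), "}: ",
      x$case, sep = "")
  if (x$case == "sets_linked")
    cat(" [", paste(vapply(x$pairwise_sets,
                           function(s) paste0("{", paste(s, collapse = ","), "}"),
                           ""), collapse = " "), ", d = ", x$d, "]", sep = "")
  cat(", requires ", x$required_datasets, " data sets",
      if (!is.na(x$classification)) paste0(" (", x$classification, ")"), "\n",
      sep = "")
  invisible(x)
}

#' Classify groups as structurally or practically non-identifiable
#'
#' For each group, re-stacks df/dp over `n_probe_inputs` designs with
#' distinct control settings and checks the rank of the group's columns in
#' the joint stack. Full column rank means different inputs break the
#' dependence (the correlation coefficients involve the controls): practical
#' non-identifiability. A deficiency identical to the single-design one
#' means no input choice helps: structural. Anything in between is reported
#' as undetermined with the attained rank.
#'
#' @param model an [ode_model].
#' @param groups list from [find_correlation_groups()].
#' @param p parameter vector.
#' @param base_design the design the groups were detected on.
#' @param n_probe_inputs number of probe control settings (default 6).
#' @param seed seed for the probe-design draw.
#' @param spread log-uniform spread of the probe controls.
#' @param points_per_design points sampled along each probe trajectory.
#' @param rank_tol relative singular-value cutoff.
#' @return the groups with `classification` (and `attained_rank`) filled.
#' @export
classify_identifiability <- function(model, groups, p, base_design,
                                     n_probe_inputs = 6, seed = 1, spread = 3,
                                     points_per_design = 40,
                                     rank_tol = .rank_tol) {
  if (!length(groups)) return(groups)
  max_req <- max(vapply(groups, `[[`, 1, "required_datasets"))
  if (n_probe_inputs < max_req)
    warning("n_probe_inputs (", n_probe_inputs, ") is below the largest group ",
            "requirement (", max_req, "); classification may be undetermined")
  probes <- generate_designs(model, n_probe_inputs, base_design$controls,
                             base_design$x0, spread = spread, seed = seed,
                             t0 = base_design$t0, t_end = base_design$t_end,
                             n_samples = base_design$n_samples)
  stack <- sample_rhs_stack(model, p, probes, points_per_design = points_per_design)
  lapply(groups, function(g) {
    idx <- match(g$members, stack$col_labels)
    r <- numerical_rank(stack$matrix[, idx, drop = FALSE], tol = rank_tol)
    g$attained_rank <- r
    g$classification <- if (r == length(idx)) "practical"
                        else if (r == g$rank_single) "structural"
                        else "undetermined"
    g
  })
}

#' Minimum number of data sets for unique estimation
#'
#' The largest per-group requirement over the practically non-identifiable
#' groups: k for a fully pairwise or jointly correlated group of size k,
#' `max(l_1, ..., l_d, d)` for linked sets. Structurally non-identifiable
#' groups are excluded with a warning (no finite number of data sets relieves
#' them). Returns 1 when there are no groups.
#'
#' @param groups list of (classified) `correlation_group` objects.
#' @return integer count.
#' @export
min_datasets <- function(groups) {
  if (!length(groups)) return(1L)
  cls <- vapply(groups, `[[`, "", "classification")
  if (any(!is.na(cls) & cls == "structural"))
    warning("structurally non-identifiable group(s) excluded: no number of ",
            "data sets relieves them")
  keep <- is.na(cls) | cls != "structural"
  if (!any(keep)) return(1L)
  as.integer(max(vapply(groups[keep], `[[`, 1, "required_datasets")))
}

#' Rank profile of the multi-design derivative stack
#'
#' Numerical rank of the stacked df/dp for each prefix of the design list —
#' the experimental-design diagnostic: the rank must reach NP before unique
#' estimation is possible.
#'
#' @param model an [ode_model].
#' @param p parameter vector.
#' @param designs list of [experiment_design] objects.
#' @param points_per_design points sampled along each trajectory.
#' @param rank_tol relative singular-value cutoff.
#' @return list with `rank` (full stack) and `rank_by_k` (named integer
#'   vector over prefixes 1..K).
#' @export
stacked_rank <- function(model, p, designs, points_per_design = 40,
                         rank_tol = .rank_tol) {
  if (inherits(designs, "experiment_design")) designs <- list(designs)
  stack <- sample_rhs_stack(model, p, designs, points_per_design)
  ids <- vapply(designs, `[[`, "", "design_id")
  rank_by_k <- vapply(seq_along(ids), function(k) {
    keep <- stack$row_info$design %in% ids[seq_len(k)]
    numerical_rank(stack$matrix[keep, , drop = FALSE], tol = rank_tol)
  }, integer(1))
  names(rank_by_k) <- paste0("k", seq_along(ids))
  list(rank = rank_by_k[[length(rank_by_k)]], rank_by_k = rank_by_k)
}

#' Full correlation analysis of a model
#'
#' End-to-end analysis at a parameter point: detects correlated groups on the
#' base (first) design, classifies them against probe inputs, derives the
#' overall minimum number of data sets, computes the sensitivity-column angle
#' matrix and dendrogram, and the rank profile over the supplied designs.
#'
#' @param model an [ode_model].
#' @param p parameter vector (typically the nominal point).
#' @param designs list of [experiment_design] objects; the first is the base
#'   design used for group detection.
#' @param n_probe_inputs probe settings for classification.
#' @param seed seed for the probe draw.
#' @param points_per_design points sampled along each trajectory.
#' @param rank_tol,angle_tol numerical thresholds (see
#'   [find_correlation_groups()]).
#' @return object of class `correlation_report` with fields `groups`,
#'   `unused_params`, `min_datasets_overall`, `angle_matrix` (from the state
#'   sensitivities of the base design), `dendrogram`, `parallel_clusters` and
#'   `rank_by_k`.
#' @export
analyze_correlations <- function(model, p, designs, n_probe_inputs = 6,
                                 seed = 1, points_per_design = 40,
                                 rank_tol = .rank_tol, angle_tol = .angle_tol) {
  if (inherits(designs, "experiment_design")) designs <- list(designs)
  base <- designs[[1]]
  stack <- sample_rhs_stack(model, p, list(base), points_per_design)
  unused <- model$param_names[attr(normalize_columns(stack$matrix), "zero_cols")]
  groups <- find_correlation_groups(stack, rank_tol, angle_tol)
  groups <- classify_identifiability(model, groups, p, base,
                                     n_probe_inputs = n_probe_inputs,
                                     seed = seed,
                                     points_per_design = points_per_design,
                                     rank_tol = rank_tol)
  sens_stack <- sample_sensitivity_stack(model, p, list(base))
  ang <- angle_matrix(sens_stack)
  structure(list(
    groups = groups,
    unused_params = unused,
    min_datasets_overall = min_datasets(groups),
    angle_matrix = ang,
    dendrogram = cluster_dendrogram(ang),
    parallel_clusters = parallel_clusters(ang, angle_tol),
    rank_by_k = stacked_rank(model, p, designs, points_per_design, rank_tol)$rank_by_k,
    n_params = n_params(model)
  ), class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("Parameter correlation analysis\n")
  cat("  correlated groups: ", length(x$groups), "\n", sep = "")
  for (g in x$groups) { cat("   - "); print(g) }
  if (length(x$unused_params))
    cat("  unused parameters: ", paste(x$unused_params, collapse = ", "), "\n", sep = "")
  cat("  pairwise-parallel clusters (base design): ",
      length(x$parallel_clusters), "\n", sep = "")
  cat("  rank by stacked designs: ",
      paste(x$rank_by_k, collapse = " -> "), " (NP = ", x$n_params, ")\n", sep = "")
  cat("  minimum data sets for unique estimation: ",
      x$min_datasets_overall, "\n", sep = "")
  invisible(x)
}
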