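## Internal numerical helpers shared across modules.

#' Evaluate code with a temporary RNG state
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded operations never disturb the global random stream.
#' With `seed = NULL` the code runs on the current stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Scale matrix columns to unit Euclidean norm
#'
#' Zero columns (norm exactly 0, or below `zero_tol` relative to the largest
#' column norm) are left untouched and flagged in the `"zero_cols"` attribute.
#' @noRd
normalize_columns <- function(A, zero_tol = 1e-14) {
  nn <- sqrt(colSums(A^2))
  zero <- nn <= zero_tol * max(nn, 0)
  keep <- !zero & nn > 0
  A[, keep] <- sweep(A[, keep, drop = FALSE], 2, nn[keep], "/")
  attr(A, "zero_cols") <- which(zero | nn == 0)
  A
}

#' Numerical rank of a matrix
#'
#' Columns are scaled to unit norm first; a singular value counts towards the
#' rank iff it exceeds `tol` times the largest singular value. All-zero
#' columns are excluded before the decomposition.
#'
#' @param A numeric matrix.
#' @param tol relative singular-value cutoff (default `1e-7`).
#' @param normalize scale columns to unit norm first (default `TRUE`).
#' @return integer rank.
#' @export
numerical_rank <- function(A, tol = 1e-7, normalize = TRUE) {
  A <- as.matrix(A)
  if (normalize) {
    A <- normalize_columns(A)
    drop <- attr(A, "zero_cols")
    if (length(drop)) A <- A[, -drop, drop = FALSE]
  }
  if (ncol(A) == 0L) return(0L)
  d <- svd(A, nu = 0, nv = 0)$d
  sum(d > tol * d[1])
}

#' Orthonormal basis of the numerical null space
#'
#' Right singular vectors whose singular values fall at or below
#' `tol * s_max` (columns scaled to unit norm first when `normalize`).
#' Returns a `ncol(A) x nullity` matrix (0 columns if full rank).
#' @noRd
null_space <- function(A, tol = 1e-7, normalize = TRUE) {
  A <- as.matrix(A)
  if (normalize) {
    An <- normalize_columns(A)
    attr(An, "zero_cols") <- NULL
    A <- An
  }
  sv <- svd(A, nu = 0)
  keep <- sv$d <= tol * sv$d[1]
  ## svd() returns min(n, p) singular values; columns beyond that are null too
  V <- sv$v[, c(which(keep), setdiff(seq_len(ncol(A)), seq_along(sv$d))), drop = FALSE]
  V
}

#' Reduced row echelon form with partial pivoting
#'
#' Used to rotate a null-space basis into its sparsest support representation.
#' Entries below `tol` (relative to the row maximum) are zeroed.
#' @noRd
rref <- function(M, tol = 1e-8) {
  M <- as.matrix(M)
  r <- 1L
  for (j in seq_len(ncol(M))) {
    if (r > nrow(M)) break
    i <- which.max(abs(M[r:nrow(M), j])) + r - 1L
    if (abs(M[i, j]) < tol) next
    M[c(r, i), ] <- M[c(i, r), ]
    M[r, ] <- M[r, ] / M[r, j]
    for (q in seq_len(nrow(M))[-r]) M[q, ] <- M[q, ] - M[q, j] * M[r, ]
    r <- r + 1L
  }
  ## clean tiny residue left by elimination
  mx <- apply(abs(M), 1, max)
  M[abs(M) < tol * pmax(mx[row(M)], 1)] <- 0
  M
}

#' Connected components of an undirected graph given as edge sets
#'
#' `supports` is a list of integer vectors; vertices sharing a support belong
#' to one component. Returns a list of sorted integer vectors.
#' @noRd
connected_components <- function(supports, n) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (s in supports) {
    if (length(s) < 2) next
    r <- find(s[1])
    for (v in s[-1]) {
      rv <- find(v)
      if (rv != r) parent[rv] <- r
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  touched <- sort(unique(unlist(supports)))
  comp <- split(touched, roots[touched])
  unname(lapply(comp, sort))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Integrate with optional non-stiff first attempt
#'
#' `method = "adams"` tries the (faster) non-stiff solver first and falls
#' back to lsoda when it fails; any other method is used directly. Returns
#' `NULL` on failure (error, truncated output, or non-finite values).
#' @noRd
ode_with_fallback <- function(y, times, func, parms, rtol, atol, maxsteps,
                              method = "lsoda") {
  methods <- if (identical(method, "adams")) c("adams", "lsoda") else method
  for (meth in methods) {
    out <- try(suppressWarnings(
      deSolve::ode(y = y, times = times, func = func, parms = parms,
                   rtol = rtol, atol = atol, maxsteps = maxsteps,
                   method = meth)), silent = TRUE)
    ok <- !inherits(out, "try-error") && nrow(out) == length(times) &&
      all(is.finite(out))
    if (ok) return(out)
  }
  NULL
}
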