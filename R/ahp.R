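#' Saaty random-index table
#'
#' Mean consistency index of randomly filled reciprocal matrices, used to
#' normalise the consistency index into the consistency ratio. Values are the
#' canonical Saaty estimates for matrix orders 1 through 10.
#'
#' @format Named numeric vector; names are matrix orders "1".."10".
#' @export
saaty_random_index <- c(
  "1" = 0, "2" = 0, "3" = 0.58, "4" = 0.90, "5" = 1.12,
  "6" = 1.24, "7" = 1.32, "8" = 1.41, "9" = 1.45, "10" = 1.49
)

#' Validate a pairwise-comparison matrix
#'
#' Checks a square table of positive preference ratios (Saaty 1-9 scale and
#' reciprocals) for the structural invariants of an analytic-hierarchy-process
#' comparison matrix: unit diagonal and reciprocity `a[j,i] == 1/a[i,j]`.
#' Violations are reported with the offending cell indices; nothing is
#' repaired.
#'
#' @param raw Square numeric matrix (or object coercible to one) of pairwise
#'   preference ratios.
#' @param factor_ids Character vector of unique factor identifiers, one per
#'   row/column of `raw`.
#' @param tol Relative tolerance for the reciprocity check. The default is
#'   strict; pass a larger value (e.g. `1e-2`) for matrices whose reciprocal
#'   entries were hand-rounded, such as 1/3 recorded as 0.33.
#' @return A `comparison_matrix`: the numeric matrix with `factor_ids` as
#'   dimnames and class `"comparison_matrix"`.
#' @examples
#' m <- validate_matrix(matrix(c(1, 2, 0.5, 1), 2, 2, byrow = TRUE),
#'                      c("pain", "wait"))
#' @export
validate_matrix <- function(raw, factor_ids, tol = 1e-9) {
  raw <- as.matrix(raw)
  if (!is.numeric(raw)) {
    stop("comparison matrix must be numeric", call. = FALSE)
  }
  if (nrow(raw) != ncol(raw)) {
    stop(sprintf("comparison matrix must be square, got %d x %d",
                 nrow(raw), ncol(raw)), call. = FALSE)
  }
  n <- nrow(raw)
  if (n < 2) {
    stop("comparison matrix needs at least 2 factors", call. = FALSE)
  }
  factor_ids <- as.character(factor_ids)
  if (length(factor_ids) != n) {
    stop(sprintf("%d factor ids supplied for a %d x %d matrix",
                 length(factor_ids), n, n), call. = FALSE)
  }
  if (anyDuplicated(factor_ids)) {
    stop("factor ids must be unique", call. = FALSE)
  }
  if (anyNA(raw)) {
    bad <- which(is.na(raw), arr.ind = TRUE)[1, ]
    stop(sprintf("missing entry at cell (%d,%d)", bad[1], bad[2]),
         call. = FALSE)
  }
  if (any(raw <= 0)) {
    bad <- which(raw <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive entry %g at cell (%d,%d)",
                 raw[bad[1], bad[2]], bad[1], bad[2]), call. = FALSE)
  }
  off_diag <- abs(diag(raw) - 1) > tol
  if (any(off_diag)) {
    i <- which(off_diag)[1]
    stop(sprintf("diagonal entry at (%d,%d) is %g, must be 1", i, i,
                 raw[i, i]), call. = FALSE)
  }
  # reciprocity: a[j,i] * a[i,j] == 1 within relative tolerance
  rec_err <- abs(raw * t(raw) - 1)
  if (any(rec_err > tol)) {
    bad <- which(rec_err > tol, arr.ind = TRUE)
    # report the lower-triangle cell, the conventional "entered" reciprocal
    bad <- bad[bad[, 1] >= bad[, 2], , drop = FALSE]
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf(
      "reciprocity violated at cell (%d,%d): %g is not 1/%g",
      i, j, raw[i, j], raw[j, i]), call. = FALSE)
  }
  dimnames(raw) <- list(factor_ids, factor_ids)
  structure(raw, class = c("comparison_matrix", "matrix", "array"))
}

#' @export
print.comparison_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("Pairwise comparison matrix (%d factors)\n", nrow(x)))
  print(round(unclass(x), digits), ...)
  invisible(x)
}

factor_ids <- function(m) rownames(m)

#' Derive priority weights from a comparison matrix
#'
#' Computes the principal right eigenvector of a pairwise-comparison matrix by
#' power iteration with L1 normalisation at each step, the standard
#' analytic-hierarchy-process weighting. The principal eigenvalue is recovered
#' as `sum(A %*% w)` for the L1-normalised eigenvector `w` and feeds the
#' consistency diagnostics.
#'
#' @param m A `comparison_matrix` from [validate_matrix()].
#' @param tol Convergence tolerance: iteration stops when successive weight
#'   vectors differ by less than `tol` in the max norm.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return List with components `weights` (a `weight_vector`: named numeric
#'   summing to 1) and `consistency` (a `consistency_report`, see
#'   [consistency_ratio()]).
#' @examples
#' m <- consistent_matrix_from_weights(c(a = 0.5, b = 0.3, c = 0.2))
#' derive_weights(m)$weights
#' @export
derive_weights <- function(m, tol = 1e-12, max_iter = 10000L) {
  stopifnot(inherits(m, "comparison_matrix"))
  A <- unclass(m)
  n <- nrow(A)
  w <- rep(1 / n, n)
  for (iter in seq_len(max_iter)) {
    w_new <- as.vector(A %*% w)
    w_new <- w_new / sum(w_new)
    if (max(abs(w_new - w)) < tol) {
      w <- w_new
      lambda_max <- sum(A %*% w)
      weights <- structure(w, names = factor_ids(m), class = "weight_vector")
      return(list(
        weights = weights,
        consistency = new_consistency_report(lambda_max, n)
      ))
    }
    w <- w_new
  }
  stop(sprintf("power iteration failed to converge in %d iterations",
               max_iter), call. = FALSE)
}

#' @export
print.weight_vector <- function(x, digits = 4, ...) {
  cat("Factor weights (sum to 1):\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' @export
format.weight_vector <- function(x, ...) format(unclass(x), ...)

new_consistency_report <- function(lambda_max, n, threshold = 0.10) {
  ci <- if (n > 1) (lambda_max - n) / (n - 1) else 0
  # numerically, lambda_max can undershoot n by machine eps on a perfectly
  # consistent matrix; clamp the diagnostics at zero
  ci <- max(ci, 0)
  ri <- saaty_random_index[as.character(n)]
  if (is.na(ri)) ri <- saaty_random_index[["10"]]  # RI plateaus beyond 10
  ri <- unname(ri)
  cr <- if (n <= 2 || ri == 0) 0 else ci / ri
  structure(
    list(
      lambda_max = lambda_max,
      n = n,
      consistency_index = ci,
      random_index = ri,
      consistency_ratio = cr,
      acceptable = cr < threshold
    ),
    class = "consistency_report"
  )
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf(
    "AHP consistency: lambda_max = %.6f (n = %d), CI = %.6f, RI = %.2f, CR = %.4f (%s)\n",
    x$lambda_max, x$n, x$consistency_index, x$random_index,
    x$consistency_ratio, if (x$acceptable) "acceptable" else "NOT acceptable"))
  invisible(x)
}

#' Consistency ratio of a comparison matrix
#'
#' Quantifies how far a set of pairwise judgments deviates from perfect
#' transitivity. The consistency index is `(lambda_max - n) / (n - 1)`; the
#' consistency ratio divides it by the Saaty random index for the matrix
#' order. A ratio below 0.10 is conventionally acceptable; matrices of order
#' 2 or less are always perfectly consistent (ratio 0).
#'
#' @inheritParams derive_weights
#' @return A `consistency_report` list: `lambda_max`, `n`,
#'   `consistency_index`, `random_index`, `consistency_ratio`, `acceptable`.
#' @export
consistency_ratio <- function(m, tol = 1e-12, max_iter = 10000L) {
  derive_weights(m, tol = tol, max_iter = max_iter)$consistency
}

#' Aggregate expert judgments by element-wise geometric mean
#'
#' Combines several experts' comparison matrices over the same factors into a
#' single group matrix (aggregation of individual judgments). The
#' element-wise geometric mean is the only symmetric mean that preserves
#' reciprocity, so the result is a valid comparison matrix by construction.
#'
#' @param matrices List of `comparison_matrix` objects with identical
#'   `factor_ids` in identical order.
#' @return A single `comparison_matrix`.
#' @export
aggregate_experts <- function(matrices) {
  if (length(matrices) < 1) {
    stop("need at least one comparison matrix", call. = FALSE)
  }
  stopifnot(all(vapply(matrices, inherits, logical(1), "comparison_matrix")))
  ids <- factor_ids(matrices[[1]])
  for (k in seq_along(matrices)) {
    if (!identical(factor_ids(matrices[[k]]), ids)) {
      stop(sprintf("matrix %d has different factor ids or order", k),
           call. = FALSE)
    }
  }
  logs <- lapply(matrices, function(m) log(unclass(m)))
  agg <- exp(Reduce(`+`, logs) / length(logs))
  # exact unit diagonal despite exp(log()) round-off
  diag(agg) <- 1
  validate_matrix(agg, ids, tol = 1e-8)
}

#' Build a perfectly consistent matrix from weights
#'
#' Constructs the comparison matrix whose entries are the pairwise ratios
#' `w[i] / w[j]` of a positive weight vector. Deriving weights from the
#' result recovers `w` exactly (up to normalisation), which makes this the
#' canonical round-trip check for any AHP weighting routine.
#'
#' @param w Named positive numeric vector of weights (any positive scale;
#'   only ratios matter).
#' @return A `comparison_matrix` with `names(w)` as factor ids.
#' @export
consistent_matrix_from_weights <- function(w) {
  if (is.null(names(w))) names(w) <- paste0("f", seq_along(w))
  if (any(w <= 0)) {
    stop("all weights must be strictly positive", call. = FALSE)
  }
  m <- outer(w, w, `/`)
  diag(m) <- 1
  validate_matrix(m, names(w), tol = 1e-9)
}
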