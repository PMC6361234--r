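#' Validate (and label) a variables-by-samples data matrix
#'
#' The package works on plain numeric matrices with variables in rows and
#' samples in columns, the usual P x N orientation of omics expression
#' matrices. `as_data_matrix()` checks the invariants every entry point
#' relies on: at least one row and column, all entries finite, and unique
#' row (variable) and column (sample) identifiers. Missing dimnames are
#' filled in with `var<i>` / `sample<j>`.
#'
#' @param x Numeric matrix (or object coercible with `as.matrix`).
#' @param variable_ids,sample_ids Optional character vectors overriding the
#'   dimnames.
#' @return The validated numeric matrix with complete dimnames.
#' @export
as_data_matrix <- function(x, variable_ids = NULL, sample_ids = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("data matrix must be numeric")
  if (nrow(x) < 1L || ncol(x) < 1L) stop("data matrix must be at least 1 x 1")
  if (!all(is.finite(x))) stop("data matrix contains non-finite entries")
  if (!is.null(variable_ids)) rownames(x) <- variable_ids
  if (!is.null(sample_ids)) colnames(x) <- sample_ids
  if (is.null(rownames(x))) rownames(x) <- paste0("var", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("sample", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x)))
    stop("duplicate variable ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  x
}

#' Variable selection maps
#'
#' A selection map is the linear map S whose transpose restricts a P x N
#' matrix to selected variables: in subset mode S has distinct standard
#' basis vectors as columns (so \eqn{S^T S = I}) and \eqn{S^T X} keeps the
#' chosen rows; in weights mode S is diagonal with one nonnegative weight
#' per variable (zero means excluded) and \eqn{S^T X} rescales rows.
#'
#' @param indices Strictly increasing variable indices (subset mode).
#' @param p Total number of variables.
#' @param weights Nonnegative weight per variable (weights mode).
#' @return An object of class `selection_map`.
#' @export
selection_subset <- function(indices, p) {
  indices <- as.integer(indices)
  if (length(indices) < 1L) stop("empty selection")
  if (anyDuplicated(indices)) stop("duplicate indices in selection")
  if (is.unsorted(indices, strictly = TRUE)) stop("indices must be strictly increasing")
  if (indices[1] < 1L || indices[length(indices)] > p)
    stop("selection indices out of range")
  structure(list(mode = "subset", indices = indices, weights = NULL, p = as.integer(p)),
            class = "selection_map")
}

#' @rdname selection_subset
#' @export
selection_weights <- function(weights) {
  if (any(weights < 0) || !all(is.finite(weights))) stop("weights must be finite and nonnegative")
  if (!any(weights > 0)) stop("at least one weight must be strictly positive")
  structure(list(mode = "weights", indices = NULL, weights = as.numeric(weights),
                 p = length(weights)),
            class = "selection_map")
}

#' @rdname selection_subset
#' @param x A `selection_map`.
#' @export
selection_all <- function(p) selection_subset(seq_len(p), p)

# S^T X: restrict (or reweight) the rows of X.
apply_selection <- function(sel, X) {
  stopifnot(inherits(sel, "selection_map"))
  if (nrow(X) != sel$p) stop("selection map has ", sel$p, " variables, matrix has ", nrow(X))
  if (sel$mode == "subset") X[sel$indices, , drop = FALSE] else sel$weights * X
}

# Number of variables effectively retained.
selection_size <- function(sel) {
  if (sel$mode == "subset") length(sel$indices) else sum(sel$weights > 0)
}

# Original row indices carried by S^T X (for subset mode the selected rows,
# for weights mode all rows); keys the permutation null streams.
selection_row_ids <- function(sel) {
  if (sel$mode == "subset") sel$indices else seq_len(sel$p)
}

#' @method print selection_map
#' @export
print.selection_map <- function(x, ...) {
  if (x$mode == "subset") {
    cat("selection_map (subset): ", length(x$indices), " of ", x$p, " variables\n", sep = "")
  } else {
    cat("selection_map (weights): ", sum(x$weights > 0), " of ", x$p,
        " variables with positive weight\n", sep = "")
  }
  invisible(x)
}

# Orthonormal basis of a subspace of sample space; columns span Pi.
check_subspace_basis <- function(basis, n) {
  basis <- as.matrix(basis)
  if (nrow(basis) != n) stop("basis must have one row per sample")
  d <- ncol(basis)
  if (d < 1L) stop("subspace dimension must be >= 1")
  if (d > n) stop("subspace dimension exceeds the number of samples")
  dev <- max(abs(crossprod(basis) - diag(d)))
  if (dev > 1e-10) stop("basis columns are not orthonormal (max deviation ", format(dev), ")")
  basis
}
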