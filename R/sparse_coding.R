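# R surface over the compiled orthogonal matching pursuit.

#' Orthogonal matching pursuit for a single signal
#'
#' Greedily selects the atom with the largest absolute (conjugated) inner
#' product with the current residual, refits all selected coefficients by
#' least squares on the support, and repeats until `T0` atoms are used or the
#' residual 2-norm falls to `tol`. Ties on correlation magnitude break to the
#' lowest atom index, so the result is deterministic.
#'
#' @param D m x n dictionary with unit-norm atoms (real or complex).
#' @param y length-m signal vector.
#' @param T0 maximum number of nonzeros (>= 1).
#' @param tol residual 2-norm stopping tolerance (default 0: pure
#'   sparsity-capped pursuit).
#' @return A length-n code vector with at most `T0` nonzeros (real if both
#'   inputs are real).
#' @export
omp <- function(D, y, T0, tol = 0) {
  if (!is.matrix(D)) stop("`D` must be a matrix")
  y <- as.vector(y)
  if (length(y) != nrow(D)) stop("signal length does not match dictionary rows")
  inputs_real <- !is.complex(D) && !is.complex(y)
  X <- .omp_batch_cx(as_complex(D), as_complex(matrix(y, ncol = 1)),
                     as.integer(T0), as.numeric(tol))
  maybe_real(X[, 1], inputs_real)
}

#' Sparse-code every patch column against a dictionary
#'
#' Runs [omp()] independently on each column of the patch matrix, preserving
#' column order.
#'
#' @param D m x n dictionary with unit-norm atoms.
#' @param patches a `patch_matrix` from [extract_patches()] or a plain m x N
#'   matrix of signals.
#' @inheritParams omp
#' @return An n x N code matrix; every column has at most `T0` nonzeros.
#' @export
sparse_code_all <- function(D, patches, T0, tol = 0) {
  Y <- if (inherits(patches, "patch_matrix")) patches$data else patches
  if (!is.matrix(Y)) stop("`patches` must be a patch_matrix or a matrix")
  if (nrow(Y) != nrow(D)) stop("patch dimension does not match dictionary rows")
  inputs_real <- !is.complex(D) && !is.complex(Y)
  X <- .omp_batch_cx(as_complex(D), as_complex(Y),
                     as.integer(T0), as.numeric(tol))
  maybe_real(X, inputs_real)
}
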