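# Dictionary initialisation and the approximate K-SVD atom sweep.

normalize_cols <- function(M) {
  nrm <- sqrt(colSums(abs(M)^2))
  if (any(nrm < 1e-12)) stop("cannot normalise a zero-norm column")
  sweep(M, 2, nrm, "/")
}

#' Initialise a dictionary from training patches
#'
#' The first `min(n_init, m)` atoms are the left singular vectors of the
#' training matrix in decreasing singular-value order; if `n_init` exceeds
#' the patch dimension the remaining atoms are randomly selected training
#' columns normalised to unit norm (columns with negligible energy — e.g.
#' empty background patches — are skipped, and random Gaussian atoms fill in
#' if too few usable columns exist).
#'
#' @param patches a `patch_matrix` or plain m x N matrix.
#' @param n_init number of atoms.
#' @param seed integer seed for the randomly drawn atoms.
#' @return An m x `n_init` matrix with unit-norm columns.
#' @export
init_dictionary <- function(patches, n_init, seed = 1L) {
  Y <- if (inherits(patches, "patch_matrix")) patches$data else patches
  if (!is.matrix(Y) || ncol(Y) == 0) stop("`patches` must be a non-empty matrix")
  if (all(abs(Y) < 1e-14)) stop("training matrix is all zero")
  m <- nrow(Y)
  n_init <- as.integer(n_init)
  if (n_init < 1L) stop("`n_init` must be >= 1")
  n_svd <- min(n_init, m)
  sv <- svd(Y, nu = n_svd, nv = 0)
  rank <- sum(sv$d > max(dim(Y)) * .Machine$double.eps * sv$d[1])
  keep <- min(n_svd, rank)
  D <- sv$u[, seq_len(keep), drop = FALSE]
  extra <- n_init - keep
  if (extra > 0) {
    more <- with_seed(seed, {
      nrm <- sqrt(colSums(abs(Y)^2))
      usable <- which(nrm > 1e-10 * max(nrm))
      pick <- sample(usable, min(extra, length(usable)))
      cols <- Y[, pick, drop = FALSE]
      if (length(pick) < extra) {
        g <- matrix(rnorm(m * (extra - length(pick))), m)
        if (is.complex(Y)) g <- g + 1i * matrix(rnorm(length(g)), m)
        cols <- cbind(cols, g)
      }
      cols
    })
    D <- cbind(D, normalize_cols(more))
  }
  D
}

#' One approximate K-SVD sweep over all atoms
#'
#' For each atom in ascending index order, with `I_j` the signals currently
#' using it: form the restricted residual with atom `j` removed, update the
#' atom to the normalised residual-weighted combination
#' `normalize(E_j conj(x_j)')`, then refit its coefficient row as `E_j^H d_j`
#' (one alternation of the approximate rank-1 update). An atom used by no
#' signal is replaced by the worst-represented training column (ties break to
#' the lowest column index), normalised.
#'
#' @param D m x n dictionary.
#' @param patches a `patch_matrix` or m x N signal matrix.
#' @param codes n x N code matrix consistent with `D` and the signals.
#' @return A list with updated `dictionary` and `codes`.
#' @export
aksvd_atom_sweep <- function(D, patches, codes) {
  Y <- if (inherits(patches, "patch_matrix")) patches$data else patches
  if (nrow(Y) != nrow(D) || ncol(D) != nrow(codes) || ncol(Y) != ncol(codes)) {
    stop("dimension mismatch between dictionary, patches and codes")
  }
  inputs_real <- !is.complex(D) && !is.complex(Y) && !is.complex(codes)
  D <- as_complex(D); Y <- as_complex(Y); X <- as_complex(codes)
  n <- ncol(D)
  # full residual, kept in sync as atoms/coefficients change
  E <- Y - D %*% X
  for (j in seq_len(n)) {
    I <- which(X[j, ] != 0)
    if (length(I) == 0L) {
      err <- colSums(abs(E)^2)
      worst <- which.max(err)  # ties -> lowest index
      cand <- Y[, worst]
      nrm <- sqrt(sum(abs(cand)^2))
      if (nrm > 1e-12) D[, j] <- cand / nrm
      next
    }
    xI <- X[j, I]
    EI <- E[, I, drop = FALSE] + outer(D[, j], xI)
    d_new <- EI %*% Conj(xI)
    nrm <- sqrt(sum(abs(d_new)^2))
    if (nrm < 1e-12) next
    d_new <- d_new / nrm
    x_new <- as.vector(Conj(t(EI)) %*% d_new)  # E^H d, refit coefficients
    D[, j] <- d_new
    X[j, I] <- Conj(x_new)
    E[, I] <- EI - outer(D[, j], X[j, I])
  }
  list(dictionary = maybe_real(D, inputs_real),
       codes = maybe_real(X, inputs_real))
}

#' Replace redundant or barely used atoms
#'
#' The standard dictionary-clearing step run between learning sweeps: an atom
#' whose coherence with any other atom exceeds `mu_thresh`, or which is used
#' by fewer than `use_thresh` signals, is replaced by the currently
#' worst-represented training column (normalised; each replacement consumes
#' its column so two atoms never take the same one). Clearing breaks the
#' local optima in which several atoms encode near-copies of one direction
#' while other directions stay unexplained, and is what lets the learned
#' atoms — and hence the size-selection criteria — separate signal structure
#' from redundancy.
#'
#' @param D m x n dictionary.
#' @param X n x N code matrix for the current coding of `Y`.
#' @param Y m x N training signals.
#' @param mu_thresh coherence threshold above which an atom counts as a
#'   duplicate (default 0.99).
#' @param use_thresh minimum number of signals that must use an atom
#'   (default 4).
#' @return The dictionary with cleared atoms replaced; the integer attribute
#'   `"replaced"` lists the replaced atom indices (codes for those rows are
#'   stale and must be recomputed).
#' @export
clear_duplicate_atoms <- function(D, X, Y, mu_thresh = 0.99, use_thresh = 4L) {
  if (inherits(Y, "patch_matrix")) Y <- Y$data
  E <- Y - D %*% X
  err <- colSums(abs(E)^2)
  G <- abs(Conj(t(D)) %*% D)
  diag(G) <- 0
  usage <- rowSums(X != 0)
  n <- ncol(D)
  replaced <- integer(0)
  for (j in seq_len(n)) {
    if (max(G[j, ]) > mu_thresh || usage[j] < use_thresh) {
      w <- which.max(err)
      cand <- Y[, w]
      err[w] <- 0  # consume this column
      nrm <- sqrt(sum(abs(cand)^2))
      if (nrm > 1e-12) {
        D[, j] <- cand / nrm
        replaced <- c(replaced, j)
        G <- abs(Conj(t(D)) %*% D)
        diag(G) <- 0
      }
    }
  }
  attr(D, "replaced") <- replaced
  D
}

# After clearing, only columns whose codes touched a replaced atom need
# re-coding; everyone else's representation is still exact.
recode_after_clearing <- function(D, X, Y, T0, tol = 0) {
  replaced <- attr(D, "replaced")
  if (length(replaced) == 0L) return(X)
  stale <- which(colSums(abs(X[replaced, , drop = FALSE])) > 0)
  if (length(stale) > 0L) {
    X[, stale] <- 0
    X[, stale] <- sparse_code_all(D, Y[, stale, drop = FALSE], T0, tol)
  }
  X[replaced, setdiff(seq_len(ncol(X)), stale)] <- 0
  X
}

#' One dictionary-learning iteration: sparse coding + AK-SVD sweep
#'
#' @inheritParams aksvd_atom_sweep
#' @inheritParams omp
#' @return A list with `dictionary`, `codes`, and `rmse` (representation
#'   root-mean-square error after the sweep).
#' @export
dl_iterate <- function(patches, D, T0, tol = 0) {
  Y <- if (inherits(patches, "patch_matrix")) patches$data else patches
  X <- sparse_code_all(D, Y, T0, tol)
  upd <- aksvd_atom_sweep(D, Y, X)
  upd$rmse <- representation_rmse(Y, upd$dictionary, upd$codes)
  upd
}
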