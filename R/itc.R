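# Information-theoretic criteria for dictionary-size selection: the
# goodness-of-fit term is the representation RMSE, the complexity count is
# P = sN + (m-1)n, and two penalised criteria (extended BIC and extended
# renormalized maximum likelihood) score candidate sub-dictionary sizes.

#' Representation root-mean-square error
#'
#' `RMSE = ||Y - D X||_F / sqrt(Q)` with `Q = m N`, the per-entry RMS of the
#' residual of the sparse approximation.
#'
#' @param Y m x N signal (patch) matrix, or a `patch_matrix`.
#' @param D m x n dictionary.
#' @param X n x N code matrix.
#' @return A nonnegative scalar.
#' @export
representation_rmse <- function(Y, D, X) {
  if (inherits(Y, "patch_matrix")) Y <- Y$data
  if (length(Y) == 0) stop("`Y` must be non-empty")
  if (nrow(Y) != nrow(D) || ncol(D) != nrow(X) || ncol(Y) != ncol(X)) {
    stop("dimension mismatch")
  }
  frob(Y - D %*% X) / sqrt(length(Y))
}

#' Model complexity of a sparse dictionary representation
#'
#' `P = s N + (m - 1) n`: the number of nonzeros in the code matrix plus the
#' number of independent dictionary entries (each unit-norm atom of dimension
#' `m` has `m - 1` free parameters).
#'
#' @param s per-signal sparsity used by the criterion.
#' @param N number of signals.
#' @param m signal dimension.
#' @param n number of atoms.
#' @return An integer (numeric for large values).
#' @export
model_complexity <- function(s, N, m, n) {
  if (any(c(s, N, m, n) < 0)) stop("all arguments must be nonnegative")
  s * N + (m - 1) * n
}

log_choose <- function(n, s) lgamma(n + 1) - lgamma(s + 1) - lgamma(n - s + 1)

#' Extended Bayesian information criterion for dictionary size
#'
#' `EBIC = 2 log(RMSE) + (log Q / Q) P + (2N / Q) log C(n, s)` with natural
#' logarithms; the binomial term accounts for the possible positions of the
#' nonzeros in the code matrix and is computed through log-gamma for
#' stability. A perfect fit (`rmse == 0`) returns `-Inf` with a warning,
#' since the fit term then dominates any penalty.
#'
#' @param rmse representation RMSE (> 0 for a finite value).
#' @param Q total number of signal entries, `m * N`.
#' @param P_complexity complexity count from [model_complexity()].
#' @param N number of signals.
#' @param n number of atoms in the candidate.
#' @param s sparsity (`n >= s`).
#' @return The criterion value (smaller is better).
#' @export
ebic <- function(rmse, Q, P_complexity, N, n, s) {
  if (n < s) stop("`n` must be at least `s`")
  if (Q <= 0) stop("`Q` must be positive")
  if (rmse < 0) stop("`rmse` must be nonnegative")
  if (rmse == 0) {
    warning("rmse is 0: perfect fit, criterion is -Inf")
    return(-Inf)
  }
  2 * log(rmse) + (log(Q) / Q) * P_complexity + (2 * N / Q) * log_choose(n, s)
}

#' Extended renormalized maximum likelihood criterion for dictionary size
#'
#' `ERML = (Q - P) log(RMSE^2 / (Q - P)) + P log(||D X||_F^2 / (Q P)) +
#' log(P (Q - P)) + 2 N log C(n, s)`, natural logarithms. A candidate with
#' `Q <= P` is over-parameterised and infeasible: the criterion returns
#' `+Inf` so it can never be selected.
#'
#' @inheritParams ebic
#' @param dx_frob_sq squared Frobenius norm of the candidate approximation
#'   `D X` (> 0).
#' @return The criterion value (smaller is better); `+Inf` if infeasible.
#' @export
erml <- function(rmse, Q, P_complexity, N, n, s, dx_frob_sq) {
  if (n < s) stop("`n` must be at least `s`")
  if (Q <= P_complexity) return(Inf)
  if (rmse <= 0) {
    warning("rmse is 0: perfect fit, criterion is -Inf")
    return(-Inf)
  }
  if (dx_frob_sq <= 0) stop("`dx_frob_sq` must be positive")
  P <- P_complexity
  (Q - P) * log(rmse^2 / (Q - P)) + P * log(dx_frob_sq / (Q * P)) +
    log(P * (Q - P)) + 2 * N * log_choose(n, s)
}

#' Per-atom representation power
#'
#' The power of atom `j` is the 2-norm of row `j` of the code matrix — how
#' much the atom contributes across all signals.
#'
#' @param X n x N code matrix.
#' @return A length-n nonnegative vector.
#' @export
atom_powers <- function(X) {
  if (!is.matrix(X)) stop("`X` must be a matrix")
  sqrt(rowSums(abs(X)^2))
}

#' Sort dictionary atoms by decreasing representation power
#'
#' Reorders atoms and the corresponding code rows so powers are
#' non-increasing; the product `D X` is unchanged. Equal powers keep their
#' original relative order (stable sort), so the result is deterministic.
#'
#' @param D m x n dictionary.
#' @param X n x N code matrix.
#' @return A list with `dictionary`, `codes` and the `permutation` applied
#'   (new position k holds old atom `permutation[k]`).
#' @export
sort_dictionary_by_power <- function(D, X) {
  if (ncol(D) != nrow(X)) stop("dimension mismatch")
  p <- atom_powers(X)
  perm <- order(p, decreasing = TRUE)  # stable: ties keep original order
  list(dictionary = D[, perm, drop = FALSE],
       codes = X[perm, , drop = FALSE],
       permutation = perm)
}

#' Score candidate sub-dictionary sizes and pick the best
#'
#' Given a power-sorted dictionary, evaluates at most `n_cand` candidate
#' sizes evenly spaced over `[max(n_min, m), n]` (both endpoints always
#' included). Candidate `h` keeps the first `h` atoms; by default
#' (`recode = TRUE`) the signals are re-coded against that sub-dictionary
#' with OMP at sparsity cap `s` -- the model whose complexity the criterion
#' counts -- so the error curve flattens once the kept atoms span the signal
#' structure and the criterion can see the size knee. With `recode = FALSE`
#' the first `h` rows of the existing codes are reused (cheaper, but the
#' error then grows with every dropped atom even when the dropped atoms are
#' redundant). For large signal sets the re-coded error is estimated on a
#' seeded column subsample of `eval_cols` signals. The selected size `n_itc`
#' attains the criterion minimum, ties going to the smallest size.
#'
#' @param D m x n dictionary sorted by power.
#' @param X n x N code matrix sorted consistently.
#' @param Y m x N signal matrix (or `patch_matrix`).
#' @param s criterion sparsity (also the re-coding sparsity cap).
#' @param n_min smallest admissible dictionary size.
#' @param n_cand maximum number of candidate sizes.
#' @param kind `"EBIC"` (default) or `"ERML"`.
#' @param recode re-code per candidate (default) or truncate existing codes.
#' @param eval_cols number of signal columns used to estimate the re-coded
#'   error (default: all, capped at 2048).
#' @param seed seed for the evaluation subsample.
#' @return A list of class `itc_evaluation`: `candidate_sizes`,
#'   `criterion_values`, `criterion_kind`, `n_itc`, `Q`, `s`.
#' @export
select_candidate_size <- function(D, X, Y, s, n_min, n_cand = 20L,
                                  kind = c("EBIC", "ERML"), recode = TRUE,
                                  eval_cols = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (inherits(Y, "patch_matrix")) Y <- Y$data
  m <- nrow(D); n <- ncol(D); N <- ncol(Y)
  if (n < n_min) stop("dictionary smaller than `n_min`")
  lo <- max(n_min, m)
  if (lo > n) lo <- n
  sizes <- unique(as.integer(round(seq(lo, n, length.out = min(n_cand, n - lo + 1L)))))
  Q <- m * N
  if (recode) {
    if (is.null(eval_cols)) eval_cols <- min(N, 2048L)
    cols <- if (eval_cols < N) {
      with_seed(seed, sort(sample.int(N, eval_cols)))
    } else seq_len(N)
    Ys <- Y[, cols, drop = FALSE]
    Qs <- m * length(cols)
  } else {
    E <- Y - D %*% X
  }
  vals <- numeric(length(sizes))
  for (i in seq_along(sizes)) {
    h <- sizes[i]
    if (recode) {
      Dh <- D[, seq_len(h), drop = FALSE]
      Xh <- sparse_code_all(Dh, Ys, s)
      Eh <- Ys - Dh %*% Xh
      rmse <- frob(Eh) / sqrt(Qs)
      dx2 <- frob(Ys - Eh)^2 * (Q / Qs)  # scale to the full signal set
    } else {
      Eh <- if (h == n) E else E + D[, (h + 1):n, drop = FALSE] %*%
        X[(h + 1):n, , drop = FALSE]
      rmse <- frob(Eh) / sqrt(Q)
      dx2 <- frob(Y - Eh)^2
    }
    P <- model_complexity(s, N, m, h)
    vals[i] <- if (kind == "EBIC") {
      suppressWarnings(ebic(rmse, Q, P, N, h, s))
    } else {
      suppressWarnings(erml(rmse, Q, P, N, h, s, dx2))
    }
  }
  feasible <- vals < Inf
  if (!any(feasible)) stop("no feasible candidate size")
  best <- which(vals == min(vals[feasible]) & feasible)[1]  # ties -> smallest h
  structure(list(candidate_sizes = sizes, criterion_values = vals,
                 criterion_kind = kind, n_itc = sizes[best],
                 Q = Q, s = s),
            class = "itc_evaluation")
}
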