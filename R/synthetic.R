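# Synthetic dictionary-learning problems with a known ground truth, used to
# exercise sparse coding, the AK-SVD sweep and the size controller under
# conditions where the right answer is known by construction.

#' Generate an exactly sparse synthetic dictionary-learning problem
#'
#' Draws a ground-truth dictionary with i.i.d. Gaussian entries normalised to
#' unit columns, codes with `s` nonzeros per column (uniformly random support,
#' standard Gaussian values), and signals `Y = D X` plus optional complex
#' Gaussian noise.
#'
#' @param m signal (patch) dimension.
#' @param n_true number of ground-truth atoms (`s <= m <= n_true`).
#' @param N number of training signals (`N >= n_true`).
#' @param s exact number of nonzeros per code column.
#' @param noise_sigma per-component noise standard deviation (default 0).
#' @param seed integer seed.
#' @return A list of class `synthetic_dl_problem` with elements
#'   `dictionary` (m x n_true), `codes` (n_true x N), `signals` (m x N),
#'   `m`, `n_true`, `N`, `s`, `noise_sigma`, `seed`.
#' @export
make_synthetic_dl_problem <- function(m, n_true, N, s, noise_sigma = 0, seed = 1L) {
  m <- as.integer(m); n_true <- as.integer(n_true)
  N <- as.integer(N); s <- as.integer(s)
  if (s > m) stop("`s` must not exceed the signal dimension `m`")
  if (m > n_true) stop("`n_true` must be at least `m` (overcomplete or complete)")
  if (N < n_true) stop("`N` must be at least `n_true`")
  if (noise_sigma < 0) stop("`noise_sigma` must be nonnegative")
  out <- with_seed(seed, {
    D <- matrix(rnorm(m * n_true), m, n_true)
    D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
    X <- matrix(0, n_true, N)
    for (k in seq_len(N)) {
      X[sample.int(n_true, s), k] <- rnorm(s)
    }
    Y <- D %*% X
    if (noise_sigma > 0) {
      Y <- Y + matrix(complex(real = rnorm(m * N, sd = noise_sigma),
                              imaginary = rnorm(m * N, sd = noise_sigma)),
                      m, N)
    }
    list(D = D, X = X, Y = Y)
  })
  structure(
    list(dictionary = out$D, codes = out$X, signals = out$Y,
         m = m, n_true = n_true, N = N, s = s,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "synthetic_dl_problem"
  )
}

#' Draw a low-coherence dictionary
#'
#' Produces `n` unit-norm atoms in dimension `m` whose pairwise coherence
#' (maximum absolute inner product) does not exceed `max_coherence`, by
#' alternating projections: clip the off-diagonal Gram entries, project the
#' Gram matrix back to rank `m`, renormalise. Useful for constructing sparse
#' recovery problems where greedy pursuit is guaranteed to behave well.
#'
#' @param m atom dimension.
#' @param n number of atoms.
#' @param max_coherence target bound on pairwise coherence (must be above the
#'   Welch bound `sqrt((n - m) / (m (n - 1)))`).
#' @param seed integer seed.
#' @param max_iter iteration cap for the alternating projections.
#' @param restarts number of fresh (deterministically seeded) starts tried
#'   before giving up — individual starts occasionally stall above the
#'   target.
#' @return An m x n real matrix with unit-norm columns; attribute
#'   `coherence` holds the achieved coherence.
#' @export
make_incoherent_dictionary <- function(m, n, max_coherence = 0.3, seed = 1L,
                                       max_iter = 1000L, restarts = 8L) {
  welch <- if (n > m) sqrt((n - m) / (m * (n - 1))) else 0
  if (max_coherence <= welch) {
    stop(sprintf("`max_coherence` must exceed the Welch bound %.4f", welch))
  }
  target <- 0.95 * max_coherence
  for (r in seq_len(restarts)) {
    D <- with_seed(seed + (r - 1L) * 100003L, matrix(rnorm(m * n), m, n))
    D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
    for (it in seq_len(max_iter)) {
      G <- crossprod(D)
      off <- G - diag(n)
      mu <- max(abs(off))
      if (mu <= max_coherence) break
      off[abs(off) > target] <- sign(off[abs(off) > target]) * target
      G <- diag(n) + off
      eg <- eigen(G, symmetric = TRUE)
      keep <- seq_len(m)
      # rank-m factor of the projected Gram: rows scaled by sqrt(eigenvalue)
      D <- sqrt(pmax(eg$values[keep], 0)) * t(eg$vectors[, keep])
      D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
    }
    mu <- max(abs(crossprod(D) - diag(n)))
    if (mu <= max_coherence) {
      attr(D, "coherence") <- mu
      return(D)
    }
  }
  stop(sprintf("coherence target %.3f not reached (achieved %.3f)",
               max_coherence, mu))
}
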