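# Independent oracles used across tests. Each deliberately recomputes the
# quantity through a different route than the package implementation.

# Point-in-ellipse membership oracle: signed intensity sum at image
# coordinates (x, y) for an ellipse table, by direct per-ellipse evaluation.
oracle_phantom_value <- function(ellipses, x, y) {
  total <- 0
  for (k in seq_len(nrow(ellipses))) {
    e <- ellipses[k, ]
    phi <- e$phi * pi / 180
    xr <- (x - e$x0) * cos(phi) + (y - e$y0) * sin(phi)
    yr <- -(x - e$x0) * sin(phi) + (y - e$y0) * cos(phi)
    if ((xr / e$a)^2 + (yr / e$b)^2 <= 1) total <- total + e$intensity
  }
  total
}

# Exhaustive best-subset least squares: the optimal k-sparse approximation of
# y over all size-k atom subsets of D.
oracle_best_subset <- function(D, y, k) {
  n <- ncol(D)
  best <- list(rss = Inf, support = integer(0), coef = numeric(0))
  for (S in utils::combn(n, k, simplify = FALSE)) {
    cf <- qr.solve(D[, S, drop = FALSE], y)
    r <- y - D[, S, drop = FALSE] %*% cf
    rss <- sum(abs(r)^2)
    if (rss < best$rss) best <- list(rss = rss, support = S, coef = cf)
  }
  best
}

# Log-binomial through explicit product sums (independent of lgamma).
oracle_log_choose <- function(n, s) {
  if (s == 0) return(0)
  sum(log(seq(n - s + 1, n))) - sum(log(seq_len(s)))
}

# Criterion formulas recomposed independently.
oracle_ebic <- function(rmse, Q, P, N, n, s) {
  2 * log(rmse) + log(Q) * P / Q + (2 * N / Q) * oracle_log_choose(n, s)
}
oracle_erml <- function(rmse, Q, P, N, n, s, dx2) {
  (Q - P) * (2 * log(rmse) - log(Q - P)) +
    P * (log(dx2) - log(Q) - log(P)) +
    log(P) + log(Q - P) + 2 * N * oracle_log_choose(n, s)
}

frob_norm <- function(x) sqrt(sum(abs(x)^2))

seeded_complex_matrix <- function(n, m = n, seed = 1) {
  set.seed(seed)
  matrix(complex(real = rnorm(n * m), imaginary = rnorm(n * m)), n, m)
}
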