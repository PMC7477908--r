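# Drives the dictionary size across learning iterations: a three-rule update
# keyed on the ITC-selected size, random atom spawning when growing, and
# freezing at the ITC size after the search phase.

#' Create a dictionary-size controller
#'
#' @param n_init starting dictionary size.
#' @param n_min smallest admissible size (the size never drops below it).
#' @param e_minus shrink step when the ITC size is much smaller than the
#'   current size (default 5).
#' @param e_plus growth step when the ITC size equals the current size
#'   (default 5).
#' @param gap_threshold gap above which the big shrink fires (defaults to
#'   `e_minus`: a gap larger than the shrink step is "much smaller").
#' @param search_iters number of adaptation iterations before the size is
#'   frozen at the last ITC value.
#' @param refine_iters learning iterations to run after freezing.
#' @param seed integer seed for spawned atoms.
#' @return A list of class `size_controller_state`.
#' @export
size_controller <- function(n_init, n_min, e_minus = 5L, e_plus = 5L,
                            gap_threshold = e_minus, search_iters = 20L,
                            refine_iters = 5L, seed = 1L) {
  if (n_init < n_min) stop("`n_init` must be at least `n_min`")
  structure(
    list(n_current = as.integer(n_init), n_min = as.integer(n_min),
         n_itc_last = NA_integer_,
         e_minus = as.integer(e_minus), e_plus = as.integer(e_plus),
         gap_threshold = as.integer(gap_threshold),
         search_iters = as.integer(search_iters),
         refine_iters = as.integer(refine_iters),
         iter_count = 0L, frozen = FALSE, seed = as.integer(seed)),
    class = "size_controller_state"
  )
}

#' Three-rule dictionary-size update
#'
#' With `n` the current size and `n_itc` the ITC-selected size:
#' (1) if `n - n_itc > gap_threshold` the size shrinks by `e_minus`;
#' (2) if `0 < n - n_itc <= gap_threshold` it shrinks by one;
#' (3) if `n_itc == n` it grows by `e_plus`. Shrinks are clamped at `n_min`.
#'
#' @param state a `size_controller_state`.
#' @param n_itc ITC-selected size (`n_min <= n_itc <= n_current`).
#' @param n_min optional override of the state's `n_min`.
#' @return A list with `new_n` and `action` (`"shrink_big"`, `"shrink_one"`
#'   or `"grow"`).
#' @export
adapt_size <- function(state, n_itc, n_min = state$n_min) {
  if (state$frozen) stop("size controller is frozen")
  n <- state$n_current
  if (n_itc > n) stop("`n_itc` cannot exceed the current size")
  gap <- n - n_itc
  if (gap > state$gap_threshold) {
    list(new_n = max(n - state$e_minus, n_min), action = "shrink_big")
  } else if (gap > 0L) {
    list(new_n = max(n - 1L, n_min), action = "shrink_one")
  } else {
    list(new_n = n + state$e_plus, action = "grow")
  }
}

#' Resize a power-sorted dictionary
#'
#' Shrinking keeps the first `new_n` atoms and code rows (the dictionary must
#' be sorted by power so the least important atoms are dropped). Growing
#' appends seeded random Gaussian atoms, normalised to unit norm, with
#' all-zero code rows.
#'
#' @param D m x n dictionary (power-sorted when shrinking).
#' @param X n x N code matrix.
#' @param new_n target size (>= `n_min`).
#' @param n_min smallest admissible size.
#' @param seed integer seed for spawned atoms.
#' @return A list with resized `dictionary` and `codes`.
#' @export
resize_dictionary <- function(D, X, new_n, n_min, seed = 1L) {
  n <- ncol(D)
  if (new_n < n_min) stop("`new_n` must be at least `n_min`")
  if (new_n <= n) {
    return(list(dictionary = D[, seq_len(new_n), drop = FALSE],
                codes = X[seq_len(new_n), , drop = FALSE]))
  }
  m <- nrow(D)
  extra <- new_n - n
  fresh <- with_seed(seed, {
    g <- matrix(rnorm(m * extra), m)
    if (is.complex(D)) g <- g + 1i * matrix(rnorm(m * extra), m)
    g
  })
  fresh <- sweep(fresh, 2, sqrt(colSums(abs(fresh)^2)), "/")
  zeros <- matrix(if (is.complex(X)) 0 + 0i else 0, extra, ncol(X))
  list(dictionary = cbind(D, fresh), codes = rbind(X, zeros))
}

#' Advance the controller one iteration, freezing after the search phase
#'
#' Increments the iteration counter; once it reaches `search_iters` the last
#' ITC size (clamped at `n_min`) is adopted as the final dictionary size and
#' the state is frozen — subsequent refinement iterations learn at fixed
#' size.
#'
#' @param state a `size_controller_state` whose `n_itc_last` has been set.
#' @return The updated state.
#' @export
step_and_maybe_freeze <- function(state) {
  state$iter_count <- state$iter_count + 1L
  if (!state$frozen && state$iter_count >= state$search_iters) {
    state$frozen <- TRUE
    if (!is.na(state$n_itc_last)) {
      state$n_current <- max(state$n_itc_last, state$n_min)
    }
  }
  state
}

#' Learn a dictionary of adaptive size from training signals
#'
#' The standalone dictionary-learning loop (no k-space involved): each
#' adaptation iteration runs `dl_inner_iters` coding + AK-SVD sweeps (with
#' dictionary clearing between sweeps), then the size controller adjusts the
#' atom count from the ITC-selected size; after `search_iters` adaptation
#' iterations the size freezes at the last ITC value and `refine_iters`
#' fixed-size iterations polish the atoms.
#'
#' @param Y m x N training signal matrix (or `patch_matrix`).
#' @param T0 sparsity cap for coding.
#' @param s criterion sparsity.
#' @param n_init,n_min,e_minus,e_plus,gap_threshold,search_iters,refine_iters
#'   controller parameters (see [size_controller()]).
#' @param n_cand number of ITC candidate sizes.
#' @param criterion `"EBIC"` or `"ERML"`.
#' @param dl_inner_iters learning sweeps per adaptation iteration (default 2;
#'   the size indicator is evaluated only at that cadence).
#' @param eval_cols ITC evaluation subsample size (see
#'   [select_candidate_size()]).
#' @param tol OMP residual tolerance.
#' @param seed integer seed.
#' @return A list with `dictionary`, `codes`, `state`, `rmse`, and a
#'   `trajectory` data frame (iteration, n, n_itc, action, criterion value).
#' @export
learn_adaptive_dictionary <- function(Y, T0 = 6L, s = 5L, n_init = 128L,
                                      n_min = 64L, n_cand = 20L,
                                      criterion = c("EBIC", "ERML"),
                                      e_minus = 5L, e_plus = 5L,
                                      gap_threshold = e_minus,
                                      search_iters = 20L, refine_iters = 5L,
                                      dl_inner_iters = 2L, eval_cols = NULL,
                                      tol = 0, seed = 1L) {
  criterion <- match.arg(criterion)
  if (inherits(Y, "patch_matrix")) Y <- Y$data
  state <- size_controller(n_init, n_min, e_minus, e_plus, gap_threshold,
                           search_iters, refine_iters, seed)
  D <- init_dictionary(Y, n_init, seed = seed)
  X <- NULL
  traj <- vector("list", state$search_iters + state$refine_iters)
  total <- state$search_iters + state$refine_iters
  for (it in seq_len(total)) {
    for (sw in seq_len(max(1L, dl_inner_iters))) {
      step <- dl_iterate(Y, D, T0, tol)
      D <- clear_duplicate_atoms(step$dictionary, step$codes, Y)
      X <- recode_after_clearing(D, step$codes, Y, T0, tol)
    }
    action <- "frozen"; crit_val <- NA_real_; n_itc <- NA_integer_
    if (!state$frozen) {
      X <- sparse_code_all(D, Y, T0, tol)
      srt <- sort_dictionary_by_power(D, X)
      D <- srt$dictionary; X <- srt$codes
      ev <- select_candidate_size(D, X, Y, s, state$n_min, n_cand, criterion,
                                  eval_cols = eval_cols, seed = seed)
      n_itc <- ev$n_itc
      crit_val <- ev$criterion_values[match(n_itc, ev$candidate_sizes)]
      state$n_itc_last <- n_itc
      upd <- adapt_size(state, n_itc)
      rs <- resize_dictionary(D, X, upd$new_n, state$n_min,
                              seed = state$seed + it)
      D <- rs$dictionary; X <- rs$codes
      state$n_current <- ncol(D)
      action <- upd$action
      state <- step_and_maybe_freeze(state)
      if (state$frozen && ncol(D) != state$n_current) {
        srt <- sort_dictionary_by_power(D, X)
        rs <- resize_dictionary(srt$dictionary, srt$codes, state$n_current,
                                state$n_min, seed = state$seed + it)
        D <- rs$dictionary; X <- rs$codes
      }
    } else {
      state$iter_count <- state$iter_count + 1L
    }
    traj[[it]] <- data.frame(iteration = it, n = ncol(D), n_itc = n_itc,
                             action = action, criterion_value = crit_val)
  }
  X <- sparse_code_all(D, Y, T0, tol)  # codes consistent with cleared atoms
  list(dictionary = D, codes = X, state = state,
       rmse = representation_rmse(Y, D, X),
       trajectory = do.call(rbind, traj))
}
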