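# Overlapping patch extraction and averaging aggregation. With periodic
# (wraparound) extraction at stride 1 every pixel is covered by exactly m
# patches, so the patch-term normal matrix is m times the identity — the
# condition under which the k-space update is the exact least-squares
# solution of the reconstruction subproblem.

patch_index_cache <- new.env(parent = emptyenv())

# Linear pixel indices of every patch: an m x N integer matrix whose column
# k lists, in column-major within-patch order, the pixels of the patch at
# origin k. Origins are enumerated row-major (column varies fastest).
patch_indices <- function(H, W, patch_side, stride, wraparound) {
  key <- paste(H, W, patch_side, stride, wraparound, sep = "_")
  cached <- patch_index_cache[[key]]
  if (!is.null(cached)) return(cached)
  p <- patch_side
  if (wraparound) {
    oi <- seq.int(1L, H, by = stride)
    oj <- seq.int(1L, W, by = stride)
  } else {
    oi <- seq.int(1L, H - p + 1L, by = stride)
    oj <- seq.int(1L, W - p + 1L, by = stride)
  }
  origins <- cbind(rep(oi, each = length(oj)), rep(oj, times = length(oi)))
  di <- rep(seq_len(p) - 1L, times = p)   # column-major within patch
  dj <- rep(seq_len(p) - 1L, each = p)
  rows <- outer(di, origins[, 1] - 1L, "+")
  cols <- outer(dj, origins[, 2] - 1L, "+")
  if (wraparound) {
    rows <- rows %% H
    cols <- cols %% W
  }
  idx <- rows + 1L + cols * H
  storage.mode(idx) <- "integer"
  out <- list(idx = idx, origins = origins)
  patch_index_cache[[key]] <- out
  out
}

#' Extract overlapping square patches from an image
#'
#' Column `k` of the result is the column-major vectorisation of the
#' `patch_side` x `patch_side` patch whose top-left corner is
#' `origins[k, ]`; origins are enumerated row-major with step `stride`. With
#' `wraparound = TRUE` patch indices are taken modulo the image size, so with
#' stride 1 there are exactly `H * W` patches.
#'
#' @param image real or complex matrix.
#' @param patch_side side length of the square patch.
#' @param stride origin step (overlap stride r).
#' @param wraparound periodic extraction (default TRUE).
#' @return An object of class `patch_matrix`: list with `data`
#'   (`patch_side^2` x N matrix), `patch_side`, `stride`, `origins`,
#'   `image_shape`, `wraparound`.
#' @export
extract_patches <- function(image, patch_side, stride = 1L, wraparound = TRUE) {
  stopifnot_matrix2d(image, "image")
  H <- nrow(image); W <- ncol(image)
  patch_side <- as.integer(patch_side); stride <- as.integer(stride)
  if (patch_side > min(H, W)) stop("patch larger than image")
  if (stride < 1L) stop("`stride` must be >= 1")
  pi_ <- patch_indices(H, W, patch_side, stride, wraparound)
  data <- matrix(image[pi_$idx], nrow = patch_side^2)
  structure(list(data = data, patch_side = patch_side, stride = stride,
                 origins = pi_$origins, image_shape = c(H, W),
                 wraparound = wraparound),
            class = "patch_matrix")
}

#' Aggregate patch columns back onto the image grid
#'
#' Sums every patch value onto the pixel it covers and counts the covering
#' patches, so `numerator / counts` is the patch-averaged image. Errors if
#' any pixel is covered by no patch.
#'
#' @param patches a `patch_matrix` (its `data` may have been replaced by an
#'   approximation of the same shape, e.g. `D %*% codes`).
#' @param data optional replacement for `patches$data` with identical shape.
#' @return A list with `numerator` (sum image), `counts` (coverage counts)
#'   and `image` (`numerator / counts`).
#' @export
aggregate_patches <- function(patches, data = NULL) {
  if (!inherits(patches, "patch_matrix")) stop("`patches` must be a patch_matrix")
  if (is.null(data)) data <- patches$data
  if (!all(dim(data) == dim(patches$data))) stop("replacement data shape differs")
  H <- patches$image_shape[1]; W <- patches$image_shape[2]
  pi_ <- patch_indices(H, W, patches$patch_side, patches$stride,
                       patches$wraparound)
  idx <- pi_$idx
  num <- rep(if (is.complex(data)) 0 + 0i else 0, H * W)
  cnt <- rep(0, H * W)
  one <- rep(1, ncol(idx))
  # within a fixed within-patch offset the covered pixels are distinct,
  # so row-wise accumulation never writes the same pixel twice
  for (k in seq_len(nrow(idx))) {
    ik <- idx[k, ]
    num[ik] <- num[ik] + data[k, ]
    cnt[ik] <- cnt[ik] + one
  }
  if (any(cnt == 0)) {
    bad <- which(cnt == 0)[1]
    stop(sprintf("pixel (%d, %d) is covered by no patch",
                 (bad - 1L) %% H + 1L, (bad - 1L) %/% H + 1L))
  }
  numerator <- matrix(num, H, W)
  counts <- matrix(cnt, H, W)
  list(numerator = numerator, counts = counts, image = numerator / counts)
}
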