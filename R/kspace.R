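# Fourier sampling operators, undersampling masks and the closed-form
# k-space data-consistency update.

fftshift2 <- function(x) {
  d <- dim(x)
  x[c(seq.int(ceiling(d[1] / 2) + 1, d[1]), seq_len(ceiling(d[1] / 2))),
    c(seq.int(ceiling(d[2] / 2) + 1, d[2]), seq_len(ceiling(d[2] / 2)))]
}

ifftshift2 <- function(x) {
  d <- dim(x)
  x[c(seq.int(floor(d[1] / 2) + 1, d[1]), seq_len(floor(d[1] / 2))),
    c(seq.int(floor(d[2] / 2) + 1, d[2]), seq_len(floor(d[2] / 2)))]
}

# 1-based index of the DC bin after centring
dc_index <- function(H) floor(H / 2) + 1L

#' Centred unitary 2D Fourier transforms
#'
#' `fft2c` maps an image to its spectrum with the DC bin at the grid centre
#' (`floor(H/2) + 1`) and unitary scaling `1/sqrt(H W)`, so Parseval's
#' identity holds exactly and `ifft2c(fft2c(x)) == x` to machine precision.
#'
#' @param image,spectrum real or complex 2D matrix.
#' @return A complex matrix of the same shape.
#' @export
fft2c <- function(image) {
  stopifnot_matrix2d(image, "image")
  if (any(!is.finite(Re(image))) || (is.complex(image) && any(!is.finite(Im(image))))) {
    stop("`image` must be finite")
  }
  fftshift2(fft(ifftshift2(as_complex(image)))) / sqrt(length(image))
}

#' @rdname fft2c
#' @export
ifft2c <- function(spectrum) {
  stopifnot_matrix2d(spectrum, "spectrum")
  fftshift2(fft(ifftshift2(as_complex(spectrum)), inverse = TRUE)) /
    sqrt(length(spectrum))
}

#' Generate a k-space undersampling mask
#'
#' Selects `round(H W / factor)` k-space locations (so the sampled fraction
#' is within 20\% of `1/factor` by construction). Kinds:
#' \describe{
#'   \item{`variable_density_2d`}{weighted sampling without replacement with
#'     density proportional to `(1 - r)^6`, `r` the distance from the DC bin
#'     normalised by the half-diagonal — samples concentrate at low spatial
#'     frequencies where MR image energy lives.}
#'   \item{`cartesian_lines`}{`round(H/factor)` fully sampled phase-encode
#'     rows, drawn with the same centre-weighted density along the row axis.}
#'   \item{`uniform_random`}{uniform sampling without replacement.}
#'   \item{`full`}{every location sampled.}
#' }
#' The DC location is always forced into the mask, which stabilises the
#' intensity scale of the zero-filled initialisation.
#'
#' @param H,W grid dimensions.
#' @param factor undersampling factor R >= 1 (a 10-fold mask keeps ~10\%).
#' @param kind one of `"variable_density_2d"`, `"cartesian_lines"`,
#'   `"uniform_random"`, `"full"`.
#' @param seed integer seed; masks are deterministic per seed.
#' @param density_power exponent of the variable-density law (default 6).
#' @return An object of class `sampling_mask`: list with logical `grid`,
#'   `factor`, `kind`, `seed`.
#' @export
make_sampling_mask <- function(H, W = H, factor = 1,
                               kind = c("variable_density_2d", "cartesian_lines",
                                        "uniform_random", "full"),
                               seed = 1L, density_power = 6) {
  kind <- match.arg(kind)
  H <- as.integer(H); W <- as.integer(W)
  if (!is.numeric(factor) || factor < 1) stop("`factor` must be >= 1")
  grid <- matrix(FALSE, H, W)
  ic <- dc_index(H); jc <- dc_index(W)
  if (kind == "full" || factor == 1) {
    grid[] <- TRUE
  } else if (kind == "cartesian_lines") {
    nlines <- max(1L, as.integer(round(H / factor)))
    rdist <- abs(seq_len(H) - ic) / max(abs(1 - ic), abs(H - ic))
    wts <- pmax(1 - rdist, 0)^density_power + 1e-12
    rows <- with_seed(seed, sample.int(H, nlines, prob = wts))
    if (!(ic %in% rows)) rows[1L] <- ic
    grid[rows, ] <- TRUE
  } else {
    k <- max(1L, as.integer(round(H * W / factor)))
    if (kind == "variable_density_2d") {
      ri <- matrix(seq_len(H) - ic, H, W)
      rj <- matrix(seq_len(W) - jc, H, W, byrow = TRUE)
      r <- sqrt(ri^2 + rj^2) / sqrt(max(abs(ri))^2 + max(abs(rj))^2)
      wts <- pmax(1 - r, 0)^density_power + 1e-12
    } else {
      wts <- rep(1, H * W)
    }
    idx <- with_seed(seed, sample.int(H * W, k, prob = as.vector(wts)))
    grid[idx] <- TRUE
    grid[ic, jc] <- TRUE
  }
  structure(list(grid = grid, factor = factor, kind = kind,
                 seed = as.integer(seed)),
            class = "sampling_mask")
}

mask_grid <- function(mask) {
  if (inherits(mask, "sampling_mask")) mask$grid
  else if (is.logical(mask) && is.matrix(mask)) mask
  else stop("`mask` must be a sampling_mask or a logical matrix")
}

#' Simulate undersampled k-space measurements of an image
#'
#' Applies the centred unitary FFT and zeroes every location outside the
#' sampled set, returning a measurement object in the zero-filled convention.
#'
#' @param image real or complex matrix.
#' @param mask a [make_sampling_mask()] object (or logical matrix) of the
#'   same shape.
#' @return A list of class `kspace_grid`: complex `values` (zero outside the
#'   mask), `mask`, `is_measurement = TRUE`.
#' @export
undersample <- function(image, mask) {
  g <- mask_grid(mask)
  if (!all(dim(g) == dim(image))) stop("image and mask shapes differ")
  values <- fft2c(image)
  values[!g] <- 0 + 0i
  structure(list(values = values, mask = mask, is_measurement = TRUE),
            class = "kspace_grid")
}

#' Zero-filled Fourier reconstruction
#'
#' The naive baseline and the reconstruction algorithm's initialiser: inverse
#' FFT of the measured spectrum with unsampled locations left at zero.
#'
#' @param y a `kspace_grid` measurement from [undersample()] (or a complex
#'   matrix already in the zero-filled convention).
#' @return A complex image matrix.
#' @export
zero_filled_recon <- function(y) {
  values <- if (inherits(y, "kspace_grid")) y$values else y
  ifft2c(values)
}

#' Closed-form k-space data-consistency update
#'
#' Solves the least-squares image update of the reconstruction objective:
#' the updated spectrum equals the model spectrum `M` off the sampled set and
#' the convex combination `(M + v M0) / (1 + v)` on it, where `M0` is the
#' zero-filled measured spectrum and `v >= 0` weights data fidelity. As
#' `v -> Inf` the measured values are enforced exactly (hard data
#' consistency); `v = 0` ignores the measurements.
#'
#' @param M complex matrix, spectrum of the current model image.
#' @param M0 complex matrix, zero-filled measured spectrum.
#' @param mask sampling mask (object or logical matrix).
#' @param v nonnegative data-fidelity weight.
#' @return The updated complex spectrum.
#' @export
kspace_data_update <- function(M, M0, mask, v) {
  g <- mask_grid(mask)
  if (!all(dim(M) == dim(M0)) || !all(dim(M) == dim(g))) {
    stop("M, M0 and mask shapes differ")
  }
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
    stop("`v` must be a single nonnegative number")
  }
  out <- as_complex(M)
  M0 <- as_complex(M0)
  out[g] <- (out[g] + v * M0[g]) / (1 + v)
  out
}
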