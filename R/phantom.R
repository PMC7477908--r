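#' Ellipse table for the contrast-modified Shepp-Logan head phantom
#'
#' The classical ten-ellipse head phantom with the widely used
#' contrast-modified additive intensities (background skull at 1, interior
#' structures on a 0.1-0.3 grey scale so they are visible without windowing).
#' Columns: `intensity` (additive), `a`, `b` (semi-axes as fractions of the
#' half field of view), `x0`, `y0` (centre in `[-1, 1]^2`, y up), `phi`
#' (rotation, degrees counter-clockwise).
#'
#' @return A data frame with one row per ellipse.
#' @export
shepp_logan_ellipses <- function() {
  data.frame(
    intensity = c(1, -0.8, -0.2, -0.2, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1),
    a   = c(0.69, 0.6624, 0.11, 0.16, 0.21, 0.046, 0.046, 0.046, 0.023, 0.023),
    b   = c(0.92, 0.8740, 0.31, 0.41, 0.25, 0.046, 0.046, 0.023, 0.023, 0.046),
    x0  = c(0, 0, 0.22, -0.22, 0, 0, 0, -0.08, 0, 0.06),
    y0  = c(0, -0.0184, 0, 0, 0.35, 0.1, -0.1, -0.605, -0.606, -0.605),
    phi = c(0, 0, -18, 18, 0, 0, 0, 0, 0, 0)
  )
}

#' Specify a piecewise-constant ellipse phantom
#'
#' @param grid_size pixels per side (>= 8).
#' @param ellipses data frame with columns `intensity`, `a`, `b`, `x0`, `y0`,
#'   `phi` (see [shepp_logan_ellipses()] for the default head phantom).
#' @param intensity_range length-2 numeric; rendered intensities are clipped
#'   to this range.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = 128L,
                         ellipses = shepp_logan_ellipses(),
                         intensity_range = c(0, 1)) {
  grid_size <- as.integer(grid_size)
  if (is.na(grid_size) || grid_size < 8L) {
    stop("`grid_size` must be an integer >= 8")
  }
  need <- c("intensity", "a", "b", "x0", "y0", "phi")
  if (!is.data.frame(ellipses) || !all(need %in% names(ellipses))) {
    stop("`ellipses` must be a data frame with columns ",
         paste(need, collapse = ", "))
  }
  if (length(intensity_range) != 2L || diff(intensity_range) < 0) {
    stop("`intensity_range` must be an increasing length-2 numeric")
  }
  structure(
    list(grid_size = grid_size, ellipses = ellipses,
         intensity_range = as.numeric(intensity_range)),
    class = "phantom_spec"
  )
}

#' Render an ellipse phantom image
#'
#' Pixels are evaluated at their centres on the square `[-1, 1]^2`, with the
#' row index increasing downward (image convention) and `y` increasing upward
#' in ellipse coordinates. Intensities of all ellipses containing a pixel
#' centre are summed, then clipped to the spec's intensity range. Rendering
#' is deterministic.
#'
#' @param spec a [phantom_spec()].
#' @return A real `grid_size` x `grid_size` matrix.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  H <- spec$grid_size
  # pixel-centre coordinates: column -> x in (-1, 1), row -> y downward
  xs <- (2 * seq_len(H) - 1) / H - 1
  ys <- 1 - (2 * seq_len(H) - 1) / H
  X <- matrix(xs, H, H, byrow = TRUE)
  Y <- matrix(ys, H, H)
  img <- matrix(0, H, H)
  for (k in seq_len(nrow(spec$ellipses))) {
    e <- spec$ellipses[k, ]
    phi <- e$phi * pi / 180
    dx <- X - e$x0
    dy <- Y - e$y0
    xr <- dx * cos(phi) + dy * sin(phi)
    yr <- -dx * sin(phi) + dy * cos(phi)
    inside <- (xr / e$a)^2 + (yr / e$b)^2 <= 1
    img <- img + e$intensity * inside
  }
  pmin(pmax(img, spec$intensity_range[1]), spec$intensity_range[2])
}

#' Add i.i.d. circular complex Gaussian noise to an image
#'
#' Noise with independent real and imaginary components, each of standard
#' deviation `sigma`, is added pixelwise. This emulates the thermal noise of
#' a low-field acquisition; adding it in the image domain is equivalent (up
#' to the unitary FFT) to adding it in k-space.
#'
#' @param image real or complex matrix.
#' @param sigma per-component noise standard deviation (>= 0).
#' @param seed integer seed; the same seed reproduces the same noise.
#' @return A complex matrix of the same shape (real if `sigma == 0` and the
#'   input was real).
#' @export
add_complex_gaussian_noise <- function(image, sigma, seed) {
  stopifnot_matrix2d(image, "image")
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0) {
    stop("`sigma` must be a single nonnegative number")
  }
  if (sigma == 0) return(image)
  n <- length(image)
  noise <- with_seed(seed, complex(real = rnorm(n, sd = sigma),
                                   imaginary = rnorm(n, sd = sigma)))
  image + matrix(noise, nrow(image), ncol(image))
}
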