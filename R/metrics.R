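# Reconstruction quality metrics. All three compare magnitude images: the
# reference phantoms are real and nonnegative, and reconstruction phase
# carries no anatomical information here.

#' Peak signal-to-noise ratio (dB)
#'
#' `20 log10( max|reference| / rms(|recon| - |reference|) )`: the peak
#' reference intensity over the root-mean-square magnitude error. Identical
#' images return `Inf`.
#'
#' @param reference,recon same-shape matrices (complex allowed; magnitudes
#'   are compared).
#' @return PSNR in dB.
#' @export
psnr <- function(reference, recon) {
  err <- metric_error(reference, recon)
  if (all(err == 0)) return(Inf)
  20 * log10(max(abs(reference)) / sqrt(mean(err^2)))
}

#' Signal-to-noise ratio of a reconstruction (dB)
#'
#' `20 log10( ||reference||_F / || |recon| - |reference| ||_F )`: total
#' signal energy over total magnitude-error energy. Identical images return
#' `Inf`; equal energies give 0 dB.
#'
#' @inheritParams psnr
#' @return SNR in dB.
#' @export
snr <- function(reference, recon) {
  err <- metric_error(reference, recon)
  if (all(err == 0)) return(Inf)
  20 * log10(frob(abs(reference)) / frob(err))
}

metric_error <- function(reference, recon) {
  if (!all(dim(reference) == dim(recon))) stop("image shapes differ")
  if (all(abs(reference) == 0)) stop("reference image is all zero")
  abs(recon) - abs(reference)
}

#' Rotationally symmetric Laplacian-of-Gaussian kernel
#'
#' The standard LoG filter used by the high-frequency error norm: `size` x
#' `size` taps, scale `sigma`, normalised so the Gaussian sums to one, then
#' mean-subtracted so a constant image filters to exactly zero.
#'
#' @param size odd kernel side (default 15).
#' @param sigma Gaussian scale in pixels (default 1.5).
#' @return A `size` x `size` matrix summing to zero.
#' @export
log_kernel <- function(size = 15L, sigma = 1.5) {
  if (size %% 2L != 1L) stop("`size` must be odd")
  half <- (size - 1L) / 2L
  x <- matrix(-half:half, size, size, byrow = TRUE)
  y <- matrix(-half:half, size, size)
  g <- exp(-(x^2 + y^2) / (2 * sigma^2))
  g <- g / sum(g)
  h <- g * (x^2 + y^2 - 2 * sigma^2) / sigma^4
  h - mean(h)
}

# 2D convolution with mirror (symmetric) boundary padding, via FFT.
conv2_symmetric <- function(img, kernel) {
  kh <- (nrow(kernel) - 1L) / 2L
  H <- nrow(img); W <- ncol(img)
  if (H <= kh || W <= kh) stop("image too small for the kernel")
  ri <- c(kh:1, 1:H, H:(H - kh + 1L))
  ci <- c(kh:1, 1:W, W:(W - kh + 1L))
  pad <- img[ri, ci]
  Hp <- nrow(pad); Wp <- ncol(pad)
  kp <- matrix(0, Hp, Wp)
  kp[1:nrow(kernel), 1:ncol(kernel)] <- kernel
  # circular convolution of the padded image equals linear convolution
  # in the interior because the pad width covers the kernel support
  full <- Re(fft(fft(pad) * fft(kp), inverse = TRUE)) / (Hp * Wp)
  full[(2L * kh + 1L):(2L * kh + H), (2L * kh + 1L):(2L * kh + W)]
}

#' High-frequency error norm
#'
#' Frobenius norm of the Laplacian-of-Gaussian-filtered difference between
#' the reconstruction and reference magnitude images; quantifies how well
#' edges and fine features are recovered. The LoG kernel is 15 x 15 with
#' sigma 1.5, applied with symmetric boundary padding; because the kernel is
#' mean-subtracted, a constant intensity offset contributes nothing.
#'
#' @inheritParams psnr
#' @param size,sigma LoG kernel parameters.
#' @return A nonnegative scalar.
#' @export
hfen <- function(reference, recon, size = 15L, sigma = 1.5) {
  if (!all(dim(reference) == dim(recon))) stop("image shapes differ")
  d <- abs(recon) - abs(reference)
  frob(conv2_symmetric(d, log_kernel(size, sigma)))
}
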