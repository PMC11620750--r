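#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor dgamma fft fitted lm.fit optim pchisq pnorm
#'   pt qnorm quantile residuals rnorm runif sd setNames var predict
#'   model.matrix as.formula vcov
#' @importFrom utils read.delim write.table head
#' @importFrom tools md5sum
NULL

# Derive a reproducible sub-seed (< 2^31) from a master seed and a stage name.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 7919 + h * 104729) %% 2147483629L)
}

# Legendre polynomials (orders 0..order) on [-1, 1], evaluated on n points.
legendre_drift <- function(n, order = 2L) {
  x <- seq(-1, 1, length.out = n)
  P <- matrix(0, n, order + 1L)
  P[, 1] <- 1
  if (order >= 1L) P[, 2] <- x
  if (order >= 2L) {
    for (k in 2:order) {
      P[, k + 1L] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1L]) / k
    }
  }
  colnames(P) <- paste0("drift", 0:order)
  P
}

# Cosine similarity between two numeric vectors.
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("cosine similarity undefined for a zero-norm input", call. = FALSE)
  }
  sum(a * b) / (na * nb)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
sigma_to_fwhm <- function(sigma) sigma * 2 * sqrt(2 * log(2))

# Gaussian random field on a 3D grid: white noise smoothed (circularly, via FFT)
# with an isotropic Gaussian kernel of the given FWHM (voxel units), normalized
# so every voxel is exactly unit variance. fwhm = 0 gives white noise.
gaussian_random_field <- function(shape, kernel_fwhm = 0) {
  w <- array(rnorm(prod(shape)), dim = shape)
  smooth_field(w, kernel_fwhm, renormalize = TRUE)
}

# Circular Gaussian smoothing of a 3D array. With renormalize = TRUE the kernel
# is scaled to unit sum of squares so white-noise input keeps unit variance;
# otherwise the kernel has unit sum (a local average).
smooth_field <- function(x, kernel_fwhm, renormalize = FALSE) {
  if (kernel_fwhm <= 0) return(x)
  shape <- dim(x)
  sig <- fwhm_to_sigma(kernel_fwhm)
  k1 <- function(n) {
    d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    exp(-d^2 / (2 * sig^2))
  }
  kx <- k1(shape[1]); ky <- k1(shape[2]); kz <- k1(shape[3])
  kern <- outer(outer(kx, ky), kz)
  dim(kern) <- shape
  kern <- if (renormalize) kern / sqrt(sum(kern^2)) else kern / sum(kern)
  out <- Re(fft(fft(x) * Conj(fft(kern)), inverse = TRUE)) / prod(shape)
  out
}

# Intensity-weighted center of mass of a voxel set, in world coordinates.
center_of_mass <- function(idx, weights, shape, affine) {
  co <- arrayInd(idx, .dim = shape) - 1L  # 0-based voxel indices
  w <- abs(weights) / sum(abs(weights))
  vox <- colSums(co * w)
  xyz <- affine %*% c(vox, 1)
  as.numeric(xyz[1:3])
}
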