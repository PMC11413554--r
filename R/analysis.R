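# Valid-region calculus and the 1-D Gaussian propagation closed form.
#
# Each RL iteration performs two convolutions, and each "valid"-mode
# convolution with a w_PSF-wide kernel shrinks the region whose values
# depend only on real data by w_PSF - 1 on either side in total; one
# iteration therefore shrinks the valid width by 2*w_PSF - 2. The valid
# width can go negative quickly: e.g. a 512-sample block with a 32-sample
# PSF has no valid samples at all after 10 iterations (512 - 10*62 =
# -108), which is why practical block processing relies on the PSF's
# decaying tails rather than on strict validity.

#' Valid-region width after RL iterations
#'
#' Returns `dataWidth - iterations * (2 * psfWidth - 2)`, the number of
#' samples in a 1-D block whose values, after the given number of RL
#' iterations, depend only on measured data and not on boundary values.
#' A non-positive result means the whole result is formally invalid.
#' Vectorized over all three arguments.
#'
#' @param dataWidth positive integer(s): contiguous data samples.
#' @param psfWidth positive integer(s): PSF support width in samples.
#' @param iterations non-negative integer(s): RL iteration count.
#' @return integer valid width(s); may be negative.
#' @examples
#' validWidth(512, 32, 10)   # -108: nothing valid after 10 iterations
#' validWidth(64, 5, 3)      # 40
#' @export
validWidth <- function(dataWidth, psfWidth, iterations) {
    stopifnot(all(dataWidth >= 1), all(psfWidth >= 1), all(iterations >= 0))
    as.integer(dataWidth - iterations * (2 * psfWidth - 2))
}

#' One-step Gaussian variance recursion of the RL iteration
#'
#' For 1-D Gaussian data the RL update has a closed form: if the
#' measured image equals the PSF (a point-like object), the PSF is a
#' centred Gaussian of variance `psfVar`, and the current estimate is a
#' centred Gaussian of variance `estVar`, then one RL iteration produces
#' another centred Gaussian. Working through the update in the
#' continuous, infinite-domain limit - the ratio of two Gaussians is a
#' Gaussian of variance `psfVar * (psfVar + estVar) / estVar`, the
#' correction convolution adds `psfVar`, and the final product combines
#' inverse variances - gives the next variance
#'
#' `1 / ( 1/estVar + estVar / (psfVar * (psfVar + 2 * estVar)) )`.
#'
#' The output amplitude is independent of the input amplitude, so the
#' recursion is a function of the variances alone. At equal unit
#' variances the first step yields 0.75; iterating from there produces a
#' strictly decreasing positive sequence, the progressive sharpening of
#' the estimate.
#'
#' @param estVar variance of the current Gaussian estimate (> 0).
#' @param psfVar variance of the Gaussian PSF / measured image (> 0).
#' @return the variance after one RL iteration.
#' @examples
#' gaussianVarianceStep(1, 1)   # 0.75
#' @export
gaussianVarianceStep <- function(estVar, psfVar) {
    if (any(estVar <= 0) || any(psfVar <= 0))
        stop("variances must be positive")
    1 / (1 / estVar + estVar / (psfVar * (psfVar + 2 * estVar)))
}

#' Fit a Gaussian to a 1-D profile by moments
#'
#' Amplitude is the maximum sample; mean and variance are the first and
#' second central moments of the mass-normalized profile. This is the
#' measurement used to track variance shrinkage across RL iterations.
#'
#' @param samples non-negative profile values with positive total mass.
#' @param coordinates sample positions (defaults to `0:(n-1)`).
#' @return a [GaussianModel].
#' @examples
#' x <- seq(-6, 6, by = 0.01)
#' fitGaussianProfile(exp(-x^2 / 2), x)
#' @export
fitGaussianProfile <- function(samples, coordinates = seq_along(samples) - 1) {
    samples <- as.numeric(samples)
    coordinates <- as.numeric(coordinates)
    stopifnot(length(samples) == length(coordinates))
    if (any(samples < 0)) stop("samples must be non-negative")
    s <- sum(samples)
    if (s <= 0) stop("profile has zero total mass")
    w <- samples / s
    mu <- sum(w * coordinates)
    v <- sum(w * (coordinates - mu)^2)
    GaussianModel(amplitude = max(samples), mean = mu, variance = v)
}
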