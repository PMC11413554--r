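# Richardson-Lucy core: the multiplicative update and the multi-iteration
# driver. Estimates live on the same grid as the measured image; all
# convolutions are circular (periodic boundary), so with a unit-sum PSF
# each update conserves the total intensity of the measured image.

rl_check_psf <- function(psf) {
    k <- as_arr(psf, "psf")
    s <- sum(k)
    if (abs(s - 1) > 1e-6)
        stop("psf must be normalized to unit sum (got sum = ", format(s),
             "); see normalizePSF()")
    k
}

# one RL update on bare arrays with precomputed kernel FFTs
rl_step <- function(est, mi, psf_fft, fsp_fft, eps) {
    denom <- cconv_fft(est, psf_fft)
    ratio <- mi / pmax(denom, eps)
    pmax(est * cconv_fft(ratio, fsp_fft), 0)
}

#' One Richardson-Lucy iteration
#'
#' The multiplicative maximum-likelihood update for Poisson noise:
#'
#' `E_{n+1} = E_n * ( FSP conv ( MI / (PSF conv E_n) ) )`
#'
#' where `FSP` is the flipped PSF and both convolutions are circular.
#' The re-blurred denominator is floored at `epsilon` to guard the
#' division; negative values from floating-point round-off are clamped
#' to zero. If `MI` was produced exactly by blurring some volume `E`
#' with the PSF, then `E` is a fixed point of the update.
#'
#' @param estimate current estimate, same shape as `mi`.
#' @param mi measured image, `Volume3D` or 3-D array.
#' @param psf unit-sum `PSF3D` (rejected otherwise; see [normalizePSF()]).
#' @param epsilon division guard; default `1e-12 * max(mi)`.
#' @return the updated estimate as a `Volume3D`.
#' @seealso [rlDeconvolve()] for the multi-iteration driver.
#' @export
rlIteration <- function(estimate, mi, psf, epsilon = NULL) {
    e <- as_arr(estimate, "estimate")
    m <- as_arr(mi, "measured image")
    if (!identical(dim(e), dim(m)))
        stop("estimate and measured image must have the same shape")
    if (any(e < 0) || any(m < 0))
        stop("estimate and measured image must be non-negative")
    k <- rl_check_psf(psf)
    check_kernel_fits(dim(m), dim(k))
    if (is.null(epsilon) || is.na(epsilon)) epsilon <- 1e-12 * max(m)
    psf_fft <- stats::fft(embed_kernel(k, dim(m)))
    fsp_fft <- stats::fft(embed_kernel(as_arr(flipPSF(k)), dim(m)))
    Volume3D(rl_step(e, m, psf_fft, fsp_fft, epsilon))
}

#' Richardson-Lucy deconvolution (non-block path)
#'
#' Runs `config@iterations` RL updates starting from the measured image
#' itself (the conventional initialization, which makes zero iterations
#' an identity). The PSF is normalized to unit sum on entry and its FFT
#' (and that of the flipped PSF) is computed once and reused by every
#' iteration, since each update needs two convolutions. The progress
#' callback, if any, is invoked after each completed iteration with
#' `(iteration, total_iterations)`.
#'
#' @param mi measured image, `Volume3D` or 3-D array.
#' @param psf the blur kernel (any positive mass; normalized internally).
#' @param config a [DeconvConfig]; `iterations` and `epsilon` are used
#'   here, the block parameters by [blockRLDeconvolve()].
#' @return the deconvolved `Volume3D`.
#' @examples
#' oi <- makeBeadPhantom(c(16, 16, 16), nBeads = 2, radius = 2,
#'                       intensity = 50, seed = 7)
#' psf <- makeGaussianPSF(c(5, 5, 5), sigmas = c(1, 1, 1))
#' mi <- forwardModel(oi, psf, noise = "none")
#' out <- rlDeconvolve(mi, psf, makeDeconvConfig(iterations = 5))
#' @export
rlDeconvolve <- function(mi, psf, config = makeDeconvConfig()) {
    stopifnot(is(config, "DeconvConfig"))
    validObject(config)
    m <- as_arr(mi, "measured image")
    if (any(m < 0)) stop("measured image must be non-negative")
    k <- as_arr(normalizePSF(psf), "psf")
    check_kernel_fits(dim(m), dim(k))
    n <- config@iterations
    if (n == 0L) return(Volume3D(m))
    eps <- config@epsilon
    if (is.na(eps)) eps <- 1e-12 * max(m)
    psf_fft <- stats::fft(embed_kernel(k, dim(m)))
    fsp_fft <- stats::fft(embed_kernel(as_arr(flipPSF(k)), dim(m)))
    est <- m
    for (i in seq_len(n)) {
        est <- rl_step(est, m, psf_fft, fsp_fft, eps)
        if (!is.null(config@callback)) config@callback(i, n)
    }
    Volume3D(est)
}
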