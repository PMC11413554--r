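#' Flip a PSF along all three axes
#'
#' Full index reversal of the kernel: the element at (i, j, k) of the
#' output equals the element at (pz+1-i, py+1-j, px+1-k) of the input.
#' The flipped PSF is the kernel of the correction convolution in the
#' Richardson-Lucy update; flipping is an involution, and any
#' centro-symmetric kernel (e.g. an isotropic Gaussian sampled on an odd
#' grid) is left unchanged.
#'
#' @param psf a `PSF3D` or 3-D array.
#' @return the flipped kernel as a `PSF3D`.
#' @examples
#' p <- PSF3D(array(1:8, c(2, 2, 2)))
#' flipPSF(flipPSF(p))
#' @export
flipPSF <- function(psf) {
    a <- as_arr(psf, "psf")
    d <- dim(a)
    PSF3D(a[d[1]:1, d[2]:1, d[3]:1, drop = FALSE])
}

#' Normalize a PSF to unit total mass
#'
#' Divides the kernel by its sum so that convolution with it conserves
#' total intensity (the flux-conservation contract of the RL update).
#' Idempotent; an all-zero kernel is rejected as degenerate.
#'
#' @param psf a `PSF3D` or 3-D array with positive total mass.
#' @return a unit-sum `PSF3D`.
#' @export
normalizePSF <- function(psf) {
    a <- as_arr(psf, "psf")
    s <- sum(a)
    if (!is.finite(s) || s <= 0)
        stop("degenerate PSF: total mass must be > 0")
    PSF3D(a / s)
}

#' Circular (periodic-boundary) convolution via FFT
#'
#' Convolves a volume with a kernel under periodic boundary conditions,
#' the natural boundary of FFT-based convolution: the volume edge wraps
#' around and reuses the volume's own data, so no padding scheme is
#' involved. The kernel is centred at its geometric centre index
#' `floor(size/2)` per axis (0-based), for odd and even sizes alike.
#' Output shape equals the volume shape; the operation is linear in both
#' arguments and conserves mass: `sum(out) = sum(vol) * sum(kernel)`.
#'
#' @param vol a `Volume3D` or 3-D array.
#' @param kernel a `PSF3D` or 3-D array, no larger than `vol` in any axis.
#' @return the convolved `Volume3D`.
#' @seealso [directCircularConvolve()] for the summation reference path.
#' @examples
#' v <- Volume3D(array(runif(64), c(4, 4, 4)))
#' delta <- array(0, c(3, 3, 3)); delta[2, 2, 2] <- 1
#' max(abs(circularConvolve(v, delta) - v))
#' @export
circularConvolve <- function(vol, kernel) {
    v <- as_arr(vol, "volume")
    k <- as_arr(kernel, "kernel")
    check_kernel_fits(dim(v), dim(k))
    out <- cconv_fft(v, stats::fft(embed_kernel(k, dim(v))))
    Volume3D(pmax(out, 0))
}

#' Circular convolution by direct summation
#'
#' The conventional summation form of the convolution, computed by
#' accumulating one wrapped, shifted copy of the volume per kernel
#' element. Same periodic boundary and `floor(size/2)` centering as
#' [circularConvolve()]; cost is O(N * K), so it is intended as the
#' small-input reference path against which the FFT path is validated.
#'
#' @inheritParams circularConvolve
#' @return the convolved `Volume3D`.
#' @export
directCircularConvolve <- function(vol, kernel) {
    v <- as_arr(vol, "volume")
    k <- as_arr(kernel, "kernel")
    vd <- dim(v); kd <- dim(k)
    check_kernel_fits(vd, kd)
    ctr <- kd %/% 2L
    out <- array(0, vd)
    for (oz in seq_len(kd[1])) for (oy in seq_len(kd[2]))
        for (ox in seq_len(kd[3])) {
            w <- k[oz, oy, ox]
            if (w == 0) next
            off <- c(oz, oy, ox) - 1L - ctr
            iz <- ((seq_len(vd[1]) - 1L - off[1]) %% vd[1]) + 1L
            iy <- ((seq_len(vd[2]) - 1L - off[2]) %% vd[2]) + 1L
            ix <- ((seq_len(vd[3]) - 1L - off[3]) %% vd[3]) + 1L
            out <- out + w * v[iz, iy, ix]
        }
    Volume3D(pmax(out, 0))
}

#' Naive inverse (Fourier) filter
#'
#' Deconvolution by direct spectral division,
#' `FFT^-1(FFT(MI) / FFT(PSF))`. Spectral magnitudes of the PSF below
#' `1e-6 * max|FFT(PSF)|` are clamped to that floor (phase preserved) so
#' the division cannot overflow. The clamp does nothing about noise:
#' on noisy data this filter amplifies high-frequency noise dramatically,
#' which is why iterative maximum-likelihood deconvolution is preferred;
#' it is provided as the baseline that demonstrates the problem.
#'
#' @param mi measured image, `Volume3D` or 3-D array.
#' @param psf the blur kernel; normalized internally.
#' @return the inverse-filtered `Volume3D` (negatives clamped to 0).
#' @export
inverseFilter <- function(mi, psf) {
    m <- as_arr(mi, "measured image")
    k <- as_arr(normalizePSF(psf), "psf")
    check_kernel_fits(dim(m), dim(k))
    kf <- stats::fft(embed_kernel(k, dim(m)))
    mag <- Mod(kf)
    floorv <- 1e-6 * max(mag)
    scale <- pmax(mag, floorv)
    # keep the phase; where |F| == 0 the phase is undefined, use the floor
    kf_clamped <- ifelse(mag > 0, kf * (scale / mag), complex(real = floorv))
    out <- Re(stats::fft(stats::fft(m) / kf_clamped, inverse = TRUE)) / length(m)
    Volume3D(pmax(out, 0))
}
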