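# shared fixtures and independent oracles, built in code at test time

rand_vol <- function(d, lo = 0, hi = 1) array(runif(prod(d), lo, hi), d)

as_a <- function(x) if (is(x, "Volume3D")) x@.Data else x

rmse_of <- function(a, b) sqrt(mean((as_a(a) - as_a(b))^2))

rel_diff <- function(a, b) {
    a <- as_a(a); b <- as_a(b)
    max(abs(a - b)) / max(abs(b), .Machine$double.eps)
}

# NaN-propagation oracle for the valid-region width: a w-sample signal
# undergoes 2 * iters same-width convolutions with a p-wide kernel whose
# out-of-range taps read NaN; the count of non-NaN survivors is the
# mechanically determined valid width.
nan_valid_width <- function(w, p, iters) {
    x <- rep(1, w)
    ctr <- p %/% 2L
    for (conv in seq_len(2L * iters)) {
        xp <- c(rep(NA_real_, p), x, rep(NA_real_, p))
        out <- rep(0, length(xp))
        for (o in 0:(p - 1L)) {
            idx <- seq_along(xp) - (o - ctr)
            v <- rep(NA_real_, length(xp))
            ok <- idx >= 1L & idx <= length(xp)
            v[ok] <- xp[idx[ok]]
            out <- out + v
        }
        x <- out[(p + 1L):(p + w)]
    }
    sum(!is.na(x))
}

# discrete 1-D RL simulation on finely sampled Gaussians: one iteration,
# variance of the output measured by second central moment
gauss_rl_sim_var <- function(estVar, psfVar = 1, amplitude = 1,
                             step = 0.01, halfwidth = 10) {
    x <- seq(-halfwidth, halfwidth, by = step)
    arr1d <- function(v) array(v, c(1L, 1L, length(v)))
    psf <- normalizePSF(arr1d(exp(-x^2 / (2 * psfVar))))
    mi <- arr1d(exp(-x^2 / (2 * psfVar)))
    est <- arr1d(amplitude * exp(-x^2 / (2 * estVar)))
    out <- rlIteration(est, mi, psf)
    fitGaussianProfile(as.vector(out@.Data), x)@variance
}
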