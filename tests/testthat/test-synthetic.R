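test_that("Gaussian PSF is unit-sum, flip-symmetric and has the right width", {
    psf <- makeGaussianPSF(c(17, 17, 17), c(1.5, 2, 1.5))
    expect_equal(sum(psf), 1, tolerance = 1e-6)
    expect_identical(as_a(flipPSF(psf)), as_a(psf))  # isotropic grid centre
    # second moment of the sampled kernel ~ sigma^2
    ctr <- 17 %/% 2
    for (a in 1:3) {
        prof <- apply(as_a(psf), a, sum)
        fit <- fitGaussianProfile(prof, seq_along(prof) - 1 - ctr)
        expect_equal(fit@variance, c(1.5, 2, 1.5)[a]^2, tolerance = 0.02)
    }
    expect_error(makeGaussianPSF(c(5, 5, 5), c(0, 1, 1)), "positive")
})

test_that("astigmatic PSF has a waist and linearly spreading, rotating lobes", {
    psf <- makeAstigmaticPSF(c(11, 33, 33), waistSigma = 1.5,
                             spreadRate = 0.6)
    expect_equal(sum(psf), 1, tolerance = 1e-6)
    k <- as_a(psf)
    zc <- 11 %/% 2 + 1L
    lat_moment <- function(z) {
        sl <- k[z, , ]
        w <- sl / sum(sl)
        yy <- row(sl) - (33 %/% 2 + 1L); xx <- col(sl) - (33 %/% 2 + 1L)
        sum(w * (yy^2 + xx^2))
    }
    moments <- vapply(seq_len(11), lat_moment, 1.0)
    expect_equal(which.min(moments), zc)    # narrowest at focus
    # elongated-axis sigma grows as waist + rate * |dz|
    sigma_axis <- function(z, margin) {
        sl <- k[z, , ]
        prof <- if (margin == "y") rowSums(sl) else colSums(sl)
        sqrt(fitGaussianProfile(prof, seq_len(33) - 1 - 33 %/% 2)@variance)
    }
    for (d in 1:3) {
        expect_equal(sigma_axis(zc - d, "y"), 1.5 + 0.6 * d,
                     tolerance = 0.03)
        expect_equal(sigma_axis(zc + d, "x"), 1.5 + 0.6 * d,
                     tolerance = 0.03)
        # the other lateral axis stays at the waist
        expect_equal(sigma_axis(zc - d, "x"), 1.5, tolerance = 0.03)
        expect_equal(sigma_axis(zc + d, "y"), 1.5, tolerance = 0.03)
    }
})

test_that("bead phantom: count, mass, determinism and overlap failure", {
    expect_identical(as_a(makeBeadPhantom(c(8, 8, 8), 0, radius = 2)),
                     array(0, c(8, 8, 8)))
    ph <- makeBeadPhantom(c(32, 32, 32), 4, radius = 2.5, intensity = 7,
                          seed = 41)
    # every bead rasterizes to the same voxel count (integer centres)
    r <- ceiling(2.5)
    off <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
    vox_per_bead <- sum(sqrt(rowSums(off^2)) <= 2.5)
    expect_equal(sum(as_a(ph)), 4 * vox_per_bead * 7)
    expect_identical(as_a(makeBeadPhantom(c(32, 32, 32), 4, radius = 2.5,
                                          intensity = 7, seed = 41)),
                     as_a(ph))
    ph2 <- makeBeadPhantom(c(32, 32, 32), 4, radius = 2.5, intensity = 7,
                           seed = 42)
    expect_false(identical(as_a(ph2), as_a(ph)))
    expect_error(makeBeadPhantom(c(10, 10, 10), 50, radius = 3),
                 "non-overlapping")
})

test_that("filament phantom marks voxels at constant intensity, deterministically", {
    expect_identical(as_a(makeFilamentPhantom(c(8, 8, 8), 0)),
                     array(0, c(8, 8, 8)))
    ph <- makeFilamentPhantom(c(24, 24, 24), 3, nSteps = 80,
                              intensity = 11, seed = 51)
    vals <- unique(as.vector(as_a(ph)))
    expect_setequal(vals, c(0, 11))
    expect_gt(sum(as_a(ph) > 0), 0)
    expect_identical(as_a(makeFilamentPhantom(c(24, 24, 24), 3, nSteps = 80,
                                              intensity = 11, seed = 51)),
                     as_a(ph))
})

test_that("noiseless forward model with a delta PSF is the identity", {
    set.seed(61)
    oi <- rand_vol(c(8, 8, 8))
    delta <- array(0, c(3, 3, 3)); delta[2, 2, 2] <- 1
    expect_lt(rel_diff(forwardModel(oi, delta, noise = "none"), oi), 1e-10)
})

test_that("Poisson noise is unbiased and has variance mean/photonScale", {
    set.seed(62)
    oi <- rand_vol(c(6, 6, 6), 1, 3)
    psf <- makeGaussianPSF(c(3, 3, 3), c(1, 1, 1))
    blurred <- as_a(circularConvolve(oi, psf))
    draws <- sapply(1:200, function(s)
        as.vector(as_a(forwardModel(oi, psf, noise = "poisson",
                                    photonScale = 50, seed = s))))
    m <- rowMeans(draws)
    se <- sqrt(as.vector(blurred) / 50 / 200)
    expect_true(all(abs(m - as.vector(blurred)) < 3.5 * se + 1e-12))

    # constant-intensity volume, ~10^4 voxels: Var ~ mean / photonScale
    const <- array(4, c(22, 22, 22))
    mi <- forwardModel(const, psf, noise = "poisson", photonScale = 25,
                       seed = 63)
    expect_equal(var(as.vector(as_a(mi))), 4 / 25, tolerance = 0.05)
    expect_equal(mean(as_a(mi)), 4, tolerance = 0.01)
})

test_that("end-to-end: deconvolution reduces RMSE on a noisy bead phantom", {
    oi <- makeBeadPhantom(c(32, 32, 32), 5, radius = 2, intensity = 100,
                          seed = 71)
    psf <- makeGaussianPSF(c(7, 7, 7), c(1.5, 1.5, 1.5))
    mi <- forwardModel(oi, psf, noise = "poisson", photonScale = 10,
                       seed = 72)
    out <- rlDeconvolve(mi, psf, makeDeconvConfig(iterations = 10))
    expect_lt(rmse_of(out, oi), rmse_of(mi, oi))
})
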