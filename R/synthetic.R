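# Synthetic-data module: phantoms, model PSFs and the noisy forward
# model. Everything is deterministic under a fixed seed, so all other
# modules are testable without any downloaded data.

#' Sampled anisotropic Gaussian PSF
#'
#' A separable Gaussian sampled on the voxel grid, centred at the
#' geometric centre index `floor(size/2)` per axis (the same centering
#' convention the convolution engine uses) and normalized to unit sum.
#'
#' @param shape integer triple (z, y, x).
#' @param sigmas standard deviations in voxels, one per axis (z, y, x).
#' @return a unit-sum `PSF3D`.
#' @examples
#' psf <- makeGaussianPSF(c(9, 9, 9), sigmas = c(2, 1.5, 1.5))
#' sum(psf)
#' @export
makeGaussianPSF <- function(shape, sigmas) {
    shape <- as.integer(shape)
    stopifnot(length(shape) == 3L, all(shape >= 1L),
              length(sigmas) == 3L)
    if (any(sigmas <= 0)) stop("sigmas must be positive")
    g <- lapply(1:3, function(a) {
        d <- seq_len(shape[a]) - 1L - shape[a] %/% 2L
        exp(-d^2 / (2 * sigmas[a]^2))
    })
    k <- outer(outer(g[[1]], g[[2]]), g[[3]])
    dim(k) <- shape
    normalizePSF(k)
}

#' Astigmatic ("hourglass") PSF
#'
#' Emulates instrumental optical astigmatism: each z-slice is a 2-D
#' Gaussian whose lateral width along the elongation axis grows linearly
#' with distance from the focal plane, `sigma(z) = waistSigma +
#' spreadRate * |z - z_centre|`, while the other axis stays at the
#' waist; the elongation axis rotates by 90 degrees across the waist
#' (y-elongated below focus, x-elongated above). The central slice is
#' the narrowest. Normalized to unit sum over the whole volume.
#'
#' @param shape integer triple (z, y, x).
#' @param waistSigma lateral sigma at focus, voxels.
#' @param spreadRate sigma growth per z-voxel away from focus.
#' @return a unit-sum `PSF3D`.
#' @export
makeAstigmaticPSF <- function(shape, waistSigma, spreadRate) {
    shape <- as.integer(shape)
    stopifnot(length(shape) == 3L, all(shape >= 1L))
    if (waistSigma <= 0 || spreadRate < 0)
        stop("waistSigma must be positive and spreadRate non-negative")
    zc <- shape[1] %/% 2L
    dy <- seq_len(shape[2]) - 1L - shape[2] %/% 2L
    dx <- seq_len(shape[3]) - 1L - shape[3] %/% 2L
    k <- array(0, shape)
    for (z in seq_len(shape[1])) {
        dz <- z - 1L - zc
        s_wide <- waistSigma + spreadRate * abs(dz)
        sy <- if (dz < 0) s_wide else waistSigma
        sx <- if (dz > 0) s_wide else waistSigma
        k[z, , ] <- outer(exp(-dy^2 / (2 * sy^2)), exp(-dx^2 / (2 * sx^2)))
    }
    normalizePSF(k)
}

#' Bead phantom
#'
#' Uniform-intensity spheres at seeded, uniform-random, non-overlapping
#' integer positions on a zero background - a synthetic stand-in for a
#' fluorescent-bead test sample. A voxel belongs to a bead iff its
#' centre lies within `radius` of the bead centre, so every bead of a
#' given radius rasterizes to the same countable voxel mass. Beads are
#' kept `2 * radius` apart (centre distance) and fully inside the
#' volume; if a non-overlapping placement cannot be found within a
#' bounded number of retries the call fails.
#'
#' @param shape integer triple (z, y, x).
#' @param nBeads number of beads (0 gives an all-zero volume).
#' @param radius bead radius in voxels.
#' @param intensity voxel intensity inside a bead (> 0).
#' @param seed integer seed; fixed seed gives a bit-identical volume.
#' @return a `Volume3D`.
#' @export
makeBeadPhantom <- function(shape, nBeads, radius, intensity = 100,
                            seed = 1L) {
    shape <- as.integer(shape)
    stopifnot(length(shape) == 3L, all(shape >= 1L), nBeads >= 0,
              radius > 0, intensity > 0)
    vol <- array(0, shape)
    if (nBeads == 0) return(Volume3D(vol))
    lo <- rep(as.integer(ceiling(radius)) + 1L, 3L)
    hi <- shape - as.integer(ceiling(radius))
    if (any(hi < lo)) stop("beads of this radius do not fit in the volume")
    centers <- with_seed(seed, {
        placed <- matrix(0, 0, 3)
        tries <- 0L
        while (nrow(placed) < nBeads) {
            cand <- vapply(1:3, function(a)
                sample(lo[a]:hi[a], 1L), 1L)
            ok <- nrow(placed) == 0 ||
                all(sqrt(rowSums(sweep(placed, 2, cand)^2)) > 2 * radius)
            if (ok) placed <- rbind(placed, cand)
            tries <- tries + 1L
            if (tries > 200L * nBeads)
                stop("could not place ", nBeads,
                     " non-overlapping beads; reduce count or radius")
        }
        placed
    })
    # identical offsets stamped at every centre
    r <- ceiling(radius)
    off <- as.matrix(expand.grid(dz = -r:r, dy = -r:r, dx = -r:r))
    off <- off[sqrt(rowSums(off^2)) <= radius, , drop = FALSE]
    for (b in seq_len(nBeads)) {
        vox <- sweep(off, 2, centers[b, ], "+")
        vol[vox] <- intensity
    }
    Volume3D(vol)
}

#' Filament phantom
#'
#' Seeded random-walk polylines rasterized at unit width and constant
#' intensity - a synthetic stand-in for microtubule-like structures.
#' Each filament starts at a uniform-random interior voxel and performs
#' a persistent random walk (a random direction perturbed a little at
#' each step), marching in half-voxel increments and marking the nearest
#' voxel; steps that would leave the volume are reflected.
#'
#' @param shape integer triple (z, y, x).
#' @param nFilaments number of filaments (0 gives an all-zero volume).
#' @param nSteps number of half-voxel steps per filament.
#' @param intensity voxel intensity on the filament (> 0).
#' @param seed integer seed.
#' @return a `Volume3D`.
#' @export
makeFilamentPhantom <- function(shape, nFilaments, nSteps = 100,
                                intensity = 100, seed = 1L) {
    shape <- as.integer(shape)
    stopifnot(length(shape) == 3L, all(shape >= 1L), nFilaments >= 0,
              nSteps >= 1, intensity > 0)
    vol <- array(0, shape)
    if (nFilaments == 0) return(Volume3D(vol))
    vol <- with_seed(seed, {
        for (f in seq_len(nFilaments)) {
            pos <- vapply(1:3, function(a) runif(1, 1, shape[a]), 1.0)
            dir <- stats::rnorm(3)
            dir <- dir / sqrt(sum(dir^2))
            for (s in seq_len(nSteps)) {
                vox <- pmin(pmax(round(pos), 1L), shape)
                vol[vox[1], vox[2], vox[3]] <- intensity
                dir <- dir + 0.25 * stats::rnorm(3)
                dir <- dir / sqrt(sum(dir^2))
                nxt <- pos + 0.5 * dir
                # reflect at the walls
                for (a in 1:3) {
                    if (nxt[a] < 1 || nxt[a] > shape[a]) {
                        dir[a] <- -dir[a]
                        nxt[a] <- pos[a] + 0.5 * dir[a]
                    }
                }
                pos <- pmin(pmax(nxt, 1), shape)
            }
        }
        vol
    })
    Volume3D(vol)
}

#' Noisy forward imaging model
#'
#' Produces a measured image from a ground-truth object: the object is
#' blurred by circular convolution with the PSF, and (optionally)
#' Poisson shot noise is applied. Intensities are converted to expected
#' photon counts by `photonScale` (counts per intensity unit), a Poisson
#' variate is drawn per voxel, and the counts are scaled back, so the
#' noise level is controlled independently of the intensity scale:
#' larger `photonScale` means more photons and a cleaner image
#' (`Var = mean / photonScale` on the intensity scale).
#'
#' @param oi ground-truth object, `Volume3D` or 3-D array.
#' @param psf the blur kernel; normalized internally.
#' @param noise `"none"` or `"poisson"`.
#' @param photonScale expected photon counts per intensity unit (> 0).
#' @param seed integer seed for the Poisson draw.
#' @return the measured image as a `Volume3D`.
#' @examples
#' oi <- makeBeadPhantom(c(16, 16, 16), 2, radius = 2, seed = 3)
#' psf <- makeGaussianPSF(c(5, 5, 5), c(1, 1, 1))
#' mi <- forwardModel(oi, psf, noise = "poisson", photonScale = 10, seed = 4)
#' @export
forwardModel <- function(oi, psf, noise = c("none", "poisson"),
                         photonScale = 1, seed = 1L) {
    noise <- match.arg(noise)
    stopifnot(photonScale > 0)
    blurred <- as_arr(circularConvolve(oi, normalizePSF(psf)))
    if (noise == "none") return(Volume3D(blurred))
    lam <- pmax(photonScale * blurred, 0)
    counts <- with_seed(seed, stats::rpois(length(lam), lam))
    out <- array(counts / photonScale, dim(blurred))
    Volume3D(out)
}
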