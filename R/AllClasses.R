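#' @import methods
NULL

setClassUnion("functionOrNULL", c("function", "NULL"))

#' 3-D intensity volume
#'
#' An S4 container for a 3-D grid of non-negative, finite intensities in
#' axis order (z, y, x). It holds measured images, ground-truth phantoms
#' and Richardson-Lucy estimates alike. The class extends `array`, so all
#' ordinary array operations (`dim`, subsetting, arithmetic) apply.
#'
#' @slot .Data three-dimensional numeric array, axis order (z, y, x).
#'
#' @param data a 3-D numeric array (z, y, x) of finite, non-negative values.
#' @return a `Volume3D` object.
#' @examples
#' v <- Volume3D(array(runif(24), dim = c(2, 3, 4)))
#' dim(v)
#' @export Volume3D
#' @exportClass Volume3D
Volume3D <- setClass("Volume3D", contains = "array")

setValidity("Volume3D", function(object) {
    d <- dim(object)
    if (is.null(d) || length(d) != 3L)
        return("data must be a 3-D array with axis order (z, y, x)")
    if (any(d < 1L))
        return("all dimensions must be positive")
    if (!is.numeric(object@.Data))
        return("data must be numeric")
    if (!all(is.finite(object@.Data)))
        return("all values must be finite")
    if (any(object@.Data < 0))
        return("all values must be non-negative")
    TRUE
})

#' 3-D point spread function
#'
#' A `Volume3D` holding a blur kernel: non-negative, finite, with strictly
#' positive total mass. Most routines expect the PSF normalized to unit
#' sum (see [normalizePSF()]); [rlDeconvolve()] normalizes on entry.
#'
#' @param data a 3-D numeric array of non-negative weights with positive sum.
#' @return a `PSF3D` object.
#' @examples
#' p <- makeGaussianPSF(c(5, 5, 5), sigmas = c(1, 1, 1))
#' sum(p)
#' @export PSF3D
#' @exportClass PSF3D
PSF3D <- setClass("PSF3D", contains = "Volume3D")

setValidity("PSF3D", function(object) {
    if (sum(object@.Data) <= 0)
        return("degenerate PSF: total mass must be > 0")
    TRUE
})

#' Deconvolution run configuration
#'
#' Bundles the tunable parameters of an RL run: iteration count, the
#' division guard applied to the re-blurred denominator, the block-path
#' padding fraction (overlap width = `round(paddingFract * psf_size)` per
#' axis), the padded-block voxel budget, the backend selector and an
#' optional progress callback.
#'
#' The callback receives `(completed_units, total_units)`; a unit is one
#' iteration in the non-block path and one block in the block path.
#'
#' @slot iterations non-negative integer; number of RL iterations.
#' @slot epsilon division guard; `NA` means `1e-12 * max(measured image)`.
#' @slot paddingFract positive multiplier of the PSF size giving the
#'   block pad width (default 1.2).
#' @slot maxBlockVoxels voxel budget per padded block; `Inf` = unlimited.
#' @slot backend `"cpu"` (reference) or `"auto"` (falls back to cpu).
#' @slot callback progress hook or `NULL`.
#'
#' @param iterations,epsilon,paddingFract,maxBlockVoxels,backend,callback
#'   see the slot descriptions.
#' @return a `DeconvConfig` object.
#' @examples
#' DeconvConfig(iterations = 10)
#' @export DeconvConfig
#' @exportClass DeconvConfig
DeconvConfig <- setClass("DeconvConfig",
    slots = c(iterations = "integer",
              epsilon = "numeric",
              paddingFract = "numeric",
              maxBlockVoxels = "numeric",
              backend = "character",
              callback = "functionOrNULL"),
    prototype = prototype(iterations = 10L,
                          epsilon = NA_real_,
                          paddingFract = 1.2,
                          maxBlockVoxels = Inf,
                          backend = "cpu",
                          callback = NULL))

setValidity("DeconvConfig", function(object) {
    if (length(object@iterations) != 1L || is.na(object@iterations) ||
        object@iterations < 0L)
        return("iterations must be a single non-negative integer")
    if (length(object@epsilon) != 1L ||
        (!is.na(object@epsilon) && object@epsilon <= 0))
        return("epsilon must be a single positive number (or NA for auto)")
    if (length(object@paddingFract) != 1L || !is.finite(object@paddingFract) ||
        object@paddingFract <= 0)
        return("paddingFract must be a single positive number")
    if (length(object@maxBlockVoxels) != 1L || object@maxBlockVoxels < 1)
        return("maxBlockVoxels must be >= 1 (Inf for unlimited)")
    if (!object@backend %in% c("cpu", "auto"))
        return("backend must be 'cpu' or 'auto'")
    TRUE
})

#' @describeIn DeconvConfig constructor with coercion of `iterations` to
#'   integer.
#' @export
makeDeconvConfig <- function(iterations = 10L, epsilon = NA_real_,
                             paddingFract = 1.2, maxBlockVoxels = Inf,
                             backend = "cpu", callback = NULL) {
    new("DeconvConfig", iterations = as.integer(iterations),
        epsilon = as.numeric(epsilon), paddingFract = paddingFract,
        maxBlockVoxels = as.numeric(maxBlockVoxels), backend = backend,
        callback = callback)
}

#' Overlapping-block partition of a volume
#'
#' Describes how a volume is split for block-wise deconvolution: disjoint
#' *core* regions that tile the volume exactly, and *padded* (outer)
#' extraction regions obtained by expanding each core by the pad width on
#' every face, clipped at the volume bounds. At volume faces the padded
#' region coincides with the core face, so the volume edge is treated as
#' if the volume had not been split. Ranges are stored 1-based inclusive;
#' blocks are ordered z-major (z slowest, x fastest).
#'
#' @slot volShape,psfShape integer triples (z, y, x).
#' @slot pad integer triple; pad width per axis (`round(paddingFract * psfShape)`).
#' @slot coreStart,coreEnd,outerStart,outerEnd n-by-3 integer matrices of
#'   1-based inclusive voxel ranges, one row per block.
#'
#' @seealso [computeBlockLayout()], [splitExtract()], [cropMerge()]
#' @exportClass BlockLayout
setClass("BlockLayout",
    slots = c(volShape = "integer", psfShape = "integer", pad = "integer",
              coreStart = "matrix", coreEnd = "matrix",
              outerStart = "matrix", outerEnd = "matrix"))

setValidity("BlockLayout", function(object) {
    n <- nrow(object@coreStart)
    mats <- list(object@coreEnd, object@outerStart, object@outerEnd)
    if (any(vapply(mats, nrow, 1L) != n))
        return("block range matrices must have matching row counts")
    if (any(object@outerStart > object@coreStart) ||
        any(object@outerEnd < object@coreEnd))
        return("padded regions must contain their cores")
    if (any(object@outerStart < 1L) ||
        any(sweep(object@outerEnd, 2, object@volShape, ">")))
        return("padded regions must lie within the volume")
    # exact tiling: per-voxel coverage count must be exactly one
    cover <- array(0L, object@volShape)
    for (b in seq_len(n)) {
        idx <- lapply(1:3, function(a)
            object@coreStart[b, a]:object@coreEnd[b, a])
        cover[idx[[1]], idx[[2]], idx[[3]]] <-
            cover[idx[[1]], idx[[2]], idx[[3]]] + 1L
    }
    if (any(cover != 1L))
        return("core regions must tile the volume exactly")
    TRUE
})

#' 1-D Gaussian model
#'
#' Amplitude/mean/variance triple describing a 1-D Gaussian profile, as
#' returned by [fitGaussianProfile()] and used by the analytic variance
#' recursion of [gaussianVarianceStep()].
#'
#' @slot amplitude peak height (> 0).
#' @slot mean profile centre, in coordinate units.
#' @slot variance second central moment (> 0), in squared coordinate units.
#'
#' @param amplitude,mean,variance see slots.
#' @return a `GaussianModel` object.
#' @export GaussianModel
#' @exportClass GaussianModel
GaussianModel <- setClass("GaussianModel",
    slots = c(amplitude = "numeric", mean = "numeric", variance = "numeric"))

setValidity("GaussianModel", function(object) {
    if (object@amplitude <= 0) return("amplitude must be > 0")
    if (object@variance <= 0) return("variance must be > 0")
    TRUE
})

setMethod("show", "Volume3D", function(object) {
    d <- dim(object)
    cat(sprintf("%s of shape (z=%d, y=%d, x=%d)\n", class(object),
                d[1], d[2], d[3]))
    cat(sprintf("  range [%g, %g], total intensity %g\n",
                min(object@.Data), max(object@.Data), sum(object@.Data)))
})

setMethod("show", "DeconvConfig", function(object) {
    cat("DeconvConfig:\n")
    cat(sprintf("  iterations: %d, epsilon: %s, backend: %s\n",
                object@iterations,
                ifelse(is.na(object@epsilon), "auto", format(object@epsilon)),
                object@backend))
    cat(sprintf("  paddingFract: %g, maxBlockVoxels: %s, callback: %s\n",
                object@paddingFract,
                ifelse(is.finite(object@maxBlockVoxels),
                       format(object@maxBlockVoxels), "unlimited"),
                ifelse(is.null(object@callback), "none", "set")))
})

setMethod("show", "BlockLayout", function(object) {
    cat(sprintf("BlockLayout: %d block(s) over (%s) volume, pad (%s)\n",
                nrow(object@coreStart),
                paste(object@volShape, collapse = "x"),
                paste(object@pad, collapse = ", ")))
})

setMethod("show", "GaussianModel", function(object) {
    cat(sprintf("GaussianModel: amplitude %g, mean %g, variance %g\n",
                object@amplitude, object@mean, object@variance))
})

#' @describeIn BlockLayout-class number of blocks in the layout.
#' @param layout a `BlockLayout`.
#' @export
nBlocks <- function(layout) nrow(layout@coreStart)

#' @describeIn BlockLayout-class 3x2 matrix of 1-based inclusive core
#'   bounds of one block (rows z, y, x; columns start, end).
#' @param blockId block index in 1..nBlocks(layout).
#' @export
blockCore <- function(layout, blockId) {
    stopifnot(blockId >= 1L, blockId <= nBlocks(layout))
    cbind(start = layout@coreStart[blockId, ], end = layout@coreEnd[blockId, ])
}

#' @describeIn BlockLayout-class 3x2 matrix of padded (extraction) bounds
#'   of one block.
#' @export
blockOuter <- function(layout, blockId) {
    stopifnot(blockId >= 1L, blockId <= nBlocks(layout))
    cbind(start = layout@outerStart[blockId, ], end = layout@outerEnd[blockId, ])
}

#' @describeIn BlockLayout-class pad width per axis actually used by the
#'   layout.
#' @export
padWidths <- function(layout) layout@pad
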