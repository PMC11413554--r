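test_that("unlimited budget gives one unpadded block covering the volume", {
    lay <- computeBlockLayout(c(20, 15, 10), c(5, 5, 5))
    expect_equal(nBlocks(lay), 1L)
    expect_equal(unname(blockCore(lay, 1)[, "start"]), c(1L, 1L, 1L))
    expect_equal(unname(blockCore(lay, 1)[, "end"]), c(20L, 15L, 10L))
    expect_identical(blockOuter(lay, 1), blockCore(lay, 1))
})

test_that("pad width is round(paddingFract * psf size); default fraction 1.2", {
    lay <- computeBlockLayout(c(200, 200, 200), c(10, 10, 10),
                              paddingFract = 1.2)
    expect_equal(unname(padWidths(lay)), c(12L, 12L, 12L))
})

test_that("a 100-wide axis split three ways gives contiguous cores {34,33,33}", {
    lay <- computeBlockLayout(c(100, 1, 1), c(3, 1, 1),
                              paddingFract = 1/3, maxBlockVoxels = 36)
    expect_equal(nBlocks(lay), 3L)
    widths <- lay@coreEnd[, 1] - lay@coreStart[, 1] + 1L
    expect_equal(unname(widths), c(34L, 33L, 33L))
    expect_equal(lay@coreStart[-1, 1], lay@coreEnd[-3, 1] + 1L)
})

test_that("cores tile the volume exactly over many budgets and shapes", {
    shapes <- list(c(12, 10, 8), c(13, 11, 7), c(17, 5, 23))  # incl. primes
    for (shp in shapes) {
        v <- rand_vol(shp)
        nb_prev <- 0L
        for (budget in c(Inf, prod(shp), 600, 300, 150, 80)) {
            lay <- tryCatch(
                computeBlockLayout(shp, c(3, 3, 3), paddingFract = 1/3,
                                   maxBlockVoxels = budget),
                error = function(e) NULL)
            if (is.null(lay)) next    # budget below the feasible minimum
            expect_no_error(validObject(lay))  # validity enforces exact tiling
            # identity per-block transform reconstructs the volume exactly
            res <- lapply(seq_len(nBlocks(lay)),
                          function(b) splitExtract(v, lay, b))
            expect_identical(as_a(cropMerge(res, lay)), v)
            # shrinking the budget never decreases the block count
            expect_gte(nBlocks(lay), nb_prev)
            nb_prev <- nBlocks(lay)
        }
    }
})

test_that("face blocks carry no padding on volume-facing sides", {
    lay <- computeBlockLayout(c(40, 40, 40), c(5, 5, 5), paddingFract = 1,
                              maxBlockVoxels = 20000)
    expect_gt(nBlocks(lay), 1L)
    for (b in seq_len(nBlocks(lay))) {
        core <- blockCore(lay, b); outer <- blockOuter(lay, b)
        for (a in 1:3) {
            if (core[a, "start"] == 1L)
                expect_equal(outer[a, "start"], core[a, "start"])
            if (core[a, "end"] == 40L)
                expect_equal(outer[a, "end"], core[a, "end"])
            if (core[a, "start"] > 1L)
                expect_equal(core[a, "start"] - outer[a, "start"],
                             unname(padWidths(lay)[a]))
        }
    }
})

test_that("identical merges arise from any layout of the same volume", {
    v <- rand_vol(c(12, 10, 8))
    outs <- lapply(c(Inf, 700, 400, 160, 90, 40), function(budget) {
        lay <- tryCatch(
            computeBlockLayout(c(12, 10, 8), c(3, 3, 3), paddingFract = 1/3,
                               maxBlockVoxels = budget),
            error = function(e) NULL)
        if (is.null(lay)) return(NULL)
        res <- lapply(seq_len(nBlocks(lay)),
                      function(b) splitExtract(v, lay, b))
        as_a(cropMerge(res, lay))
    })
    outs <- Filter(Negate(is.null), outs)
    expect_gte(length(outs), 3L)
    for (o in outs[-1]) expect_identical(o, outs[[1]])
})

test_that("layout rejects budgets below one padded PSF-sized block", {
    expect_error(computeBlockLayout(c(30, 30, 30), c(5, 5, 5),
                                    paddingFract = 1.2, maxBlockVoxels = 10),
                 "too small")
    expect_error(splitExtract(rand_vol(c(4, 4, 4)),
                              computeBlockLayout(c(4, 4, 4), c(3, 3, 3)), 2),
                 "out of range")
})

test_that("single-block path is bit-identical to the non-block path", {
    oi <- makeBeadPhantom(c(20, 20, 20), 2, radius = 2, intensity = 100,
                          seed = 9)
    psf <- makeGaussianPSF(c(5, 5, 5), c(1.2, 1.2, 1.2))
    mi <- forwardModel(oi, psf, noise = "poisson", photonScale = 10,
                       seed = 10)
    cfg <- makeDeconvConfig(iterations = 5)
    expect_identical(as_a(blockRLDeconvolve(mi, psf, cfg)),
                     as_a(rlDeconvolve(mi, psf, cfg)))
})

test_that("block path with zero iterations returns the input for any layout", {
    v <- rand_vol(c(16, 12, 10))
    psf <- makeGaussianPSF(c(3, 3, 3), c(1, 1, 1))
    for (budget in c(Inf, 800, 300)) {
        cfg <- makeDeconvConfig(iterations = 0, paddingFract = 1/3,
                                maxBlockVoxels = budget)
        expect_identical(as_a(blockRLDeconvolve(v, psf, cfg)), v)
    }
})

test_that("block callback fires once per block", {
    v <- rand_vol(c(16, 12, 10))
    psf <- makeGaussianPSF(c(3, 3, 3), c(1, 1, 1))
    seen <- integer(0)
    cfg <- makeDeconvConfig(iterations = 2, paddingFract = 1/3,
                            maxBlockVoxels = 400,
                            callback = function(done, total)
                                seen <<- c(seen, done))
    lay <- computeBlockLayout(c(16, 12, 10), c(3, 3, 3), 1/3, 400)
    blockRLDeconvolve(v, psf, cfg)
    expect_equal(seen, seq_len(nBlocks(lay)))
})

test_that("multi-block output agrees with non-block away from core seams", {
    oi <- makeBeadPhantom(c(64, 64, 64), 8, radius = 3, intensity = 100,
                          seed = 31)
    psf <- makeGaussianPSF(c(9, 9, 9), c(1.8, 1.8, 1.8))
    mi <- forwardModel(oi, psf, noise = "poisson", photonScale = 10,
                       seed = 32)
    cfg <- makeDeconvConfig(iterations = 10, maxBlockVoxels = 1e5)
    lay <- computeBlockLayout(c(64, 64, 64), c(9, 9, 9),
                              maxBlockVoxels = 1e5)
    expect_equal(nBlocks(lay), 8L)   # 2 x 2 x 2 split
    blocked <- as_a(blockRLDeconvolve(mi, psf, cfg))
    plain <- as_a(rlDeconvolve(mi, psf, makeDeconvConfig(iterations = 10)))
    # mask voxels within one PSF width of any core boundary (inter-core
    # seams and volume faces; at a face the two paths wrap different data)
    coord_ok <- vapply(seq_len(64), function(c)
        min(abs(c - 0.5), abs(c - 32.5), abs(c - 64.5)) > 9, TRUE)
    keep <- outer(outer(coord_ok, coord_ok, "&"), coord_ok, "&")
    scale <- max(plain)
    expect_lt(max(abs(blocked[keep] - plain[keep])) / scale, 0.02)
})
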