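test_that("slab boundary sets are the top and bottom cartilage rows", {
    m <- slabMask(k = 10, rows = 16, cols = 8)
    b <- boundarySets(m, 2L)
    expect_true(all(b$articular[, "row"] == 3L))   # 0-based: row 4 in 1-based
    expect_true(all(b$bone[, "row"] == 12L))
    expect_equal(nrow(b$articular), 8L)
    expect_equal(nrow(b$bone), 8L)
})

test_that("a single-voxel-thick sheet is in both boundary sets", {
    m <- slabMask(k = 1, rows = 8, cols = 6)
    b <- boundarySets(m, 2L)
    expect_equal(nrow(b$articular), 6L)
    expect_equal(b$articular, b$bone)
})

test_that("boundary sets equal an exhaustive adjacency scan on the annulus", {
    sp <- phantomSpec(dim = c(1, 48, 48), boneRadius = 12,
        shellThickness = 2.19, regionLabels = c(r = 2L), sigma = 0)
    ph <- generatePhantom(sp, seed = 8)
    lab <- labelVolume(ph$mask)[1, , ]
    b <- boundarySets(ph$mask, 2L)
    oracle <- bruteBoundary(lab, 2L)
    toSet <- function(m) sort(paste(m[, 1], m[, 2]))
    expect_equal(toSet(b$articular[, c("row", "col")] + 1L),
        toSet(oracle$articular))
    expect_equal(toSet(b$bone[, c("row", "col")] + 1L), toSet(oracle$bone))
})

test_that("degenerate regions error out of boundary extraction", {
    ## cartilage with no bone anywhere
    lab <- array(0L, c(1, 6, 6)); lab[1, 3, ] <- 2L
    m <- CartilageMask(lab, 0.365, 3,
        labelDict = c(background = 0L, bone = 1L, r = 2L))
    expect_error(boundarySets(m, 2L), "degenerate")
    expect_error(boundarySets(m, 5L), "not present")
})

test_that("laminar split halves a slab and ties go superficial", {
    m6 <- slabMask(k = 6, rows = 14, cols = 10)
    lam <- laminarSplit(m6)
    codes <- laminarCodes(lam)[1, , ]
    expect_equal(sum(codes == 1L), 30L)  # 3 rows of 10
    expect_equal(sum(codes == 2L), 30L)
    ## superficial rows are the articular-facing ones
    expect_true(all(codes[4:6, ] == 1L))
    expect_true(all(codes[7:9, ] == 2L))
    ## single-row slab: equidistant, tie goes superficial
    m1 <- slabMask(k = 1, rows = 8, cols = 6)
    expect_true(all(laminarCodes(laminarSplit(m1))[1, 4, ] == 1L))
})

test_that("laminar split matches brute-force nearest-boundary membership", {
    sp <- phantomSpec(dim = c(1, 48, 48), boneRadius = 12,
        shellThickness = 2.19, sigma = 0)   # six regions
    ph <- generatePhantom(sp, seed = 9)
    lam <- laminarSplit(ph$mask)
    lab <- labelVolume(ph$mask)[1, , ]
    for (reg in unname(regionLabels(ph$mask))) {
        if (!any(lab == reg)) next
        oracle <- bruteLaminar(lab, reg)
        inReg <- lab == reg
        expect_identical(laminarCodes(lam)[1, , ][inReg], oracle[inReg])
    }
    ## partition is disjoint and exhaustive over cartilage
    expect_identical(laminarCodes(lam) != 0L, labelVolume(ph$mask) >= 2L)
    ## equidistance rule holds voxel by voxel against the generator truth
    expect_identical(laminarCodes(lam), ph$truth@laminar)
})

test_that("load-bearing slice selection is centred, odd and bounded", {
    expect_equal(selectLoadbearingSlices(31L, 15, 3), 14:16)
    expect_equal(selectLoadbearingSlices(31L, 15, 7), 12:18)
    expect_error(selectLoadbearingSlices(31L, 0, 3), "exceeds")
    expect_error(selectLoadbearingSlices(31L, 15, 4), "odd")
    expect_error(selectLoadbearingSlices(31L, 30, 3), "exceeds")
})

test_that("mask resampling is exact on identical grids and conserves area", {
    m <- slabMask(k = 6, nSlices = 2, rows = 14, cols = 10)
    same <- resampleMask(m, dim = gridDim(m), pixelSize = pixelSize(m),
        sliceThickness = sliceThickness(m), affine = affineMatrix(m))
    expect_identical(labelVolume(same), labelVolume(m))
    ## 2x finer grid: each source voxel becomes a 2x2 block
    f <- 2L
    fine <- resampleMask(m, dim = c(2L, 14L * f, 10L * f),
        pixelSize = pixelSize(m) / f, sliceThickness = sliceThickness(m))
    srcArea <- sum(labelVolume(m)[1, , ] == 2L) * pixelSize(m)^2
    fineArea <- sum(labelVolume(fine)[1, , ] == 2L) * (pixelSize(m) / f)^2
    expect_lt(abs(fineArea - srcArea), pixelSize(m)^2 + 1e-12)
    ## round trip back to the source grid restores the original labels
    back <- resampleMask(fine, dim = gridDim(m), pixelSize = pixelSize(m),
        sliceThickness = sliceThickness(m))
    expect_identical(labelVolume(back), labelVolume(m))
    ## empty mask stays empty
    e <- CartilageMask(array(0L, c(1, 6, 6)), 0.365, 3)
    expect_equal(sum(labelVolume(resampleMask(e, c(1L, 12L, 12L),
        0.1825, 3))), 0L)
})

test_that("slab thickness equals k * s for random slabs", {
    set.seed(13)
    for (i in 1:8) {
        k <- sample(1:12, 1)
        s <- runif(1, 0.2, 1.5)
        m <- slabMask(k = k, rows = k + 6L, cols = 9L, pixelSize = s)
        expect_equal(regionalThickness(m, 2L)$meanThickness, k * s,
            tolerance = 1e-12)
    }
    ## degenerate single-voxel sheet measures exactly one pixel
    expect_equal(regionalThickness(slabMask(1, pixelSize = 0.5), 2L)$meanThickness,
        0.5)
})

test_that("annulus thickness matches the analytic ring width", {
    sp <- phantomSpec(dim = c(1, 64, 64), boneRadius = 18,
        shellThickness = 6 * 0.365, regionLabels = c(r = 2L), sigma = 0)
    ph <- generatePhantom(sp, seed = 10)
    got <- regionalThickness(ph$mask, 2L)$meanThickness
    expect_lt(abs(got - 2.19), 0.365 / 2 + 1e-12)
})

test_that("thickness is invariant under 90-degree rotation and translation", {
    sp <- phantomSpec(dim = c(1, 40, 40), boneRadius = 9,
        shellThickness = 2.19, arcSpan = c(0, pi / 2),
        regionLabels = c(r = 2L), sigma = 0)
    ph <- generatePhantom(sp, seed = 12)
    base <- regionalThickness(ph$mask, 2L)$meanThickness
    lab <- labelVolume(ph$mask)
    rot <- array(t(apply(lab[1, , ], 2, rev)), c(1, 40, 40))
    mRot <- CartilageMask(rot, pixelSize(ph$mask), 3,
        labelDict = labelDict(ph$mask))
    expect_equal(regionalThickness(mRot, 2L)$meanThickness, base,
        tolerance = 1e-12)
    shifted <- array(0L, c(1, 44, 44))
    shifted[1, 3 + seq_len(40), 2 + seq_len(40)] <- lab[1, , ]
    mSh <- CartilageMask(shifted, pixelSize(ph$mask), 3,
        labelDict = labelDict(ph$mask))
    expect_equal(regionalThickness(mSh, 2L)$meanThickness, base,
        tolerance = 1e-12)
})
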