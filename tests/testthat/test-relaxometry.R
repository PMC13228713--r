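test_that("log-linear initialization recovers T2 from the decay ratio", {
    ## two-point closed form: T20 = dTE / ln(S1/S2)
    init <- loglinearInit(c(1000 * exp(-1), 1000 * exp(-2)), c(22.2, 44.4))
    expect_equal(init$t20, 22.2, tolerance = 1e-12)
    ## exact on noiseless six-point data
    te <- TE7[-1]
    s <- 800 * exp(-te / 45)
    init <- loglinearInit(s, te)
    expect_equal(init$t20, 45, tolerance = 1e-9)
    expect_equal(init$pd0, 800, tolerance = 1e-9)
    ## flat signal clamps to the upper bound
    expect_equal(loglinearInit(rep(100, 4), te[1:4])$t20, 500)
    ## non-positive signal falls back
    init <- loglinearInit(c(100, -1, 50), te[1:3], t2Bounds = c(1, 500))
    expect_equal(init$t20, 250.5)
    expect_equal(init$pd0, 100)
})

test_that("voxel fit recovers noiseless parameters to 1e-6", {
    for (t2 in c(12, 45, 80, 200)) {
        s <- signalModel(800, t2, TE7, echoIndex = seq_along(TE7))
        vf <- fitVoxel(s, TE7, fitOptions())
        expect_true(vf$valid)
        expect_equal(vf$t2, t2, tolerance = 1e-6)
        expect_equal(vf$pd, 800, tolerance = 1e-4)
    }
})

test_that("degenerate voxels come back invalid, not as exceptions", {
    expect_false(fitVoxel(rep(0, 7), TE7, fitOptions())$valid)
    ## fewer than 3 usable echoes after exclusion
    expect_false(fitVoxel(c(900, 800, 700), TE7[1:3], fitOptions())$valid)
    ## below the minimum-signal floor
    o <- fitOptions(minSignal = 50)
    expect_false(fitVoxel(rep(10, 7), TE7, o)$valid)
})

test_that("first-echo exclusion removes the stimulated-echo bias", {
    alpha <- 1.25
    s <- signalModel(800, 45, TE7, alpha = alpha,
        echoIndex = seq_along(TE7))
    ## with exclusion: exact
    withEx <- fitVoxel(s, TE7, fitOptions(excludeFirst = TRUE))
    expect_equal(withEx$t2, 45, tolerance = 1e-6)
    ## without exclusion: biased, and the LM minimum matches a dense
    ## brute-force grid search over PD x T2 within one grid step
    without <- fitVoxel(s, TE7, fitOptions(excludeFirst = FALSE))
    t2Grid <- seq(20, 70, by = 0.01)
    sse <- vapply(t2Grid, function(t2) {
        e <- exp(-TE7 / t2)
        pdHat <- sum(s * e) / sum(e^2)   # profiled-out linear PD
        sum((s - pdHat * e)^2)
    }, numeric(1))
    t2Oracle <- t2Grid[which.min(sse)]
    expect_gt(abs(without$t2 - 45), 0.5)       # strictly worse than exact
    expect_lt(abs(without$t2 - t2Oracle), 0.01 + 1e-9)
    expect_gt(abs(without$t2 - 45), abs(withEx$t2 - 45))
})

test_that("fits are scale-equivariant: PD scales, T2 unchanged", {
    s <- signalModel(600, 38, TE7, echoIndex = seq_along(TE7))
    f1 <- fitVoxel(s, TE7)
    f2 <- fitVoxel(7.5 * s, TE7)
    expect_equal(f2$t2, f1$t2, tolerance = 1e-8)
    expect_equal(f2$pd, 7.5 * f1$pd, tolerance = 1e-6)
})

test_that("noiseless map fitting reproduces phantom truth everywhere", {
    sp <- phantomSpec(dim = c(2, 40, 40), boneRadius = 10,
        shellThickness = 2.19, sigma = 0, alpha = 1.15)
    ph <- generatePhantom(sp, seed = 4)
    map <- fitMap(ph$series, ph$mask)
    cart <- ph$truth@laminar > 0L
    expect_true(all(validMask(map)[cart]))
    expect_equal(t2Values(map)[cart], ph$truth@trueT2[cart],
        tolerance = 1e-6)
    ## unmasked voxels carry the sentinel
    expect_true(all(is.na(t2Values(map)[!cart])))
})

test_that("map fitting respects slice restriction and grid checks", {
    sp <- phantomSpec(dim = c(3, 40, 40), boneRadius = 10, sigma = 0)
    ph <- generatePhantom(sp, seed = 6)
    map <- fitMap(ph$series, ph$mask, slices = c(0L, 2L))
    expect_true(all(!validMask(map)[2, , ]))
    expect_true(any(validMask(map)[1, , ]))
    badMask <- CartilageMask(array(0L, c(3, 20, 20)), 0.365, 3)
    expect_error(fitMap(ph$series, badMask), "does not match")
})

test_that("noisy map accuracy agrees with a Monte-Carlo voxel oracle", {
    ## SNR ~ 30 on the first included echo
    sigma <- 25
    nMC <- 1000L
    truthT2 <- 52
    sTrue <- signalModel(1000, truthT2, TE7, echoIndex = seq_along(TE7))
    set.seed(41)
    errs <- replicate(nMC, {
        noisy <- sqrt((sTrue + rnorm(7, 0, sigma))^2 + rnorm(7, 0, sigma)^2)
        vf <- fitVoxel(noisy, TE7)
        if (vf$valid) abs(vf$t2 - truthT2) else NA_real_
    })
    oracleMedian <- median(errs, na.rm = TRUE)
    sp <- phantomSpec(dim = c(2, 48, 48), boneRadius = 12,
        shellThickness = 2.19, sigma = sigma, regionLabels = c(r = 2L))
    ph <- generatePhantom(sp, seed = 42)
    map <- fitMap(ph$series, ph$mask)
    sup <- ph$truth@laminar == 1L & validMask(map)
    medErr <- median(abs(t2Values(map)[sup] - truthT2))
    expect_gt(medErr, oracleMedian / 2)
    expect_lt(medErr, oracleMedian * 2)
})
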