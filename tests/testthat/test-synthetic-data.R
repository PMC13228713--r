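test_that("signal model evaluates the mono-exponential decay", {
    expect_equal(signalModel(1000, 50, te = 0), 1000)
    expect_equal(signalModel(1000, 50, te = 50), 1000 * exp(-1))
    ## first-echo inflation is multiplicative and echo-1 only
    base <- signalModel(1000, 50, te = 11.1)
    expect_equal(signalModel(1000, 50, te = 11.1, alpha = 1.1,
        echoIndex = 1L), 1.1 * base)
    expect_equal(signalModel(1000, 50, te = 11.1, alpha = 1.1,
        echoIndex = 2L), base)
    expect_error(signalModel(1000, -5, te = 10), "positive")
    expect_error(signalModel(1000, 0, te = 10), "positive")
})

test_that("noiseless phantom echoes reproduce the forward model exactly", {
    sp <- phantomSpec(dim = c(2, 48, 48), sigma = 0, alpha = 1.2)
    ph <- generatePhantom(sp, seed = 3)
    sig <- intensities(ph$series)
    t2 <- ph$truth@trueT2
    for (e in c(1L, 4L, 7L)) {
        expected <- array(0, dim(t2))
        cart <- !is.na(t2)
        expected[cart] <-
            1000 * exp(-TE7[e] / t2[cart]) * (if (e == 1L) 1.2 else 1)
        expect_equal(sig[e, , , ], expected, tolerance = 1e-12)
    }
})

test_that("phantom generation is seed-reproducible and seed-mandatory", {
    sp <- phantomSpec(dim = c(1, 64, 64), sigma = 20)
    a <- generatePhantom(sp, seed = 11)
    b <- generatePhantom(sp, seed = 11)
    expect_identical(intensities(a$series), intensities(b$series))
    c <- generatePhantom(sp, seed = 12)
    expect_false(identical(intensities(a$series), intensities(c$series)))
    expect_error(generatePhantom(sp), "seed")
})

test_that("slab phantom with even-thickness shell splits half and half", {
    sp <- phantomSpec(dim = c(1, 24, 24), geometry = "slab",
        shellThickness = 6 * 0.365, regionLabels = c(r = 2L), sigma = 0)
    ph <- generatePhantom(sp, seed = 1)
    expect_equal(sum(ph$truth@laminar == 1L), sum(ph$truth@laminar == 2L))
    ## laminar truth is defined exactly on cartilage voxels
    expect_identical(ph$truth@laminar != 0L,
        labelVolume(ph$mask) >= 2L)
})

test_that("phantom truth thickness matches the shell within half a pixel", {
    sp <- phantomSpec(dim = c(1, 64, 64), boneRadius = 18,
        shellThickness = 6 * 0.365, regionLabels = c(r = 2L), sigma = 0)
    ph <- generatePhantom(sp, seed = 2)
    expect_equal(unname(ph$truth@thickness), 2.19, tolerance = 1e-12)
    measured <- regionalThickness(ph$mask, 2L)$meanThickness
    expect_lt(abs(measured - 2.19), 0.365 / 2 + 1e-12)
})

test_that("a too-thin shell errors", {
    expect_error(generatePhantom(
        phantomSpec(dim = c(1, 40, 40), shellThickness = 0.1), seed = 1),
        "thinner than one voxel")
})

test_that("Rician noise has the right zero-signal magnitude mean", {
    ## E|n| at true signal 0 is sigma * sqrt(pi/2)
    sigma <- 20
    sp <- phantomSpec(dim = c(4, 40, 40), sigma = sigma,
        regionLabels = c(r = 2L))
    ph <- generatePhantom(sp, seed = 21)
    bg <- ph$truth@backgroundMask
    vals <- apply(intensities(ph$series), 1, function(v) mean(v[bg]))
    expected <- sigma * sqrt(pi / 2)
    n <- sum(bg)
    mcErr <- 4 * sigma * sqrt((2 - pi / 2)) / sqrt(n)
    expect_true(all(abs(vals - expected) < mcErr))
})

test_that("cohort generation hits its degenerate and stochastic contracts", {
    means <- cellMeans(list(healthy = c(50, 46), at_risk = c(52, 49)))
    ## degenerate noise: values equal cell means exactly
    tab <- generateCohort(cohortSpec(groupSizes = c(healthy = 3L,
        at_risk = 3L), means = means, sigmaB = 0, sigmaE = 0), seed = 5)
    got <- merge(tab, means, by = c("group", "time", "region", "layer"))
    expect_equal(got$value, got$mean)
    ## seeded reproducibility
    spec <- cohortSpec(groupSizes = c(healthy = 4L, at_risk = 4L),
        means = means, sigmaB = 8, sigmaE = 2)
    expect_identical(generateCohort(spec, seed = 7),
        generateCohort(spec, seed = 7))
    expect_error(generateCohort(spec), "seed")
    ## law-of-large-numbers bound on empirical cell means
    big <- cohortSpec(groupSizes = c(healthy = 2000L, at_risk = 2000L),
        means = means, sigmaB = 8, sigmaE = 2)
    tabB <- generateCohort(big, seed = 17)
    agg <- stats::aggregate(value ~ group + time, tabB, mean)
    agg <- merge(agg, means)
    bound <- 4 * sqrt(8^2 + 2^2) / sqrt(2000)
    expect_true(all(abs(agg$value - agg$mean) < bound))
})

test_that("cohort tables are balanced: one row per cell per participant", {
    tab <- generateCohort(cohortSpec(), seed = 31)
    counts <- table(tab$participant_id, tab$time, tab$region, tab$layer)
    expect_true(all(counts == 1L))
    expect_equal(length(unique(tab$participant_id)), 32L)
})

test_that("cohort spec validity catches broken worlds", {
    means <- cellMeans(list(healthy = c(50, 46), at_risk = c(52, 49)))
    expect_error(cohortSpec(groupSizes = c(healthy = 0L, at_risk = 3L),
        means = means), "at least one participant")
    expect_error(cohortSpec(means = means, sigmaE = -1), ">= 0")
    ## missing cell mean for one group/time
    expect_error(cohortSpec(means = means[means$group != "healthy" |
        means$time != "post", ]), "every region x layer")
})
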