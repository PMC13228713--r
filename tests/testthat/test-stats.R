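test_that("region-layer means exclude invalid voxels and count the rest", {
    d <- c(1L, 10L, 10L)
    t2 <- array(NA_real_, d); valid <- array(FALSE, d)
    codes <- array(0L, d); regions <- array(0L, d)
    ## ten superficial voxels of region 2, one invalid
    idx <- cbind(1L, 1:10, 3L)
    t2[idx] <- 50; valid[idx] <- TRUE
    t2[1, 4, 3] <- NA; valid[1, 4, 3] <- FALSE
    codes[idx] <- 1L; regions[idx] <- 2L
    ## five deep voxels at 40, five at 60
    idx2 <- cbind(1L, 1:10, 5L)
    t2[idx2] <- rep(c(40, 60), each = 5); valid[idx2] <- TRUE
    codes[idx2] <- 2L; regions[idx2] <- 2L
    map <- new("T2Map", t2 = t2, pd = t2, rss = t2 * 0, valid = valid,
        pixelSize = 0.365, sliceThickness = 3,
        affine = diag(4))
    lam <- new("LaminarMask", codes = codes, regions = regions,
        pixelSize = 0.365, sliceThickness = 3, affine = diag(4))
    out <- regionLayerMeans(map, lam)
    sup <- out[out$layer == "superficial", ]
    expect_equal(sup$value, 50)
    expect_equal(sup$nVoxels, 9L)
    expect_equal(out$value[out$layer == "deep"], 50)
})

test_that("composite is the unweighted mean over six regions, or missing", {
    regs <- names(cartilageT2:::defaultLabelDict())[-(1:2)]
    vals <- c(45, 47, 49, 51, 53, 55)
    tab <- data.frame(participant_id = "p1", group = "healthy",
        time = "pre", region = regs, layer = "superficial", value = vals,
        stringsAsFactors = FALSE)
    comp <- compositeMeasure(tab)
    expect_equal(comp$value, 50)
    expect_equal(comp$region, "composite")
    ## all equal
    tab$value <- 50
    expect_equal(compositeMeasure(tab)$value, 50)
    ## one region missing -> composite missing
    expect_true(is.na(compositeMeasure(tab[-3, ])$value))
})

test_that("Sidak adjustment follows its closed form and is monotone", {
    expect_equal(sidakAdjust(0.05, 1), 0.05)
    expect_equal(sidakAdjust(0, 5), 0)
    expect_equal(sidakAdjust(0.01, 3), 1 - 0.99^3)  # 0.029701
    expect_error(sidakAdjust(1.2, 3), "0, 1")
    p <- seq(0, 1, by = 0.05)
    for (m in c(1L, 3L, 6L)) {
        adj <- sidakAdjust(p, m)
        expect_true(all(diff(adj) >= -1e-15))     # monotone in p
        expect_true(all(adj >= p - 1e-15))        # adjusted >= raw
        if (m > 1L)
            expect_true(all(sidakAdjust(p, m + 1L) >= adj - 1e-15))
    }
})

test_that("balanced noiseless tables reduce to cell-mean arithmetic", {
    means <- cellMeans(list(healthy = c(50, 46), at_risk = c(52, 49)))
    tab <- noiselessTable(means)
    fit <- suppressWarnings(fitGroupTimeModel(tab, "r", "superficial"))
    ctr <- contrastTable(fit)
    expect_equal(ctr$estimate[ctr$contrast == "healthy: post - pre"], -4)
    expect_equal(ctr$estimate[ctr$contrast == "at_risk: post - pre"], -3)
    expect_equal(ctr$estimate[ctr$type == "between"], 1)
    ## adjusted means equal the raw cell means
    am <- adjustedMeans(fit)
    expect_equal(am$estimate[am$group == "healthy" & am$time == "pre"], 50)
    expect_equal(am$estimate[am$group == "at_risk" & am$time == "post"], 49)
    ## between-group difference equals the interaction coefficient
    expect_equal(ctr$estimate[ctr$type == "between"],
        unname(fixedEffects(fit)[["groupat_risk:timepost"]]))
})

test_that("printed-table cell means reproduce the printed within changes", {
    tab <- noiselessTable(defaultT2Means())
    fitMT <- suppressWarnings(
        fitGroupTimeModel(tab, "medial_tibia", "superficial"))
    ctr <- contrastTable(fitMT)
    expect_equal(ctr$estimate[ctr$contrast == "healthy: post - pre"],
        -5.03, tolerance = 1e-10)
    fitMF <- suppressWarnings(
        fitGroupTimeModel(tab, "medial_femur", "superficial"))
    expect_equal(contrastTable(fitMF)$estimate[
        contrastTable(fitMF)$contrast == "at_risk: post - pre"],
        -5.44, tolerance = 1e-10)
})

test_that("adding a constant shifts the intercept, not the contrasts", {
    means <- cellMeans(list(healthy = c(50, 46), at_risk = c(52, 49)))
    spec <- cohortSpec(groupSizes = c(healthy = 6L, at_risk = 6L),
        means = means, sigmaB = 4, sigmaE = 1)
    tab <- generateCohort(spec, seed = 23)
    f0 <- fitGroupTimeModel(tab, "r", "superficial")
    tab2 <- tab; tab2$value <- tab2$value + 100
    f1 <- fitGroupTimeModel(tab2, "r", "superficial")
    expect_equal(fixedEffects(f1)[["(Intercept)"]],
        fixedEffects(f0)[["(Intercept)"]] + 100, tolerance = 1e-6)
    expect_equal(contrastTable(f1)$estimate, contrastTable(f0)$estimate,
        tolerance = 1e-6)
})

test_that("three-group noiseless tables give pairwise cell-mean contrasts", {
    means <- cellMeans(list(healthy = c(50, 46), at_risk_acl = c(52, 49),
        at_risk_noacl = c(51, 46)))
    tab <- noiselessTable(means)
    fit <- suppressWarnings(fitGroupTimeModel(tab, "r", "superficial"))
    ctr <- contrastTable(fit)
    expect_equal(sum(ctr$type == "within"), 3L)
    expect_equal(sum(ctr$type == "between"), 3L)
    getB <- function(a, b) ctr$estimate[ctr$contrast ==
        sprintf("between: %s - %s", a, b)]
    ## changes: healthy -4, acl -3, noacl -5
    expect_equal(getB("at_risk_acl", "healthy"), 1)
    expect_equal(getB("at_risk_noacl", "healthy"), -1)
    expect_equal(getB("at_risk_noacl", "at_risk_acl"), -2)
    expect_equal(unique(ctr$m), 6L)
})

test_that("singular designs are refused", {
    means <- cellMeans(list(healthy = c(50, 46), at_risk = c(52, 49)))
    tab <- noiselessTable(means)
    expect_error(fitGroupTimeModel(tab[tab$group == "healthy", ], "r",
        "superficial"), "singular design")
    expect_error(fitGroupTimeModel(
        tab[tab$group == "healthy" | tab$time == "pre", ], "r",
        "superficial"), "singular design")
})

test_that("a group-orthogonal covariate leaves the interaction unbiased", {
    means <- cellMeans(list(healthy = c(50, 46), at_risk = c(52, 49)))
    ## age influences the response but is independent of group x time
    cd <- data.frame(group = c("healthy", "at_risk"),
        ageMean = c(30, 30), ageSD = c(5, 5),
        bmiMean = c(25, 25), bmiSD = c(2, 2))
    spec <- cohortSpec(groupSizes = c(healthy = 12L, at_risk = 12L),
        means = means, sigmaB = 2, sigmaE = 1,
        covariateCoefs = c(age = 0.4, bmi = 0), covariateDist = cd)
    diffs <- vapply(1:12, function(i) {
        tab <- generateCohort(spec, seed = 400 + i)
        fPlain <- fitGroupTimeModel(tab, "r", "superficial")
        fCov <- fitGroupTimeModel(tab, "r", "superficial",
            covariates = "age")
        bPlain <- contrastTable(fPlain)
        bCov <- contrastTable(fCov)
        bCov$estimate[bCov$type == "between"] -
            bPlain$estimate[bPlain$type == "between"]
    }, numeric(1))
    ## interaction is time-within-participant: covariate adjustment
    ## cannot move it systematically
    expect_lt(abs(mean(diffs)), 0.05)
})
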