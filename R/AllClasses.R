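#' @import methods
NULL

## Shared voxel-grid geometry: in-plane pixel size (mm), slice thickness (mm)
## and a 4x4 affine mapping 0-based (row, col, slice) indices to world mm.
setClass("ImageGrid",
    representation("VIRTUAL",
        pixelSize      = "numeric",
        sliceThickness = "numeric",
        affine         = "matrix"))

.validImageGrid <- function(object) {
    msg <- character()
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
        msg <- c(msg, "'pixelSize' must be a single positive number (mm)")
    if (length(object@sliceThickness) != 1L ||
        !is.finite(object@sliceThickness) || object@sliceThickness <= 0)
        msg <- c(msg, "'sliceThickness' must be a single positive number (mm)")
    if (!identical(dim(object@affine), c(4L, 4L)))
        msg <- c(msg, "'affine' must be a 4x4 matrix")
    if (length(msg)) msg else TRUE
}
setValidity("ImageGrid", .validImageGrid)

## Default diagonal affine for a grid laid out (slice, row, col).
defaultAffine <- function(pixelSize, sliceThickness) {
    A <- diag(4)
    A[1, 1] <- pixelSize
    A[2, 2] <- pixelSize
    A[3, 3] <- sliceThickness
    A
}

#' EchoSeries: a multi-echo image stack
#'
#' Container for a multi-echo spin-echo (MESE) acquisition: one image
#' volume per echo time, plus the voxel geometry needed downstream.
#' Intensities are stored as a 4-D array indexed
#' \code{[echo, slice, row, col]} in arbitrary scanner units.
#'
#' @slot intensities 4-D numeric array \code{[echo, slice, row, col]}.
#' @slot echoTimes numeric vector of echo times TE in ms, strictly
#'   increasing and positive; one per echo volume.
#' @slot pixelSize in-plane pixel size (mm), isotropic.
#' @slot sliceThickness slice thickness (mm).
#' @slot affine 4x4 voxel-index-to-world transform (mm).
#' @seealso [EchoSeries()], [fitMap()], [generatePhantom()]
#' @export
setClass("EchoSeries",
    contains = "ImageGrid",
    representation(
        intensities = "array",
        echoTimes   = "numeric"))

setValidity("EchoSeries", function(object) {
    msg <- character()
    d <- dim(object@intensities)
    if (length(d) != 4L)
        msg <- c(msg, "'intensities' must be a 4-D array [echo, slice, row, col]")
    te <- object@echoTimes
    if (length(d) == 4L && length(te) != d[1L])
        msg <- c(msg, "number of echo times must equal number of echo volumes")
    if (any(!is.finite(te)) || any(te <= 0))
        msg <- c(msg, "echo times must be positive and finite")
    if (length(te) > 1L && any(diff(te) <= 0))
        msg <- c(msg, "echo times must be strictly increasing")
    if (length(msg)) msg else TRUE
})

#' CartilageMask: labelled cartilage regions on a voxel grid
#'
#' Integer label volume with the convention 0 = background/synovial
#' space, 1 = bone, and labels >= 2 for cartilage regions (medial/lateral
#' femur and tibia, patella, trochlea in the default dictionary).
#'
#' @slot labels 3-D integer array \code{[slice, row, col]}.
#' @slot labelDict named integer vector mapping region names to label
#'   values; must contain \code{background = 0} and \code{bone = 1}.
#' @slot pixelSize,sliceThickness,affine grid geometry, see
#'   \linkS4class{EchoSeries}.
#' @seealso [CartilageMask()], [laminarSplit()], [regionalThickness()]
#' @export
setClass("CartilageMask",
    contains = "ImageGrid",
    representation(
        labels    = "array",
        labelDict = "integer"))

setValidity("CartilageMask", function(object) {
    msg <- character()
    if (length(dim(object@labels)) != 3L)
        msg <- c(msg, "'labels' must be a 3-D array [slice, row, col]")
    dict <- object@labelDict
    if (is.null(names(dict)) || any(!nzchar(names(dict))))
        msg <- c(msg, "'labelDict' must be a named integer vector")
    if (!all(c(0L, 1L) %in% dict))
        msg <- c(msg, "'labelDict' must include background (0) and bone (1)")
    if (anyDuplicated(dict))
        msg <- c(msg, "'labelDict' values must be unique")
    present <- unique(as.integer(object@labels))
    if (!all(present %in% dict))
        msg <- c(msg, "mask contains labels absent from the declared dictionary")
    if (length(msg)) msg else TRUE
})

#' LaminarMask: superficial/deep laminar codes over cartilage voxels
#'
#' Per-voxel laminar membership produced by [laminarSplit()]: 0 outside
#' cartilage, 1 superficial (nearer the articular surface), 2 deep
#' (nearer the bone-cartilage interface).  The originating region label
#' is carried alongside so region x layer cells can be formed directly.
#'
#' @slot codes 3-D integer array of laminar codes (0/1/2).
#' @slot regions 3-D integer array of region labels (0 outside cartilage).
#' @slot pixelSize,sliceThickness,affine grid geometry.
#' @seealso [laminarSplit()], [regionLayerMeans()]
#' @export
setClass("LaminarMask",
    contains = "ImageGrid",
    representation(
        codes   = "array",
        regions = "array"))

setValidity("LaminarMask", function(object) {
    msg <- character()
    if (!identical(dim(object@codes), dim(object@regions)))
        msg <- c(msg, "'codes' and 'regions' must share dimensions")
    if (!all(as.integer(object@codes) %in% 0:2))
        msg <- c(msg, "laminar codes must be 0 (none), 1 (superficial) or 2 (deep)")
    cart <- object@regions >= 2L
    if (any((object@codes != 0L) != cart))
        msg <- c(msg, "laminar codes must be defined exactly on cartilage voxels")
    if (length(msg)) msg else TRUE
})

#' T2Map: voxel-wise fitted T2 and PD with validity flags
#'
#' Output of [fitMap()]: per-voxel T2 (ms), proton density PD, residual
#' sum of squares of the mono-exponential fit, and a validity mask.
#' Voxels outside the fitted mask, or whose fit failed the quality
#' rules, carry \code{NA} sentinels and are excluded from every
#' downstream mean.
#'
#' @slot t2,pd,rss 3-D numeric arrays \code{[slice, row, col]}; \code{NA}
#'   where invalid.
#' @slot valid 3-D logical array marking usable voxels.
#' @slot pixelSize,sliceThickness,affine grid geometry.
#' @seealso [fitMap()], [regionLayerMeans()]
#' @export
setClass("T2Map",
    contains = "ImageGrid",
    representation(
        t2    = "array",
        pd    = "array",
        rss   = "array",
        valid = "array"))

setValidity("T2Map", function(object) {
    msg <- character()
    d <- dim(object@t2)
    if (length(d) != 3L)
        msg <- c(msg, "'t2' must be a 3-D array [slice, row, col]")
    for (s in c("pd", "rss", "valid"))
        if (!identical(dim(slot(object, s)), d))
            msg <- c(msg, sprintf("'%s' must match the dimensions of 't2'", s))
    if (!is.logical(object@valid))
        msg <- c(msg, "'valid' must be logical")
    if (any(object@valid & !is.finite(object@t2)))
        msg <- c(msg, "valid voxels must carry finite T2")
    if (any(!object@valid & !is.na(object@t2)))
        msg <- c(msg, "invalid voxels must carry the NA sentinel in 't2'")
    if (length(msg)) msg else TRUE
})

#' PhantomSpec: parameters of the synthetic multi-echo knee phantom
#'
#' Describes the knee-like phantom [generatePhantom()] builds: a bone
#' disc with a cartilage shell over it (annular arc) or a rectangular
#' slab variant, a two-layer T2 structure (superficial/deep), a
#' multiplicative stimulated-echo inflation on the first echo, and
#' Rician noise.  Constructed with [phantomSpec()], which supplies the
#' documented defaults.
#'
#' @slot dim integer grid shape (slices, rows, cols).
#' @slot pixelSize,sliceThickness voxel geometry (mm).
#' @slot geometry \code{"annulus"} or \code{"slab"}.
#' @slot boneCenter,boneRadius bone disc centre (row, col voxels) and
#'   radius (voxels); annulus geometry only.
#' @slot arcSpan angular span (radians, two values) of the cartilage arc.
#' @slot shellThickness cartilage shell thickness h (mm).
#' @slot regionLabels named integer vector of cartilage region labels
#'   (>= 2), laid out as angular sectors (annulus) or column bands (slab).
#' @slot t2Superficial,t2Deep true layer T2 (ms).
#' @slot pd proton density (arbitrary intensity units).
#' @slot echoTimes echo times TE (ms), strictly increasing.
#' @slot alpha first-echo inflation factor (>= 1), the stimulated-echo
#'   artifact.
#' @slot sigma Rician noise scale (intensity units, >= 0).
#' @seealso [phantomSpec()], [generatePhantom()]
#' @export
setClass("PhantomSpec",
    representation(
        dim            = "integer",
        pixelSize      = "numeric",
        sliceThickness = "numeric",
        geometry       = "character",
        boneCenter     = "numeric",
        boneRadius     = "numeric",
        arcSpan        = "numeric",
        shellThickness = "numeric",
        regionLabels   = "integer",
        t2Superficial  = "numeric",
        t2Deep         = "numeric",
        pd             = "numeric",
        echoTimes      = "numeric",
        alpha          = "numeric",
        sigma          = "numeric"))

setValidity("PhantomSpec", function(object) {
    msg <- character()
    if (length(object@dim) != 3L || any(object@dim < 1L))
        msg <- c(msg, "'dim' must be three positive integers (slices, rows, cols)")
    te <- object@echoTimes
    if (length(te) < 2L || any(te <= 0) || any(diff(te) <= 0))
        msg <- c(msg, "echo times must be positive and strictly increasing")
    if (object@shellThickness <= 0)
        msg <- c(msg, "shell thickness h must be > 0")
    nReg <- length(object@regionLabels)
    for (s in c("t2Superficial", "t2Deep")) {
        v <- slot(object, s)
        if (!length(v) %in% c(1L, nReg) || any(v <= 0))
            msg <- c(msg, sprintf(
                "'%s' must be positive, length 1 or one value per region", s))
    }
    if (object@pd <= 0)
        msg <- c(msg, "proton density must be > 0")
    if (object@alpha < 1)
        msg <- c(msg, "first-echo inflation alpha must be >= 1")
    if (object@sigma < 0)
        msg <- c(msg, "noise sigma must be >= 0")
    if (!object@geometry %in% c("annulus", "slab"))
        msg <- c(msg, "geometry must be 'annulus' or 'slab'")
    if (length(object@regionLabels) < 1L || any(object@regionLabels < 2L))
        msg <- c(msg, "at least one cartilage region label (>= 2) is required")
    if (object@pixelSize <= 0 || object@sliceThickness <= 0)
        msg <- c(msg, "voxel geometry must be positive")
    if (length(msg)) msg else TRUE
})

#' PhantomTruth: ground truth accompanying a synthetic phantom
#'
#' Voxel-wise and regional truth emitted by [generatePhantom()] so every
#' downstream stage can be tested against known values: the true T2 at
#' each voxel, the true laminar membership (by the same
#' nearest-boundary rule the splitter must reproduce), the true shell
#' thickness per region, and the bone/background masks.
#'
#' @slot trueT2 3-D numeric array of true T2 (ms); \code{NA} off cartilage.
#' @slot laminar 3-D integer array: 0 none, 1 superficial, 2 deep.
#' @slot thickness named numeric vector, true thickness per region (mm).
#' @slot boneMask,backgroundMask 3-D logical arrays.
#' @export
setClass("PhantomTruth",
    representation(
        trueT2         = "array",
        laminar        = "array",
        thickness      = "numeric",
        boneMask       = "array",
        backgroundMask = "array"))

#' CohortSpec: generating model for simulated pre/post cohorts
#'
#' The statistical world [generateCohort()] draws from: group sizes,
#' true cell means per group x time x region x layer, a participant
#' random-intercept SD, a residual SD, and optional age/BMI covariates
#' with linear coefficients.  Constructed with [cohortSpec()].
#'
#' @slot groupSizes named integer vector (2 or 3 groups).
#' @slot means data.frame with columns group, time, region, layer, mean;
#'   every (group, time) cell must cover every region x layer in scope.
#' @slot sigmaB random-intercept SD (same units as the response).
#' @slot sigmaE residual SD.
#' @slot covariateCoefs named numeric, coefficients for age (per year)
#'   and bmi (per kg/m^2); zero disables the covariate term.
#' @slot covariateDist data.frame with columns group, ageMean, ageSD,
#'   bmiMean, bmiSD used to draw per-participant covariates.
#' @seealso [cohortSpec()], [generateCohort()], [fitGroupTimeModel()]
#' @export
setClass("CohortSpec",
    representation(
        groupSizes     = "integer",
        means          = "data.frame",
        sigmaB         = "numeric",
        sigmaE         = "numeric",
        covariateCoefs = "numeric",
        covariateDist  = "data.frame"))

setValidity("CohortSpec", function(object) {
    msg <- character()
    g <- object@groupSizes
    if (is.null(names(g)) || length(g) < 2L || length(g) > 3L)
        msg <- c(msg, "'groupSizes' must name 2 or 3 groups")
    if (any(g < 1L))
        msg <- c(msg, "every group must have at least one participant")
    m <- object@means
    need <- c("group", "time", "region", "layer", "mean")
    if (!all(need %in% names(m))) {
        msg <- c(msg, "means must have columns group, time, region, layer, mean")
    } else {
        cells <- unique(m[, c("region", "layer")])
        for (gr in names(g)) for (tm in unique(m$time)) {
            have <- m[m$group == gr & m$time == tm, c("region", "layer")]
            if (nrow(merge(cells, have)) != nrow(cells))
                msg <- c(msg, sprintf(
                    "every region x layer needs a mean for group '%s', time '%s'",
                    gr, tm))
        }
        if (!all(is.finite(m$mean)))
            msg <- c(msg, "cell means must be finite")
    }
    if (object@sigmaB < 0 || object@sigmaE < 0)
        msg <- c(msg, "sigmaB and sigmaE must be >= 0")
    if (length(msg)) msg else TRUE
})

#' T2ModelFit: fitted group-by-time mixed model with contrasts
#'
#' Result of [fitGroupTimeModel()]: fixed effects and their covariance,
#' variance components, adjusted cell means per group x time with 95%
#' CIs, and the within-/between-group contrasts with raw and
#' Sidak-adjusted p-values.
#'
#' @slot model the underlying fit (a \code{merMod}, or \code{lm} in the
#'   degenerate zero-variance fallback).
#' @slot fixedEffects named numeric vector of fixed-effect estimates.
#' @slot vcovFixed covariance matrix of the fixed effects.
#' @slot sigmaB2,sigmaE2 random-intercept and residual variances.
#' @slot adjustedMeans data.frame (group, time, estimate, se, lo, hi).
#' @slot contrasts data.frame of contrasts (see [modelContrasts()]).
#' @slot familySize Sidak family size m used for adjustment.
#' @slot groups group labels in model order (reference first).
#' @slot response label of the response cell (region x layer).
#' @slot converged logical.
#' @seealso [fitGroupTimeModel()], [modelContrasts()], [sidakAdjust()]
#' @export
setClass("T2ModelFit",
    representation(
        model         = "ANY",
        fixedEffects  = "numeric",
        vcovFixed     = "matrix",
        sigmaB2       = "numeric",
        sigmaE2       = "numeric",
        adjustedMeans = "data.frame",
        contrasts     = "data.frame",
        familySize    = "integer",
        groups        = "character",
        response      = "character",
        converged     = "logical"))
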