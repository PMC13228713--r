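#' Accessors for image-grid objects
#'
#' Every image-like object (\linkS4class{EchoSeries},
#' \linkS4class{CartilageMask}, \linkS4class{LaminarMask},
#' \linkS4class{T2Map}) carries the same voxel geometry; these generics
#' expose it without slot access.
#'
#' @param x an image-grid object.
#' @return \code{pixelSize}, \code{sliceThickness}: a single numeric
#'   (mm); \code{affineMatrix}: a 4x4 matrix; \code{gridDim}: integer
#'   (slices, rows, cols).
#' @name grid-accessors
#' @aliases pixelSize sliceThickness affineMatrix gridDim
#' @examples
#' sp <- phantomSpec(dim = c(1, 48, 48), boneRadius = 12, sigma = 0)
#' ph <- generatePhantom(sp, seed = 1)
#' pixelSize(ph$series)
#' gridDim(ph$mask)
NULL

#' @rdname grid-accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname grid-accessors
#' @export
setGeneric("sliceThickness", function(x) standardGeneric("sliceThickness"))
#' @rdname grid-accessors
#' @export
setGeneric("affineMatrix", function(x) standardGeneric("affineMatrix"))
#' @rdname grid-accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname grid-accessors
setMethod("pixelSize", "ImageGrid", function(x) x@pixelSize)
#' @rdname grid-accessors
setMethod("sliceThickness", "ImageGrid", function(x) x@sliceThickness)
#' @rdname grid-accessors
setMethod("affineMatrix", "ImageGrid", function(x) x@affine)

setMethod("gridDim", "EchoSeries", function(x) dim(x@intensities)[-1L])
setMethod("gridDim", "CartilageMask", function(x) dim(x@labels))
setMethod("gridDim", "LaminarMask", function(x) dim(x@codes))
setMethod("gridDim", "T2Map", function(x) dim(x@t2))

#' @describeIn EchoSeries-class echo times (ms), one per echo volume.
#' @param x,object an \code{EchoSeries}.
#' @export
setGeneric("echoTimes", function(x) standardGeneric("echoTimes"))
setMethod("echoTimes", "EchoSeries", function(x) x@echoTimes)

#' @describeIn EchoSeries-class the 4-D intensity array
#'   \code{[echo, slice, row, col]}.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
setMethod("intensities", "EchoSeries", function(x) x@intensities)

#' @describeIn CartilageMask-class the 3-D integer label volume.
#' @param x,object a \code{CartilageMask}.
#' @export
setGeneric("labelVolume", function(x) standardGeneric("labelVolume"))
setMethod("labelVolume", "CartilageMask", function(x) x@labels)

#' @describeIn CartilageMask-class the named label dictionary.
#' @export
setGeneric("labelDict", function(x) standardGeneric("labelDict"))
setMethod("labelDict", "CartilageMask", function(x) x@labelDict)

#' @describeIn CartilageMask-class cartilage region labels (>= 2) present
#'   in the dictionary.
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))
setMethod("regionLabels", "CartilageMask",
    function(x) x@labelDict[x@labelDict >= 2L])

#' @describeIn LaminarMask-class 3-D laminar code array
#'   (0 none, 1 superficial, 2 deep).
#' @param x,object a \code{LaminarMask}.
#' @export
setGeneric("laminarCodes", function(x) standardGeneric("laminarCodes"))
setMethod("laminarCodes", "LaminarMask", function(x) x@codes)

#' @describeIn LaminarMask-class 3-D region label array carried through
#'   the split.
#' @export
setGeneric("laminarRegions", function(x) standardGeneric("laminarRegions"))
setMethod("laminarRegions", "LaminarMask", function(x) x@regions)

#' Accessors for T2Map objects
#'
#' @param x a \linkS4class{T2Map}.
#' @return 3-D arrays: fitted T2 (ms), PD, residual sum of squares
#'   (each \code{NA} where invalid), and the logical validity mask.
#' @name T2Map-accessors
#' @aliases t2Values pdValues rssValues validMask
NULL

#' @rdname T2Map-accessors
#' @export
setGeneric("t2Values", function(x) standardGeneric("t2Values"))
setMethod("t2Values", "T2Map", function(x) x@t2)
#' @rdname T2Map-accessors
#' @export
setGeneric("pdValues", function(x) standardGeneric("pdValues"))
setMethod("pdValues", "T2Map", function(x) x@pd)
#' @rdname T2Map-accessors
#' @export
setGeneric("rssValues", function(x) standardGeneric("rssValues"))
setMethod("rssValues", "T2Map", function(x) x@rss)
#' @rdname T2Map-accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
setMethod("validMask", "T2Map", function(x) x@valid)

#' Accessors for fitted group-by-time models
#'
#' @param x a \linkS4class{T2ModelFit}.
#' @name T2ModelFit-accessors
#' @aliases fixedEffects varianceComponents adjustedMeans contrastTable
NULL

#' @rdname T2ModelFit-accessors
#' @export
setGeneric("fixedEffects", function(x) standardGeneric("fixedEffects"))
setMethod("fixedEffects", "T2ModelFit", function(x) x@fixedEffects)
#' @rdname T2ModelFit-accessors
#' @export
setGeneric("varianceComponents",
    function(x) standardGeneric("varianceComponents"))
setMethod("varianceComponents", "T2ModelFit",
    function(x) c(sigmaB2 = x@sigmaB2, sigmaE2 = x@sigmaE2))
#' @rdname T2ModelFit-accessors
#' @export
setGeneric("adjustedMeans", function(x) standardGeneric("adjustedMeans"))
setMethod("adjustedMeans", "T2ModelFit", function(x) x@adjustedMeans)
#' @rdname T2ModelFit-accessors
#' @export
setGeneric("contrastTable", function(x) standardGeneric("contrastTable"))
setMethod("contrastTable", "T2ModelFit", function(x) x@contrasts)

setMethod("show", "EchoSeries", function(object) {
    d <- dim(object@intensities)
    cat(sprintf("EchoSeries: %d echoes, grid %d x %d x %d (slice x row x col)\n",
        d[1], d[2], d[3], d[4]))
    cat(sprintf("  TE (ms): %s\n", paste(format(object@echoTimes), collapse = ", ")))
    cat(sprintf("  pixel %.4g mm, slice %.4g mm\n",
        object@pixelSize, object@sliceThickness))
})

setMethod("show", "CartilageMask", function(object) {
    d <- dim(object@labels)
    cat(sprintf("CartilageMask: grid %d x %d x %d\n", d[1], d[2], d[3]))
    tab <- table(factor(object@labels, levels = object@labelDict,
        labels = names(object@labelDict)))
    tab <- tab[tab > 0]
    cat("  voxels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "LaminarMask", function(object) {
    cat(sprintf(
        "LaminarMask: %d superficial, %d deep voxels over %d region(s)\n",
        sum(object@codes == 1L), sum(object@codes == 2L),
        length(setdiff(unique(as.integer(object@regions)), 0L))))
})

setMethod("show", "T2Map", function(object) {
    d <- dim(object@t2)
    v <- object@valid
    cat(sprintf("T2Map: grid %d x %d x %d, %d valid voxels\n",
        d[1], d[2], d[3], sum(v)))
    if (any(v))
        cat(sprintf("  T2 (valid): median %.2f ms [%.2f, %.2f]\n",
            stats::median(object@t2[v]), min(object@t2[v]), max(object@t2[v])))
})

setMethod("show", "PhantomSpec", function(object) {
    cat(sprintf("PhantomSpec (%s): grid %s, pixel %.4g mm, shell %.3g mm\n",
        object@geometry, paste(object@dim, collapse = " x "),
        object@pixelSize, object@shellThickness))
    cat(sprintf("  T2 sup/deep %.1f/%.1f ms, PD %.4g, alpha %.3g, sigma %.3g\n",
        object@t2Superficial, object@t2Deep, object@pd,
        object@alpha, object@sigma))
})

setMethod("show", "CohortSpec", function(object) {
    cat(sprintf("CohortSpec: %s; sigma_b %.3g, sigma_e %.3g\n",
        paste(sprintf("%s n=%d", names(object@groupSizes), object@groupSizes),
            collapse = ", "),
        object@sigmaB, object@sigmaE))
    cat(sprintf("  %d cell means over %d region(s) x %d layer(s)\n",
        nrow(object@means), length(unique(object@means$region)),
        length(unique(object@means$layer))))
})

setMethod("show", "T2ModelFit", function(object) {
    cat(sprintf("T2ModelFit [%s]: groups %s\n", object@response,
        paste(object@groups, collapse = ", ")))
    cat(sprintf("  sigma_b^2 = %.4g, sigma_e^2 = %.4g, Sidak m = %d\n",
        object@sigmaB2, object@sigmaE2, object@familySize))
    print(object@contrasts, row.names = FALSE, digits = 4)
})
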