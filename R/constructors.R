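#' Construct an EchoSeries
#'
#' @param intensities 4-D numeric array \code{[echo, slice, row, col]}.
#' @param echoTimes echo times (ms), strictly increasing, one per echo.
#' @param pixelSize in-plane pixel size (mm).
#' @param sliceThickness slice thickness (mm).
#' @param affine optional 4x4 voxel-to-world transform; defaults to the
#'   diagonal transform implied by the voxel sizes.
#' @return an \linkS4class{EchoSeries}.
#' @examples
#' te <- c(11.1, 22.2, 33.3, 44.4, 55.5, 66.6, 77.7)
#' arr <- array(exp(-outer(te, rep(1, 4 * 4 * 4)) / 50), c(7, 4, 4, 4))
#' EchoSeries(arr, te, pixelSize = 0.365, sliceThickness = 3)
#' @export
EchoSeries <- function(intensities, echoTimes, pixelSize, sliceThickness,
                       affine = NULL) {
    if (is.null(affine))
        affine <- defaultAffine(pixelSize, sliceThickness)
    new("EchoSeries", intensities = intensities,
        echoTimes = as.numeric(echoTimes),
        pixelSize = as.numeric(pixelSize),
        sliceThickness = as.numeric(sliceThickness),
        affine = affine)
}

#' Construct a CartilageMask
#'
#' @param labels 3-D integer array \code{[slice, row, col]} using the
#'   convention 0 = background, 1 = bone, >= 2 = cartilage regions.
#' @param pixelSize,sliceThickness,affine grid geometry, as for
#'   [EchoSeries()].
#' @param labelDict named integer label dictionary; defaults to the
#'   six-region knee dictionary (medial/lateral femur and tibia,
#'   patella, trochlea).
#' @return a \linkS4class{CartilageMask}.
#' @export
CartilageMask <- function(labels, pixelSize, sliceThickness,
                          affine = NULL, labelDict = defaultLabelDict()) {
    if (is.null(affine))
        affine <- defaultAffine(pixelSize, sliceThickness)
    storage.mode(labels) <- "integer"
    new("CartilageMask", labels = labels, labelDict = labelDict,
        pixelSize = as.numeric(pixelSize),
        sliceThickness = as.numeric(sliceThickness),
        affine = affine)
}
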