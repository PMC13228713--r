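## Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
##
## Only what this package emits is supported: 3-D and 4-D volumes,
## float32/float64/int16/int32/uint8 storage, pixdim, and the sform
## affine.  NIfTI stores x (column) fastest; package arrays are
## [slice, row, col] (3-D) or [echo, slice, row, col] (4-D), so axes are
## permuted on the way in and out.

.niftiDatatypes <- c(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L,
    float64 = 64L)
.niftiBitpix <- c(uint8 = 8L, int16 = 16L, int32 = 32L, float32 = 32L,
    float64 = 64L)

.openConn <- function(path, mode) {
    if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a volume as NIfTI-1
#'
#' @param data 3-D array \code{[slice, row, col]} or 4-D array
#'   \code{[echo, slice, row, col]}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @param pixelSize in-plane pixel size (mm).
#' @param sliceThickness slice thickness (mm).
#' @param affine optional 4x4 (row, col, slice) voxel-to-world
#'   transform; stored as the sform.
#' @param datatype one of \code{"float32"}, \code{"float64"},
#'   \code{"int16"}, \code{"int32"}, \code{"uint8"}.
#' @return the path, invisibly.
#' @seealso [readNifti()]
#' @export
writeNifti <- function(data, path, pixelSize = 1, sliceThickness = 1,
                       affine = NULL, datatype = "float32") {
    nd <- length(dim(data))
    stopifnot(nd %in% c(3L, 4L), datatype %in% names(.niftiDatatypes))
    if (is.null(affine))
        affine <- defaultAffine(pixelSize, sliceThickness)
    d <- dim(data)
    ## NIfTI dims (x = col, y = row, z = slice, t = echo)
    ndim <- if (nd == 3L) c(d[3L], d[2L], d[1L], 1L)
        else c(d[4L], d[3L], d[2L], d[1L])
    perm <- if (nd == 3L) c(3L, 2L, 1L) else c(4L, 3L, 2L, 1L)
    vec <- as.vector(aperm(data, perm))

    con <- .openConn(path, "wb")
    on.exit(close(con))
    wInt <- function(x, size) writeBin(as.integer(x), con, size = size,
        endian = "little")
    wFlt <- function(x) writeBin(as.numeric(x), con, size = 4L,
        endian = "little")
    wRaw <- function(n) writeBin(raw(n), con)

    wInt(348L, 4L)                       # sizeof_hdr
    wRaw(36L)                            # data_type..dim_info
    wInt(c(if (nd == 3L) 3L else 4L, ndim, 1L, 1L, 1L), 2L)  # dim[8]
    wRaw(14L)                            # intent_p1..intent_code
    wInt(.niftiDatatypes[[datatype]], 2L)
    wInt(.niftiBitpix[[datatype]], 2L)
    wInt(0L, 2L)                         # slice_start
    wFlt(c(1, pixelSize, pixelSize, sliceThickness, 1, 1, 1, 1))  # pixdim
    wFlt(352)                            # vox_offset
    wFlt(c(1, 0))                        # scl_slope, scl_inter
    wRaw(8L)                             # slice_end..glmin
    wRaw(80L + 24L)                      # descrip + aux_file
    wInt(c(0L, 1L), 2L)                  # qform_code, sform_code = 1
    wFlt(rep(0, 6))                      # quatern b,c,d + offsets
    S <- affine[, c(2L, 1L, 3L, 4L)]     # (x=col, y=row, z=slice) order
    wFlt(S[1L, ]); wFlt(S[2L, ]); wFlt(S[3L, ])
    wRaw(16L)                            # intent_name
    writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
    wRaw(4L)                             # extension flag

    if (datatype %in% c("float32", "float64"))
        writeBin(as.numeric(vec), con,
            size = if (datatype == "float32") 4L else 8L, endian = "little")
    else
        writeBin(as.integer(vec), con,
            size = .niftiBitpix[[datatype]] / 8L, endian = "little")
    invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path a \code{.nii} or \code{.nii.gz} file.
#' @return list with \code{data} (3-D \code{[slice, row, col]} or 4-D
#'   \code{[echo, slice, row, col]} array), \code{pixelSize},
#'   \code{sliceThickness} and \code{affine} (4x4, (row, col, slice)
#'   convention).
#' @export
readNifti <- function(path) {
    con <- .openConn(path, "rb")
    on.exit(close(con))
    endian <- "little"
    sz <- readBin(con, "integer", 1L, 4L, endian = endian)
    if (sz != 348L) {
        endian <- "big"
        if (.swapInt(sz) != 348L) stop("not a NIfTI-1 file: ", path)
    }
    rInt <- function(n, size) readBin(con, "integer", n, size,
        endian = endian)
    rFlt <- function(n, size = 4L) readBin(con, "double", n, size,
        endian = endian)
    readBin(con, "raw", 36L)
    dims <- rInt(8L, 2L)
    readBin(con, "raw", 14L)
    datatype <- rInt(1L, 2L)
    rInt(1L, 2L); rInt(1L, 2L)           # bitpix, slice_start
    pixdim <- rFlt(8L)
    voxOffset <- rFlt(1L)
    sclSlope <- rFlt(1L); sclInter <- rFlt(1L)
    readBin(con, "raw", 8L + 80L + 24L)
    rInt(2L, 2L)                         # qform_code, sform_code
    rFlt(6L)
    S <- rbind(rFlt(4L), rFlt(4L), rFlt(4L))
    readBin(con, "raw", 16L + 4L + 4L)
    nd <- dims[1L]
    if (!nd %in% c(3L, 4L)) stop("unsupported NIfTI dimensionality: ", nd)
    nxyz <- dims[2:(1L + nd)]
    n <- prod(nxyz)
    skip <- voxOffset - 352
    if (skip > 0) readBin(con, "raw", skip)
    vec <- switch(as.character(datatype),
        "2" = rInt(n, 1L), "4" = rInt(n, 2L), "8" = rInt(n, 4L),
        "16" = rFlt(n, 4L), "64" = rFlt(n, 8L),
        stop("unsupported NIfTI datatype: ", datatype))
    if (is.finite(sclSlope) && sclSlope != 0 &&
        !(sclSlope == 1 && sclInter == 0))
        vec <- vec * sclSlope + sclInter
    arr <- array(vec, nxyz)              # x fastest
    perm <- if (nd == 3L) c(3L, 2L, 1L) else c(4L, 3L, 2L, 1L)
    arr <- aperm(arr, perm)
    affine <- rbind(S[, c(2L, 1L, 3L, 4L)], c(0, 0, 0, 1))
    list(data = arr, pixelSize = pixdim[2L], sliceThickness = pixdim[4L],
        affine = affine)
}

.swapInt <- function(x) {
    b <- writeBin(as.integer(x), raw(), size = 4L, endian = "little")
    readBin(rev(b), "integer", 1L, 4L, endian = "little")
}

#' Write / read an EchoSeries with its JSON sidecar
#'
#' The echo stack goes to a single 4-D NIfTI-1 file; echo times (ms) and
#' voxel geometry go to a JSON sidecar next to it (same path with
#' \code{.json} substituted for the image extension).
#'
#' @param series an \linkS4class{EchoSeries}.
#' @param path image path (\code{.nii} or \code{.nii.gz}).
#' @return \code{readEchoSeries}: the reconstructed
#'   \linkS4class{EchoSeries}.
#' @name echoseries-io
#' @export
writeEchoSeries <- function(series, path) {
    stopifnot(is(series, "EchoSeries"))
    writeNifti(series@intensities, path, series@pixelSize,
        series@sliceThickness, series@affine, datatype = "float64")
    side <- sub("\\.nii(\\.gz)?$", ".json", path)
    jsonlite::write_json(list(
        EchoTimes = series@echoTimes,
        PixelSize = series@pixelSize,
        SliceThickness = series@sliceThickness), side,
        auto_unbox = FALSE, digits = NA)
    invisible(path)
}

#' @rdname echoseries-io
#' @export
readEchoSeries <- function(path) {
    vol <- readNifti(path)
    side <- sub("\\.nii(\\.gz)?$", ".json", path)
    if (!file.exists(side))
        stop("echo-time sidecar not found: ", side)
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    EchoSeries(vol$data, meta$EchoTimes, meta$PixelSize,
        meta$SliceThickness, vol$affine)
}

#' Write / read a CartilageMask with its label dictionary sidecar
#'
#' @param mask a \linkS4class{CartilageMask}.
#' @param path image path (\code{.nii} or \code{.nii.gz}); the label
#'   dictionary goes to a JSON sidecar alongside.
#' @return \code{readMask}: the reconstructed
#'   \linkS4class{CartilageMask}.
#' @name mask-io
#' @export
writeMask <- function(mask, path) {
    stopifnot(is(mask, "CartilageMask"))
    writeNifti(mask@labels, path, mask@pixelSize, mask@sliceThickness,
        mask@affine, datatype = "int32")
    side <- sub("\\.nii(\\.gz)?$", ".json", path)
    jsonlite::write_json(list(
        Labels = as.list(mask@labelDict),
        PixelSize = mask@pixelSize,
        SliceThickness = mask@sliceThickness), side,
        auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname mask-io
#' @export
readMask <- function(path) {
    vol <- readNifti(path)
    side <- sub("\\.nii(\\.gz)?$", ".json", path)
    if (!file.exists(side))
        stop("label dictionary sidecar not found: ", side)
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    dict <- unlist(meta$Labels)
    CartilageMask(vol$data, meta$PixelSize, meta$SliceThickness,
        vol$affine, labelDict = stats::setNames(as.integer(dict),
            names(dict)))
}
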