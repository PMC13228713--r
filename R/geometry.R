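## Cartilage geometry: boundary sets, laminar splitting, slice
## selection, grid resampling and thickness morphometry.
##
## All distances are computed in-plane (2-D, per sagittal slice), centre
## to centre, in mm: the 3 mm slice thickness dwarfs the 0.365 mm pixel,
## so 3-D distances would be dominated by slice anisotropy.

## --- internal: 4-connected in-plane adjacency -------------------------

## Voxels of 'sourceMask' 4-adjacent (in-plane) to a TRUE of 'targetMask'.
.adjacent4 <- function(sourceMask, targetMask) {
    R <- nrow(sourceMask); C <- ncol(sourceMask)
    near <- matrix(FALSE, R, C)
    near[-R, ] <- near[-R, ] | targetMask[-1, ]   # neighbour below
    near[-1, ] <- near[-1, ] | targetMask[-R, ]   # neighbour above
    near[, -C] <- near[, -C] | targetMask[, -1]   # neighbour right
    near[, -1] <- near[, -1] | targetMask[, -C]   # neighbour left
    sourceMask & near
}

## Boundary voxels of one region on one slice: articular = adjacent to
## background (0), bone-facing = adjacent to bone (1).
.sliceBoundary <- function(lab, region) {
    reg <- lab == region
    list(
        articular = which(.adjacent4(reg, lab == 0L), arr.ind = TRUE),
        bone      = which(.adjacent4(reg, lab == 1L), arr.ind = TRUE))
}

## --- internal: exact Euclidean distance transform ---------------------

## 1-D squared-distance lower envelope (Felzenszwalb & Huttenlocher).
.dt1d <- function(f) {
    n <- length(f)
    idx <- which(is.finite(f))
    if (!length(idx)) return(rep(Inf, n))
    d <- numeric(n)
    v <- integer(n); z <- numeric(n + 1L)
    k <- 0L
    for (q in idx) {
        if (k > 0L) {
            repeat {
                s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) /
                     (2 * q - 2 * v[k])
                if (s <= z[k]) { k <- k - 1L; if (k == 0L) break }
                else break
            }
        }
        k <- k + 1L
        if (k == 1L) { v[1L] <- q; z[1L] <- -Inf; z[2L] <- Inf }
        else { v[k] <- q; z[k] <- s; z[k + 1L] <- Inf }
    }
    j <- 1L
    for (q in seq_len(n)) {
        while (z[j + 1L] < q) j <- j + 1L
        d[q] <- (q - v[j])^2 + f[v[j]]
    }
    d
}

## Exact squared EDT (pixel^2) of a 2-D site mask.
.edt2 <- function(sites) {
    f <- matrix(Inf, nrow(sites), ncol(sites))
    f[sites] <- 0
    for (j in seq_len(ncol(f))) f[, j] <- .dt1d(f[, j])
    for (i in seq_len(nrow(f))) f[i, ] <- .dt1d(f[i, ])
    f
}

## In-plane distances (pixel units, squared) from every voxel of one
## region to its articular and bone boundary sets, computed on the
## region's bounding box (all sites are region voxels, so cropping is
## exact).  Returns full-slice matrices, Inf outside the box.
.regionDistances2 <- function(sl, reg) {
    inReg <- sl == reg
    b <- .sliceBoundary(sl, reg)
    if (nrow(b$articular) == 0L || nrow(b$bone) == 0L)
        return(NULL)
    rr <- range(which(rowSums(inReg) > 0L))
    cc <- range(which(colSums(inReg) > 0L))
    subDim <- c(rr[2L] - rr[1L] + 1L, cc[2L] - cc[1L] + 1L)
    art <- bone <- matrix(FALSE, subDim[1L], subDim[2L])
    art[cbind(b$articular[, 1L] - rr[1L] + 1L,
              b$articular[, 2L] - cc[1L] + 1L)] <- TRUE
    bone[cbind(b$bone[, 1L] - rr[1L] + 1L,
               b$bone[, 2L] - cc[1L] + 1L)] <- TRUE
    dArt <- dBone <- matrix(Inf, nrow(sl), ncol(sl))
    dArt[rr[1L]:rr[2L], cc[1L]:cc[2L]] <- .edt2(art)
    dBone[rr[1L]:rr[2L], cc[1L]:cc[2L]] <- .edt2(bone)
    list(art = dArt, bone = dBone)
}

## --- public operations ------------------------------------------------

#' Articular and bone-facing boundary sets of a cartilage region
#'
#' The articular set holds the region's voxels 4-adjacent (in-plane) to
#' background; the bone set holds those 4-adjacent to the bone label.  A
#' voxel may belong to both (a single-voxel-thick sheet is entirely in
#' both sets).
#'
#' @param mask a \linkS4class{CartilageMask}.
#' @param region cartilage region label (>= 2).
#' @return a list with integer coordinate matrices \code{articular} and
#'   \code{bone}; columns \code{slice}, \code{row}, \code{col}, 0-based.
#' @seealso [laminarSplit()], [regionalThickness()]
#' @export
boundarySets <- function(mask, region) {
    stopifnot(is(mask, "CartilageMask"))
    lab <- mask@labels
    if (!any(lab == region))
        stop(sprintf("region %d not present in mask", region))
    art <- bone <- vector("list", dim(lab)[1L])
    for (s in seq_len(dim(lab)[1L])) {
        b <- .sliceBoundary(lab[s, , ], region)
        if (nrow(b$articular))
            art[[s]] <- cbind(slice = s - 1L, row = b$articular[, 1L] - 1L,
                col = b$articular[, 2L] - 1L)
        if (nrow(b$bone))
            bone[[s]] <- cbind(slice = s - 1L, row = b$bone[, 1L] - 1L,
                col = b$bone[, 2L] - 1L)
    }
    art <- do.call(rbind, art); bone <- do.call(rbind, bone)
    if (is.null(art) || is.null(bone))
        stop(sprintf(
            "degenerate geometry: region %d has no %s-adjacent voxels",
            region, if (is.null(art)) "background" else "bone"))
    list(articular = art, bone = bone)
}

#' Split cartilage regions into superficial and deep laminae
#'
#' For each cartilage voxel the minimum in-plane Euclidean distance (mm,
#' centre to centre) to the articular boundary set and to the
#' bone-facing boundary set is computed with an exact distance
#' transform; the voxel is superficial iff its articular distance is
#' less than or equal to its bone distance (ties are superficial, a
#' deterministic reading of an equidistant laminar border), deep
#' otherwise.  The partition is exhaustive and disjoint over each
#' region.
#'
#' @param mask a \linkS4class{CartilageMask}.
#' @param regions cartilage labels to split; default all regions in the
#'   dictionary that are present.
#' @return a \linkS4class{LaminarMask}.
#' @examples
#' ph <- generatePhantom(phantomSpec(dim = c(1, 48, 48), boneRadius = 12),
#'     seed = 1)
#' lam <- laminarSplit(ph$mask)
#' table(laminarCodes(lam))
#' @export
laminarSplit <- function(mask, regions = NULL) {
    stopifnot(is(mask, "CartilageMask"))
    lab <- mask@labels
    if (is.null(regions)) {
        regions <- regionLabels(mask)
        regions <- regions[regions %in% unique(as.integer(lab))]
    }
    if (!length(regions))
        stop("no cartilage regions to split")
    codes <- array(0L, dim(lab))
    regOut <- array(0L, dim(lab))
    for (s in seq_len(dim(lab)[1L])) {
        sl <- lab[s, , ]
        for (reg in regions) {
            inReg <- sl == reg
            if (!any(inReg)) next
            d2 <- .regionDistances2(sl, reg)
            if (is.null(d2))
                stop(sprintf(
                    "degenerate geometry: region %d on slice %d lacks a boundary",
                    reg, s - 1L))
            sup <- inReg & (d2$art <= d2$bone)
            sliceCodes <- codes[s, , ]
            sliceRegs <- regOut[s, , ]
            sliceCodes[sup] <- 1L
            sliceCodes[inReg & !sup] <- 2L
            sliceRegs[inReg] <- reg
            codes[s, , ] <- sliceCodes
            regOut[s, , ] <- sliceRegs
        }
    }
    new("LaminarMask", codes = codes, regions = regOut,
        pixelSize = mask@pixelSize, sliceThickness = mask@sliceThickness,
        affine = mask@affine)
}

#' Select load-bearing slices around a central slice
#'
#' Returns the \code{nSlices} consecutive slice indices centred on the
#' landmark central slice (the slice through the distal femoral apex in
#' the source protocol): 3 slices for the T2 analysis, 7 for thickness.
#' Slice indices are 0-based and the range is inclusive.
#'
#' @param mask a \linkS4class{CartilageMask} (supplies the volume size),
#'   or an integer giving the number of slices.
#' @param centralSlice 0-based central slice index.
#' @param nSlices odd slice count.
#' @return integer vector of 0-based slice indices.
#' @examples
#' selectLoadbearingSlices(31L, centralSlice = 15, nSlices = 3)
#' selectLoadbearingSlices(31L, centralSlice = 15, nSlices = 7)
#' @export
selectLoadbearingSlices <- function(mask, centralSlice, nSlices = 3L) {
    nTotal <- if (is(mask, "CartilageMask")) gridDim(mask)[1L]
        else as.integer(mask)
    if (nSlices %% 2L != 1L)
        stop("'nSlices' must be odd")
    half <- (nSlices - 1L) %/% 2L
    lo <- as.integer(centralSlice) - half
    hi <- as.integer(centralSlice) + half
    if (lo < 0L || hi > nTotal - 1L)
        stop(sprintf(
            "slice range [%d, %d] exceeds the volume (0..%d)", lo, hi,
            nTotal - 1L))
    seq.int(lo, hi)
}

#' Resample a label mask onto another voxel grid
#'
#' Nearest-neighbour label resampling through the world-coordinate
#' mapping of the two affines: each target voxel centre is mapped to
#' world mm, back into source voxel indices, and takes the label of the
#' nearest source voxel (0 outside the source volume).  Labels are never
#' interpolated.  This is the rigid-grid stand-in for the anatomical
#' registration between the T2 grid and the finer morphometry grid.
#'
#' @param mask a \linkS4class{CartilageMask}.
#' @param dim target grid shape (slices, rows, cols).
#' @param pixelSize,sliceThickness target voxel geometry (mm).
#' @param affine optional 4x4 target voxel-to-world transform; defaults
#'   to the diagonal transform of the target voxel sizes.
#' @return a \linkS4class{CartilageMask} on the target grid.
#' @export
resampleMask <- function(mask, dim, pixelSize, sliceThickness,
                         affine = NULL) {
    stopifnot(is(mask, "CartilageMask"))
    dim <- as.integer(dim)
    if (is.null(affine))
        affine <- defaultAffine(pixelSize, sliceThickness)
    Ainv <- tryCatch(solve(mask@affine),
        error = function(e) stop("singular source affine"))
    if (abs(det(affine)) < .Machine$double.eps)
        stop("singular target affine")
    ## 0-based target indices (row, col, slice order irrelevant: build
    ## the full index grid once)
    idx <- as.matrix(expand.grid(
        row = seq_len(dim[2L]) - 1L,
        col = seq_len(dim[3L]) - 1L,
        slice = seq_len(dim[1L]) - 1L))
    world <- affine %*% rbind(t(idx), 1)
    src <- Ainv %*% world
    si <- round(src[1L, ]); sj <- round(src[2L, ]); sk <- round(src[3L, ])
    d <- base::dim(mask@labels)
    inside <- si >= 0 & si <= d[2L] - 1L & sj >= 0 & sj <= d[3L] - 1L &
              sk >= 0 & sk <= d[1L] - 1L
    out <- integer(nrow(idx))
    lin <- (sk[inside]) + d[1L] * (si[inside]) + d[1L] * d[2L] * (sj[inside])
    out[inside] <- as.integer(mask@labels)[lin + 1L]
    labels <- array(0L, dim)
    labels[cbind(idx[, "slice"], idx[, "row"], idx[, "col"]) + 1L] <- out
    CartilageMask(labels, pixelSize, sliceThickness, affine,
        labelDict = mask@labelDict)
}

#' Regional cartilage thickness over a slice range
#'
#' Local thickness at each cartilage voxel is
#' \eqn{t(v) = d_{art}(v) + d_{bone}(v) + s}, the sum of the in-plane
#' distances (mm) to the articular and bone boundary sets plus one pixel
#' \eqn{s}; on a slab of k voxel rows this is exactly \eqn{k s} for
#' every voxel.  The regional thickness is the mean of \eqn{t(v)} over
#' the region's voxels in the slice range.
#'
#' @param mask a \linkS4class{CartilageMask}.
#' @param region cartilage region label (>= 2).
#' @param slices 0-based slice indices (see
#'   [selectLoadbearingSlices()]); default all slices.
#' @return one-row data.frame: \code{region}, \code{sliceFirst},
#'   \code{sliceLast}, \code{meanThickness} (mm), \code{nVoxels}.
#' @export
regionalThickness <- function(mask, region, slices = NULL) {
    stopifnot(is(mask, "CartilageMask"))
    lab <- mask@labels
    if (is.null(slices)) slices <- seq_len(dim(lab)[1L]) - 1L
    if (any(slices < 0L) || any(slices > dim(lab)[1L] - 1L))
        stop("slice range exceeds the volume")
    s <- mask@pixelSize
    tvals <- numeric(0)
    for (sl in slices) {
        m <- lab[sl + 1L, , ]
        inReg <- m == region
        if (!any(inReg)) next
        d2 <- .regionDistances2(m, region)
        if (is.null(d2))
            stop(sprintf(
                "degenerate geometry: region %d on slice %d lacks a boundary",
                region, sl))
        dArt <- sqrt(d2$art[inReg]) * s
        dBone <- sqrt(d2$bone[inReg]) * s
        tvals <- c(tvals, dArt + dBone + s)
    }
    if (!length(tvals))
        stop(sprintf("region %d is empty on the requested slices", region))
    regName <- names(mask@labelDict)[match(region, mask@labelDict)]
    data.frame(
        region = if (is.na(regName)) as.character(region) else regName,
        sliceFirst = min(slices), sliceLast = max(slices),
        meanThickness = mean(tvals), nVoxels = length(tvals),
        stringsAsFactors = FALSE)
}
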