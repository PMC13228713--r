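## Shared fixtures, all built in code.

TE7 <- c(11.1, 22.2, 33.3, 44.4, 55.5, 66.6, 77.7)

## A slab mask: background rows on top, k cartilage rows, bone below.
slabMask <- function(k, nSlices = 1L, rows = k + 6L, cols = 12L,
                     pixelSize = 0.365, region = 2L) {
    top <- 3L
    lab <- matrix(0L, rows, cols)
    lab[top + seq_len(k), ] <- region
    lab[(top + k + 1L):rows, ] <- 1L
    arr <- array(rep(lab, each = nSlices), c(nSlices, rows, cols))
    CartilageMask(arr, pixelSize = pixelSize, sliceThickness = 3,
        labelDict = c(background = 0L, bone = 1L, slab = region))
}

## Brute-force boundary scan: explicit loops, independent of the
## package's vectorized adjacency.
bruteBoundary <- function(lab, region) {
    art <- bone <- NULL
    for (r in seq_len(nrow(lab))) for (c in seq_len(ncol(lab))) {
        if (lab[r, c] != region) next
        nb <- c(
            if (r > 1) lab[r - 1, c], if (r < nrow(lab)) lab[r + 1, c],
            if (c > 1) lab[r, c - 1], if (c < ncol(lab)) lab[r, c + 1])
        if (any(nb == 0L)) art <- rbind(art, c(r, c))
        if (any(nb == 1L)) bone <- rbind(bone, c(r, c))
    }
    list(articular = art, bone = bone)
}

## Brute-force laminar rule: per-voxel nearest-neighbour comparison.
bruteLaminar <- function(lab, region) {
    b <- bruteBoundary(lab, region)
    out <- matrix(0L, nrow(lab), ncol(lab))
    for (r in seq_len(nrow(lab))) for (c in seq_len(ncol(lab))) {
        if (lab[r, c] != region) next
        dArt <- min((b$articular[, 1] - r)^2 + (b$articular[, 2] - c)^2)
        dBone <- min((b$bone[, 1] - r)^2 + (b$bone[, 2] - c)^2)
        out[r, c] <- if (dArt <= dBone) 1L else 2L
    }
    out
}

## Balanced noiseless table straight from a means data.frame.
noiselessTable <- function(means, nPerGroup = 4L) {
    spec <- cohortSpec(
        groupSizes = stats::setNames(rep(nPerGroup, length(unique(means$group))),
            unique(means$group)),
        means = means, sigmaB = 0, sigmaE = 0)
    generateCohort(spec, seed = 99L)
}

## One-cell means table for small statistical fixtures.
cellMeans <- function(prePost, region = "r", layer = "superficial") {
    ## prePost: named list group -> c(pre, post)
    do.call(rbind, lapply(names(prePost), function(g)
        data.frame(group = g, time = c("pre", "post"), region = region,
            layer = layer, mean = prePost[[g]], stringsAsFactors = FALSE)))
}
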