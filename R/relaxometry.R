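#' Options controlling the voxel-wise T2 fit
#'
#' @param t2Bounds lower/upper T2 bounds (ms).  The default 1-500 ms
#'   covers the physiologic cartilage range with wide margin; estimates
#'   that end on a bound are flagged not converged (and hence invalid).
#' @param maxIter maximum Levenberg-Marquardt iterations.
#' @param tol convergence tolerance: relative change in the residual sum
#'   of squares.
#' @param excludeFirst drop the first echo before fitting (default TRUE:
#'   the first echo of a MESE train is contaminated by stimulated
#'   echoes).
#' @param minSignal absolute floor on the mean included signal; voxels
#'   below it (or with any non-positive included echo) are returned
#'   invalid without fitting.
#' @return a list of class \code{FitOptions}.
#' @seealso [fitVoxel()], [fitMap()]
#' @export
fitOptions <- function(t2Bounds = c(1, 500), maxIter = 200L, tol = 1e-10,
                       excludeFirst = TRUE, minSignal = 0) {
    stopifnot(length(t2Bounds) == 2L, t2Bounds[1L] > 0,
        t2Bounds[2L] > t2Bounds[1L], maxIter >= 1L, tol > 0, minSignal >= 0)
    structure(list(t2Bounds = as.numeric(t2Bounds),
        maxIter = as.integer(maxIter), tol = tol,
        excludeFirst = isTRUE(excludeFirst), minSignal = minSignal),
        class = "FitOptions")
}

#' Log-linear initialization of the mono-exponential fit
#'
#' Ordinary least squares of \eqn{\ln S} on TE: the slope estimates
#' \eqn{-1/T2} and the intercept \eqn{\ln PD}.  Exact on noiseless
#' mono-exponential data, and the standard warm start for the
#' Levenberg-Marquardt refinement.
#'
#' @param signal intensity vector (one value per echo).
#' @param tes echo times (ms), same length.
#' @param t2Bounds T2 clamp range (ms).
#' @return list with \code{pd0} and \code{t20} (clamped to bounds).
#' @details With any non-positive signal the log is undefined; the
#'   initializer then falls back to \code{pd0 = max(signal)},
#'   \code{t20 =} midpoint of the bounds.  A non-negative slope (flat or
#'   rising signal) clamps \code{t20} to the upper bound.
#' @examples
#' loglinearInit(c(1000 * exp(-1), 1000 * exp(-2)), c(22.2, 44.4))$t20 # 22.2
#' @export
loglinearInit <- function(signal, tes, t2Bounds = c(1, 500)) {
    stopifnot(length(signal) == length(tes), length(signal) >= 2L)
    if (any(signal <= 0) || any(!is.finite(signal)))
        return(list(pd0 = max(signal, 0), t20 = mean(t2Bounds)))
    ls <- log(signal)
    slope <- stats::cov(tes, ls) / stats::var(tes)
    intercept <- mean(ls) - slope * mean(tes)
    t20 <- if (slope >= 0) t2Bounds[2L] else -1 / slope
    t20 <- min(max(t20, t2Bounds[1L]), t2Bounds[2L])
    list(pd0 = exp(intercept), t20 = t20)
}

#' Fit the mono-exponential decay in one voxel
#'
#' Levenberg-Marquardt minimization of
#' \eqn{\sum_k (S_k - PD e^{-TE_k/T2})^2} from the log-linear start,
#' after dropping the first echo when \code{excludeFirst} is on.  The
#' fit is declared converged when the relative change in RSS falls below
#' \code{tol} (or the gradient vanishes); it is valid when it converged
#' with T2 strictly inside the bounds and the signal passed the
#' minimum-signal rule.
#'
#' @param signal intensity vector, one value per echo.
#' @param tes echo times (ms), same length as \code{signal}.
#' @param options a [fitOptions()] list.
#' @return list (class \code{VoxelFit}): \code{t2}, \code{pd},
#'   \code{rss}, \code{converged}, \code{valid}, \code{nEchoes}.
#'   Degenerate inputs (too few usable echoes, sub-threshold signal)
#'   yield \code{valid = FALSE} with \code{NA} estimates — never an
#'   exception.
#' @examples
#' te <- c(11.1, 22.2, 33.3, 44.4, 55.5, 66.6, 77.7)
#' fitVoxel(signalModel(800, 45, te, echoIndex = seq_along(te)), te,
#'          fitOptions())$t2  # 45
#' @export
fitVoxel <- function(signal, tes, options = fitOptions()) {
    stopifnot(length(signal) == length(tes))
    invalid <- structure(list(t2 = NA_real_, pd = NA_real_, rss = NA_real_,
        converged = FALSE, valid = FALSE, nEchoes = 0L), class = "VoxelFit")
    if (options$excludeFirst && length(signal) > 1L) {
        signal <- signal[-1L]
        tes <- tes[-1L]
    }
    n <- length(signal)
    if (n < 3L) return(invalid)
    if (any(signal <= 0) || mean(signal) < options$minSignal) {
        invalid$nEchoes <- n
        return(invalid)
    }
    lb <- options$t2Bounds[1L]; ub <- options$t2Bounds[2L]
    init <- loglinearInit(signal, tes, options$t2Bounds)
    pd <- init$pd0; t2 <- init$t20
    resid <- signal - pd * exp(-tes / t2)
    rss <- sum(resid^2)
    lambda <- 1e-3
    converged <- FALSE
    for (it in seq_len(options$maxIter)) {
        e <- exp(-tes / t2)
        J <- cbind(e, pd * e * tes / t2^2)     # d model / d(PD, T2)
        g <- crossprod(J, resid)
        if (sqrt(sum(g^2)) < 1e-14 * (1 + rss)) { converged <- TRUE; break }
        JtJ <- crossprod(J)
        improved <- FALSE
        for (try in 1:30) {
            A <- JtJ + lambda * diag(diag(JtJ), 2L)
            step <- tryCatch(solve(A, g), error = function(err) NULL)
            if (!is.null(step)) {
                pdNew <- pd + step[1L]
                t2New <- min(max(t2 + step[2L], lb), ub)
                residNew <- signal - pdNew * exp(-tes / t2New)
                rssNew <- sum(residNew^2)
                if (is.finite(rssNew) && rssNew <= rss) {
                    relChange <- (rss - rssNew) / max(rss, .Machine$double.xmin)
                    pd <- pdNew; t2 <- t2New
                    resid <- residNew; rss <- rssNew
                    lambda <- max(lambda / 10, 1e-12)
                    improved <- TRUE
                    if (relChange < options$tol) converged <- TRUE
                    break
                }
            }
            lambda <- lambda * 10
        }
        if (!improved) { converged <- TRUE; break }  # stalled at a minimum
        if (converged) break
    }
    onBound <- t2 <= lb + 1e-12 || t2 >= ub - 1e-12
    if (onBound) converged <- FALSE
    structure(list(t2 = t2, pd = pd, rss = rss, converged = converged,
        valid = converged && !onBound && pd > 0, nEchoes = n),
        class = "VoxelFit")
}

#' Fit a voxel-wise T2 map over a cartilage mask
#'
#' Applies [fitVoxel()] to every cartilage voxel (labels >= 2) of the
#' mask, optionally restricted to a slice range and minus an exclusion
#' mask (e.g. voxels affected by chemical shift, flagged upstream).
#' Unmasked and failed voxels carry \code{NA} sentinels and are excluded
#' from every downstream mean.  Deterministic given its inputs.
#'
#' @param series an \linkS4class{EchoSeries}.
#' @param mask a \linkS4class{CartilageMask} on the same grid.
#' @param options a [fitOptions()] list.
#' @param slices optional 0-based slice indices to fit (default all).
#' @param exclude optional logical array \code{[slice, row, col]}; TRUE
#'   voxels are skipped.
#' @return a \linkS4class{T2Map}.
#' @examples
#' ph <- generatePhantom(phantomSpec(dim = c(1, 40, 40), boneRadius = 10),
#'     seed = 2)
#' fitMap(ph$series, ph$mask)
#' @export
fitMap <- function(series, mask, options = fitOptions(), slices = NULL,
                   exclude = NULL) {
    stopifnot(is(series, "EchoSeries"), is(mask, "CartilageMask"))
    d <- gridDim(series)
    if (!identical(d, gridDim(mask)) ||
        abs(pixelSize(series) - pixelSize(mask)) > 1e-6)
        stop("mask grid does not match the echo series grid")
    if (!is.null(exclude) && !identical(dim(exclude), d))
        stop("'exclude' must match the volume dimensions")
    lab <- mask@labels
    fit <- lab >= 2L
    if (!is.null(slices)) {
        keep <- array(FALSE, d)
        keep[slices + 1L, , ] <- TRUE
        fit <- fit & keep
    }
    if (!is.null(exclude)) fit <- fit & !exclude
    t2 <- pd <- rss <- array(NA_real_, d)
    valid <- array(FALSE, d)
    te <- series@echoTimes
    sig <- series@intensities
    idx <- which(fit)
    for (v in idx) {
        vf <- fitVoxel(sig[(v - 1L) * length(te) + seq_along(te)], te, options)
        if (vf$valid) {
            t2[v] <- vf$t2; pd[v] <- vf$pd; rss[v] <- vf$rss
            valid[v] <- TRUE
        }
    }
    new("T2Map", t2 = t2, pd = pd, rss = rss, valid = valid,
        pixelSize = series@pixelSize, sliceThickness = series@sliceThickness,
        affine = series@affine)
}
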