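#' Region-by-layer means of a T2 map
#'
#' Aggregates a fitted \linkS4class{T2Map} over a laminar split: for
#' each region x layer cell, the arithmetic mean of the valid voxels on
#' the requested slices.  Invalid voxels are excluded; a cell with zero
#' valid voxels is emitted with \code{NA} and a message, so downstream
#' completeness rules can act on it.
#'
#' @param map a \linkS4class{T2Map}.
#' @param laminae a \linkS4class{LaminarMask} on the same grid.
#' @param slices 0-based slice indices (default all).
#' @param labelDict named label dictionary used to name regions.
#' @return data.frame with columns \code{region}, \code{layer},
#'   \code{value}, \code{nVoxels}.
#' @export
regionLayerMeans <- function(map, laminae, slices = NULL,
                             labelDict = defaultLabelDict()) {
    stopifnot(is(map, "T2Map"), is(laminae, "LaminarMask"))
    if (!identical(gridDim(map), gridDim(laminae)))
        stop("laminar mask grid does not match the map grid")
    d <- gridDim(map)
    keep <- array(TRUE, d)
    if (!is.null(slices)) {
        if (any(slices < 0L) || any(slices > d[1L] - 1L))
            stop("slice range exceeds the volume")
        keep[] <- FALSE
        keep[slices + 1L, , ] <- TRUE
    }
    regs <- sort(setdiff(unique(as.integer(laminae@regions)), 0L))
    layers <- c(superficial = 1L, deep = 2L)
    out <- vector("list", length(regs) * 2L)
    i <- 0L
    for (reg in regs) for (ly in names(layers)) {
        cell <- keep & laminae@regions == reg & laminae@codes == layers[[ly]]
        vox <- map@t2[cell & map@valid]
        i <- i + 1L
        nm <- names(labelDict)[match(reg, labelDict)]
        if (length(vox) == 0L) {
            message(sprintf("no valid voxels for region %s, layer %s",
                if (is.na(nm)) reg else nm, ly))
            val <- NA_real_
        } else val <- mean(vox)
        out[[i]] <- data.frame(
            region = if (is.na(nm)) as.character(reg) else nm,
            layer = ly, value = val, nVoxels = length(vox),
            stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
}

#' Whole-knee composite measure
#'
#' The primary endpoint of the analysis: per participant x time x layer,
#' the unweighted arithmetic mean of the regional means over the
#' segmented load-bearing regions, emitted with region label
#' \code{"composite"}.  A participant x time cell missing any region (or
#' holding a non-finite value) yields a missing composite for that cell.
#'
#' @param table a measurement table (see [generateCohort()]).
#' @param regions region labels entering the composite; default the six
#'   load-bearing regions.
#' @param layers layers to compose (default superficial and deep).
#' @return composite rows in the same long format.
#' @export
compositeMeasure <- function(table,
                             regions = names(defaultLabelDict())[-(1:2)],
                             layers = c("superficial", "deep")) {
    sub <- table[table$region %in% regions & table$layer %in% layers, ]
    if (nrow(sub) == 0L)
        stop("no rows for the requested regions/layers")
    key <- c("participant_id", "group", "time", "layer")
    keep <- intersect(c(key, "age", "bmi"), names(sub))
    split.. <- split(sub, sub[, key], drop = TRUE)
    out <- lapply(split.., function(g) {
        row <- g[1L, keep, drop = FALSE]
        complete <- all(regions %in% g$region) && all(is.finite(g$value))
        row$region <- "composite"
        row$value <- if (complete) mean(g$value[match(regions, g$region)])
            else NA_real_
        row
    })
    out <- do.call(rbind, out)
    cols <- c("participant_id", "group", "time", "region", "layer", "value",
        intersect(c("age", "bmi"), names(out)))
    out <- out[order(out$participant_id, out$time, out$layer), cols]
    rownames(out) <- NULL
    out
}

#' Sidak correction for multiple comparisons
#'
#' \eqn{p_{adj} = 1 - (1 - p)^m}, capped at 1; monotone non-decreasing
#' in both the raw p-value and the family size.
#'
#' @param p raw p-value(s) between 0 and 1.
#' @param m family size (integer >= 1).
#' @return adjusted p-value(s).
#' @examples
#' sidakAdjust(0.01, 3)  # 0.029701
#' @export
sidakAdjust <- function(p, m) {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
        stop("'p' must lie in [0, 1]")
    if (length(m) != 1L || m < 1 || m != round(m))
        stop("'m' must be a single integer >= 1")
    pmin(1 - (1 - p)^m, 1)
}

## Deterministic group ordering: healthy (the control group) first when
## present, remaining groups alphabetical.
.groupLevels <- function(g) {
    u <- sort(unique(g))
    if ("healthy" %in% u) c("healthy", setdiff(u, "healthy")) else u
}

#' Fit the group-by-time mixed-effects model for one response cell
#'
#' Fits, by REML via \pkg{lme4},
#' \deqn{y = \beta_0 + \beta_g\,group + \beta_t\,time +
#'   \beta_{gt}\,group{\times}time\ (+\ covariates) + b_i + \varepsilon}
#' with a random intercept per participant, to the rows of one region x
#' layer cell, and derives adjusted group x time means, within-group
#' changes (post - pre), and between-group differences of changes with
#' normal-approximation 95\% CIs and raw + Sidak-adjusted p-values.
#' For balanced complete data without covariates the adjusted means
#' equal the raw cell means and the 2-group between-difference equals
#' the interaction coefficient exactly.
#'
#' If the response carries no residual variability (a noiseless
#' simulated table), the mixed model is degenerate; the fit then falls
#' back to ordinary least squares on the same fixed effects, which
#' yields the identical cell-mean arithmetic with zero-width intervals.
#'
#' @param table a measurement table.
#' @param region,layer the response cell to model.
#' @param covariates optional character vector among
#'   \code{c("age", "bmi")}.
#' @param familySize Sidak family size m; default the number of reported
#'   comparisons (per-group within changes + between-group differences:
#'   3 for 2 groups, 6 for 3).
#' @param confLevel confidence level (default 0.95).
#' @return a \linkS4class{T2ModelFit}.
#' @examples
#' tab <- generateCohort(cohortSpec(), seed = 5)
#' fit <- fitGroupTimeModel(tab, "medial_tibia", "superficial")
#' contrastTable(fit)
#' @export
fitGroupTimeModel <- function(table, region, layer, covariates = NULL,
                              familySize = NULL, confLevel = 0.95) {
    dat <- table[table$region == region & table$layer == layer, ]
    dat <- dat[is.finite(dat$value), ]
    if (nrow(dat) == 0L)
        stop(sprintf("no usable rows for region '%s', layer '%s'",
            region, layer))
    if (!is.null(covariates)) {
        bad <- setdiff(covariates, c("age", "bmi"))
        if (length(bad))
            stop("unsupported covariates: ", paste(bad, collapse = ", "))
        if (!all(covariates %in% names(dat)))
            stop("covariate columns missing from the table")
    }
    dat$group <- factor(dat$group, levels = .groupLevels(dat$group))
    dat$time <- factor(dat$time, levels = c("pre", "post"))
    nGroups <- nlevels(dat$group)
    perGroup <- tapply(dat$participant_id, dat$group,
        function(x) length(unique(x)))
    if (nGroups < 2L || any(is.na(perGroup)) || any(perGroup < 2L))
        stop("singular design: need >= 2 participants in each of >= 2 groups")
    seen <- table(dat$group, dat$time)
    if (any(seen == 0L))
        stop("singular design: every group needs both timepoints")

    fixed <- paste(c("group * time", covariates), collapse = " + ")
    fullForm <- stats::as.formula(
        paste("value ~", fixed, "+ (1 | participant_id)"))
    lmForm <- stats::as.formula(paste("value ~", fixed))

    mixed <- tryCatch({
        fit <- suppressMessages(lme4::lmer(fullForm, data = dat,
            REML = TRUE))
        vc <- as.data.frame(lme4::VarCorr(fit))
        list(fit = fit, beta = lme4::fixef(fit),
            V = as.matrix(stats::vcov(fit)),
            sigmaB2 = vc$vcov[vc$grp == "participant_id"],
            sigmaE2 = vc$vcov[vc$grp == "Residual"],
            converged = length(fit@optinfo$conv$lme4) == 0L)
    }, error = function(e) e)
    if (inherits(mixed, "error")) {
        ## degenerate (e.g. zero-variance) response: OLS fallback keeps
        ## the cell-mean arithmetic
        fit <- stats::lm(lmForm, data = dat)
        beta <- stats::coef(fit)
        V <- stats::vcov(fit)
        V[!is.finite(V)] <- 0
        sigmaE2 <- stats::sigma(fit)^2
        sigmaB2 <- 0
        converged <- TRUE
    } else {
        fit <- mixed$fit
        beta <- mixed$beta
        V <- mixed$V
        sigmaB2 <- mixed$sigmaB2
        sigmaE2 <- mixed$sigmaE2
        converged <- mixed$converged
    }

    ## design rows for the group x time grid, covariates at their mean
    grid <- expand.grid(group = levels(dat$group),
        time = levels(dat$time), KEEP.OUT.ATTRS = FALSE)
    for (cv in covariates) grid[[cv]] <- mean(dat[[cv]])
    X <- stats::model.matrix(stats::as.formula(paste("~", fixed)), grid)
    X <- X[, names(beta), drop = FALSE]
    z <- stats::qnorm(1 - (1 - confLevel) / 2)
    est <- drop(X %*% beta)
    se <- sqrt(pmax(diag(X %*% V %*% t(X)), 0))
    adjusted <- data.frame(grid[, c("group", "time")], estimate = est,
        se = se, lo = est - z * se, hi = est + z * se)

    ## contrasts: per-group within change, all pairwise between-group
    ## differences of changes
    lev <- levels(dat$group)
    rowsFor <- function(g, tm) which(grid$group == g & grid$time == tm)
    Lwithin <- t(vapply(lev, function(g)
        X[rowsFor(g, "post"), ] - X[rowsFor(g, "pre"), ], numeric(ncol(X))))
    pairs <- if (nGroups == 2L) matrix(c(2L, 1L), 1L)
        else t(utils::combn(nGroups, 2L))[, 2:1, drop = FALSE]
    Lbetween <- Lwithin[pairs[, 1L], , drop = FALSE] -
        Lwithin[pairs[, 2L], , drop = FALSE]
    L <- rbind(Lwithin, Lbetween)
    labels <- c(sprintf("%s: post - pre", lev),
        sprintf("between: %s - %s", lev[pairs[, 1L]], lev[pairs[, 2L]]))
    type <- c(rep("within", nGroups), rep("between", nrow(pairs)))

    cEst <- drop(L %*% beta)
    cSe <- sqrt(pmax(diag(L %*% V %*% t(L)), 0))
    zstat <- ifelse(cSe > 0, cEst / cSe, ifelse(abs(cEst) > 0, Inf, 0))
    pRaw <- 2 * stats::pnorm(-abs(zstat))
    if (is.null(familySize))
        familySize <- nGroups + nrow(pairs)
    ctr <- data.frame(contrast = labels, type = type, estimate = cEst,
        se = cSe, lo = cEst - z * cSe, hi = cEst + z * cSe,
        pRaw = pRaw, pSidak = sidakAdjust(pRaw, familySize),
        m = as.integer(familySize), stringsAsFactors = FALSE)
    rownames(ctr) <- NULL

    new("T2ModelFit", model = fit, fixedEffects = beta, vcovFixed = V,
        sigmaB2 = as.numeric(sigmaB2), sigmaE2 = as.numeric(sigmaE2),
        adjustedMeans = adjusted, contrasts = ctr,
        familySize = as.integer(familySize), groups = lev,
        response = paste(region, layer, sep = "/"),
        converged = isTRUE(converged))
}

#' Extract the contrast set of a fitted model
#'
#' Within-group changes (post - pre adjusted means, one per group) and
#' between-group differences of changes (all group pairs), each with SE,
#' 95\% CI, and raw + Sidak-adjusted p-values.  In the 2-group case the
#' between-group difference equals the interaction coefficient exactly.
#'
#' @param fit a \linkS4class{T2ModelFit}.
#' @return data.frame of contrasts.
#' @export
modelContrasts <- function(fit) {
    stopifnot(is(fit, "T2ModelFit"))
    fit@contrasts
}
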