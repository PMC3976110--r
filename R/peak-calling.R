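#' @include signal-processing.R
NULL

## FWHM of the -dF/dT peak of a logistic melt component, per unit of the
## logistic scale parameter: 2*log(3 + 2*sqrt(2)) ~= 3.5255
.LOGISTIC_FWHM_FACTOR <- 2 * log(3 + 2 * sqrt(2))

#' Peak-calling configuration
#'
#' @param y_threshold analysis threshold on the derivative axis. In
#'   `"absolute"` mode (default) it is in -dF/dT units (default 0.05,
#'   calibrated to normalized curves where a unit-amplitude specific
#'   product peaks at ~0.7); in `"fraction"` mode it is a fraction of
#'   the curve maximum, the tactic of raising the line under a strong
#'   specific peak so that weak broad artifacts fall below it.
#' @param x_exclusions list of length-2 numeric intervals (degrees C)
#'   removed from analysis, the x-axis-threshold remedy for known
#'   artifact regions; peaks inside them are never reported.
#' @param max_fwhm full width at half maximum (degrees C) above which a
#'   peak is flagged broad (`is_broad`). Default 2.0: comfortably above
#'   the ~1.23 degC FWHM of a specific product melt and far below
#'   primer-dimer humps (>= 5 degC).
#' @param min_separation peaks closer than this (degrees C) are merged,
#'   keeping the taller (ties: the lower temperature). Default 0.5.
#' @param threshold_mode `"absolute"` or `"fraction"`.
#' @return a list of class `peakCallConfig`.
#' @export
peakCallConfig <- function(y_threshold = 0.05, x_exclusions = list(),
                           max_fwhm = 2.0, min_separation = 0.5,
                           threshold_mode = c("absolute", "fraction")) {
    threshold_mode <- match.arg(threshold_mode)
    stopifnot(y_threshold >= 0, max_fwhm > 0, min_separation >= 0)
    for (iv in x_exclusions)
        stopifnot(length(iv) == 2, iv[1] <= iv[2])
    structure(list(y_threshold = y_threshold, x_exclusions = x_exclusions,
                   max_fwhm = max_fwhm, min_separation = min_separation,
                   threshold_mode = threshold_mode),
              class = "peakCallConfig")
}

## prominence of peak at index i: height above the higher of the two
## deepest valleys separating it from taller terrain (or the curve edge)
.prominence <- function(v, i) {
    n <- length(v)
    left <- v[seq_len(i - 1)]
    right <- if (i < n) v[seq.int(i + 1, n)] else numeric(0)
    base_side <- function(side, rev_order) {
        if (!length(side)) return(min(v[i], min(v)))
        if (rev_order) side <- rev(side)
        higher <- which(side > v[i])       # nearest taller point
        if (length(higher)) min(side[seq_len(higher[1])]) else min(side)
    }
    v[i] - max(base_side(left, TRUE), base_side(right, FALSE))
}

## Full width at the given level around peak i, by linear interpolation
## of the crossings. The search is confined to [lb, rb] (the saddles
## toward neighbouring peaks, or the curve ends): a neighbour's flank
## must not masquerade as this peak's width. When the saddle on one
## side sits above the level, that side never crosses; the resolved
## side's half-width is mirrored (melt peaks are near-symmetric). If
## neither side crosses, the region width is returned (errs broad).
.fwhm <- function(tt, v, i, level, lb, rb) {
    xl <- NA_real_; xr <- NA_real_
    if (i > lb) for (j in seq(i, lb + 1)) if (v[j - 1] < level) {
        xl <- tt[j - 1] + (tt[j] - tt[j - 1]) * (level - v[j - 1]) / (v[j] - v[j - 1])
        break
    }
    if (i < rb) for (j in seq(i, rb - 1)) if (v[j + 1] < level) {
        xr <- tt[j] + (tt[j + 1] - tt[j]) * (v[j] - level) / (v[j] - v[j + 1])
        break
    }
    if (is.na(xl) && is.na(xr)) return(tt[rb] - tt[lb])
    if (is.na(xl)) xl <- tt[i] - (xr - tt[i])
    if (is.na(xr)) xr <- tt[i] + (tt[i] - xl)
    xr - xl
}

.callPeaksVec <- function(tt, v, config) {
    empty <- data.frame(tm = numeric(0), height = numeric(0),
                        fwhm = numeric(0), prominence = numeric(0),
                        is_broad = logical(0))
    n <- length(v)
    if (n < 3) return(empty)
    thr <- if (config$threshold_mode == "fraction")
        config$y_threshold * max(v) else config$y_threshold
    ## strict rise, non-strict fall admits flat-topped maxima once
    idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1
    idx <- idx[v[idx] >= thr]
    if (!length(idx)) return(empty)
    ## sub-grid Tm and height by parabola through the 3 points at the max
    refine <- function(i) {
        y1 <- v[i - 1]; y2 <- v[i]; y3 <- v[i + 1]
        den <- y1 - 2 * y2 + y3
        if (den >= 0) return(c(tt[i], y2))
        delta <- 0.5 * (y1 - y3) / den
        delta <- max(-0.5, min(0.5, delta))
        step <- tt[i + 1] - tt[i]
        c(tt[i] + delta * step, y2 - 0.25 * (y1 - y3) * delta)
    }
    ref <- vapply(idx, refine, numeric(2))
    pk <- data.frame(i = idx, tm = ref[1, ], height = ref[2, ])
    ## x-axis exclusions
    for (iv in config$x_exclusions)
        pk <- pk[pk$tm < iv[1] | pk$tm > iv[2], , drop = FALSE]
    if (!nrow(pk)) return(empty)
    ## merge peaks closer than min_separation, keeping the taller
    ## (equal heights: the lower temperature)
    pk <- pk[order(-pk$height, pk$tm), , drop = FALSE]
    keep <- logical(nrow(pk))
    for (r in seq_len(nrow(pk))) {
        kept_tms <- pk$tm[keep]
        if (!length(kept_tms) ||
            all(abs(kept_tms - pk$tm[r]) >= config$min_separation))
            keep[r] <- TRUE
    }
    pk <- pk[keep, , drop = FALSE]
    pk <- pk[order(pk$tm), , drop = FALSE]
    pk$prominence <- vapply(pk$i, function(i) .prominence(v, i), 0)
    ## width-search regions bounded by the saddles between retained peaks
    nb <- nrow(pk)
    bounds <- function(r) {
        lb <- if (r == 1) 1L
              else pk$i[r - 1] - 1L + which.min(v[pk$i[r - 1]:pk$i[r]])
        rb <- if (r == nb) n
              else pk$i[r] - 1L + which.min(v[pk$i[r]:pk$i[r + 1]])
        c(lb, rb)
    }
    pk$fwhm <- vapply(seq_len(nb), function(r) {
        b <- bounds(r)
        .fwhm(tt, v, pk$i[r], pk$height[r] - pk$prominence[r] / 2, b[1], b[2])
    }, 0)
    pk$is_broad <- pk$fwhm > config$max_fwhm
    data.frame(tm = round(pk$tm, 1), height = pk$height, fwhm = pk$fwhm,
               prominence = pk$prominence, is_broad = pk$is_broad,
               row.names = NULL)
}

#' Call peaks on derivative melt curves
#'
#' Finds local maxima of -dF/dT above the analysis threshold and outside
#' all excluded temperature intervals, merges maxima closer than the
#' separation radius (keeping the taller), refines each Tm by parabolic
#' interpolation through the three grid points at the maximum, measures
#' FWHM at half prominence (the crossing search is bounded by the
#' saddles toward neighbouring peaks, mirroring the resolved side when
#' a saddle sits above the level), and flags abnormally broad peaks
#' (`fwhm > max_fwhm`) as artifacts. Broad peaks are retained in the
#' output but never assign to markers downstream. Reported `tm` is
#' rounded to 0.1 degC, the precision of the published windows.
#'
#' @param deriv a derivative [MeltCurveSet] from [derivativeCurves()].
#' @param config a [peakCallConfig()].
#' @return `data.frame` with columns `sample_id`, `tm`, `height`,
#'   `fwhm`, `prominence`, `is_broad` (zero rows if nothing is called).
#' @examples
#' p <- builtinPanel("hexaplex")
#' mcs <- simulateSample(meltComponents(82.7, marker = "TGM4"),
#'                       simConfig(p, noise_sd = 0))
#' callPeaks(derivativeCurves(normalizeCurves(mcs)))
#' @export
callPeaks <- function(deriv, config = peakCallConfig()) {
    stopifnot(is(deriv, "MeltCurveSet"), inherits(config, "peakCallConfig"))
    if (curveType(deriv) != "derivative")
        stop("callPeaks expects a derivative MeltCurveSet")
    tt <- temperatures(deriv)
    v <- assay(deriv)
    out <- lapply(seq_len(ncol(v)), function(j) {
        pk <- .callPeaksVec(tt, v[, j], config)
        if (nrow(pk)) cbind(sample_id = colnames(v)[j], pk)
        else cbind(sample_id = character(0), pk)
    })
    res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
    if (is.null(res))
        res <- data.frame(sample_id = character(0), tm = numeric(0),
                          height = numeric(0), fwhm = numeric(0),
                          prominence = numeric(0), is_broad = logical(0))
    res
}
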