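#' @include melt-curve-set.R
NULL

#' Baseline-normalize melt curves
#'
#' Fits a linear pre-melt baseline to the first `premelt_fraction` of
#' the grid and a post-melt baseline to the last `postmelt_fraction`,
#' then rescales each curve pointwise so the pre-melt baseline maps to 1
#' and the post-melt baseline to 0:
#' `(F(T) - post(T)) / (pre(T) - post(T))`. Values are not clamped, so
#' noise excursions outside `[0, 1]` survive. Curves with no usable
#' dynamic range -- flat traces, and blank/no-template curves whose
#' pre/post baseline separation is below 10x the baseline-fit residual
#' noise -- cannot be normalized meaningfully (rescaling would only
#' amplify noise); they are returned unscaled and flagged in
#' `colData()$flat`.
#'
#' Normalization is affine per curve, so the position of any subsequent
#' derivative peak is unchanged; it only standardizes amplitudes so one
#' absolute peak-calling threshold is meaningful across samples.
#'
#' @param mcs a raw [MeltCurveSet].
#' @param premelt_fraction,postmelt_fraction fractions of the grid used
#'   for the two baseline fits; each in `(0, 0.3]`, summing to < 1.
#'   Defaults 0.1.
#' @return a normalized [MeltCurveSet] (same grid); `colData()$flat`
#'   marks curves returned unscaled.
#' @export
normalizeCurves <- function(mcs, premelt_fraction = 0.1,
                            postmelt_fraction = 0.1) {
    stopifnot(is(mcs, "MeltCurveSet"))
    if (premelt_fraction <= 0 || premelt_fraction > 0.3 ||
        postmelt_fraction <= 0 || postmelt_fraction > 0.3 ||
        premelt_fraction + postmelt_fraction >= 1)
        stop("baseline fractions must lie in (0, 0.3] and sum to < 1")
    tt <- temperatures(mcs)
    np <- length(tt)
    f <- assay(mcs)
    i_pre <- seq_len(max(2, floor(np * premelt_fraction)))
    i_post <- seq.int(np - max(2, floor(np * postmelt_fraction)) + 1, np)
    out <- f
    flat <- logical(ncol(f))
    for (j in seq_len(ncol(f))) {
        fit_pre <- stats::lm.fit(cbind(1, tt[i_pre]), f[i_pre, j])
        fit_post <- stats::lm.fit(cbind(1, tt[i_post]), f[i_post, j])
        pre <- fit_pre$coefficients
        post <- fit_post$coefficients
        denom <- (pre[1] + pre[2] * tt) - (post[1] + post[2] * tt)
        rng <- mean(denom)
        ## a curve with no melt transition (blank/no-template) has a
        ## dynamic range indistinguishable from baseline noise; scaling
        ## by it would only amplify noise into spurious peaks
        noise_hat <- max(stats::sd(fit_pre$residuals),
                         stats::sd(fit_post$residuals))
        if (!is.finite(rng) ||
            abs(rng) < max(1e-8 * max(1, max(abs(f[, j]))), 10 * noise_hat)) {
            flat[j] <- TRUE
            next
        }
        out[, j] <- (f[, j] - (post[1] + post[2] * tt)) / denom
    }
    if (any(flat))
        warning("flat curve(s) returned unscaled: ",
                paste(colnames(f)[flat], collapse = ", "))
    res <- MeltCurveSet(tt, out, sample_ids = colnames(f),
                        curve_type = "normalized",
                        colData = colData(mcs))
    colData(res)$flat <- flat
    res
}

## Savitzky-Golay first-derivative convolution weights for the window
## centre: least-squares fit of a degree-p polynomial over 2h+1 points.
.sgDerivWeights <- function(window, degree) {
    h <- (window - 1) / 2
    A <- outer(seq(-h, h), 0:degree, `^`)
    ## row of the pseudo-inverse giving the linear-term coefficient
    solve(crossprod(A), t(A))[2, ]
}

#' Negative-derivative melt plot
#'
#' Transforms curves into the -dF/dT representation in which each
#' amplicon appears as a peak at its melting temperature. Smoothing and
#' differentiation are one linear operation: a Savitzky-Golay filter
#' (local least-squares polynomial, default 7-point window, degree 2)
#' whose analytic first-derivative weights are applied by convolution.
#' Half a window is trimmed from each end of the grid rather than padded;
#' no marker window of the built-in panels comes near the grid ends.
#'
#' @param mcs a raw or normalized [MeltCurveSet].
#' @param smooth_window odd window length in grid points (default 7,
#'   i.e. 0.7 degC); must be >= `smooth_degree + 2` and <= a quarter of
#'   the grid.
#' @param smooth_degree polynomial degree. The default 2 is the
#'   noise-robust choice: it localizes peak positions without bias but
#'   attenuates the height of sharp peaks (about -4.5% for a specific
#'   product of unit amplitude). Degree 3 recovers heights and widths to
#'   within a few tenths of a percent at the cost of ~2.7x higher noise
#'   amplification; use it when absolute peak heights matter and curves
#'   are clean.
#' @return a derivative [MeltCurveSet] on the trimmed grid; values are
#'   -dF/dT in units per degree C.
#' @examples
#' p <- builtinPanel("singleplex_HTN3")
#' mcs <- simulateSample(meltComponents(76.3), simConfig(p, noise_sd = 0))
#' d <- derivativeCurves(normalizeCurves(mcs))
#' temperatures(d)[which.max(assay(d)[, 1])]   # 76.3
#' @export
derivativeCurves <- function(mcs, smooth_window = 7, smooth_degree = 2) {
    stopifnot(is(mcs, "MeltCurveSet"))
    tt <- temperatures(mcs)
    np <- length(tt)
    if (smooth_window %% 2 != 1 || smooth_window < smooth_degree + 2)
        stop("smooth_window must be odd and >= smooth_degree + 2")
    if (smooth_window > np / 4)
        stop("curve too short for the requested smoothing window")
    step <- (tt[np] - tt[1]) / (np - 1)
    w <- .sgDerivWeights(smooth_window, smooth_degree) / step
    h <- (smooth_window - 1) / 2
    f <- assay(mcs)
    keep <- seq.int(h + 1, np - h)
    d <- matrix(0, nrow = length(keep), ncol = ncol(f),
                dimnames = list(NULL, colnames(f)))
    for (k in seq_len(smooth_window))
        d <- d + w[k] * f[keep + (k - h - 1), , drop = FALSE]
    MeltCurveSet(tt[keep], -d, sample_ids = colnames(f),
                 curve_type = "derivative", colData = colData(mcs))
}
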