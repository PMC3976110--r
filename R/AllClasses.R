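#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData colData<-
NULL

## Marker table column contract shared by HRMPanel validity and constructors.
## One row per (marker, product window); multi-product markers such as the
## MMP10 amplicon pair occupy consecutive rows sharing `marker`.
.MARKER_COLS <- c("marker", "fluid", "window_index", "tm_mean",
                  "window_low", "window_high", "required",
                  "amplicon_size", "primer_fwd", "primer_rev")

.BODY_FLUIDS <- c("blood", "semen", "saliva", "vaginal", "menstrual", "skin")

#' HRMPanel: a multiplex HRM assay definition
#'
#' An `HRMPanel` bundles the marker set of one melt assay: for every
#' amplicon product it stores the published mean melting temperature
#' (Tm, in degrees Celsius) and the closed mean +/- 3SD window inside
#' which an observed derivative peak counts as that marker. A panel also
#' carries the programmed melt range, the temperature grid step, and an
#' optional genomic-DNA product window used as an RNA-quality flag.
#'
#' @slot name panel identifier.
#' @slot markers `data.frame` with one row per marker product window;
#'   columns `marker`, `fluid`, `window_index`, `tm_mean`, `window_low`,
#'   `window_high`, `required` (does a peak in this window make the marker
#'   call positive), `amplicon_size`, `primer_fwd`, `primer_rev`.
#' @slot meltRange length-2 numeric, programmed melt range in degrees C.
#' @slot gridStep temperature grid increment in degrees C (0.1 for the
#'   built-in assays).
#' @slot dnaWindow length-2 numeric (or `numeric(0)` when absent): closed
#'   Tm window of a known genomic-DNA-derived product.
#'
#' @seealso [builtinPanel()], [validatePanel()], [readPanelFile()]
#' @export
setClass("HRMPanel",
         representation(name = "character",
                        markers = "data.frame",
                        meltRange = "numeric",
                        gridStep = "numeric",
                        dnaWindow = "numeric"))

setValidity("HRMPanel", function(object) {
    m <- object@markers
    msgs <- character(0)
    if (!all(.MARKER_COLS %in% names(m)))
        return(paste("markers must have columns:",
                     paste(setdiff(.MARKER_COLS, names(m)), collapse = ", ")))
    if (length(object@meltRange) != 2 || diff(object@meltRange) <= 0)
        msgs <- c(msgs, "meltRange must be an increasing length-2 numeric")
    if (length(object@gridStep) != 1 || object@gridStep <= 0)
        msgs <- c(msgs, "gridStep must be a single positive number")
    if (!all(m$fluid %in% .BODY_FLUIDS))
        msgs <- c(msgs, paste("unknown body fluid(s):",
                              paste(setdiff(m$fluid, .BODY_FLUIDS), collapse = ", ")))
    bad <- m$window_low >= m$window_high |
        m$tm_mean < m$window_low | m$tm_mean > m$window_high
    if (any(bad))
        msgs <- c(msgs, paste("window must satisfy low < high and contain its mean:",
                              paste(m$marker[bad], collapse = ", ")))
    if (any(m$window_low < object@meltRange[1] | m$window_high > object@meltRange[2]))
        msgs <- c(msgs, "every marker window must lie inside meltRange")
    ## windows within one marker: sorted ascending and pairwise disjoint
    for (mk in unique(m$marker)) {
        w <- m[m$marker == mk, , drop = FALSE]
        w <- w[order(w$window_index), , drop = FALSE]
        if (nrow(w) > 1) {
            if (is.unsorted(w$window_low, strictly = TRUE) ||
                any(w$window_low[-1] <= w$window_high[-nrow(w)]))
                msgs <- c(msgs, paste0("windows of marker ", mk,
                                       " must be disjoint and ascending"))
        }
        if (sum(w$required) != 1)
            msgs <- c(msgs, paste0("marker ", mk,
                                   " must have exactly one required window"))
    }
    dw <- object@dnaWindow
    if (length(dw) != 0) {
        if (length(dw) != 2 || dw[1] >= dw[2])
            msgs <- c(msgs, "dnaWindow must be an increasing length-2 numeric")
        else if (any(m$window_low <= dw[2] & dw[1] <= m$window_high))
            msgs <- c(msgs, "dnaWindow must be disjoint from all marker windows")
    }
    if (length(msgs)) msgs else TRUE
})

#' PanelValidationReport: pairwise Tm-window resolvability check
#'
#' Result of [validatePanel()]: all marker-marker and marker-DNA window
#' pairs whose closed intervals overlap, or whose separation gap is
#' smaller than the requested margin, are recorded as conflicts.
#'
#' @slot panel name of the validated panel.
#' @slot conflicts `data.frame` with columns `marker_a`, `window_a`,
#'   `marker_b`, `window_b` (printed as "low-high"), and `gap` (degrees C;
#'   negative values are overlap depth).
#' @slot passed `TRUE` iff `conflicts` has no rows.
#' @slot margin margin (degrees C) the check was run at.
#' @export
setClass("PanelValidationReport",
         representation(panel = "character",
                        conflicts = "data.frame",
                        passed = "logical",
                        margin = "numeric"))

setValidity("PanelValidationReport", function(object) {
    if (object@passed != (nrow(object@conflicts) == 0L))
        "passed must be TRUE iff conflicts is empty" else TRUE
})

#' MeltCurveSet: melt curves of a sample cohort
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one
#' fluorescence trace per sample over a shared uniform temperature grid.
#' `rowData()$Temperature` carries the grid (degrees C, ascending, uniform
#' step); the single assay holds fluorescence (arbitrary units) for raw
#' and normalized curves, or -dF/dT (units per degree C) for derivative
#' curves. `metadata()$curve_type` is one of `"raw"`, `"normalized"`,
#' `"derivative"`.
#'
#' @seealso [MeltCurveSet()], [normalizeCurves()], [derivativeCurves()]
#' @export
setClass("MeltCurveSet", contains = "SummarizedExperiment")

setValidity("MeltCurveSet", function(object) {
    tt <- rowData(object)$Temperature
    if (is.null(tt))
        return("rowData must contain a Temperature column")
    if (length(tt) < 20)
        return("melt curves need at least 20 temperature points")
    d <- diff(tt)
    if (any(d <= 0) || (max(d) - min(d)) > 1e-6)
        return("temperature grid must be ascending and uniform (to 1e-6)")
    a <- assay(object)
    if (ncol(a) > 0 && any(!is.finite(a)))
        return("fluorescence values must be finite")
    ct <- metadata(object)$curve_type
    if (is.null(ct) || !ct %in% c("raw", "normalized", "derivative"))
        return("metadata curve_type must be raw, normalized or derivative")
    TRUE
})

#' SpecificityTable: body fluid x marker detection summary
#'
#' Aggregated detection counts of a donor cohort: for each true body
#' fluid (rows) and panel marker (columns), the number of samples in
#' which the marker was detected out of the number of samples of that
#' fluid tested on a panel containing the marker. Cells are shaded
#' white (no detection), light or dark by the detection-rate band of the
#' chosen scheme (dark at >= 60% for the duplex scheme, >= 75% for the
#' hexaplex scheme).
#'
#' @slot positives integer matrix (fluid x marker) of detection counts.
#' @slot tested integer matrix of denominators, same dimensions.
#' @slot shading character matrix, entries in `"white"`, `"light"`,
#'   `"dark"`.
#' @slot scheme `"duplex"` or `"hexaplex"`.
#' @seealso [aggregateSpecificity()], [shadeCell()]
#' @export
setClass("SpecificityTable",
         representation(positives = "matrix",
                        tested = "matrix",
                        shading = "matrix",
                        scheme = "character"))

setValidity("SpecificityTable", function(object) {
    if (!identical(dim(object@positives), dim(object@tested)) ||
        !identical(dim(object@positives), dim(object@shading)))
        return("positives, tested and shading must share dimensions")
    if (any(object@positives < 0) || any(object@positives > object@tested))
        return("0 <= positives <= tested must hold in every cell")
    if (!all(object@shading %in% c("white", "light", "dark")))
        return("shading entries must be white, light or dark")
    if (!object@scheme %in% c("duplex", "hexaplex"))
        return("scheme must be duplex or hexaplex")
    TRUE
})
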