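#' @include AllClasses.R
NULL

#' Accessors for HRMPanel and MeltCurveSet objects
#'
#' `panelName()`, `markerTable()`, `meltRange()`, `gridStep()` and
#' `dnaWindow()` read the corresponding panel slots; `markerNames()` and
#' `panelFluids()` list the distinct markers and the body fluids they
#' report. `temperatures()` and `curveType()` read the temperature grid
#' and the curve type of a [MeltCurveSet].
#'
#' @param x an `HRMPanel` or `MeltCurveSet` object.
#' @return the slot value (see each generic's description).
#' @name panel-accessors
#' @aliases panelName markerTable meltRange gridStep dnaWindow markerNames
#'   panelFluids temperatures curveType
#' @examples
#' p <- builtinPanel("hexaplex")
#' markerNames(p)
#' dnaWindow(p)
NULL

#' @rdname panel-accessors
#' @export
setGeneric("panelName", function(x) standardGeneric("panelName"))
#' @rdname panel-accessors
#' @export
setGeneric("markerTable", function(x) standardGeneric("markerTable"))
#' @rdname panel-accessors
#' @export
setGeneric("meltRange", function(x) standardGeneric("meltRange"))
#' @rdname panel-accessors
#' @export
setGeneric("gridStep", function(x) standardGeneric("gridStep"))
#' @rdname panel-accessors
#' @export
setGeneric("dnaWindow", function(x) standardGeneric("dnaWindow"))
#' @rdname panel-accessors
#' @export
setGeneric("markerNames", function(x) standardGeneric("markerNames"))
#' @rdname panel-accessors
#' @export
setGeneric("panelFluids", function(x) standardGeneric("panelFluids"))
#' @rdname panel-accessors
#' @export
setGeneric("temperatures", function(x) standardGeneric("temperatures"))
#' @rdname panel-accessors
#' @export
setGeneric("curveType", function(x) standardGeneric("curveType"))

#' Validate that a panel's Tm windows are mutually resolvable
#'
#' A multiplex HRM assay can only be deconvolved by Tm if no two marker
#' windows (including the genomic-DNA product window, when defined)
#' overlap. `validatePanel()` tests every pair of windows belonging to
#' different markers and reports a conflict when the closed intervals
#' overlap or when the gap separating them is smaller than `margin`.
#'
#' @param panel an [HRMPanel].
#' @param margin non-negative separation (degrees C) additionally
#'   required between windows. The default `0` demands strict
#'   disjointness only; the built-in hexaplex passes at this margin (its
#'   tightest gap, MMP10 to TGM4, is 0.1 degrees C).
#' @return a [PanelValidationReport].
#' @examples
#' validatePanel(builtinPanel("hexaplex"))
#' @export
setGeneric("validatePanel", function(panel, margin = 0)
    standardGeneric("validatePanel"))

setMethod("panelName", "HRMPanel", function(x) x@name)
setMethod("markerTable", "HRMPanel", function(x) x@markers)
setMethod("meltRange", "HRMPanel", function(x) x@meltRange)
setMethod("gridStep", "HRMPanel", function(x) x@gridStep)
setMethod("dnaWindow", "HRMPanel", function(x)
    if (length(x@dnaWindow)) x@dnaWindow else NULL)
setMethod("markerNames", "HRMPanel", function(x) unique(x@markers$marker))
setMethod("panelFluids", "HRMPanel", function(x) unique(x@markers$fluid))

setMethod("temperatures", "MeltCurveSet",
          function(x) rowData(x)$Temperature)
setMethod("curveType", "MeltCurveSet",
          function(x) metadata(x)$curve_type)
setMethod("gridStep", "MeltCurveSet",
          function(x) {
              tt <- rowData(x)$Temperature
              (tt[length(tt)] - tt[1]) / (length(tt) - 1)
          })

setMethod("show", "HRMPanel", function(object) {
    m <- object@markers
    cat(sprintf("HRMPanel '%s': %d marker(s), melt %.1f-%.1f degC (step %.1f)\n",
                object@name, length(unique(m$marker)),
                object@meltRange[1], object@meltRange[2], object@gridStep))
    for (i in seq_len(nrow(m)))
        cat(sprintf("  %-6s %-9s Tm %.1f  window [%.1f, %.1f]%s\n",
                    m$marker[i], m$fluid[i], m$tm_mean[i],
                    m$window_low[i], m$window_high[i],
                    if (m$required[i]) "" else "  (supporting)"))
    if (length(object@dnaWindow))
        cat(sprintf("  DNA product window [%.1f, %.1f]\n",
                    object@dnaWindow[1], object@dnaWindow[2]))
    invisible(object)
})

setMethod("show", "PanelValidationReport", function(object) {
    cat(sprintf("Panel '%s' Tm-window validation (margin %.2f degC): %s\n",
                object@panel, object@margin,
                if (object@passed) "PASSED" else "FAILED"))
    if (nrow(object@conflicts)) {
        cf <- object@conflicts
        for (i in seq_len(nrow(cf)))
            cat(sprintf("  %s [%s] vs %s [%s]: %s\n",
                        cf$marker_a[i], cf$window_a[i],
                        cf$marker_b[i], cf$window_b[i],
                        if (cf$gap[i] < 0)
                            sprintf("overlap by %.2f degC", -cf$gap[i])
                        else sprintf("gap %.2f degC < margin", cf$gap[i])))
    }
    invisible(object)
})

setMethod("show", "MeltCurveSet", function(object) {
    tt <- rowData(object)$Temperature
    cat(sprintf("MeltCurveSet (%s): %d sample(s), grid %.1f-%.1f degC x %d points\n",
                metadata(object)$curve_type, ncol(object),
                tt[1], tt[length(tt)], length(tt)))
    invisible(object)
})

setMethod("show", "SpecificityTable", function(object) {
    cat(sprintf("SpecificityTable (%s scheme): %d fluid(s) x %d marker(s)\n",
                object@scheme, nrow(object@positives), ncol(object@positives)))
    cells <- matrix(sprintf("%d/%d", object@positives, object@tested),
                    nrow = nrow(object@positives),
                    dimnames = dimnames(object@positives))
    mark <- c(white = " ", light = "+", dark = "*")[object@shading]
    print(matrix(paste0(cells, mark), nrow = nrow(cells),
                 dimnames = dimnames(cells)), quote = FALSE)
    cat("shading: ' ' white (0 detections), '+' light, '*' dark\n")
    invisible(object)
})

#' @describeIn validatePanel pairwise window comparison over all marker
#'   and DNA windows of the panel.
setMethod("validatePanel", "HRMPanel", function(panel, margin = 0) {
    stopifnot(is.numeric(margin), length(margin) == 1, margin >= 0)
    m <- panel@markers
    win <- data.frame(owner = m$marker,
                      low = m$window_low, high = m$window_high,
                      stringsAsFactors = FALSE)
    if (length(panel@dnaWindow))
        win <- rbind(win, data.frame(owner = "DNA",
                                     low = panel@dnaWindow[1],
                                     high = panel@dnaWindow[2]))
    cf <- list()
    n <- nrow(win)
    if (n > 1) {
        for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
            if (win$owner[i] == win$owner[j]) next  # intra-marker products
            gap <- max(win$low[j] - win$high[i], win$low[i] - win$high[j])
            if (gap <= 0 || gap < margin)   # gap <= 0: closed intervals touch/overlap
                cf[[length(cf) + 1]] <- data.frame(
                    marker_a = win$owner[i],
                    window_a = sprintf("%.1f-%.1f", win$low[i], win$high[i]),
                    marker_b = win$owner[j],
                    window_b = sprintf("%.1f-%.1f", win$low[j], win$high[j]),
                    gap = gap, stringsAsFactors = FALSE)
        }
    }
    conflicts <- if (length(cf)) do.call(rbind, cf) else
        data.frame(marker_a = character(0), window_a = character(0),
                   marker_b = character(0), window_b = character(0),
                   gap = numeric(0), stringsAsFactors = FALSE)
    new("PanelValidationReport", panel = panel@name, conflicts = conflicts,
        passed = nrow(conflicts) == 0L, margin = margin)
})
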