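#' @include AllClasses.R
NULL

#' Construct a MeltCurveSet from a temperature grid and trace matrix
#'
#' @param temperatures numeric vector, ascending uniform grid in
#'   degrees C (step uniform to 1e-6).
#' @param fluorescence numeric matrix, one column per sample, rows
#'   matching `temperatures`; a plain vector is taken as one sample.
#' @param sample_ids optional column names; defaults to existing
#'   colnames or `sample_1 ... sample_n`.
#' @param curve_type `"raw"`, `"normalized"` or `"derivative"`.
#' @param colData optional `DataFrame`/`data.frame` of per-sample
#'   metadata (e.g. the true body fluid of simulated donors).
#' @return a [MeltCurveSet].
#' @examples
#' tt <- seq(65, 90, by = 0.1)
#' mcs <- MeltCurveSet(tt, matrix(rev(seq_along(tt)), ncol = 1))
#' temperatures(mcs)[1:3]
#' @export
MeltCurveSet <- function(temperatures, fluorescence,
                         sample_ids = NULL, curve_type = "raw",
                         colData = NULL) {
    if (is.vector(fluorescence))
        fluorescence <- matrix(fluorescence, ncol = 1)
    if (nrow(fluorescence) != length(temperatures))
        stop("fluorescence must have one row per temperature")
    if (is.null(sample_ids))
        sample_ids <- colnames(fluorescence)
    if (is.null(sample_ids))
        sample_ids <- if (ncol(fluorescence))
            paste0("sample_", seq_len(ncol(fluorescence))) else character(0)
    colnames(fluorescence) <- sample_ids
    cd <- if (is.null(colData))
        S4Vectors::DataFrame(row.names = sample_ids)
    else S4Vectors::DataFrame(colData, row.names = sample_ids)
    an <- if (curve_type == "derivative") "dFdT" else "fluorescence"
    se <- SummarizedExperiment(
        assays = stats::setNames(list(fluorescence), an),
        rowData = S4Vectors::DataFrame(Temperature = temperatures),
        colData = cd,
        metadata = list(curve_type = curve_type))
    new("MeltCurveSet", se)
}

#' Temperature grid of an assay panel
#'
#' The uniform grid the instrument melts over: `meltRange[1]` to
#' `meltRange[2]` in `gridStep` increments (0.1 degC for the built-in
#' panels).
#'
#' @param panel an [HRMPanel].
#' @return numeric vector of temperatures in degrees C.
#' @export
panelGrid <- function(panel) {
    r <- meltRange(panel)
    n <- round((r[2] - r[1]) / gridStep(panel))
    r[1] + seq.int(0, n) * gridStep(panel)
}
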