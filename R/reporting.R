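#' @include marker-classification.R
NULL

.SHADE_DARK <- c(duplex = 60, hexaplex = 75)

#' Shading band of one specificity cell
#'
#' Pure function of the detection count, the denominator and the scheme:
#' `"white"` when nothing was detected, otherwise `"light"` below and
#' `"dark"` at or above the scheme's dark threshold of the detection
#' percentage (`>= 60%` for the duplex scheme, `>= 75%` for the
#' hexaplex scheme). Vectorized over cells.
#'
#' @param positives detections, `0 <= positives <= tested`.
#' @param tested denominators.
#' @param scheme `"duplex"` or `"hexaplex"`.
#' @return character vector in `"white"`, `"light"`, `"dark"`.
#' @examples
#' shadeCell(4, 18, "duplex")   # 22% -> light
#' shadeCell(3, 4, "hexaplex")  # 75% -> dark
#' @export
shadeCell <- function(positives, tested, scheme) {
    if (length(scheme) != 1 || !scheme %in% names(.SHADE_DARK))
        stop("scheme must be one of: ", paste(names(.SHADE_DARK), collapse = ", "))
    stopifnot(all(positives >= 0), all(positives <= tested))
    pct <- ifelse(tested > 0, 100 * positives / tested, 0)
    ifelse(positives == 0, "white",
           ifelse(pct >= .SHADE_DARK[[scheme]], "dark", "light"))
}

#' Aggregate cohort interpretations into a specificity table
#'
#' Builds the body fluid x marker detection matrix of a donor study:
#' cell (f, m) counts samples of true fluid f in which marker m was
#' detected, over the number of fluid-f samples run on a panel carrying
#' m. Pass one interpretation table, or a list of tables from different
#' panel runs of the same donors; denominators then differ by marker
#' exactly as they do when each duplex tests a different subset of
#' donors.
#'
#' @param interpretations a [classifyCohort()] result, or a list of them
#'   (one per panel run).
#' @param truth `data.frame` with `sample_id` and `fluid` columns giving
#'   each sample's true source (a [simulateCohort()] truth table works).
#' @param scheme shading scheme, `"duplex"` or `"hexaplex"`.
#' @return a [SpecificityTable].
#' @export
aggregateSpecificity <- function(interpretations, truth, scheme) {
    if (length(scheme) != 1 || !scheme %in% names(.SHADE_DARK))
        stop("scheme must be one of: ", paste(names(.SHADE_DARK), collapse = ", "))
    runs <- if (is.data.frame(interpretations)) list(interpretations)
            else interpretations
    truth <- unique(truth[, c("sample_id", "fluid")])
    fluids <- intersect(.BODY_FLUIDS, unique(truth$fluid))
    markers <- unique(unlist(lapply(runs, function(r)
        sub("_detected$", "", grep("_detected$", names(r), value = TRUE)))))
    pos <- tst <- matrix(0L, length(fluids), length(markers),
                         dimnames = list(fluids, markers))
    for (r in runs) {
        fl <- truth$fluid[match(r$sample_id, truth$sample_id)]
        if (any(is.na(fl)))
            stop("interpretation sample(s) missing from the truth table: ",
                 paste(r$sample_id[is.na(fl)], collapse = ", "))
        mk <- sub("_detected$", "", grep("_detected$", names(r), value = TRUE))
        for (f in fluids) {
            sel <- fl == f
            if (!any(sel)) next
            for (m in mk) {
                tst[f, m] <- tst[f, m] + sum(sel)
                pos[f, m] <- pos[f, m] + sum(r[[paste0(m, "_detected")]][sel])
            }
        }
    }
    new("SpecificityTable", positives = pos, tested = tst,
        shading = matrix(shadeCell(pos, tst, scheme), nrow(pos),
                         dimnames = dimnames(pos)),
        scheme = scheme)
}

## ---------------------------------------------------------------------
## CSV dialects

#' Read and write melt-curve CSV files
#'
#' The curve dialect is instrument-style: first column `Temperature`
#' (degrees C), one column per sample holding fluorescence. Derivative
#' sets are written with a `dFdT_` prefix on each sample column and
#' recognized as derivative on reading.
#'
#' @param mcs a [MeltCurveSet].
#' @param path file path.
#' @return `readCurvesCSV()` a [MeltCurveSet]; writers return `path`
#'   invisibly.
#' @export
writeCurvesCSV <- function(mcs, path) {
    stopifnot(is(mcs, "MeltCurveSet"))
    a <- assay(mcs)
    cn <- colnames(a)
    if (curveType(mcs) == "derivative") cn <- paste0("dFdT_", cn)
    df <- data.frame(Temperature = temperatures(mcs), a, check.names = FALSE)
    names(df) <- c("Temperature", cn)
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeCurvesCSV
#' @export
readCurvesCSV <- function(path) {
    if (!file.exists(path)) stop("curve CSV not found: ", path)
    df <- utils::read.csv(path, check.names = FALSE)
    if (names(df)[1] != "Temperature")
        stop("malformed curve CSV (first column must be Temperature): ", path)
    cn <- names(df)[-1]
    deriv <- length(cn) > 0 && all(startsWith(cn, "dFdT_"))
    if (deriv) cn <- sub("^dFdT_", "", cn)
    MeltCurveSet(df$Temperature,
                 as.matrix(df[, -1, drop = FALSE]),
                 sample_ids = cn,
                 curve_type = if (deriv) "derivative" else "raw")
}

#' Write a run manifest
#'
#' Records tool version, subcommand, parameters and seed of a pipeline
#' run as JSON next to its outputs, so any output file can be traced to
#' the exact invocation that produced it.
#'
#' @param path output JSON path.
#' @param command character label of the operation.
#' @param params named list of parameters (seeds included).
#' @return `path`, invisibly.
#' @export
writeManifest <- function(path, command, params = list()) {
    jsonlite::write_json(
        list(tool = "meltID",
             version = as.character(utils::packageVersion("meltID")),
             command = command, params = params,
             timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
        path, auto_unbox = TRUE, digits = NA, null = "null")
    invisible(path)
}

#' Specificity table CSV (long format)
#'
#' One row per (fluid, marker) cell: `fluid`, `marker`, `positives`,
#' `tested`, `shading`. Round-trips through `readSpecificityCSV()`.
#'
#' @param x a [SpecificityTable].
#' @param path file path.
#' @return the reader returns a [SpecificityTable]; the writer `path`,
#'   invisibly.
#' @export
writeSpecificityCSV <- function(x, path) {
    stopifnot(is(x, "SpecificityTable"))
    df <- expand.grid(fluid = rownames(x@positives),
                      marker = colnames(x@positives),
                      stringsAsFactors = FALSE)
    df$positives <- x@positives[cbind(df$fluid, df$marker)]
    df$tested <- x@tested[cbind(df$fluid, df$marker)]
    df$shading <- x@shading[cbind(df$fluid, df$marker)]
    df$scheme <- x@scheme
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeSpecificityCSV
#' @export
readSpecificityCSV <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    fluids <- unique(df$fluid); markers <- unique(df$marker)
    mk <- function(col, mode) {
        m <- matrix(vector(mode, 1), length(fluids), length(markers),
                    dimnames = list(fluids, markers))
        m[cbind(df$fluid, df$marker)] <- df[[col]]
        m
    }
    new("SpecificityTable", positives = mk("positives", "integer"),
        tested = mk("tested", "integer"), shading = mk("shading", "character"),
        scheme = df$scheme[1])
}
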