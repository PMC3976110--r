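#' @include peak-calling.R
NULL

.in_window <- function(tm, low, high, tol = 1e-9)
    tm >= low - tol & tm <= high + tol

#' Assign called peaks to panel marker windows
#'
#' Tests every non-broad peak of one sample against the panel's marker
#' windows (closed intervals, membership of the 0.1-degC-rounded Tm) and
#' against the genomic-DNA product window. A marker is detected iff some
#' peak falls in its required window; supporting windows (the secondary
#' MMP10 product on the original design) record a match but do not by
#' themselves make the call positive. Peaks in the DNA window raise the
#' DNA-contamination flag instead of a marker call. Broad artifact peaks
#' never assign. Peaks matching nothing are returned as unassigned.
#'
#' @param peaks `data.frame` of one sample's peaks ([callPeaks()]
#'   columns; `sample_id` optional).
#' @param panel an [HRMPanel]; must pass [validatePanel()] at margin 0,
#'   otherwise window membership would be ambiguous and the call is
#'   rejected.
#' @return list with `marker_calls` (`data.frame`: `marker`, `fluid`,
#'   `detected`, `observed_tm`, `matched_window_index`), `unassigned`
#'   (the non-matching non-broad peaks), and `dna_flag`.
#' @export
assignPeaks <- function(peaks, panel) {
    stopifnot(is(panel, "HRMPanel"))
    if (!validatePanel(panel, margin = 0)@passed)
        stop("panel '", panelName(panel),
             "' has overlapping Tm windows; validate and fix it first")
    m <- markerTable(panel)
    usable <- peaks[!peaks$is_broad, , drop = FALSE]
    assigned <- rep(FALSE, nrow(usable))
    dna_flag <- FALSE
    dw <- dnaWindow(panel)
    if (!is.null(dw)) {
        hit <- .in_window(usable$tm, dw[1], dw[2])
        dna_flag <- any(hit)
        assigned <- assigned | hit
    }
    calls <- list()
    for (mk in markerNames(panel)) {
        w <- m[m$marker == mk, , drop = FALSE]
        detected <- FALSE; obs_tm <- NA_real_; widx <- NA_integer_
        for (i in seq_len(nrow(w))) {
            hit <- .in_window(usable$tm, w$window_low[i], w$window_high[i])
            assigned <- assigned | hit
            if (any(hit) && w$required[i]) {
                detected <- TRUE
                tallest <- which(hit)[which.max(usable$height[hit])]
                obs_tm <- usable$tm[tallest]
                widx <- w$window_index[i]
            }
        }
        calls[[mk]] <- data.frame(marker = mk, fluid = w$fluid[1],
                                  detected = detected, observed_tm = obs_tm,
                                  matched_window_index = widx,
                                  stringsAsFactors = FALSE)
    }
    list(marker_calls = do.call(rbind, c(calls, list(make.row.names = FALSE))),
         unassigned = usable[!assigned, , drop = FALSE],
         dna_flag = dna_flag)
}

#' Interpret one sample's marker calls as body-fluid calls
#'
#' Applies the multiplex interpretation rules: the fluids called are
#' exactly those of detected markers; two or more distinct fluids raise
#' the `mixture` flag; co-detection of MMP10 and ALAS2 raises
#' `possible_menstrual` (menstrual blood carries peripheral blood, so
#' the pair is expected rather than a contradiction); any broad peak
#' raises `artifact_hump_present`; a peak in the genomic-DNA window
#' raises `dna_contamination` (an RNA-quality alert, not a fluid call);
#' leftover peaks raise `unassigned_peaks`.
#'
#' @param assignment the list returned by [assignPeaks()].
#' @param peaks the same sample's full peak table (used for the broad
#'   artifact flag).
#' @param sample_id label carried into the result.
#' @return one-row `data.frame`: `sample_id`, `fluid_calls` and `flags`
#'   (`;`-separated, empty string when none), one `<marker>_detected`
#'   and `<marker>_tm` column pair per panel marker, `n_unassigned`.
#' @export
interpretSample <- function(assignment, peaks, sample_id = "sample_1") {
    mc <- assignment$marker_calls
    fluids <- sort(unique(mc$fluid[mc$detected]))
    flags <- character(0)
    if (assignment$dna_flag) flags <- c(flags, "dna_contamination")
    if (any(peaks$is_broad)) flags <- c(flags, "artifact_hump_present")
    if (nrow(assignment$unassigned)) flags <- c(flags, "unassigned_peaks")
    if (all(c("MMP10", "ALAS2") %in% mc$marker[mc$detected]))
        flags <- c(flags, "possible_menstrual")
    if (length(fluids) >= 2) flags <- c(flags, "mixture")
    row <- data.frame(sample_id = sample_id,
                      fluid_calls = paste(fluids, collapse = ";"),
                      flags = paste(flags, collapse = ";"),
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(mc))) {
        row[[paste0(mc$marker[i], "_detected")]] <- mc$detected[i]
        row[[paste0(mc$marker[i], "_tm")]] <- mc$observed_tm[i]
    }
    row$n_unassigned <- nrow(assignment$unassigned)
    row
}

#' Classify a cohort of melt curves end to end
#'
#' Runs the full chain per sample: baseline normalization, derivative
#' transform, peak calling, window assignment and interpretation.
#' Samples whose grid does not match the panel produce per-sample error
#' records instead of aborting the cohort.
#'
#' @param mcs a raw [MeltCurveSet].
#' @param panel an [HRMPanel].
#' @param peak_config a [peakCallConfig()].
#' @param smooth_window,smooth_degree passed to [derivativeCurves()].
#' @return `data.frame` with one row per sample ([interpretSample()]
#'   columns plus `error`, `NA` when the sample processed cleanly).
#' @examples
#' p <- builtinPanel("duplex_blood_menstrual")
#' mcs <- simulateSample(meltComponents(85.8, marker = "ALAS2"),
#'                       simConfig(p, noise_sd = 0), "blood_01")
#' classifyCohort(mcs, p)[, c("sample_id", "fluid_calls", "ALAS2_tm")]
#' @export
classifyCohort <- function(mcs, panel, peak_config = peakCallConfig(),
                           smooth_window = 7, smooth_degree = 2) {
    stopifnot(is(mcs, "MeltCurveSet"), is(panel, "HRMPanel"))
    ids <- colnames(mcs)
    if (!length(ids)) {
        res <- interpretSample(assignPeaks(.emptyPeaks(), panel),
                               .emptyPeaks())[0, , drop = FALSE]
        res$error <- character(0)
        return(res)
    }
    grid_ok <- isTRUE(all.equal(temperatures(mcs), panelGrid(panel),
                                tolerance = 1e-6))
    rows <- vector("list", length(ids))
    norm <- if (grid_ok) normalizeCurves(mcs) else NULL
    deriv <- if (grid_ok)
        derivativeCurves(norm, smooth_window, smooth_degree) else NULL
    all_peaks <- if (grid_ok) callPeaks(deriv, peak_config) else NULL
    for (j in seq_along(ids)) {
        if (!grid_ok) {
            row <- interpretSample(assignPeaks(.emptyPeaks(), panel),
                                   .emptyPeaks(), ids[j])
            row$error <- "temperature grid does not match panel"
        } else {
            pk <- all_peaks[all_peaks$sample_id == ids[j], , drop = FALSE]
            row <- interpretSample(assignPeaks(pk, panel), pk, ids[j])
            row$error <- NA_character_
        }
        rows[[j]] <- row
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

.emptyPeaks <- function()
    data.frame(sample_id = character(0), tm = numeric(0), height = numeric(0),
               fwhm = numeric(0), prominence = numeric(0),
               is_broad = logical(0))
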