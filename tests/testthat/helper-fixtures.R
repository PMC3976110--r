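# Shared fixture builders. All synthetic; built in code at test time.

assay <- SummarizedExperiment::assay
colData <- SummarizedExperiment::colData

# noise-free single/multi-component sample on a panel's grid
nf_sample <- function(panel, tm, marker = NA, amplitude = 1,
                      width_scale = 0.35, kind = "amplicon") {
    simulateSample(meltComponents(tm, amplitude, width_scale, kind, marker),
                   simConfig(panel, noise_sd = 0))
}

# full pipeline to peaks with default configs
pipeline_peaks <- function(mcs, ...) {
    callPeaks(derivativeCurves(normalizeCurves(mcs)), ...)
}

# analytic -dF/dT of a logistic melt component
logistic_deriv <- function(T, tm, w, A = 1) {
    u <- (T - tm) / w
    e <- exp(u)
    A * e / (1 + e)^2 / w
}

LOGISTIC_FWHM <- 2 * log(3 + 2 * sqrt(2))   # fwhm of -dF/dT per unit w
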