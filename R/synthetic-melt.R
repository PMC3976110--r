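#' @include melt-curve-set.R
NULL

.COMPONENT_KINDS <- c("amplicon", "dimer_hump", "dna_product")

#' Melt components: two-state amplicon melts and artifacts
#'
#' A melt component is one double-stranded product in the reaction. Its
#' contribution to the raw fluorescence trace is a falling logistic
#' sigmoid centred on the transition midpoint `tm`:
#' `f(T) = amplitude / (1 + exp((T - tm) / width_scale))`,
#' the simplest two-state melting model. Specific amplicons use a sharp
#' transition (`width_scale` ~0.35 degC, giving a -dF/dT peak of FWHM
#' ~1.2 degC); primer-dimer "humps" use `width_scale` >= 1.5 degC, which
#' is what makes them broad and rejectable downstream; genomic-DNA
#' products melt like amplicons but at their own Tm.
#'
#' @param tm transition midpoint(s), degrees C.
#' @param amplitude fluorescence amplitude(s), >= 0 (recycled).
#' @param width_scale logistic scale(s) in degrees C, > 0 (recycled).
#' @param kind `"amplicon"`, `"dimer_hump"` or `"dna_product"` (recycled).
#' @param marker optional marker symbol(s) for bookkeeping.
#' @return a `data.frame` with columns `kind`, `marker`, `tm`,
#'   `amplitude`, `width_scale`, one row per component.
#' @examples
#' meltComponents(tm = c(82.2, 83.5), marker = "MMP10")
#' @export
meltComponents <- function(tm, amplitude = 1, width_scale = 0.35,
                           kind = "amplicon", marker = NA_character_) {
    n <- length(tm)
    comp <- data.frame(kind = rep_len(kind, n),
                       marker = rep_len(marker, n),
                       tm = tm,
                       amplitude = rep_len(amplitude, n),
                       width_scale = rep_len(width_scale, n),
                       stringsAsFactors = FALSE)
    if (!all(comp$kind %in% .COMPONENT_KINDS))
        stop("kind must be one of: ", paste(.COMPONENT_KINDS, collapse = ", "))
    if (any(comp$amplitude < 0)) stop("amplitude must be >= 0")
    if (any(comp$width_scale <= 0)) stop("width_scale must be > 0")
    comp
}

.checkGrid <- function(grid) {
    if (length(grid) < 2 || any(diff(grid) <= 0) ||
        (max(diff(grid)) - min(diff(grid))) > 1e-6)
        stop("temperature grid must be ascending and uniform")
    invisible(grid)
}

#' Evaluate melt components on a temperature grid
#'
#' Returns the noise-free fluorescence trace of one or more components
#' (summed when several rows are given). Each component contributes
#' `amplitude / (1 + exp((T - tm) / width_scale))`: monotone
#' non-increasing in T, equal to `amplitude / 2` at `tm`, with analytic
#' -dF/dT peak height `amplitude / (4 * width_scale)` and FWHM
#' `2 * log(3 + 2 * sqrt(2)) * width_scale` (about `3.5255 * width_scale`).
#'
#' @param components a `data.frame` from [meltComponents()].
#' @param grid ascending uniform temperature grid, degrees C.
#' @return numeric trace, same length as `grid`.
#' @export
componentCurve <- function(components, grid) {
    .checkGrid(grid)
    tr <- numeric(length(grid))
    for (i in seq_len(nrow(components)))
        tr <- tr + components$amplitude[i] /
            (1 + exp((grid - components$tm[i]) / components$width_scale[i]))
    tr
}

#' Simulation configuration
#'
#' Bundles everything [simulateSample()] and [simulateCohort()] need
#' besides the components themselves: the temperature grid (taken from a
#' panel or given directly), the additive measurement-noise SD, and a
#' linear baseline `intercept + slope * T` emulating the slow
#' background-fluorescence decay of the dye.
#'
#' @param panel an [HRMPanel] supplying grid and melt range (optional if
#'   `grid` is given).
#' @param grid explicit temperature grid (overrides `panel`).
#' @param noise_sd SD of i.i.d. Gaussian noise per grid point, in
#'   fluorescence units relative to unit component amplitudes;
#'   default 0.003.
#' @param baseline_intercept,baseline_slope linear background
#'   fluorescence; defaults 2.0 and -0.01 units/degC.
#' @param seed integer seed making simulation deterministic; `NULL`
#'   leaves the RNG state alone.
#' @return a list of class `simConfig`.
#' @export
simConfig <- function(panel = NULL, grid = NULL, noise_sd = 0.003,
                      baseline_intercept = 2, baseline_slope = -0.01,
                      seed = NULL) {
    if (is.null(grid)) {
        if (is.null(panel)) stop("give either a panel or an explicit grid")
        grid <- panelGrid(panel)
    }
    .checkGrid(grid)
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    structure(list(grid = grid, noise_sd = noise_sd,
                   baseline_intercept = baseline_intercept,
                   baseline_slope = baseline_slope, seed = seed),
              class = "simConfig")
}

## core trace builder; never touches the RNG seed itself
.simTrace <- function(components, config) {
    grid <- config$grid
    if (nrow(components) &&
        (any(components$tm < grid[1]) || any(components$tm > grid[length(grid)])))
        stop("component tm outside the temperature grid range")
    tr <- componentCurve(components, grid) +
        config$baseline_intercept + config$baseline_slope * grid
    if (config$noise_sd > 0)
        tr <- tr + stats::rnorm(length(grid), 0, config$noise_sd)
    tr
}

#' Simulate one melt curve
#'
#' Sums the component sigmoids, adds the linear baseline and i.i.d.
#' Gaussian noise. With `noise_sd = 0` the curve is noise-free;
#' with a fixed `seed` in the configuration the output is bit-identical
#' across calls.
#'
#' @param components `data.frame` from [meltComponents()] (zero rows
#'   give baseline plus noise only).
#' @param config a [simConfig()].
#' @param sample_id column name of the sample.
#' @return a one-sample raw [MeltCurveSet].
#' @examples
#' p <- builtinPanel("duplex_blood_menstrual")
#' cfg <- simConfig(p, noise_sd = 0)
#' mcs <- simulateSample(meltComponents(85.8, marker = "ALAS2"), cfg)
#' @export
simulateSample <- function(components, config, sample_id = "sample_1") {
    if (!is.null(config$seed)) set.seed(config$seed)
    MeltCurveSet(config$grid, .simTrace(components, config),
                 sample_ids = sample_id)
}

## Detection frequencies of the published donor cohorts, per assay scheme.
## duplex: original primer designs; hexaplex: redesigned hexaplex assay.
.MARKER_PROBS <- list(
    duplex = list(
        vaginal   = c(IL19 = 6 / 10, MMP10 = 4 / 18),
        skin      = c(IL1F7 = 1),
        blood     = c(ALAS2 = 7 / 8),
        menstrual = c(MMP10 = 1, ALAS2 = 4 / 5, IL19 = 3 / 5),
        saliva    = c(HTN3 = 15 / 18),
        semen     = c(TGM4 = 4 / 5)),
    hexaplex = list(
        saliva    = c(HTN3 = 11 / 13),
        vaginal   = c(IL19 = 1, MMP10 = 3 / 9),
        menstrual = c(MMP10 = 1, ALAS2 = 3 / 4),
        semen     = c(TGM4 = 11 / 12),
        skin      = c(CCL27 = 1),
        blood     = c(ALAS2 = 1)))

#' Donor model: what a body-fluid sample contains, probabilistically
#'
#' Describes the generative model of one donor's reaction on a panel:
#' per-marker presence probabilities (defaults are the published
#' detection frequencies of the donor cohorts, e.g. menstrual blood
#' carries MMP10 always, ALAS2 with probability 0.8 and vaginal IL19
#' with probability 0.6 on the duplex assays), artifact probabilities,
#' a log-normal amplitude law, and per-marker Tm dispersion: each
#' product's Tm is normal around the published mean with the SD implied
#' by its +/- 3SD window, truncated to that window. Products of one
#' marker (the dual-product MMP10 reaction) share a single standardized
#' shift, since both amplicons melt under the same reaction conditions;
#' this keeps their separation near the published 1.3 degC instead of
#' letting independent draws collapse the pair below the resolution
#' limit of the derivative plot.
#'
#' @param fluid body fluid of the donor (`blood`, `semen`, `saliva`,
#'   `vaginal`, `menstrual`, `skin`).
#' @param panel the [HRMPanel] the sample will be run on; decides the
#'   default probability table (hexaplex vs duplex-era designs) and the
#'   panel-specific genomic-DNA product Tms.
#' @param marker_probs named numeric overriding/extending the default
#'   marker presence probabilities.
#' @param artifact_probs named numeric with entries `dimer_hump` and
#'   `dna_product`, each in `[0, 1]`. Defaults: `dimer_hump` 0.5 for the
#'   fluids whose primers produce broad low-temperature humps on the
#'   original duplexes (semen on saliva/semen, vaginal on vaginal/skin),
#'   otherwise 0; `dna_product` 0.
#' @param amplitude_law `c(meanlog, sdlog)` of the log-normal amplitude
#'   distribution (one draw per marker, shared by its products);
#'   default `c(0, 0.4)`.
#' @return a list of class `donorModel`.
#' @export
donorModel <- function(fluid, panel,
                       marker_probs = NULL,
                       artifact_probs = NULL,
                       amplitude_law = c(meanlog = 0, sdlog = 0.4)) {
    stopifnot(is(panel, "HRMPanel"))
    scheme <- if (panelName(panel) == "hexaplex") "hexaplex" else "duplex"
    if (!fluid %in% names(.MARKER_PROBS[[scheme]]))
        stop("unknown body fluid '", fluid, "'")
    probs <- .MARKER_PROBS[[scheme]][[fluid]]
    if (!is.null(marker_probs)) probs[names(marker_probs)] <- marker_probs
    ap <- c(dimer_hump = 0, dna_product = 0)
    if (scheme == "duplex" &&
        ((fluid == "semen" && panelName(panel) == "duplex_saliva_semen") ||
         (fluid == "vaginal" && panelName(panel) == "duplex_vaginal_skin")))
        ap["dimer_hump"] <- 0.5
    if (!is.null(artifact_probs)) ap[names(artifact_probs)] <- artifact_probs
    if (any(probs < 0 | probs > 1) || any(ap < 0 | ap > 1))
        stop("probabilities must lie in [0, 1]")
    ## genomic-DNA product Tms known for these assays: the hexaplex IL19
    ## DNA product (80.6) and the original-design MMP10 DNA products
    ## (78.5 and 83.1)
    dna_tms <- if (scheme == "hexaplex") 80.6
               else if ("MMP10" %in% markerNames(panel)) c(78.5, 83.1)
               else numeric(0)
    structure(list(body_fluid = fluid, marker_probs = probs,
                   artifact_probs = ap, amplitude_law = amplitude_law,
                   dna_tms = dna_tms),
              class = "donorModel")
}

## normal(mean, sd) truncated to [low, high]; sd = 0 degenerates to mean
.rtruncnorm1 <- function(mean, sd, low, high) {
    if (sd <= 0) return(mean)
    for (i in 1:100) {
        x <- stats::rnorm(1, mean, sd)
        if (x >= low && x <= high) return(x)
    }
    mean
}

## draw one donor's components; uses the current RNG stream
.drawDonorComponents <- function(model, panel, grid) {
    m <- markerTable(panel)
    comps <- meltComponents(numeric(0))
    for (mk in markerNames(panel)) {
        p <- model$marker_probs[mk]
        if (is.na(p) || stats::runif(1) > p) next
        amp <- stats::rlnorm(1, model$amplitude_law[1], model$amplitude_law[2])
        w <- m[m$marker == mk, , drop = FALSE]
        ## one standardized Tm shift per marker: all products of one
        ## reaction see the same salt/dye/ramp conditions, so their Tms
        ## co-vary (each scaled to its own window SD). Truncation to
        ## |z| <= 3 keeps every product inside its +/- 3SD window.
        z <- .rtruncnorm1(0, 1, -3, 3)
        for (i in seq_len(nrow(w))) {
            sd <- sdFromWindow(c(w$window_low[i], w$window_high[i]))
            comps <- rbind(comps, meltComponents(w$tm_mean[i] + z * sd,
                                                 amp, 0.35, "amplicon", mk))
        }
    }
    if (stats::runif(1) <= model$artifact_probs["dimer_hump"]) {
        lo <- max(grid[1] + 1.5, 71)
        tm <- stats::runif(1, lo, min(77.5, grid[length(grid)] - 1))
        comps <- rbind(comps, meltComponents(
            tm, 0.5 * stats::rlnorm(1, model$amplitude_law[1],
                                    model$amplitude_law[2]),
            stats::runif(1, 1.5, 2.5), "dimer_hump"))
    }
    if (length(model$dna_tms) &&
        stats::runif(1) <= model$artifact_probs["dna_product"]) {
        amp <- stats::rlnorm(1, model$amplitude_law[1], model$amplitude_law[2])
        comps <- rbind(comps, meltComponents(model$dna_tms, amp, 0.35,
                                             "dna_product"))
    }
    comps
}

#' Simulate one donor of a body fluid
#'
#' Draws which markers and artifacts the donor's reaction contains
#' (independent Bernoulli draws with the model's probabilities), draws
#' Tms and amplitudes, and renders the melt curve. The returned truth
#' record lists every included component.
#'
#' @param fluid body-fluid label, known to `model`.
#' @param model a [donorModel()].
#' @param panel the [HRMPanel] simulated.
#' @param config a [simConfig()]; its `seed`, when non-NULL, seeds the
#'   draw.
#' @param sample_id sample identifier.
#' @return list with elements `curves` (one-sample raw [MeltCurveSet]
#'   whose `colData()$fluid` is the true fluid) and `truth` (components
#'   `data.frame` with `sample_id` and `fluid` columns).
#' @export
sampleDonor <- function(fluid, model, panel, config,
                        sample_id = "sample_1") {
    stopifnot(inherits(model, "donorModel"), model$body_fluid == fluid)
    if (!is.null(config$seed)) set.seed(config$seed)
    comps <- .drawDonorComponents(model, panel, config$grid)
    curves <- MeltCurveSet(config$grid, .simTrace(comps, config),
                           sample_ids = sample_id,
                           colData = S4Vectors::DataFrame(fluid = fluid))
    truth <- if (nrow(comps))
        cbind(sample_id = sample_id, fluid = fluid, comps)
    else data.frame(sample_id = sample_id, fluid = fluid, kind = "none",
                    marker = NA_character_, tm = NA_real_,
                    amplitude = NA_real_, width_scale = NA_real_,
                    stringsAsFactors = FALSE)
    list(curves = curves, truth = truth)
}

#' Simulate a donor cohort
#'
#' Generates `fluid_counts[f]` independent donors of each fluid `f`,
#' reproducibly under the configuration seed.
#'
#' @param fluid_counts named integer vector, donors per body fluid
#'   (e.g. `c(menstrual = 5, blood = 8)`).
#' @param panel the [HRMPanel].
#' @param config a [simConfig()]; `config$seed` seeds the whole cohort.
#' @param models optional named list of [donorModel()]s per fluid;
#'   defaults are built per fluid.
#' @return list with `curves` (a raw [MeltCurveSet], `colData()$fluid`
#'   holding truth labels) and `truth` (long `data.frame` of included
#'   components, one row per component, `kind == "none"` rows for blank
#'   samples).
#' @examples
#' p <- builtinPanel("duplex_blood_menstrual")
#' sim <- simulateCohort(c(menstrual = 3), p, simConfig(p, seed = 7))
#' sim$truth
#' @export
simulateCohort <- function(fluid_counts, panel, config, models = NULL) {
    stopifnot(!is.null(names(fluid_counts)), all(fluid_counts >= 0))
    if (!is.null(config$seed)) set.seed(config$seed)
    grid <- config$grid
    n <- sum(fluid_counts)
    traces <- matrix(0, nrow = length(grid), ncol = n)
    fluids <- character(n)
    truth <- list()
    ids <- character(n)
    k <- 0
    for (f in names(fluid_counts)) {
        model <- if (!is.null(models[[f]])) models[[f]] else donorModel(f, panel)
        for (j in seq_len(fluid_counts[[f]])) {
            k <- k + 1
            ids[k] <- sprintf("%s_%03d", f, j)
            fluids[k] <- f
            comps <- .drawDonorComponents(model, panel, grid)
            traces[, k] <- .simTrace(comps, config)
            truth[[k]] <- if (nrow(comps))
                cbind(sample_id = ids[k], fluid = f, comps)
            else data.frame(sample_id = ids[k], fluid = f, kind = "none",
                            marker = NA_character_, tm = NA_real_,
                            amplitude = NA_real_, width_scale = NA_real_,
                            stringsAsFactors = FALSE)
        }
    }
    curves <- MeltCurveSet(grid, traces, sample_ids = ids,
                           colData = S4Vectors::DataFrame(fluid = fluids))
    truth <- if (length(truth)) do.call(rbind, truth)
    else data.frame(sample_id = character(0), fluid = character(0),
                    kind = character(0), marker = character(0),
                    tm = numeric(0), amplitude = numeric(0),
                    width_scale = numeric(0), stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    list(curves = curves, truth = truth)
}
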