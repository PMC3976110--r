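test_that("peak calling recovers isolated published-Tm products exactly", {
    h <- builtinPanel("hexaplex")
    pk <- pipeline_peaks(nf_sample(h, 82.7, "TGM4"))
    expect_equal(nrow(pk), 1)
    expect_equal(pk$tm, 82.7)
    expect_false(pk$is_broad)

    # all-zero derivative yields no peaks
    grid <- seq(65, 90, by = 0.1)
    zero <- derivativeCurves(MeltCurveSet(grid, rep(1, length(grid))))
    expect_equal(nrow(callPeaks(zero)), 0)
})

test_that("broad humps are flagged by their FWHM", {
    p <- builtinPanel("duplex_saliva_semen")
    # w = 2 gives FWHM ~ 3.5255 * 2 = 7.05, far above the 2.0 cutoff
    pk <- pipeline_peaks(nf_sample(p, 77, width_scale = 2))
    expect_equal(nrow(pk), 1)
    expect_true(pk$is_broad)
    expect_equal(pk$fwhm, LOGISTIC_FWHM * 2, tolerance = 0.05)

    # sharp product against the same analytic oracle; the cubic filter
    # preserves the width to < 2%, the default quadratic broadens it ~6%
    grid <- seq(65, 90, by = 0.1)
    sharp <- MeltCurveSet(grid, componentCurve(meltComponents(80), grid))
    pk2 <- callPeaks(derivativeCurves(sharp, smooth_degree = 3))
    expect_equal(pk2$fwhm, LOGISTIC_FWHM * 0.35, tolerance = 0.02)
    expect_false(pk2$is_broad)
    pk2q <- callPeaks(derivativeCurves(sharp))
    expect_equal(pk2q$fwhm, LOGISTIC_FWHM * 0.35, tolerance = 0.08)
    expect_false(pk2q$is_broad)
})

test_that("close peaks merge keeping the taller component", {
    grid <- seq(65, 90, by = 0.1)
    # 1.5 degC apart: two distinct derivative maxima exist
    comps <- rbind(meltComponents(80.0, amplitude = 1),
                   meltComponents(81.5, amplitude = 0.6))
    d <- derivativeCurves(MeltCurveSet(grid, componentCurve(comps, grid)))
    pk2 <- callPeaks(d, peakCallConfig(min_separation = 0.5))
    expect_equal(nrow(pk2), 2)
    # a merge radius wider than the separation keeps only the taller;
    # brute-force oracle on the constructed curve: the global maximum
    v <- assay(d)[, 1]
    tm_oracle <- round(temperatures(d)[which.max(v)], 1)
    pk <- callPeaks(d, peakCallConfig(min_separation = 2.0))
    expect_equal(nrow(pk), 1)
    expect_equal(pk$tm, tm_oracle)
    # exactly equal heights: deterministic tie-break keeps the lower
    # temperature (constructed symmetric twin-peak derivative)
    g2 <- seq(70, 75, by = 0.1)
    tri <- function(centre) pmax(0, 1 - abs(g2 - centre) / 0.3)
    dt <- MeltCurveSet(g2, tri(71) + tri(74), curve_type = "derivative")
    pkt <- callPeaks(dt, peakCallConfig(min_separation = 5))
    expect_equal(nrow(pkt), 1)
    expect_equal(pkt$tm, 71.0)
})

test_that("raising the threshold never increases the peak count", {
    p <- builtinPanel("hexaplex")
    set.seed(17)
    sim <- simulateCohort(c(menstrual = 3, saliva = 2), p,
                          simConfig(p, seed = 17))
    d <- derivativeCurves(normalizeCurves(sim$curves))
    for (j in colnames(sim$curves)) {
        dj <- d[, j]
        counts <- vapply(c(0, 0.01, 0.05, 0.1, 0.3, 0.7), function(thr)
            nrow(callPeaks(dj, peakCallConfig(y_threshold = thr))), 0L)
        expect_true(all(diff(counts) <= 0))
    }
})

test_that("no called peak lies inside an x-axis exclusion", {
    p <- builtinPanel("duplex_saliva_semen")
    mcs <- simulateSample(rbind(meltComponents(76.3, marker = "HTN3"),
                                meltComponents(71, width_scale = 2)),
                          simConfig(p, noise_sd = 0))
    cfgx <- peakCallConfig(x_exclusions = list(c(65, 74.5)))
    pk <- pipeline_peaks(mcs, cfgx)
    expect_true(all(pk$tm > 74.5))
    expect_equal(pk$tm[!pk$is_broad], 76.3)
    # property over random exclusions
    set.seed(4)
    d <- derivativeCurves(normalizeCurves(mcs))
    for (k in 1:20) {
        iv <- sort(65 + 25 * runif(2))
        pk <- callPeaks(d, peakCallConfig(x_exclusions = list(iv)))
        expect_false(any(pk$tm >= iv[1] & pk$tm <= iv[2]))
    }
})

test_that("K separated components yield exactly K non-broad peaks (K <= 6)", {
    grid <- seq(65, 90, by = 0.1)
    set.seed(8)
    for (K in 1:6) {
        for (rep in 1:3) {
            # pairwise separations >= 1.5 degC, amplitudes >= 10x threshold
            tms <- sort(67 + cumsum(runif(K, 1.5, 3.0)))
            amps <- runif(K, 0.7, 2)
            comps <- meltComponents(tms, amps, 0.35)
            d <- derivativeCurves(MeltCurveSet(grid, componentCurve(comps, grid)))
            pk <- callPeaks(d, peakCallConfig(y_threshold = 0.05))
            expect_equal(nrow(pk), K)
            expect_false(any(pk$is_broad))
            # brute-force oracle: local maxima of the constructed dense curve
            fine <- seq(66, 89, by = 1e-3)
            dv <- rowSums(vapply(seq_len(K), function(i)
                logistic_deriv(fine, tms[i], 0.35, amps[i]),
                numeric(length(fine))))
            loc <- which(dv[2:(length(dv) - 1)] > dv[1:(length(dv) - 2)] &
                         dv[2:(length(dv) - 1)] >= dv[3:length(dv)]) + 1
            expect_equal(pk$tm, round(fine[loc], 1), tolerance = 0.1 + 1e-9)
        }
    }
})

test_that("recovered Tm is grid-exact for isolated noise-free components", {
    grid <- seq(65, 90, by = 0.1)
    set.seed(12)
    for (k in 1:25) {
        tm <- round(runif(1, 70, 88), 3)
        d <- derivativeCurves(MeltCurveSet(
            grid, componentCurve(meltComponents(tm), grid)))
        pk <- callPeaks(d)
        expect_equal(nrow(pk), 1)
        expect_lt(abs(pk$tm - tm), 0.1 + 1e-9)
    }
})

test_that("fraction-of-max thresholding suppresses weak humps under strong peaks", {
    p <- builtinPanel("duplex_saliva_semen")
    grid <- panelGrid(p)
    comps <- rbind(meltComponents(76.3, 3, marker = "HTN3"),
                   meltComponents(71, 1, width_scale = 2))
    d <- derivativeCurves(MeltCurveSet(grid, componentCurve(comps, grid)))
    pk_abs <- callPeaks(d, peakCallConfig(y_threshold = 0.05))
    expect_equal(nrow(pk_abs), 2)
    expect_true(pk_abs$is_broad[pk_abs$tm == 71])
    pk_frac <- callPeaks(d, peakCallConfig(y_threshold = 0.2,
                                           threshold_mode = "fraction"))
    expect_equal(nrow(pk_frac), 1)
    expect_equal(pk_frac$tm, 76.3)
})
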