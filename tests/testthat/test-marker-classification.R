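mkpeaks <- function(tm, height = 0.5, is_broad = FALSE) {
    n <- length(tm)
    data.frame(sample_id = rep("s", n), tm = tm,
               height = rep_len(height, n),
               fwhm = rep_len(ifelse(is_broad, 7, 1.2), n),
               prominence = rep_len(height, n),
               is_broad = rep_len(is_broad, n))
}

test_that("peaks assign to marker windows; DNA window raises the flag only", {
    h <- builtinPanel("hexaplex")
    a <- assignPeaks(mkpeaks(80.6), h)
    expect_true(a$dna_flag)
    expect_false(any(a$marker_calls$detected))
    expect_equal(nrow(a$unassigned), 0)

    # no peaks: nothing detected
    a0 <- assignPeaks(mkpeaks(numeric(0)), h)
    expect_false(any(a0$marker_calls$detected))
    expect_false(a0$dna_flag)

    # boundary membership is inclusive (closed windows)
    a_edge <- assignPeaks(mkpeaks(c(82.4, 83.0)), h)   # TGM4 window edges
    expect_true(a_edge$marker_calls$detected[a_edge$marker_calls$marker == "TGM4"])
})

test_that("genomic-DNA MMP10 products never call MMP10 on the duplex", {
    p <- builtinPanel("duplex_blood_menstrual")
    a <- assignPeaks(mkpeaks(c(78.5, 83.1)), p)
    mc <- a$marker_calls
    expect_false(mc$detected[mc$marker == "MMP10"])
    # 83.1 matches the supporting second-product window; 78.5 matches nothing
    expect_equal(a$unassigned$tm, 78.5)
    expect_false(a$dna_flag)

    # true mRNA products in the required window do call MMP10
    a2 <- assignPeaks(mkpeaks(c(82.2, 83.5)), p)
    mc2 <- a2$marker_calls
    expect_true(mc2$detected[mc2$marker == "MMP10"])
    expect_equal(mc2$observed_tm[mc2$marker == "MMP10"], 82.2)
    expect_equal(nrow(a2$unassigned), 0)
})

test_that("broad peaks and overlapping panels are handled defensively", {
    p <- builtinPanel("duplex_saliva_semen")
    # a broad hump sitting on HTN3's window must not call saliva
    a <- assignPeaks(mkpeaks(76.3, is_broad = TRUE), p)
    expect_false(any(a$marker_calls$detected))
    expect_equal(nrow(a$unassigned), 0)

    mks <- rbind(markerTable(builtinPanel("singleplex_MMP10")),
                 markerTable(builtinPanel("singleplex_IL1F7")))
    bad <- new("HRMPanel", name = "bad", markers = mks,
               meltRange = c(65, 90), gridStep = 0.1, dnaWindow = numeric(0))
    expect_error(assignPeaks(mkpeaks(83.2), bad), "overlapping")
})

test_that("interpretation derives fluids and flags from marker calls", {
    h <- builtinPanel("hexaplex")
    # saliva + vaginal co-detection: both fluids, mixture flag
    a <- assignPeaks(mkpeaks(c(76.6, 78.6)), h)
    row <- interpretSample(a, mkpeaks(c(76.6, 78.6)))
    expect_equal(row$fluid_calls, "saliva;vaginal")
    expect_match(row$flags, "mixture")

    # MMP10 + ALAS2 co-detection flags possible menstrual blood
    p <- builtinPanel("duplex_blood_menstrual")
    a2 <- assignPeaks(mkpeaks(c(82.2, 85.8)), p)
    row2 <- interpretSample(a2, mkpeaks(c(82.2, 85.8)))
    expect_match(row2$flags, "possible_menstrual")
    expect_match(row2$flags, "mixture")
    expect_equal(row2$fluid_calls, "blood;menstrual")

    # empty calls: no fluids, no flags
    a3 <- assignPeaks(mkpeaks(numeric(0)), h)
    row3 <- interpretSample(a3, mkpeaks(numeric(0)))
    expect_equal(row3$fluid_calls, "")
    expect_equal(row3$flags, "")

    # broad artifact raises the hump flag
    row4 <- interpretSample(a3, mkpeaks(72, is_broad = TRUE))
    expect_match(row4$flags, "artifact_hump_present")
})

test_that("classifyCohort recovers published Tms end to end", {
    p <- builtinPanel("duplex_blood_menstrual")
    res <- classifyCohort(nf_sample(p, 85.8, "ALAS2"), p)
    expect_equal(res$fluid_calls, "blood")
    expect_equal(res$ALAS2_tm, 85.8)
    expect_true(is.na(res$error))

    h <- builtinPanel("hexaplex")
    res2 <- classifyCohort(nf_sample(h, 86.8, "ALAS2"), h)
    expect_equal(res2$fluid_calls, "blood")
    expect_equal(res2$ALAS2_tm, 86.8)

    # empty cohort: empty interpretation table with the same columns
    empty <- MeltCurveSet(panelGrid(p),
                          matrix(0, length(panelGrid(p)), 0))
    res3 <- classifyCohort(empty, p)
    expect_equal(nrow(res3), 0)
    expect_true(all(c("sample_id", "fluid_calls", "flags", "error")
                    %in% names(res3)))

    # grid mismatch yields per-sample error records, not an abort
    wrong <- nf_sample(h, 86.8, "ALAS2")     # hexaplex grid vs duplex panel
    res4 <- classifyCohort(wrong, p)
    expect_equal(nrow(res4), 1)
    expect_match(res4$error, "grid")
})

test_that("every called peak is assigned, unassigned or broad (partition)", {
    h <- builtinPanel("hexaplex")
    set.seed(41)
    sim <- simulateCohort(c(menstrual = 5, vaginal = 5, semen = 5), h,
                          simConfig(h, seed = 41))
    peaks <- suppressWarnings(
        callPeaks(derivativeCurves(normalizeCurves(sim$curves))))
    for (id in unique(peaks$sample_id)) {
        pk <- peaks[peaks$sample_id == id, ]
        a <- assignPeaks(pk, h)
        n_broad <- sum(pk$is_broad)
        n_dna <- sum(!pk$is_broad &
                     pk$tm >= dnaWindow(h)[1] & pk$tm <= dnaWindow(h)[2])
        m <- markerTable(h)
        in_any <- vapply(pk$tm, function(tm)
            any(tm >= m$window_low - 1e-9 & tm <= m$window_high + 1e-9), TRUE)
        n_marker <- sum(!pk$is_broad & in_any)
        expect_equal(n_marker + n_dna + nrow(a$unassigned) + n_broad, nrow(pk))
    }
})

test_that("no fluid is called without an in-window peak", {
    h <- builtinPanel("hexaplex")
    m <- markerTable(h)
    set.seed(52)
    sim <- simulateCohort(c(blood = 4, saliva = 4, skin = 4), h,
                          simConfig(h, seed = 52))
    res <- suppressWarnings(classifyCohort(sim$curves, h))
    peaks <- suppressWarnings(
        callPeaks(derivativeCurves(normalizeCurves(sim$curves))))
    for (i in seq_len(nrow(res))) {
        fluids <- strsplit(res$fluid_calls[i], ";")[[1]]
        pk <- peaks[peaks$sample_id == res$sample_id[i] & !peaks$is_broad, ]
        for (f in fluids) {
            w <- m[m$fluid == f & m$required, ]
            expect_true(any(pk$tm >= w$window_low - 1e-9 &
                            pk$tm <= w$window_high + 1e-9),
                        label = paste("peak support for", f))
        }
    }
})

test_that("end-to-end fluid recovery: 100% noise-free, >= 99% at default noise", {
    h <- builtinPanel("hexaplex")
    m <- markerTable(h)
    n_per <- 150
    for (noise in c(0, 0.003)) {
        set.seed(63)
        correct <- 0
        for (f in panelFluids(h)) {
            w <- m[m$fluid == f, , drop = FALSE]
            cfg <- simConfig(h, noise_sd = noise)
            traces <- vapply(seq_len(n_per), function(k) {
                sd <- (w$window_high - w$window_low) / 6
                tm <- pmin(pmax(stats::rnorm(nrow(w), w$tm_mean, sd),
                                w$window_low), w$window_high)
                amp <- stats::rlnorm(1, 0, 0.4)
                meltID:::.simTrace(
                    meltComponents(tm, amp, 0.35, marker = w$marker), cfg)
            }, numeric(length(cfg$grid)))
            res <- classifyCohort(MeltCurveSet(cfg$grid, traces), h)
            hits <- vapply(strsplit(res$fluid_calls, ";"),
                           function(s) f %in% s, TRUE)
            correct <- correct + sum(hits)
        }
        acc <- correct / (n_per * 6)
        if (noise == 0) expect_equal(acc, 1) else expect_gte(acc, 0.99)
    }
})

test_that("menstrual co-detection frequencies are recovered on cohorts", {
    p <- builtinPanel("duplex_blood_menstrual")
    n <- 800
    sim <- simulateCohort(c(menstrual = n), p, simConfig(p, seed = 19))
    res <- classifyCohort(sim$curves, p)
    # MMP10 always included (truth) and recovered at the pipeline's
    # noisy-recovery standard; ALAS2 at its 0.8 inclusion probability
    expect_equal(length(unique(
        sim$truth$sample_id[sim$truth$marker %in% "MMP10"])), n)
    expect_gte(mean(res$MMP10_detected), 0.99)
    expect_lt(abs(mean(res$ALAS2_detected) - 0.8), 3 * sqrt(0.8 * 0.2 / n))
    both <- res$MMP10_detected & res$ALAS2_detected
    expect_true(all(grepl("possible_menstrual", res$flags[both])))
})
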