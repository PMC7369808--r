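test_that("simulated traces honour the editing-fraction limits", {
    tpl <- traceTemplate()
    site <- 30L

    # f = 0: site G channel sits at baseline level
    set.seed(1)
    g0 <- replicate(1000, traceHeights(simulateTrace(tpl, site, 0))[site, "G"])
    model <- TraceModel()
    baselineMean <- model@noiseFloor / 2 + model@crosstalk
    expect_lt(abs(mean(g0) - baselineMean), 2 * stats::sd(g0) / sqrt(1000))

    # f = 1: site A channel at baseline, G at full height
    set.seed(2)
    t1 <- traceHeights(simulateTrace(tpl, site, 1))
    expect_lt(t1[site, "A"], 0.5)
    expect_gt(t1[site, "G"], 0.5)

    # f = 0.5 with zero noise: A and G heights exactly equal
    quiet <- TraceModel(peakHeightCv = 0, noiseFloor = 0, crosstalk = 0)
    th <- traceHeights(simulateTrace(tpl, site, 0.5, quiet, seed = 3))
    expect_identical(unname(th[site, "A"]), unname(th[site, "G"]))
    expect_identical(unname(th[site, "A"]), 0.5)

    expect_error(simulateTrace(tpl, site, 1.2), "\\[0, 1\\]")
    notA <- which(strsplit(transcriptSeq(tpl), "")[[1]] != "A")[1]
    expect_error(simulateTrace(tpl, notA, 0.5), "not A")
})

test_that("traces are bit-identical under a fixed seed", {
    tpl <- traceTemplate()
    a <- simulateTrace(tpl, 30, 0.4, seed = 99)
    b <- simulateTrace(tpl, 30, 0.4, seed = 99)
    expect_identical(traceHeights(a), traceHeights(b))
    e1 <- estimateEditedFraction(a, 30)
    e2 <- estimateEditedFraction(b, 30)
    expect_identical(estimatedFraction(e1), estimatedFraction(e2))
    # the model's own seed slot drives reproducibility too
    m <- TraceModel(seed = 7L)
    expect_identical(traceHeights(simulateTrace(tpl, 30, 0.4, m)),
                     traceHeights(simulateTrace(tpl, 30, 0.4, m)))
})

test_that("a noise-free half-edited site is estimated at exactly 0.5", {
    tpl <- traceTemplate()
    quiet <- TraceModel(peakHeightCv = 0, noiseFloor = 0, crosstalk = 0)
    tr <- simulateTrace(tpl, 30, 0.5, quiet, seed = 5)
    est <- estimateEditedFraction(tr, 30)
    expect_identical(estimatedFraction(est), 0.5)
    expect_true(peakDetected(est))
})

test_that("the fraction estimator is nearly unbiased under the default model", {
    tpl <- traceTemplate()
    set.seed(17)
    for (f in c(0.1, 0.5, 0.9)) {
        fh <- replicate(500, estimatedFraction(
            estimateEditedFraction(simulateTrace(tpl, 30, f), 30)))
        expect_lt(abs(mean(fh) - f), 0.02)
    }
})

test_that("a 5% edited fraction stays below the detection rule", {
    tpl <- traceTemplate()
    set.seed(23)
    det <- replicate(200, peakDetected(
        estimateEditedFraction(simulateTrace(tpl, 30, 0.05), 30)))
    expect_gte(mean(!det), 0.9)
})

test_that("detection rate is monotone in the edited fraction", {
    tpl <- traceTemplate()
    for (s in 1:5) {
        lim <- detectionLimit(tpl, 30, nReps = 40L, seed = s)
        rates <- attr(lim, "rates")
        expect_true(all(diff(rates) >= -0.1))  # monotone up to MC jitter
        expect_true(all(cummax(rates >= 0.9) == (rates >= 0.9)) ||
                    !any(rates >= 0.9))
    }
})

test_that("a noise-free model detects the smallest nonzero fraction", {
    tpl <- traceTemplate()
    quiet <- TraceModel(peakHeightCv = 0, noiseFloor = 1e-6, crosstalk = 0)
    lim <- detectionLimit(tpl, 30, fractions = c(0.05, 0.10), nReps = 10L,
                          model = quiet, seed = 1)
    expect_equal(as.numeric(lim), 0.05)
})

test_that("detectionLimit validates its grid and is seed-deterministic", {
    tpl <- traceTemplate()
    expect_error(detectionLimit(tpl, 30, fractions = numeric(0)),
                 "non-empty")
    expect_error(detectionLimit(tpl, 30, fractions = c(0.3, 0.2)),
                 "ascending")
    l1 <- detectionLimit(tpl, 30, nReps = 30L, seed = 11)
    l2 <- detectionLimit(tpl, 30, nReps = 30L, seed = 11)
    expect_identical(attr(l1, "rates"), attr(l2, "rates"))
})

test_that("trace tables round-trip through TSV", {
    tpl <- traceTemplate()
    tr <- simulateTrace(tpl, 30, 0.35, seed = 12)
    path <- tempfile(fileext = ".tsv")
    writeTraceTable(tr, path)
    back <- readTraceTable(path)
    expect_equal(traceHeights(back), traceHeights(tr), tolerance = 1e-12)

    tiny <- Trace("t", matrix(runif(24), ncol = 4))
    path2 <- tempfile(fileext = ".tsv")
    writeTraceTable(tiny, path2)
    expect_identical(nrow(traceHeights(readTraceTable(path2))), 6L)
})

test_that("trace table errors are explicit", {
    path <- tempfile(fileext = ".tsv")
    writeLines(c("position\tA\tC\tG", "1\t1\t0\t0"), path)
    expect_error(readTraceTable(path), "missing columns: T")
    path2 <- tempfile(fileext = ".tsv")
    writeLines(c("position\tA\tC\tG\tT", "1\t1\t0\t0\t0",
                 "2\tx\t0\t0\t0"), path2)
    expect_error(readTraceTable(path2), "line 2")
    expect_error(readTraceTable("trace.ab1"), "not enabled")
})

test_that("sites too close to the trace edge are rejected, short flanks warned", {
    tpl <- traceTemplate()
    tr <- simulateTrace(tpl, 30, 0.5, seed = 8)
    expect_error(estimateEditedFraction(tr, 2), "flanking")
    expect_warning(estimateEditedFraction(tr, 55), "flank truncated")
})
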