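test_that("the worked 50-34 design has the printed geometry", {
    cftr <- fixturePreset("cftr-w1282x")
    d <- designSpacer(cftr, 3846, DesignParams(50, 34))
    expect_identical(spacerLength(d), 50L)
    expect_identical(mismatchDistance(d), 34L)
    # C at position 34 from the 3' end
    expect_identical(substr(spacerSeq(d), 50 - 34 + 1, 50 - 34 + 1), "C")
    expect_identical(designWindow(d), c(3846L - 34L + 1L, 3846L + 50L - 34L))
    expect_identical(substr(spacerSeq(d), 1, 1), "G")
    # no structural defects (advisory sequence-context warnings aside)
    expect_false(any(validateDesign(d)$code != "warning"))
})

test_that("a mismatch at the 5' base requires the prepend policy", {
    set.seed(12)
    rec <- randomRecordWithA(80, 40)
    expect_error(designSpacer(rec, 40, DesignParams(30, 30)),
                 "prepend")
    d <- designSpacer(rec, 40, DesignParams(30, 30, "prepend"))
    expect_identical(spacerLength(d), 31L)
    expect_identical(substr(spacerSeq(d), 1, 1), "G")
    expect_identical(substr(spacerSeq(d), 2, 2), "C")
})

test_that("5'-G substitute is a no-op when the spacer already starts with G", {
    # window top base C -> spacer 5' base G naturally
    rec <- TranscriptRecord("t", paste0(strrep("T", 5), "A", strrep("T", 10), "C"))
    d <- designSpacer(rec, 6, DesignParams(12, 1, minLength = 5))
    expect_identical(substr(spacerSeq(d), 1, 1), "G")
    expect_false(d@fivePrimeBaseModified)
    # and acts (with flag) when it does not
    rec2 <- TranscriptRecord("t2", paste0(strrep("T", 5), "A", strrep("T", 11)))
    d2 <- designSpacer(rec2, 6, DesignParams(12, 1, minLength = 5))
    expect_identical(substr(spacerSeq(d2), 1, 1), "G")
    expect_true(d2@fivePrimeBaseModified)
})

test_that("prepend and require policies behave as declared", {
    rec <- TranscriptRecord("t", paste0(strrep("T", 5), "A", strrep("T", 11)))
    p <- designSpacer(rec, 6, DesignParams(12, 1, "prepend", minLength = 5))
    expect_identical(spacerLength(p), 13L)
    expect_identical(substr(spacerSeq(p), 1, 1), "G")
    expect_true(p@fivePrimeBaseModified)
    expect_error(
        designSpacer(rec, 6, DesignParams(12, 1, "require", minLength = 5)),
        "not G")
})

test_that("every spacer/window hybrid has exactly one C:A mismatch at distance d", {
    set.seed(55)
    for (i in 1:200) {
        L <- sample(25:60, 1)
        d <- sample(1:(L - 1), 1)  # d = L needs the prepend policy
        n <- L + 40L
        aPos <- sample(seq(d, n - (L - d)), 1)
        rec <- randomRecordWithA(n, aPos)
        des <- designSpacer(rec, aPos, DesignParams(L, d))
        win <- designWindow(des)
        winSeq <- substr(transcriptSeq(rec), win[1], win[2])
        mism <- oracleHybridMismatches(spacerSeq(des), winSeq)
        # the C:A mismatch at d, plus at most the 5'-substituted base (3'-position L)
        expect_true(d %in% mism)
        extra <- setdiff(mism, d)
        if (des@fivePrimeBaseModified) expect_true(all(extra == L))
        else expect_length(extra, 0L)
        # the mismatch really is C opposite the target A
        spacerChars <- strsplit(spacerSeq(des), "")[[1]]
        expect_identical(spacerChars[L - d + 1], "C")
        expect_identical(substr(transcriptSeq(rec), aPos, aPos), "A")
        expect_true(aPos >= win[1] && aPos <= win[2])
    }
})

test_that("designSpacer rejects invalid targets, windows and parameters", {
    rec <- TranscriptRecord("t", strrep("ATG", 30))
    expect_error(designSpacer(rec, 3, DesignParams(30, 10)),
                 "not an adenosine")
    expect_error(designSpacer(rec, 4, DesignParams(50, 45)), "window")
    expect_error(DesignParams(50, 55), "must not exceed")
    expect_error(DesignParams(20, 10), "below minimum")
    expect_error(DesignParams(90, 10), "above maximum")
})

test_that("enumerateDesigns walks the grids of the two worked systems", {
    gfp <- fixturePreset("h2bgfp-opal")
    grids <- presetDesignGrids()
    resG <- enumerateDesigns(gfp, 570, grids$GFP)
    expect_length(resG$designs, 4L)
    expect_length(resG$failures, 0L)
    expect_identical(vapply(resG$designs, spacerLength, integer(1)),
                     c(50L, 50L, 50L, 30L))
    expect_identical(vapply(resG$designs, mismatchDistance, integer(1)),
                     c(32L, 34L, 35L, 25L))

    cftr <- fixturePreset("cftr-w1282x")
    resC <- enumerateDesigns(cftr, 3846, grids$CFTR)
    expect_length(resC$designs, 3L)

    # a failing grid entry is reported without aborting the batch
    mixed <- c(grids$CFTR[1:2],
               list(DesignParams(50, 34)))
    res <- enumerateDesigns(TranscriptRecord("short", strrep("TA", 30)),
                            2, mixed)
    expect_length(res$designs, 0L)
    expect_length(res$failures, 3L)
    expect_error(enumerateDesigns(gfp, 570, list()), "at least one")

    # singleton grid is equivalent to designSpacer
    single <- enumerateDesigns(gfp, 570, grids$GFP[2])$designs[[1]]
    expect_identical(spacerSeq(single),
                     spacerSeq(designSpacer(gfp, 570, grids$GFP[[2]])))
})

test_that("oligo pairs reconstruct the spacer after overhang stripping", {
    gfp <- fixturePreset("h2bgfp-opal")
    d <- designSpacer(gfp, 570, DesignParams(50, 34))
    pair <- emitOligoPair(d)
    expect_identical(nchar(pair@topOligo), 54L)
    expect_identical(nchar(pair@bottomOligo), 54L)
    top <- sub(paste0("^", pair@topOverhang), "", pair@topOligo)
    bottom <- sub(paste0("^", pair@bottomOverhang), "", pair@bottomOligo)
    expect_identical(top, spacerSeq(d))
    expect_identical(oracleRevComp(bottom), spacerSeq(d))

    empty <- emitOligoPair(d, topOverhang = "", bottomOverhang = "")
    expect_identical(empty@topOligo, spacerSeq(d))
    expect_identical(empty@bottomOligo, oracleRevComp(spacerSeq(d)))
    expect_error(emitOligoPair(d, topOverhang = "CANC"), "N")
})

test_that("oligo round trip holds for random overhangs and spacers", {
    set.seed(77)
    for (i in 1:30) {
        rec <- randomRecordWithA(80, 40)
        d <- designSpacer(rec, 40, DesignParams(sample(25:40, 1), 10))
        ov1 <- randomSeq(sample(0:6, 1))
        ov2 <- randomSeq(sample(0:6, 1))
        pair <- emitOligoPair(d, ov1, ov2)
        expect_identical(substring(pair@topOligo, nchar(ov1) + 1),
                         spacerSeq(d))
        expect_identical(
            oracleRevComp(substring(pair@bottomOligo, nchar(ov2) + 1)),
            spacerSeq(d))
    }
})

test_that("validateDesign flags length, BbsI and mismatch issues", {
    gfp <- fixturePreset("h2bgfp-opal")
    d <- designSpacer(gfp, 570, DesignParams(50, 34))
    expect_identical(nrow(validateDesign(d)), 0L)

    short <- designSpacer(gfp, 570, DesignParams(20, 10, minLength = 10))
    expect_true("length-below-min" %in% validateDesign(short)$code)

    # build a design whose window forces an internal BbsI site (GAAGAC in
    # the spacer = GTCTTC in the transcript window)
    rec <- TranscriptRecord("b", paste0("TTTTA", "GTCTTC",
                                        strrep("T", 30)))
    db <- designSpacer(rec, 5, DesignParams(30, 4))
    expect_true(any(grepl("BbsI", designWarnings(db))))
    expect_true("bbsi-site" %in% validateDesign(db)$code)

    tampered <- db
    tampered@spacer <- chartr("C", "A", db@spacer)
    expect_true("mismatch-not-C" %in%
                suppressWarnings(validateDesign(tampered))$code)
})

test_that("homopolymer runs and non-stop targets raise design warnings", {
    rec <- TranscriptRecord("h", paste0("TTA", strrep("T", 10),
                                        strrep("G", 20)))
    d <- designSpacer(rec, 3, DesignParams(12, 2, minLength = 5))
    expect_true(any(grepl("homopolymer", designWarnings(d))))
    expect_true(any(grepl("not a stop codon|upstream", designWarnings(d))))
})
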