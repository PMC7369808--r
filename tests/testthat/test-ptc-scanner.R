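test_that("classifyStop agrees with the standard genetic code on all 64 codons", {
    bases <- c("T", "C", "A", "G")
    all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
    stops <- character(0)
    for (codon in all64) {
        cls <- classifyStop(codon)
        isStopOracle <- unname(Biostrings::GENETIC_CODE[codon]) == "*"
        if (cls$stopClass != "none") {
            stops <- c(stops, codon)
            expect_true(isStopOracle, info = codon)
            # applying the plan must give the declared sense codon
            edited <- codon
            for (off in cls$editOffsets) {
                expect_identical(substr(codon, off, off), "A", info = codon)
                substr(edited, off, off) <- "G"
            }
            expect_identical(edited, cls$restoredCodon, info = codon)
            expect_identical(unname(Biostrings::GENETIC_CODE[edited]),
                             cls$restoredResidue, info = codon)
        } else {
            expect_false(isStopOracle, info = codon)
            expect_identical(cls$restoredCodon, codon)
            expect_identical(cls$restoredResidue,
                             unname(Biostrings::GENETIC_CODE[codon]))
        }
    }
    expect_length(stops, 3L)
    expect_setequal(stops, c("TGA", "TAG", "TAA"))
    expect_identical(classifyStop("TGA")$stopClass, "opal")
    expect_identical(classifyStop("uga")$restoredResidue, "W")
    expect_error(classifyStop("TG"), "3 nt")
})

test_that("codonToNt does the 1-based inclusive arithmetic", {
    expect_identical(codonToNt(1, 1)[1, ], c(start = 1L, end = 3L))
    expect_identical(codonToNt(190, 1)[1, ], c(start = 568L, end = 570L))
    expect_identical(codonToNt(1282, 1)[1, ], c(start = 3844L, end = 3846L))
    expect_identical(codonToNt(2, 5)[1, ], c(start = 8L, end = 10L))
    expect_error(codonToNt(0), ">= 1")
    expect_error(codonToNt(10, 1, seqLength = 20), "past the end")
})

test_that("scanPtcs locates the worked opal sites with their coordinates", {
    gfp <- fixturePreset("h2bgfp-opal")
    sites <- scanPtcs(gfp)
    expect_length(sites, 1L)
    s <- sites[[1]]
    expect_identical(codonIndex(s), 190L)
    expect_identical(stopClass(s), "opal")
    expect_identical(adenosinePositions(s), 570L)
    expect_identical(editPlan(s), 570L)
    # cross-check by slicing the transcript directly
    expect_identical(substr(transcriptSeq(gfp), 568, 570), "TGA")

    cftr <- fixturePreset("cftr-w1282x")
    sc <- scanPtcs(cftr)[[1]]
    expect_identical(codonIndex(sc), 1282L)
    expect_identical(gNotation(sc), "g.3846G>A")
    expect_identical(restoredResidue(sc), "W")
})

test_that("the terminal stop is never reported as a PTC", {
    expect_identical(scanPtcs(TranscriptRecord("x", "ATGTGGTAA")), list())
    rec <- TranscriptRecord("x", "ATGTAGTAA")
    expect_length(scanPtcs(rec), 1L)
    expect_length(scanPtcs(rec, includeTerminal = TRUE), 2L)
    expect_warning(out <- scanPtcs(TranscriptRecord("x", "ATGTGGTGG")),
                   "truncated")
    expect_identical(out, list())
})

test_that("scan results are invariant to case and U/T input", {
    seqU <- "AUGUGAUGGUAA"
    a <- scanPtcs(TranscriptRecord("x", seqU))
    b <- scanPtcs(TranscriptRecord("x", tolower(chartr("U", "T", seqU))))
    expect_identical(ptcTable(a), ptcTable(b))
})

test_that("edit plans retranslate to the restored residue, moving the stop downstream", {
    set.seed(33)
    for (i in 1:60) {
        n <- sample(10:60, 1)
        idx <- sample(2:(n - 1), 1)
        codon <- sample(c("TGA", "TAG", "TAA"), 1)
        rec <- generateOrf(FixtureSpec(n, idx, codon,
                                       seed = sample.int(1e6, 1)))
        s <- scanPtcs(rec)[[1]]
        before <- translateOrf(rec)
        edited <- applyEditing(rec, editPlan(s))
        after <- translateOrf(edited)
        resAt <- substr(after@residues, codonIndex(s), codonIndex(s))
        expect_identical(resAt, restoredResidue(s))
        expect_gt(after@stopIndex, before@stopIndex)
        # g-notation coordinate equals codon start + edited offset - 1
        if (!is.na(gNotation(s))) {
            span <- codonToNt(codonIndex(s), orfStart(rec))
            off <- match(editPlan(s), span[1, "start"]:span[1, "end"])
            pos <- as.integer(sub("^g\\.([0-9]+)G>A$", "\\1", gNotation(s)))
            expect_identical(pos, unname(span[1, "start"]) + off - 1L)
        }
    }
})

test_that("both c. and record-relative notations are emitted when orfStart != 1", {
    rec <- TranscriptRecord("x", "GGGGGATGTGATGGTAA", orfStart = 6L)
    s <- scanPtcs(rec)[[1]]
    expect_identical(gNotation(s), "g.11G>A")
    expect_identical(s@cNotation, "c.6G>A")
})
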