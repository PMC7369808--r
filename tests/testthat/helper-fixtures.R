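# Shared helpers. Oracles here are deliberately independent of the package
# code paths they check: plain-string arithmetic only.

.compMap <- c(A = "T", C = "G", G = "C", T = "A")

# independent base-by-base reverse complement
oracleRevComp <- function(s) {
    if (!nzchar(s)) return("")
    paste(rev(.compMap[strsplit(s, "")[[1]]]), collapse = "")
}

# random A/C/G/T string
randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# random transcript guaranteed to carry an A at a chosen position
randomRecordWithA <- function(n, aPos, id = "rnd") {
    s <- randomSeq(n)
    substr(s, aPos, aPos) <- "A"
    TranscriptRecord(id, s, 1L)
}

# independent antiparallel pairing of a spacer against its window slice:
# 3'-position i of the spacer (character L - i + 1, 5'->3') pairs with
# window base i (window written 5'->3', lowest transcript coordinate
# first). Returns the 3'-positions at which the pair is not Watson-Crick.
oracleHybridMismatches <- function(spacer, windowSeq) {
    sp <- strsplit(spacer, "")[[1]]
    win <- strsplit(windowSeq, "")[[1]]
    L <- length(win)
    stopifnot(length(sp) == L)
    mism <- integer(0)
    for (i in seq_len(L)) {
        spBase <- sp[L - i + 1L]
        if (spBase != unname(.compMap[win[i]])) mism <- c(mism, i)
    }
    mism
}

writeTempFasta <- function(lines) {
    path <- tempfile(fileext = ".fa")
    writeLines(lines, path)
    path
}

# small template for trace simulations: 20 codons, opal PTC at codon 10,
# editable A at transcript position 30 (centred in the 60-nt amplicon)
traceTemplate <- function(seed = 1L) generateOrf(FixtureSpec(20, 10, seed = seed))
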