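# Synthetic ORF generation. The two worked systems -- an H2BGFP reporter
# with a W190X opal codon (editable A at transcript position 570) and a
# CFTR cDNA with W1282X (g.3846G>A) -- are emulated by random ORFs with the
# stop codon placed at the right codon index: all coordinate arithmetic is
# sequence-independent given that index, so real cDNA (user-suppliable via
# FASTA) is never required.

#' Specification for a synthetic ORF fixture
#'
#' @param nCodons total codons including the terminal stop (>= 3).
#' @param ptcCodonIndex 1-based codon index of the premature stop, or NA
#'   for a PTC-free ORF; must satisfy 1 < index < nCodons.
#' @param ptcCodon the premature stop codon (TGA, TAG or TAA; default TGA).
#' @param gcContent target GC fraction of the random codons (default 0.5).
#' @param seed RNG seed (default 1).
#' @return A plain list of class `FixtureSpec`.
#' @export
FixtureSpec <- function(nCodons, ptcCodonIndex = NA_integer_,
                        ptcCodon = "TGA", gcContent = 0.5, seed = 1L) {
    nCodons <- as.integer(nCodons)
    ptcCodonIndex <- as.integer(ptcCodonIndex)
    if (is.na(nCodons) || nCodons < 3L)
        stop("'nCodons' must be at least 3", call. = FALSE)
    if (!is.na(ptcCodonIndex) &&
        (ptcCodonIndex <= 1L || ptcCodonIndex >= nCodons))
        stop("'ptcCodonIndex' must satisfy 1 < index < nCodons",
             call. = FALSE)
    ptcCodon <- .normalizeSeq(ptcCodon, "ptcCodon")
    if (!ptcCodon %in% names(.STOP_CODONS))
        stop("'ptcCodon' must be TGA, TAG or TAA", call. = FALSE)
    if (gcContent < 0 || gcContent > 1)
        stop("'gcContent' must lie in [0, 1]", call. = FALSE)
    structure(list(nCodons = nCodons, ptcCodonIndex = ptcCodonIndex,
                   ptcCodon = ptcCodon, gcContent = gcContent,
                   seed = as.integer(seed)),
              class = "FixtureSpec")
}

.SENSE_CODONS <- local({
    all64 <- as.vector(outer(outer(c("T", "C", "A", "G"),
                                   c("T", "C", "A", "G"), paste0),
                             c("T", "C", "A", "G"), paste0))
    sort(all64[!all64 %in% c("TGA", "TAG", "TAA")])
})

.codonWeights <- function(gc) {
    # weight each sense codon by its base composition under a gc target
    pGC <- gc / 2
    pAT <- (1 - gc) / 2
    vapply(.SENSE_CODONS, function(cd) {
        b <- strsplit(cd, "")[[1]]
        prod(ifelse(b %in% c("G", "C"), pGC, pAT))
    }, numeric(1))
}

#' Generate a synthetic ORF with a placed premature stop codon
#'
#' Codon 1 is ATG, the final codon the natural terminal stop (TAA), the
#' PTC codon (if any) the specified stop, and all other codons are drawn
#' from the 61 sense codons (so the PTC is the only premature stop).
#' Deterministic under the spec's seed. Sequence context that would create
#' a BbsI recognition site (GAAGAC/GTCTTC) -- which would complicate
#' spacer cloning -- is removed by resampling the offending codons.
#'
#' @param spec a [FixtureSpec()].
#' @param id record id (default "fixture").
#' @return A [TranscriptRecord-class] with `orfStart = 1`.
#' @examples
#' rec <- generateOrf(FixtureSpec(400, 190))   # editable A at position 570
#' scanPtcs(rec)[[1]]
#' @export
generateOrf <- function(spec, id = "fixture") {
    stopifnot(inherits(spec, "FixtureSpec"))
    set.seed(spec$seed)
    w <- .codonWeights(spec$gcContent)
    nRandom <- spec$nCodons - 2L  # minus ATG and terminal stop
    codons <- c("ATG",
                sample(.SENSE_CODONS, nRandom, replace = TRUE, prob = w),
                "TAA")
    if (!is.na(spec$ptcCodonIndex))
        codons[spec$ptcCodonIndex] <- spec$ptcCodon
    fixed <- c(1L, spec$nCodons,
               if (!is.na(spec$ptcCodonIndex)) spec$ptcCodonIndex)
    seq <- paste(codons, collapse = "")
    repeat {
        hit <- regexpr(paste(.BBSI_SITES, collapse = "|"), seq)
        if (hit == -1L) break
        # resample a free codon overlapping the BbsI site
        overlapping <- unique((as.integer(hit) + 0:5 - 1L) %/% 3L + 1L)
        free <- setdiff(overlapping, fixed)
        if (!length(free))
            stop("cannot remove BbsI site without touching fixed codons",
                 call. = FALSE)
        codons[free] <- sample(.SENSE_CODONS, length(free),
                               replace = TRUE, prob = w)
        seq <- paste(codons, collapse = "")
    }
    TranscriptRecord(id, seq, orfStart = 1L)
}

#' Built-in fixture presets for the two worked editing systems
#'
#' `"h2bgfp-opal"`: a 400-codon ORF with TGA at codon 190, emulating an
#' H2BGFP reporter carrying W190X (editable adenosine at transcript
#' position 570). `"cftr-w1282x"`: a 1500-codon ORF with TGA at codon
#' 1282, emulating a CFTR cDNA carrying W1282X (g.3846G>A).
#'
#' @param preset `"h2bgfp-opal"` or `"cftr-w1282x"`.
#' @param seed RNG seed (default 1).
#' @return A [TranscriptRecord-class].
#' @export
fixturePreset <- function(preset = c("h2bgfp-opal", "cftr-w1282x"),
                          seed = 1L) {
    preset <- match.arg(preset)
    switch(preset,
        "h2bgfp-opal" = generateOrf(
            FixtureSpec(400L, 190L, "TGA", seed = seed), id = "H2BGFPopal"),
        "cftr-w1282x" = generateOrf(
            FixtureSpec(1500L, 1282L, "TGA", seed = seed),
            id = "CFTR-W1282X"))
}

#' Spacer parameter grids of the two worked editing systems
#'
#' The H2BGFP ("GFP") system used four spacers: three 50-mers with the
#' C:A mismatch 32, 34 and 35 nt from the 3' end, plus one 30-mer with the
#' mismatch at 25 nt. The CFTR system used the three 50-mers only.
#'
#' @param fivePrimePolicy policy applied to every grid entry
#'   (default "substitute").
#' @return A named list of two lists of [DesignParams-class]: `GFP`
#'   (4 entries) and `CFTR` (3 entries).
#' @export
presetDesignGrids <- function(fivePrimePolicy = "substitute") {
    mk <- function(L, d) DesignParams(L, d, fivePrimePolicy = fivePrimePolicy)
    fifty <- lapply(c(32L, 34L, 35L), function(d) mk(50L, d))
    list(GFP = c(fifty, list(mk(30L, 25L))), CFTR = fifty)
}
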