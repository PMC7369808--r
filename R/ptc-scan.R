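#' Map a codon index to transcript coordinates
#'
#' Coordinate arithmetic behind all PTC reporting: codon `i` of an ORF
#' starting at `orfStart` spans transcript bases
#' `orfStart + 3*(i - 1)` to `orfStart + 3*(i - 1) + 2`, inclusive,
#' 1-based. So with `orfStart = 1`, codon 190 ends at base 570 and codon
#' 1282 at base 3846.
#'
#' @param codonIndex 1-based codon number (vectorised).
#' @param orfStart 1-based ORF start coordinate.
#' @param seqLength optional transcript length; when given, spans running
#'   past it raise a range error.
#' @return Integer matrix with columns `start`, `end`.
#' @examples
#' codonToNt(190)  # 568 568+2
#' @export
codonToNt <- function(codonIndex, orfStart = 1L, seqLength = NULL) {
    codonIndex <- as.integer(codonIndex)
    if (any(is.na(codonIndex)) || any(codonIndex < 1L))
        stop("'codonIndex' must be >= 1", call. = FALSE)
    start <- as.integer(orfStart) + 3L * (codonIndex - 1L)
    end <- start + 2L
    if (!is.null(seqLength) && any(end > seqLength))
        stop(sprintf("codon %d spans past the end of the transcript (%d nt)",
                     codonIndex[which(end > seqLength)[1L]],
                     as.integer(seqLength)), call. = FALSE)
    cbind(start = start, end = end)
}

#' Classify a codon as a stop and plan its A-to-G repair
#'
#' For a G>A-derived nonsense codon, deamination of the right adenosine
#' restores a sense codon. The three stops each admit exactly one
#' tryptophan-restoring plan: TGA (opal) -> edit the 3rd base -> TGG;
#' TAG (amber) -> edit the 2nd base -> TGG; TAA (ochre) -> edit both the
#' 2nd and 3rd bases -> TGG (two edits, outside single-site editing scope).
#'
#' @param codon a 3-mer over {A,C,G,T} (U accepted).
#' @return A list: `stopClass` ("opal", "amber", "ochre" or "none"),
#'   `editOffsets` (1-based within-codon offsets of the A's to edit;
#'   empty for sense codons), `restoredCodon` and `restoredResidue`.
#' @examples
#' classifyStop("TGA")  # opal; edit offset 3; TGG -> W
#' @export
classifyStop <- function(codon) {
    codon <- .normalizeSeq(codon, what = "codon")
    if (nchar(codon) != 3L)
        stop("'codon' must be exactly 3 nt", call. = FALSE)
    switch(codon,
        TGA = list(stopClass = "opal", editOffsets = 3L,
                   restoredCodon = "TGG", restoredResidue = "W"),
        TAG = list(stopClass = "amber", editOffsets = 2L,
                   restoredCodon = "TGG", restoredResidue = "W"),
        TAA = list(stopClass = "ochre", editOffsets = c(2L, 3L),
                   restoredCodon = "TGG", restoredResidue = "W"),
        list(stopClass = "none", editOffsets = integer(0),
             restoredCodon = codon,
             restoredResidue = unname(Biostrings::GENETIC_CODE[codon])))
}

.makePtcSite <- function(record, codonIdx, codon) {
    cls <- classifyStop(codon)
    span <- codonToNt(codonIdx, orfStart(record))
    aOffsets <- which(strsplit(codon, "")[[1]] == "A")
    aPositions <- span[1L, "start"] + aOffsets - 1L
    plan <- span[1L, "start"] + cls$editOffsets - 1L
    if (length(cls$editOffsets) == 1L) {
        gPos <- plan
        g <- sprintf("g.%dG>A", gPos)
        cNot <- sprintf("c.%dG>A", gPos - orfStart(record) + 1L)
    } else {
        g <- NA_character_
        cNot <- NA_character_
    }
    new("PtcSite", recordId = transcriptId(record),
        codonIndex = as.integer(codonIdx), codonSeq = codon,
        stopClass = cls$stopClass,
        adenosinePositions = as.integer(aPositions),
        editPlan = as.integer(plan),
        restoredCodon = cls$restoredCodon,
        restoredResidue = cls$restoredResidue,
        gNotation = g, cNotation = cNot)
}

#' Scan an ORF for premature termination codons
#'
#' Walks the reading frame from `orfStart` and reports every in-frame stop
#' codon strictly before the last one (the terminal, natural stop is never
#' a PTC). Each site carries its editable adenosine coordinates, the
#' minimal A->G edit plan restoring a sense codon, and a "g.<pos>G>A"
#' notation for the presumed G>A origin (record-relative coordinates; an
#' ORF-relative "c." form is also stored, identical when `orfStart` is 1).
#'
#' Ochre (TAA) sites are reported but need two edits, outside the scope of
#' single-site C:A-mismatch editing; [predictOutcome()] requires an
#' explicit override for them.
#'
#' @param record a [TranscriptRecord-class] with an ORF of >= 2 codons.
#' @param includeTerminal also report the terminal stop (default FALSE).
#' @return A list of [PtcSite-class], ordered by codon index; empty when
#'   the only stop is terminal. When no stop exists anywhere in frame, an
#'   empty list with a warning that the ORF may be truncated.
#' @examples
#' rec <- TranscriptRecord("x", "ATGTGATGGTAA")
#' scanPtcs(rec)  # one opal PTC at codon 2
#' @export
scanPtcs <- function(record, includeTerminal = FALSE) {
    stopifnot(is(record, "TranscriptRecord"))
    codons <- .codonsOf(record)
    if (length(codons) < 2L)
        stop("ORF must contain at least 2 codons", call. = FALSE)
    isStop <- codons %in% names(.STOP_CODONS)
    stopIdx <- which(isStop)
    if (!length(stopIdx)) {
        warning("no in-frame stop codon found; the ORF may be truncated",
                call. = FALSE)
        return(list())
    }
    ptcIdx <- if (includeTerminal) stopIdx
              else stopIdx[-length(stopIdx)]  # last in-frame stop = terminal
    lapply(ptcIdx, function(i) .makePtcSite(record, i, codons[i]))
}

#' Tabulate PTC sites
#'
#' @param sites list of [PtcSite-class] as returned by [scanPtcs()].
#' @return A data.frame with one row per site (record id, codon index,
#'   codon, stop class, adenosine positions, edit plan, g-notation,
#'   restored codon/residue), suitable for TSV export; zero rows for an
#'   empty site list.
#' @export
ptcTable <- function(sites) {
    if (is(sites, "PtcSite")) sites <- list(sites)
    df <- data.frame(
        recordId = vapply(sites, function(s) s@recordId, character(1)),
        codonIndex = vapply(sites, codonIndex, integer(1)),
        codonSeq = vapply(sites, function(s) s@codonSeq, character(1)),
        stopClass = vapply(sites, stopClass, character(1)),
        adenosinePositions = vapply(sites, function(s)
            paste(adenosinePositions(s), collapse = ","), character(1)),
        editPlan = vapply(sites, function(s)
            paste(editPlan(s), collapse = ","), character(1)),
        gNotation = vapply(sites, gNotation, character(1)),
        cNotation = vapply(sites, function(s) s@cNotation, character(1)),
        restoredCodon = vapply(sites, function(s) s@restoredCodon,
                               character(1)),
        restoredResidue = vapply(sites, restoredResidue, character(1)),
        stringsAsFactors = FALSE)
    df
}
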