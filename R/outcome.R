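#' Apply A-to-I(=G) edits to a transcript
#'
#' ADAR deamination converts adenosine to inosine, which the ribosome and
#' sequencing polymerases read as guanosine; inosine is therefore modelled
#' as G throughout. Returns a new record with G substituted at each given
#' position; the input record is unmodified.
#'
#' @param record a [TranscriptRecord-class].
#' @param positions transcript coordinates to edit; every one must hold an
#'   A (re-applying to an already-edited position is an error).
#' @return A new [TranscriptRecord-class] (id suffixed "|edited" when any
#'   position was edited).
#' @examples
#' applyEditing(TranscriptRecord("x", "ATGTGA"), 6)  # ATGTGG
#' @export
applyEditing <- function(record, positions) {
    stopifnot(is(record, "TranscriptRecord"))
    positions <- as.integer(positions)
    if (!length(positions)) return(record)
    seq <- transcriptSeq(record)
    if (any(positions < 1L | positions > nchar(seq)))
        stop("edit position outside the transcript", call. = FALSE)
    bases <- substring(seq, positions, positions)
    bad <- which(bases != "A")
    if (length(bad))
        stop(sprintf(
            "cannot edit position %d of '%s': base is %s, not A",
            positions[bad[1L]], transcriptId(record), bases[bad[1L]]),
            call. = FALSE)
    for (p in positions) substr(seq, p, p) <- "G"
    TranscriptRecord(paste0(transcriptId(record), "|edited"), seq,
                     orfStart(record))
}

#' Predict the translated outcome of repairing a PTC
#'
#' Applies the site's edit plan, re-translates, and reports the repair
#' relative to the unedited transcript: the restored residue and its codon
#' index, whether the premature stop was removed, and whether translation
#' now runs full length (i.e. the first stop of the edited ORF is the
#' terminal stop).
#'
#' @param record the [TranscriptRecord-class] the site was scanned from.
#' @param ptc a [PtcSite-class] from [scanPtcs()].
#' @param allowMultiEdit permit multi-edit plans (ochre/TAA sites need two
#'   A->G edits, outside single-site editing scope; default FALSE).
#' @return An [EditOutcome-class].
#' @examples
#' rec <- TranscriptRecord("x", "ATGTGATGGTAA")
#' predictOutcome(rec, scanPtcs(rec)[[1]])
#' @export
predictOutcome <- function(record, ptc, allowMultiEdit = FALSE) {
    stopifnot(is(record, "TranscriptRecord"), is(ptc, "PtcSite"))
    plan <- editPlan(ptc)
    if (!length(plan))
        stop("PTC site has an empty edit plan: not rescuable by A->G editing",
             call. = FALSE)
    if (length(plan) > 1L && !allowMultiEdit)
        stop(sprintf(
            "%s (%s) is not single-edit rescuable: %d A->G edits required; set allowMultiEdit = TRUE to override",
            ptc@codonSeq, stopClass(ptc), length(plan)), call. = FALSE)
    before <- translateOrf(record)
    edited <- applyEditing(record, plan)
    after <- translateOrf(edited)
    codons <- .codonsOf(edited)
    terminalStop <- {
        stops <- which(codons %in% names(.STOP_CODONS))
        if (length(stops)) stops[length(stops)] else NA_integer_
    }
    stopRemoved <- is.na(before@stopIndex) ||
        (!is.na(after@stopIndex) && after@stopIndex > before@stopIndex) ||
        (is.na(after@stopIndex) && !is.na(before@stopIndex))
    fullLength <- !is.na(after@stopIndex) && !is.na(terminalStop) &&
        after@stopIndex == terminalStop
    new("EditOutcome", editedRecord = edited,
        editedPositions = plan,
        restoredResidueIndex = codonIndex(ptc),
        restoredResidue = restoredResidue(ptc),
        prematureStopRemoved = stopRemoved,
        fullLength = fullLength,
        proteinBefore = before, proteinAfter = after)
}
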