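# Accessor generics. Bioconductor convention: users touch slots through
# these, never with @.

#' @export
setGeneric("transcriptId", function(x) standardGeneric("transcriptId"))
#' @export
setGeneric("transcriptSeq", function(x) standardGeneric("transcriptSeq"))
#' @export
setGeneric("orfStart", function(x) standardGeneric("orfStart"))
#' @export
setGeneric("codonIndex", function(x) standardGeneric("codonIndex"))
#' @export
setGeneric("stopClass", function(x) standardGeneric("stopClass"))
#' @export
setGeneric("adenosinePositions", function(x) standardGeneric("adenosinePositions"))
#' @export
setGeneric("editPlan", function(x) standardGeneric("editPlan"))
#' @export
setGeneric("gNotation", function(x) standardGeneric("gNotation"))
#' @export
setGeneric("restoredResidue", function(x) standardGeneric("restoredResidue"))
#' @export
setGeneric("spacerSeq", function(x, ...) standardGeneric("spacerSeq"))
#' @export
setGeneric("spacerLength", function(x) standardGeneric("spacerLength"))
#' @export
setGeneric("mismatchDistance", function(x) standardGeneric("mismatchDistance"))
#' @export
setGeneric("designWindow", function(x) standardGeneric("designWindow"))
#' @export
setGeneric("designWarnings", function(x) standardGeneric("designWarnings"))
#' @export
setGeneric("traceHeights", function(x) standardGeneric("traceHeights"))
#' @export
setGeneric("estimatedFraction", function(x) standardGeneric("estimatedFraction"))
#' @export
setGeneric("peakDetected", function(x) standardGeneric("peakDetected"))

#' Accessors for repairguide classes
#'
#' `transcriptId()`, `transcriptSeq()` and `orfStart()` read
#' [TranscriptRecord-class] slots; `codonIndex()`, `stopClass()`,
#' `adenosinePositions()`, `editPlan()`, `gNotation()` and
#' `restoredResidue()` read [PtcSite-class]; `spacerSeq()` (with
#' `rna = TRUE` for the U-alphabet rendering), `spacerLength()`,
#' `mismatchDistance()`, `designWindow()` and `designWarnings()` read
#' [GuideDesign-class]; `traceHeights()` reads [Trace-class];
#' `estimatedFraction()` and `peakDetected()` read
#' [EditingEstimate-class].
#'
#' @param x the object.
#' @param rna logical; render the spacer in the RNA alphabet (T -> U).
#' @param ... unused.
#' @return The slot value (see the class documentation for units).
#' @name accessors
#' @aliases transcriptId transcriptSeq orfStart codonIndex stopClass
#'   adenosinePositions editPlan gNotation restoredResidue spacerSeq
#'   spacerLength mismatchDistance designWindow designWarnings traceHeights
#'   estimatedFraction peakDetected
#' @examples
#' rec <- TranscriptRecord("x", "ATGTGGTAA")
#' transcriptId(rec)
#' transcriptSeq(rec)
NULL

setMethod("transcriptId", "TranscriptRecord", function(x) x@id)
setMethod("transcriptSeq", "TranscriptRecord", function(x) x@sequence)
setMethod("orfStart", "TranscriptRecord", function(x) x@orfStart)

setMethod("codonIndex", "PtcSite", function(x) x@codonIndex)
setMethod("stopClass", "PtcSite", function(x) x@stopClass)
setMethod("adenosinePositions", "PtcSite", function(x) x@adenosinePositions)
setMethod("editPlan", "PtcSite", function(x) x@editPlan)
setMethod("gNotation", "PtcSite", function(x) x@gNotation)
setMethod("restoredResidue", "PtcSite", function(x) x@restoredResidue)
setMethod("restoredResidue", "EditOutcome", function(x) x@restoredResidue)

setMethod("spacerSeq", "GuideDesign", function(x, rna = FALSE) {
    if (rna) chartr("T", "U", x@spacer) else x@spacer
})
setMethod("spacerLength", "GuideDesign", function(x) nchar(x@spacer))
setMethod("spacerLength", "DesignParams", function(x) x@spacerLength)
setMethod("mismatchDistance", "GuideDesign", function(x) x@mismatchPosFrom3prime)
setMethod("mismatchDistance", "DesignParams", function(x) x@mismatchDistance)
setMethod("designWindow", "GuideDesign", function(x) x@window)
setMethod("designWarnings", "GuideDesign", function(x) x@warnings)

setMethod("traceHeights", "Trace", function(x) x@heights)

setMethod("estimatedFraction", "EditingEstimate", function(x) x@estimatedFraction)
setMethod("peakDetected", "EditingEstimate", function(x) x@detected)

setMethod("show", "TranscriptRecord", function(object) {
    n <- nchar(object@sequence)
    preview <- if (n > 40L)
        paste0(substr(object@sequence, 1L, 37L), "...") else object@sequence
    cat(sprintf("TranscriptRecord '%s': %d nt, orfStart %d\n  %s\n",
                object@id, n, object@orfStart, preview))
})

setMethod("show", "PtcSite", function(object) {
    cat(sprintf(
        "PtcSite: codon %d %s (%s)%s\n  editable A at %s; edit plan %s -> %s (%s)\n",
        object@codonIndex, object@codonSeq, object@stopClass,
        if (is.na(object@gNotation)) "" else paste0(" [", object@gNotation, "]"),
        paste(object@adenosinePositions, collapse = ", "),
        paste(object@editPlan, collapse = "+"),
        object@restoredCodon, object@restoredResidue))
})

setMethod("show", "DesignParams", function(object) {
    cat(sprintf("DesignParams: L = %d nt, mismatch distance d = %d nt, 5'-G policy '%s'\n",
                object@spacerLength, object@mismatchDistance,
                object@fivePrimePolicy))
})

setMethod("show", "GuideDesign", function(object) {
    cat(sprintf(
        "GuideDesign on '%s' targeting A at %d\n  window %d-%d, spacer %d nt, C:A mismatch %d nt from 3' end\n  5'->3': %s\n",
        object@targetRecordId, object@targetA, object@window[1L],
        object@window[2L], nchar(object@spacer),
        object@mismatchPosFrom3prime, object@spacer))
    if (length(object@warnings))
        cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})

setMethod("show", "OligoPair", function(object) {
    cat(sprintf("OligoPair (%s overhangs)\n  top:    5'-%s-3'\n  bottom: 5'-%s-3'\n",
                object@enzyme, object@topOligo, object@bottomOligo))
})

setMethod("show", "Trace", function(object) {
    cat(sprintf("Trace '%s': %d base-called positions x 4 channels (A,C,G,T)\n",
                object@templateId, nrow(object@heights)))
})

setMethod("show", "EditingEstimate", function(object) {
    cat(sprintf(
        "EditingEstimate at position %d: primary %s, secondary %s\n  f-hat = %.3f, noise = %.3f, minor peak %s\n",
        object@position, object@primaryBase,
        ifelse(is.na(object@secondaryBase), "none", object@secondaryBase),
        object@estimatedFraction, object@noiseEstimate,
        if (object@detected) "DETECTED" else "not detected"))
})

setMethod("show", "EditOutcome", function(object) {
    cat(sprintf(
        "EditOutcome: %d position(s) edited; restored %s at codon %s\n  premature stop removed: %s; full length: %s\n",
        length(object@editedPositions),
        ifelse(is.na(object@restoredResidue), "nothing", object@restoredResidue),
        ifelse(is.na(object@restoredResidueIndex), "-",
               object@restoredResidueIndex),
        object@prematureStopRemoved, object@fullLength))
})

setMethod("show", "BystanderReport", function(object) {
    cat(sprintf("BystanderReport: %d adenosine(s) in window (target A at %d)\n",
                nrow(object@entries), object@designTargetA))
    for (nm in names(object@counts))
        cat(sprintf("  %-20s %d\n", nm, object@counts[[nm]]))
})
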