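#' @import methods
NULL

.STOP_CODONS <- c(TGA = "opal", TAG = "amber", TAA = "ochre")

.validNucleotides <- function(x) grepl("^[ACGT]*$", x)

#' TranscriptRecord: a named transcript with an ORF start
#'
#' The substrate of all coordinate arithmetic in the package: a cDNA/mRNA
#' sequence (DNA alphabet internally; U on input is mapped to T) together
#' with the 1-based transcript coordinate of the first base of codon 1.
#' All reported coordinates are 1-based and inclusive, with `orfStart`
#' defining codon 1.
#'
#' @slot id character(1), record identifier.
#' @slot sequence character(1) over {A,C,G,T}, length >= 3.
#' @slot orfStart integer(1), 1 <= orfStart <= nchar(sequence) - 2.
#'
#' @exportClass TranscriptRecord
setClass("TranscriptRecord",
    representation(id = "character", sequence = "character",
                   orfStart = "integer"),
    prototype(id = NA_character_, sequence = "", orfStart = 1L))

setValidity("TranscriptRecord", function(object) {
    msg <- character()
    if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
        msg <- c(msg, "'id' must be a single non-empty string")
    if (length(object@sequence) != 1L || !.validNucleotides(object@sequence))
        msg <- c(msg, "'sequence' must contain only A, C, G, T")
    else if (nchar(object@sequence) < 3L)
        msg <- c(msg, "'sequence' must be at least 3 nt long")
    if (length(object@orfStart) != 1L || is.na(object@orfStart) ||
        object@orfStart < 1L)
        msg <- c(msg, "'orfStart' must be a positive integer")
    else if (nzchar(object@sequence) &&
             object@orfStart > nchar(object@sequence) - 2L)
        msg <- c(msg, "'orfStart' leaves no complete codon downstream")
    if (length(msg)) msg else TRUE
})

#' ProteinTranslation: result of translating an ORF
#'
#' @slot residues character(1), one-letter amino acids up to and excluding
#'   the first stop.
#' @slot stopIndex integer(1), 1-based codon index of the first stop
#'   encountered, or NA if none.
#' @slot complete logical(1), TRUE if translation reached a stop (rather
#'   than running off the end of the sequence).
#'
#' @exportClass ProteinTranslation
setClass("ProteinTranslation",
    representation(residues = "character", stopIndex = "integer",
                   complete = "logical"),
    prototype(residues = "", stopIndex = NA_integer_, complete = FALSE))

setValidity("ProteinTranslation", function(object) {
    if (!is.na(object@stopIndex) &&
        object@stopIndex != nchar(object@residues) + 1L)
        return("'stopIndex' must be one past the translated residues")
    TRUE
})

#' PtcSite: a located premature termination codon
#'
#' A premature stop codon found in frame, annotated with its editable
#' adenosine(s) and the minimal A-to-G edit plan that converts it to a
#' sense codon (TGA/TAG -> TGG, Trp; TAA needs two edits).
#'
#' @slot recordId character(1), id of the scanned transcript.
#' @slot codonIndex integer(1), 1-based codon number within the ORF.
#' @slot codonSeq character(1), the 3-mer at that codon.
#' @slot stopClass character(1), one of "opal", "amber", "ochre".
#' @slot adenosinePositions integer, 1-based transcript coordinates of the
#'   A's within the codon.
#' @slot editPlan integer, transcript coordinates whose A->G conversion
#'   yields the restored codon.
#' @slot restoredCodon character(1) 3-mer after applying the edit plan.
#' @slot restoredResidue character(1), one-letter amino acid.
#' @slot gNotation character(1), record-relative "g.<pos>G>A" describing the
#'   presumed G>A origin when the restored codon differs from the stop at
#'   exactly one position; NA otherwise.
#' @slot cNotation character(1), ORF-relative "c.<pos>G>A" (differs from
#'   gNotation only when orfStart != 1); NA when gNotation is NA.
#'
#' @exportClass PtcSite
setClass("PtcSite",
    representation(recordId = "character", codonIndex = "integer",
                   codonSeq = "character", stopClass = "character",
                   adenosinePositions = "integer", editPlan = "integer",
                   restoredCodon = "character", restoredResidue = "character",
                   gNotation = "character", cNotation = "character"))

setValidity("PtcSite", function(object) {
    msg <- character()
    if (nchar(object@codonSeq) != 3L)
        msg <- c(msg, "'codonSeq' must be a 3-mer")
    if (!object@stopClass %in% c(.STOP_CODONS, "none"))
        msg <- c(msg, "'stopClass' must be opal, amber, ochre or none")
    if (length(object@editPlan) &&
        !all(object@editPlan %in% object@adenosinePositions))
        msg <- c(msg, "'editPlan' must be a subset of 'adenosinePositions'")
    if (length(msg)) msg else TRUE
})

#' DesignParams: spacer geometry parameters
#'
#' Spacer length L and mismatch distance d, the position of the deliberately
#' mispaired C counted from the spacer 3' end (the 3'-terminal base is
#' position 1; d equals the distance between the target adenine and the
#' first scaffold nucleotide, since the scaffold abuts the spacer 3' end).
#'
#' @slot spacerLength integer(1), L in nt.
#' @slot mismatchDistance integer(1), d in nt, 1 <= d <= L.
#' @slot fivePrimePolicy character(1): "substitute" (overwrite the 5' base
#'   with G, preserving L), "prepend" (add a 5' G, length L + 1) or
#'   "require" (error unless the 5' base is already G). The 5' guanine
#'   enhances transcription from the U6 promoter.
#' @slot minLength,maxLength integer(1), guide-length bounds (defaults 25
#'   and 80 nt, the working range of the dCas13b guide).
#'
#' @exportClass DesignParams
setClass("DesignParams",
    representation(spacerLength = "integer", mismatchDistance = "integer",
                   fivePrimePolicy = "character", minLength = "integer",
                   maxLength = "integer"),
    prototype(fivePrimePolicy = "substitute", minLength = 25L,
              maxLength = 80L))

setValidity("DesignParams", function(object) {
    msg <- character()
    L <- object@spacerLength; d <- object@mismatchDistance
    if (length(L) != 1L || is.na(L) || L < 1L)
        msg <- c(msg, "'spacerLength' must be a positive integer")
    if (length(d) != 1L || is.na(d) || d < 1L)
        msg <- c(msg, "'mismatchDistance' must be a positive integer")
    else if (length(L) == 1L && !is.na(L) && d > L)
        msg <- c(msg, sprintf(
            "'mismatchDistance' (%d) must not exceed 'spacerLength' (%d)",
            d, L))
    if (length(L) == 1L && !is.na(L) && L >= 1L) {
        if (L < object@minLength)
            msg <- c(msg, sprintf("spacer length %d below minimum %d",
                                  L, object@minLength))
        if (L > object@maxLength)
            msg <- c(msg, sprintf("spacer length %d above maximum %d",
                                  L, object@maxLength))
    }
    if (!object@fivePrimePolicy %in% c("substitute", "prepend", "require"))
        msg <- c(msg, "'fivePrimePolicy' must be substitute, prepend or require")
    if (length(msg)) msg else TRUE
})

#' GuideDesign: one antisense spacer against a target adenosine
#'
#' The spacer is the reverse complement of the transcript window
#' `[targetA - d + 1, targetA + L - d]` with a C placed opposite the target
#' adenosine (the C:A mismatch that licenses ADAR deamination). Aligned
#' antiparallel to the window, the spacer matches the window's complement
#' everywhere except at position d from its 3' end (and, when the 5'-G
#' substitute policy acted, at its 5'-terminal base).
#'
#' @slot targetRecordId character(1).
#' @slot targetA integer(1), transcript coordinate of the adenosine to edit.
#' @slot params the [DesignParams-class] used.
#' @slot window integer(2), inclusive transcript coordinates covered by the
#'   spacer (before any 5' prepend).
#' @slot spacer character(1), spacer sequence written 5'->3' (DNA alphabet).
#' @slot mismatchPosFrom3prime integer(1), position of the mismatched C
#'   counted from the 3' end.
#' @slot fivePrimeBaseModified logical(1), TRUE when the 5'-G policy changed
#'   or extended the spacer.
#' @slot warnings character, design warnings (internal BbsI site,
#'   homopolymer run, non-stop target codon).
#'
#' @exportClass GuideDesign
setClass("GuideDesign",
    representation(targetRecordId = "character", targetA = "integer",
                   params = "DesignParams", window = "integer",
                   spacer = "character", mismatchPosFrom3prime = "integer",
                   fivePrimeBaseModified = "logical", warnings = "character"))

setValidity("GuideDesign", function(object) {
    msg <- character()
    if (length(object@window) != 2L || diff(object@window) < 0L)
        msg <- c(msg, "'window' must be (start, end) with start <= end")
    if (!.validNucleotides(object@spacer) || !nzchar(object@spacer))
        msg <- c(msg, "'spacer' must be a non-empty A/C/G/T string")
    L <- object@params@spacerLength
    if (length(object@window) == 2L &&
        object@window[2L] - object@window[1L] + 1L != L)
        msg <- c(msg, "window length must equal the spacer length parameter")
    d <- object@mismatchPosFrom3prime
    n <- nchar(object@spacer)
    if (d < 1L || d > n)
        msg <- c(msg, "mismatch position outside the spacer")
    else if (substr(object@spacer, n - d + 1L, n - d + 1L) != "C")
        msg <- c(msg, "base at the mismatch position must be C")
    if (length(msg)) msg else TRUE
})

#' OligoPair: annealing-ready top/bottom oligonucleotides
#'
#' The two single-strand oligos that anneal into the spacer insert, each
#' carrying a distinct 5' overhang for directional (golden-gate style)
#' cloning into the BbsI-digested guide backbone. After removing the
#' overhangs, the top oligo and the reverse complement of the bottom oligo
#' are identical and equal to the spacer.
#'
#' @slot topOligo,bottomOligo character(1) oligo sequences 5'->3'.
#' @slot topOverhang,bottomOverhang character(1) the 5' overhangs.
#' @slot enzyme character(1), restriction enzyme the overhangs serve.
#'
#' @exportClass OligoPair
setClass("OligoPair",
    representation(topOligo = "character", bottomOligo = "character",
                   topOverhang = "character", bottomOverhang = "character",
                   enzyme = "character"),
    prototype(enzyme = "BbsI"))

setValidity("OligoPair", function(object) {
    ok <- vapply(c(object@topOligo, object@bottomOligo,
                   object@topOverhang, object@bottomOverhang),
                 .validNucleotides, logical(1))
    if (!all(ok))
        return("oligos and overhangs must contain only A, C, G, T")
    if (!startsWith(object@topOligo, object@topOverhang) ||
        !startsWith(object@bottomOligo, object@bottomOverhang))
        return("each oligo must begin with its overhang")
    TRUE
})

#' TraceModel: noise model for simulated Sanger peak heights
#'
#' Peak heights are modelled at base-call resolution: the called channel at
#' each position receives a height drawn from Normal(1, peakHeightCv), every
#' channel receives a uniform baseline on [0, noiseFloor] (in units of the
#' mean called-peak height), and a fraction `crosstalk` of each real signal
#' bleeds into the other channels.
#'
#' The default `noiseFloor` is calibrated so that, under the 3-SD minor-peak
#' detection rule, the smallest detectable edited fraction on a 5% grid is
#' 30% -- the empirical visibility threshold of a minor G peak in standard
#' Sanger sequencing of a mixed template population.
#'
#' @slot peakHeightCv numeric(1), relative SD of the called-peak height
#'   (default 0.10).
#' @slot noiseFloor numeric(1), upper bound of the per-channel uniform
#'   baseline, as a fraction of the mean called-peak height (default 0.21).
#' @slot crosstalk numeric(1), fraction of a called peak bleeding into the
#'   other three channels (default 0.02).
#' @slot seed integer(1), RNG seed used by simulation entry points when no
#'   explicit seed is given; NA means "use the current RNG stream".
#'
#' @exportClass TraceModel
setClass("TraceModel",
    representation(peakHeightCv = "numeric", noiseFloor = "numeric",
                   crosstalk = "numeric", seed = "integer"),
    prototype(peakHeightCv = 0.10, noiseFloor = 0.21, crosstalk = 0.02,
              seed = NA_integer_))

setValidity("TraceModel", function(object) {
    msg <- character()
    for (nm in c("peakHeightCv", "noiseFloor", "crosstalk")) {
        v <- slot(object, nm)
        if (length(v) != 1L || is.na(v) || v < 0)
            msg <- c(msg, sprintf("'%s' must be a single nonnegative number", nm))
    }
    if (length(object@peakHeightCv) == 1L && !is.na(object@peakHeightCv) &&
        object@peakHeightCv >= 1)
        msg <- c(msg, "'peakHeightCv' must be < 1")
    if (length(msg)) msg else TRUE
})

#' Trace: four-channel Sanger peak heights at base-called positions
#'
#' @slot templateId character(1).
#' @slot heights numeric matrix, one row per template base, columns
#'   A, C, G, T; nonnegative, arbitrary units.
#'
#' @exportClass Trace
setClass("Trace",
    representation(templateId = "character", heights = "matrix"))

setValidity("Trace", function(object) {
    h <- object@heights
    if (!is.numeric(h) || ncol(h) != 4L ||
        !identical(colnames(h), c("A", "C", "G", "T")))
        return("'heights' must be a numeric matrix with columns A, C, G, T")
    if (any(h < 0))
        return("peak heights must be nonnegative")
    TRUE
})

#' EditingEstimate: minor-peak call and edited-fraction estimate at a site
#'
#' @slot position integer(1), trace position interrogated.
#' @slot primaryBase character(1), channel with the tallest peak at the site.
#' @slot secondaryBase character(1), channel of the called minor peak, or NA
#'   when no minor peak exceeds the noise threshold.
#' @slot estimatedFraction numeric(1) in `[0, 1]`: G / (A + G) of the
#'   baseline-subtracted site heights, clipped at 0.
#' @slot noiseEstimate numeric(1), mean non-called-channel height over the
#'   flanking positions.
#' @slot detected logical(1), TRUE when the minor peak clears the
#'   noise-mean + k * SD threshold.
#'
#' @exportClass EditingEstimate
setClass("EditingEstimate",
    representation(position = "integer", primaryBase = "character",
                   secondaryBase = "character", estimatedFraction = "numeric",
                   noiseEstimate = "numeric", detected = "logical"))

setValidity("EditingEstimate", function(object) {
    f <- object@estimatedFraction
    if (length(f) != 1L || is.na(f) || f < 0 || f > 1)
        return("'estimatedFraction' must lie in [0, 1]")
    if (object@detected && is.na(object@secondaryBase))
        return("a detected minor peak must name its channel")
    TRUE
})

#' EditOutcome: consequence of applying an edit plan to a transcript
#'
#' @slot editedRecord the [TranscriptRecord-class] after A->G substitution.
#' @slot editedPositions integer, transcript coordinates edited.
#' @slot restoredResidueIndex integer(1), 1-based codon index of the
#'   restored residue, or NA.
#' @slot restoredResidue character(1), one-letter amino acid, or NA.
#' @slot prematureStopRemoved logical(1).
#' @slot fullLength logical(1), TRUE when translation of the edited ORF
#'   reaches the terminal stop.
#' @slot proteinBefore,proteinAfter [ProteinTranslation-class] objects.
#'
#' @exportClass EditOutcome
setClass("EditOutcome",
    representation(editedRecord = "TranscriptRecord",
                   editedPositions = "integer",
                   restoredResidueIndex = "integer",
                   restoredResidue = "character",
                   prematureStopRemoved = "logical",
                   fullLength = "logical",
                   proteinBefore = "ProteinTranslation",
                   proteinAfter = "ProteinTranslation"))

#' BystanderReport: window adenosines and their editing consequences
#'
#' Every adenosine inside a design's editing window, annotated with the
#' protein consequence of editing that adenosine alone (one A at a time;
#' combinatorial multi-site editing is out of scope).
#'
#' @slot designTargetA integer(1), the intended target adenosine.
#' @slot entries data.frame with columns `position`, `codonIndex`,
#'   `codonOffset`, `codonBefore`, `codonAfter`, `consequence` (one of
#'   intended-PTC-repair, synonymous, missense, stop-introducing,
#'   noncoding).
#' @slot counts named integer, entries per consequence class.
#'
#' @exportClass BystanderReport
setClass("BystanderReport",
    representation(designTargetA = "integer", entries = "data.frame",
                   counts = "integer"))

setValidity("BystanderReport", function(object) {
    need <- c("position", "codonIndex", "codonOffset", "codonBefore",
              "codonAfter", "consequence")
    if (!all(need %in% names(object@entries)))
        return("'entries' is missing required columns")
    if (sum(object@counts) != nrow(object@entries))
        return("class counts must sum to the number of entries")
    TRUE
})
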