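.BBSI_SITES <- c("GAAGAC", "GTCTTC")

#' Construct DesignParams
#'
#' @param spacerLength spacer length L in nt (guide bounds default 25-80).
#' @param mismatchDistance position d of the mismatched C counted from the
#'   spacer 3' end (3'-terminal base = position 1); equals the distance
#'   between the target adenine and the first scaffold nucleotide.
#' @param fivePrimePolicy "substitute" (default), "prepend" or "require";
#'   see [DesignParams-class].
#' @param minLength,maxLength guide-length bounds.
#' @return A [DesignParams-class].
#' @examples
#' DesignParams(50, 34)
#' @export
DesignParams <- function(spacerLength, mismatchDistance,
                         fivePrimePolicy = "substitute",
                         minLength = 25L, maxLength = 80L) {
    new("DesignParams", spacerLength = as.integer(spacerLength),
        mismatchDistance = as.integer(mismatchDistance),
        fivePrimePolicy = fivePrimePolicy,
        minLength = as.integer(minLength), maxLength = as.integer(maxLength))
}

.charAt <- function(s, i) substr(s, i, i)
`.charAt<-` <- function(s, i, value) {
    substr(s, i, i) <- value
    s
}

.homopolymerRun <- function(s) {
    r <- rle(strsplit(s, "")[[1]])
    max(r$lengths)
}

#' Design an antisense spacer against a target adenosine
#'
#' Builds the spacer as the reverse complement of the transcript window
#' `[targetA - d + 1, targetA + L - d]` (the spacer 3' end pairs with the
#' window's lowest coordinate, since the dCas13b scaffold abuts the spacer
#' 3' end), then replaces the base opposite the target adenosine with C,
#' creating the C:A mismatch at position `d` from the 3' end that directs
#' ADAR deamination to that adenosine. A 5'-terminal guanine, which
#' enhances transcription from the U6 promoter, is enforced per
#' `fivePrimePolicy`.
#'
#' Warnings (not errors) are attached when the spacer contains an internal
#' BbsI recognition site (GAAGAC/GTCTTC, which would interfere with
#' golden-gate cloning), a homopolymer run of 6 or more, or when the
#' target adenosine does not sit in a stop codon.
#'
#' @param record a [TranscriptRecord-class].
#' @param targetA transcript coordinate of the adenosine to edit; the base
#'   there must be A.
#' @param params a [DesignParams-class].
#' @return A [GuideDesign-class].
#' @examples
#' rec <- fixturePreset("h2bgfp-opal")
#' designSpacer(rec, 570, DesignParams(50, 34))
#' @export
designSpacer <- function(record, targetA, params) {
    stopifnot(is(record, "TranscriptRecord"), is(params, "DesignParams"))
    validObject(params)
    targetA <- as.integer(targetA)
    seq <- transcriptSeq(record)
    if (targetA < 1L || targetA > nchar(seq))
        stop(sprintf("target coordinate %d outside record '%s' (1-%d)",
                     targetA, transcriptId(record), nchar(seq)),
             call. = FALSE)
    if (.charAt(seq, targetA) != "A")
        stop(sprintf("base at position %d of '%s' is %s, not an adenosine",
                     targetA, transcriptId(record), .charAt(seq, targetA)),
             call. = FALSE)
    L <- params@spacerLength
    d <- params@mismatchDistance
    win <- c(targetA - d + 1L, targetA + L - d)
    if (win[1L] < 1L || win[2L] > nchar(seq))
        stop(sprintf(
            "editing window %d-%d falls outside record '%s' (1-%d)",
            win[1L], win[2L], transcriptId(record), nchar(seq)),
             call. = FALSE)
    spacer <- reverseComplement(substr(seq, win[1L], win[2L]))
    # the base opposite targetA sits at 5'->3' index L - d + 1
    mmIdx <- L - d + 1L
    .charAt(spacer, mmIdx) <- "C"
    warnings <- character()
    modified <- FALSE
    if (params@fivePrimePolicy == "substitute") {
        if (mmIdx == 1L)
            stop("mismatch C occupies the 5'-terminal base (d = L): the 'substitute' 5'-G policy would destroy the C:A mismatch; use fivePrimePolicy = 'prepend'",
                 call. = FALSE)
        if (.charAt(spacer, 1L) != "G") {
            .charAt(spacer, 1L) <- "G"
            modified <- TRUE
        }
    } else if (params@fivePrimePolicy == "prepend") {
        spacer <- paste0("G", spacer)
        modified <- TRUE
    } else if (.charAt(spacer, 1L) != "G") {
        stop(sprintf(
            "5' base of the spacer is %s, not G (policy 'require')",
            .charAt(spacer, 1L)), call. = FALSE)
    }
    for (site in .BBSI_SITES)
        if (grepl(site, spacer, fixed = TRUE)) {
            warnings <- c(warnings, sprintf(
                "spacer contains internal BbsI site %s", site))
            break
        }
    if (.homopolymerRun(spacer) >= 6L)
        warnings <- c(warnings, "spacer contains a homopolymer run >= 6")
    codonOfA <- (targetA - orfStart(record)) %/% 3L + 1L
    if (targetA >= orfStart(record)) {
        span <- codonToNt(codonOfA, orfStart(record))
        codon <- substr(seq, span[1L, "start"], span[1L, "end"])
        if (nchar(codon) == 3L && !codon %in% names(.STOP_CODONS))
            warnings <- c(warnings, sprintf(
                "target adenosine lies in sense codon %s, not a stop codon",
                codon))
    } else {
        warnings <- c(warnings, "target adenosine lies upstream of the ORF")
    }
    new("GuideDesign", targetRecordId = transcriptId(record),
        targetA = targetA, params = params, window = win, spacer = spacer,
        mismatchPosFrom3prime = d, fivePrimeBaseModified = modified,
        warnings = warnings)
}

#' Enumerate designs over a parameter grid
#'
#' One design per parameter set, in grid order; per-design failures are
#' collected rather than aborting the batch.
#'
#' @param record a [TranscriptRecord-class].
#' @param targetA transcript coordinate of the adenosine to edit.
#' @param paramGrid a non-empty list of [DesignParams-class].
#' @return A list with elements `designs` (list of [GuideDesign-class],
#'   successes in grid order) and `failures` (named character of error
#'   messages, named by grid position).
#' @export
enumerateDesigns <- function(record, targetA, paramGrid) {
    if (!length(paramGrid))
        stop("'paramGrid' must contain at least one parameter set",
             call. = FALSE)
    if (is(paramGrid, "DesignParams")) paramGrid <- list(paramGrid)
    designs <- list()
    failures <- character()
    for (i in seq_along(paramGrid)) {
        res <- tryCatch(designSpacer(record, targetA, paramGrid[[i]]),
                        error = function(e) conditionMessage(e))
        if (is(res, "GuideDesign"))
            designs[[length(designs) + 1L]] <- res
        else
            failures[[as.character(i)]] <- res
    }
    list(designs = designs, failures = failures)
}

#' Emit the annealing-ready oligo pair for a design
#'
#' The top oligo is the spacer with a 5' overhang; the bottom oligo is the
#' reverse complement of the spacer with its own 5' overhang. Distinct
#' overhangs make the cloning directional into the BbsI-digested guide
#' backbone. The overhang sequences are conventional defaults and fully
#' configurable; the structural invariant is that stripping the overhangs
#' and annealing reconstructs the spacer duplex exactly.
#'
#' @param design a [GuideDesign-class].
#' @param topOverhang,bottomOverhang 5' overhang sequences (A/C/G/T).
#' @param enzyme restriction enzyme the overhangs serve (annotation only).
#' @return An [OligoPair-class].
#' @export
emitOligoPair <- function(design, topOverhang = "CACC",
                          bottomOverhang = "CAAC", enzyme = "BbsI") {
    stopifnot(is(design, "GuideDesign"))
    topOverhang <- if (nzchar(topOverhang))
        .normalizeSeq(topOverhang, "top overhang") else ""
    bottomOverhang <- if (nzchar(bottomOverhang))
        .normalizeSeq(bottomOverhang, "bottom overhang") else ""
    spacer <- spacerSeq(design)
    new("OligoPair",
        topOligo = paste0(topOverhang, spacer),
        bottomOligo = paste0(bottomOverhang, reverseComplement(spacer)),
        topOverhang = topOverhang, bottomOverhang = bottomOverhang,
        enzyme = enzyme)
}

#' Validate a design against guide constraints
#'
#' Machine-readable issue list; an empty result means the design is clean.
#' Unlike [designSpacer()], the validator never throws.
#'
#' @param design a [GuideDesign-class].
#' @param minLength,maxLength acceptable spacer length bounds (the 25-80 nt
#'   working range of the dCas13b guide).
#' @return data.frame with columns `code` and `message`, zero rows when
#'   clean. Codes: `length-below-min`, `length-above-max`, `bbsi-site`,
#'   `mismatch-not-C`, plus any design-time warnings (`warning`).
#' @export
validateDesign <- function(design, minLength = 25L, maxLength = 80L) {
    issues <- list()
    add <- function(code, message)
        issues[[length(issues) + 1L]] <<- data.frame(
            code = code, message = message, stringsAsFactors = FALSE)
    n <- nchar(design@spacer)
    if (n < minLength)
        add("length-below-min",
            sprintf("spacer length %d below minimum %d", n, minLength))
    if (n > maxLength)
        add("length-above-max",
            sprintf("spacer length %d above maximum %d", n, maxLength))
    for (site in .BBSI_SITES)
        if (grepl(site, design@spacer, fixed = TRUE))
            add("bbsi-site",
                sprintf("spacer contains internal BbsI site %s", site))
    mmIdx <- n - design@mismatchPosFrom3prime + 1L
    if (mmIdx < 1L || mmIdx > n || .charAt(design@spacer, mmIdx) != "C")
        add("mismatch-not-C",
            "base at the mismatch position is not C")
    for (w in design@warnings)
        if (!grepl("BbsI", w)) add("warning", w)
    if (!length(issues))
        return(data.frame(code = character(0), message = character(0),
                          stringsAsFactors = FALSE))
    do.call(rbind, issues)
}

#' Tabulate guide designs
#'
#' @param designs a [GuideDesign-class] or list of them.
#' @return One row per design: target record/coordinate, geometry, spacer
#'   sequence, 5'-G flag and collapsed warnings. Suitable for TSV export.
#' @export
designTable <- function(designs) {
    if (is(designs, "GuideDesign")) designs <- list(designs)
    data.frame(
        recordId = vapply(designs, function(d) d@targetRecordId, character(1)),
        targetA = vapply(designs, function(d) d@targetA, integer(1)),
        spacerLength = vapply(designs, spacerLength, integer(1)),
        mismatchDistance = vapply(designs, mismatchDistance, integer(1)),
        windowStart = vapply(designs, function(d) d@window[1L], integer(1)),
        windowEnd = vapply(designs, function(d) d@window[2L], integer(1)),
        spacer = vapply(designs, spacerSeq, character(1)),
        fivePrimeBaseModified = vapply(designs,
            function(d) d@fivePrimeBaseModified, logical(1)),
        warnings = vapply(designs, function(d)
            paste(d@warnings, collapse = "; "), character(1)),
        stringsAsFactors = FALSE)
}
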