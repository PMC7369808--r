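#' Enumerate bystander adenosines within a design's editing window
#'
#' Every adenosine covered by the spacer is a potential collateral ADAR
#' substrate. For each window A, the consequence of editing that A alone
#' (substituting G and re-translating its codon) is classified as
#' intended-PTC-repair (the design's target adenosine),
#' synonymous, missense, stop-introducing, or noncoding (outside the ORF
#' or in a trailing partial codon). One A at a time: no editing-efficiency
#' model is available to weight multi-site combinations, so none is
#' invented.
#'
#' @param record the [TranscriptRecord-class] the design was built on.
#' @param design a [GuideDesign-class] whose window lies within the record.
#' @return A [BystanderReport-class]; its `entries` data.frame has one row
#'   per window adenosine and `counts` sums to the number of window A's.
#' @examples
#' rec <- fixturePreset("h2bgfp-opal")
#' des <- designSpacer(rec, 570, DesignParams(50, 34))
#' assessBystanders(rec, des)
#' @export
assessBystanders <- function(record, design) {
    stopifnot(is(record, "TranscriptRecord"), is(design, "GuideDesign"))
    seq <- transcriptSeq(record)
    win <- designWindow(design)
    if (win[1L] < 1L || win[2L] > nchar(seq))
        stop("design window lies outside the record", call. = FALSE)
    start <- orfStart(record)
    nCodons <- (nchar(seq) - start + 1L) %/% 3L
    positions <- win[1L]:win[2L]
    positions <- positions[substring(seq, positions, positions) == "A"]
    rows <- lapply(positions, function(p) {
        if (p < start)
            return(data.frame(position = p, codonIndex = NA_integer_,
                              codonOffset = NA_integer_,
                              codonBefore = NA_character_,
                              codonAfter = NA_character_,
                              consequence = "noncoding",
                              stringsAsFactors = FALSE))
        ci <- (p - start) %/% 3L + 1L
        if (ci > nCodons)  # trailing partial codon or past the ORF frame
            return(data.frame(position = p, codonIndex = NA_integer_,
                              codonOffset = NA_integer_,
                              codonBefore = NA_character_,
                              codonAfter = NA_character_,
                              consequence = "noncoding",
                              stringsAsFactors = FALSE))
        span <- codonToNt(ci, start)
        codon <- substr(seq, span[1L, "start"], span[1L, "end"])
        off <- p - span[1L, "start"] + 1L
        after <- codon
        substr(after, off, off) <- "G"
        consequence <- if (p %in% design@targetA)
            "intended-PTC-repair"
        else if (unname(Biostrings::GENETIC_CODE[after]) == "*")
            "stop-introducing"
        else if (Biostrings::GENETIC_CODE[codon] == Biostrings::GENETIC_CODE[after])
            "synonymous"
        else if (Biostrings::GENETIC_CODE[codon] == "*")
            "missense"  # un-targeted repair of a stop into a sense codon
        else
            "missense"
        data.frame(position = p, codonIndex = ci, codonOffset = off,
                   codonBefore = codon, codonAfter = after,
                   consequence = consequence, stringsAsFactors = FALSE)
    })
    entries <- if (length(rows)) do.call(rbind, rows)
        else data.frame(position = integer(0), codonIndex = integer(0),
                        codonOffset = integer(0),
                        codonBefore = character(0),
                        codonAfter = character(0),
                        consequence = character(0), stringsAsFactors = FALSE)
    classes <- c("intended-PTC-repair", "synonymous", "missense",
                 "stop-introducing", "noncoding")
    counts <- vapply(classes, function(cl) sum(entries$consequence == cl),
                     integer(1))
    new("BystanderReport", designTargetA = design@targetA,
        entries = entries, counts = counts)
}
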