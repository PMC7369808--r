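#' Construct a TranscriptRecord
#'
#' Normalises the sequence (uppercase, U -> T) and validates it. Ambiguity
#' codes are rejected: guide design against ambiguous bases is undefined,
#' and failing loudly avoids silently wrong spacers.
#'
#' @param id single character identifier.
#' @param sequence nucleotide string; DNA or RNA alphabet, any case.
#' @param orfStart 1-based transcript coordinate of the first base of
#'   codon 1 (default 1, i.e. the record is the ORF).
#' @return A [TranscriptRecord-class].
#' @examples
#' TranscriptRecord("x", "auguga")   # RNA input is normalised to DNA
#' @export
TranscriptRecord <- function(id, sequence, orfStart = 1L) {
    new("TranscriptRecord", id = as.character(id),
        sequence = .normalizeSeq(sequence, what = sprintf("record '%s'", id)),
        orfStart = as.integer(orfStart))
}

.normalizeSeq <- function(x, what = "sequence") {
    x <- toupper(as.character(x))
    x <- chartr("U", "T", x)
    bad <- setdiff(strsplit(x, "")[[1]], c("A", "C", "G", "T"))
    if (length(bad))
        stop(sprintf("%s contains non-A/C/G/T/U characters: %s",
                     what, paste(sort(unique(bad)), collapse = ", ")),
             call. = FALSE)
    x
}

#' Read transcripts from a FASTA file
#'
#' Wraps `Biostrings::readBStringSet()` and normalises every entry to the
#' internal DNA alphabet (uppercase, U -> T). File order is preserved.
#'
#' @param path path to a FASTA file (wrapped or unwrapped lines).
#' @param orfStart 1-based ORF start applied to every record; either a
#'   single value or a vector named by record id.
#' @return A list of [TranscriptRecord-class] objects.
#' @seealso [writeFasta()]
#' @export
readFasta <- function(path, orfStart = 1L) {
    if (!file.exists(path))
        stop("FASTA file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    nonEmpty <- which(nzchar(trimws(lines)))
    if (!length(nonEmpty))
        stop("no records in FASTA file: ", path, call. = FALSE)
    if (!startsWith(trimws(lines[nonEmpty[1L]]), ">"))
        stop(sprintf("malformed FASTA at line %d of %s: expected '>' header",
                     nonEmpty[1L], path), call. = FALSE)
    set <- Biostrings::readBStringSet(path)
    if (!length(set))
        stop("no records in FASTA file: ", path, call. = FALSE)
    ids <- sub("\\s.*$", "", names(set))
    starts <- if (is.null(names(orfStart))) rep_len(as.integer(orfStart),
                                                   length(set))
              else {
                  s <- rep_len(1L, length(set))
                  hit <- match(ids, names(orfStart))
                  s[!is.na(hit)] <- as.integer(orfStart[hit[!is.na(hit)]])
                  s
              }
    lapply(seq_along(set), function(i)
        TranscriptRecord(ids[i], as.character(set[[i]]), starts[i]))
}

#' Write transcripts to a FASTA file
#'
#' @param records a [TranscriptRecord-class] or list of them.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(records, path, width = 70L) {
    if (is(records, "TranscriptRecord")) records <- list(records)
    set <- Biostrings::DNAStringSet(vapply(records, transcriptSeq,
                                           character(1)))
    names(set) <- vapply(records, transcriptId, character(1))
    Biostrings::writeXStringSet(set, path, width = as.integer(width))
    invisible(path)
}

#' @importFrom Biostrings reverseComplement
#' @rawNamespace export(reverseComplement)
#' @name reverseComplement-reexport
#' @title Re-export of the Biostrings reverseComplement generic
#' @keywords internal
NULL

#' Reverse complement of a plain nucleotide string
#'
#' Adds a `character` method to the `Biostrings::reverseComplement()`
#' generic so that spacer construction can stay in plain strings. The
#' empty string maps to itself; the operation is an involution.
#'
#' @param x character(1) over {A,C,G,T} (U accepted, mapped to T).
#' @param ... unused.
#' @return character(1), the Watson-Crick reverse complement.
#' @examples
#' reverseComplement("ATGC")  # "GCAT"
#' @export
setMethod("reverseComplement", "character", function(x, ...) {
    x <- .normalizeSeq(x)
    if (!nzchar(x)) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
})

.codonsOf <- function(record) {
    seq <- transcriptSeq(record)
    start <- orfStart(record)
    nCodons <- (nchar(seq) - start + 1L) %/% 3L  # trailing partial codon ignored
    if (nCodons < 1L)
        stop("fewer than one complete codon downstream of orfStart",
             call. = FALSE)
    starts <- start + 3L * (seq_len(nCodons) - 1L)
    substring(seq, starts, starts + 2L)
}

#' Translate the ORF of a transcript
#'
#' Translates codons from `orfStart` with the standard genetic code until
#' the first stop codon or the end of the sequence; a trailing incomplete
#' codon is ignored.
#'
#' @param record a [TranscriptRecord-class].
#' @return A [ProteinTranslation-class]: residues up to (excluding) the
#'   first stop, the 1-based codon index of that stop (NA if none), and
#'   whether translation terminated at a stop.
#' @examples
#' translateOrf(TranscriptRecord("x", "ATGTGGTAA"))  # "MW", stop at codon 3
#' @export
translateOrf <- function(record) {
    stopifnot(is(record, "TranscriptRecord"))
    codons <- .codonsOf(record)
    aa <- unname(Biostrings::GENETIC_CODE[codons])
    stopAt <- which(aa == "*")
    if (length(stopAt)) {
        first <- stopAt[1L]
        new("ProteinTranslation",
            residues = paste(aa[seq_len(first - 1L)], collapse = ""),
            stopIndex = first, complete = TRUE)
    } else {
        new("ProteinTranslation", residues = paste(aa, collapse = ""),
            stopIndex = NA_integer_, complete = FALSE)
    }
}
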