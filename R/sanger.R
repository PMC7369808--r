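.CHANNELS <- c("A", "C", "G", "T")

#' Construct a TraceModel
#'
#' @param peakHeightCv relative SD of the called-base peak height
#'   (default 0.10).
#' @param noiseFloor per-channel baseline upper bound, as a fraction of the
#'   mean called-peak height; sampled uniformly on `[0, noiseFloor]`
#'   (default 0.21, calibrated -- see [TraceModel-class]).
#' @param crosstalk fraction of a called peak bleeding into the other
#'   channels (default 0.02).
#' @param seed optional default seed for simulation entry points.
#' @return A [TraceModel-class].
#' @export
TraceModel <- function(peakHeightCv = 0.10, noiseFloor = 0.21,
                       crosstalk = 0.02, seed = NA_integer_) {
    new("TraceModel", peakHeightCv = as.numeric(peakHeightCv),
        noiseFloor = as.numeric(noiseFloor),
        crosstalk = as.numeric(crosstalk), seed = as.integer(seed))
}

#' Construct a Trace from a height matrix
#'
#' @param templateId identifier of the sequenced template.
#' @param heights numeric matrix, one row per base-called position,
#'   columns A, C, G, T (set if unnamed), nonnegative.
#' @return A [Trace-class].
#' @export
Trace <- function(templateId, heights) {
    heights <- as.matrix(heights)
    if (is.null(colnames(heights)) && ncol(heights) == 4L)
        colnames(heights) <- .CHANNELS
    storage.mode(heights) <- "double"
    new("Trace", templateId = as.character(templateId), heights = heights)
}

#' Simulate Sanger peak heights for a partially edited template
#'
#' Models the electropherogram of a pooled cDNA amplicon population in
#' which a fraction `f` of molecules carries the A->G edit at `site`. At
#' every position the called channel receives a height drawn from
#' Normal(1, cv); at the edited site the signal is split, channel A
#' receiving `(1 - f)` and channel G `f` of an independent called-height
#' draw each, producing the double A/G peak of a mixed template. All
#' channels additionally receive a uniform baseline on
#' `[0, noiseFloor]` and a `crosstalk` fraction of the real signal in the
#' other channels. Heights are clipped at zero.
#'
#' @param template a [TranscriptRecord-class]; the amplicon sequence.
#' @param site transcript coordinate of the editable adenosine (base must
#'   be A).
#' @param editedFraction f in `[0, 1]`, fraction of edited molecules.
#' @param model a [TraceModel-class].
#' @param seed optional seed; when NULL, `model`'s seed slot is used if
#'   set, otherwise the current RNG stream continues (so that ensembles of
#'   traces can be drawn under one outer seed).
#' @return A [Trace-class] with one row per template base.
#' @examples
#' tpl <- generateOrf(FixtureSpec(nCodons = 20, ptcCodonIndex = 10, seed = 1))
#' simulateTrace(tpl, 30, editedFraction = 0.5, seed = 7)
#' @export
simulateTrace <- function(template, site, editedFraction,
                          model = TraceModel(), seed = NULL) {
    stopifnot(is(template, "TranscriptRecord"), is(model, "TraceModel"))
    validObject(model)
    f <- editedFraction
    if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0 || f > 1)
        stop("'editedFraction' must be a single number in [0, 1]",
             call. = FALSE)
    seq <- transcriptSeq(template)
    n <- nchar(seq)
    site <- as.integer(site)
    if (site < 1L || site > n)
        stop("'site' outside the template", call. = FALSE)
    if (.charAt(seq, site) != "A")
        stop(sprintf("template base at site %d is %s, not A",
                     site, .charAt(seq, site)), call. = FALSE)
    if (is.null(seed) && !is.na(model@seed)) seed <- model@seed
    if (!is.null(seed)) set.seed(as.integer(seed))
    called <- match(strsplit(seq, "")[[1]], .CHANNELS)
    signal <- matrix(0, nrow = n, ncol = 4L,
                     dimnames = list(NULL, .CHANNELS))
    h <- stats::rnorm(n, mean = 1, sd = model@peakHeightCv)
    signal[cbind(seq_len(n), called)] <- h
    # split the site's signal between the unedited (A) and edited (G) allele
    hG <- stats::rnorm(1L, mean = 1, sd = model@peakHeightCv)
    signal[site, "A"] <- (1 - f) * h[site]
    signal[site, "G"] <- f * hG
    baseline <- matrix(stats::runif(4L * n, 0, model@noiseFloor),
                       nrow = n, ncol = 4L)
    bleed <- model@crosstalk * (rowSums(signal) - signal)
    heights <- pmax(signal + baseline + bleed, 0)
    Trace(transcriptId(template), heights)
}

.flankNoise <- function(heights, site, flank = 10L, minFlank = 3L) {
    n <- nrow(heights)
    left <- seq(max(1L, site - flank), site - 1L)
    right <- seq(site + 1L, min(n, site + flank))
    left <- left[left >= 1L & left < site]
    right <- right[right > site & right <= n]
    if (length(left) < minFlank || length(right) < minFlank)
        stop(sprintf(
            "site %d too close to the trace edge: need >= %d flanking positions per side",
            site, minFlank), call. = FALSE)
    if (length(left) < flank || length(right) < flank)
        warning("flank truncated near the trace edge; noise estimate uses fewer positions",
                call. = FALSE)
    pos <- c(left, right)
    calledAt <- max.col(heights[pos, , drop = FALSE], ties.method = "first")
    # heights of the three non-called channels at each flanking position
    noise <- unlist(lapply(seq_along(pos), function(i)
        heights[pos[i], -calledAt[i]]), use.names = FALSE)
    list(mean = mean(noise), sd = stats::sd(noise))
}

#' Estimate the edited fraction from a trace at a site
#'
#' The per-channel noise level is estimated from the non-called channels
#' of up to `flank` base-called positions on each side of the site
#' (excluding the site itself). A minor (secondary) peak is called when
#' the largest non-primary channel height at the site reaches
#' `noise mean + k * noise SD`. The edited fraction is estimated as
#' G / (A + G) of the baseline-subtracted site heights, clipped at zero.
#'
#' @param trace a [Trace-class].
#' @param site position within the trace.
#' @param k detection stringency in noise SDs (default 3).
#' @param flank flanking positions per side for the noise estimate
#'   (default 10; shrunk with a warning near trace ends, error if fewer
#'   than 3 remain on either side).
#' @return An [EditingEstimate-class].
#' @export
estimateEditedFraction <- function(trace, site, k = 3, flank = 10L) {
    stopifnot(is(trace, "Trace"))
    heights <- traceHeights(trace)
    site <- as.integer(site)
    if (site < 1L || site > nrow(heights))
        stop("'site' outside the trace", call. = FALSE)
    ns <- .flankNoise(heights, site, flank = as.integer(flank))
    siteH <- heights[site, ]
    primary <- .CHANNELS[which.max(siteH)]
    rest <- siteH[setdiff(.CHANNELS, primary)]
    secondary <- names(rest)[which.max(rest)]
    threshold <- ns$mean + k * ns$sd
    detected <- unname(rest[secondary]) >= threshold
    a <- max(siteH[["A"]] - ns$mean, 0)
    g <- max(siteH[["G"]] - ns$mean, 0)
    fhat <- if (a + g > 0) g / (a + g) else 0
    new("EditingEstimate", position = site, primaryBase = primary,
        secondaryBase = if (detected) secondary else NA_character_,
        estimatedFraction = fhat, noiseEstimate = ns$mean,
        detected = detected)
}

#' Smallest detectable edited fraction under the trace model
#'
#' For each fraction on the grid, simulates `nReps` traces and calls the
#' fraction detectable when the minor peak is called in at least
#' `detectRate` of the replicates; returns the smallest detectable grid
#' value. This is the in-silico analogue of asking how much edited
#' transcript a pooled Sanger read needs before the minor G peak becomes
#' visible over baseline noise.
#'
#' @param template a [TranscriptRecord-class]; the sequenced amplicon.
#' @param site transcript coordinate of the editable adenosine.
#' @param fractions ascending grid of edited fractions in `[0, 1]`
#'   (default 0.05 to 0.50 in steps of 0.05).
#' @param nReps replicate traces per fraction (default 100).
#' @param model a [TraceModel-class].
#' @param seed RNG seed for the whole experiment (default: the model's
#'   seed slot, or 42); one stream drives all replicates, so a fixed seed
#'   gives bit-identical results.
#' @param detectRate required per-fraction detection rate (default 0.9).
#' @param k,flank passed to [estimateEditedFraction()].
#' @return The smallest detectable fraction (numeric), or `NA` if none
#'   qualifies; the per-fraction detection rates are attached as the
#'   `"rates"` attribute.
#' @export
detectionLimit <- function(template, site,
                           fractions = seq(0.05, 0.50, by = 0.05),
                           nReps = 100L, model = TraceModel(), seed = NULL,
                           detectRate = 0.9, k = 3, flank = 10L) {
    if (!length(fractions))
        stop("'fractions' must be a non-empty ascending grid", call. = FALSE)
    if (is.unsorted(fractions, strictly = TRUE))
        stop("'fractions' must be strictly ascending", call. = FALSE)
    if (is.null(seed)) seed <- if (!is.na(model@seed)) model@seed else 42L
    set.seed(as.integer(seed))
    rates <- vapply(fractions, function(f) {
        hits <- vapply(seq_len(nReps), function(i) {
            tr <- simulateTrace(template, site, f, model, seed = NULL)
            peakDetected(estimateEditedFraction(tr, site, k = k,
                                                flank = flank))
        }, logical(1))
        mean(hits)
    }, numeric(1))
    names(rates) <- formatC(fractions, format = "g")
    idx <- which(rates >= detectRate)
    out <- if (length(idx)) fractions[idx[1L]] else NA_real_
    attr(out, "rates") <- rates
    out
}

#' Read a trace from a tab-separated table
#'
#' Expected columns: `position`, `A`, `C`, `G`, `T`. AB1 binary traces are
#' not supported by this reader; requesting one raises an explicit error
#' rather than a silent fallback.
#'
#' @param path path to the TSV.
#' @param templateId id for the resulting trace (default: file name).
#' @return A [Trace-class].
#' @seealso [writeTraceTable()]
#' @export
readTraceTable <- function(path, templateId = NULL) {
    if (grepl("\\.ab1$", path, ignore.case = TRUE))
        stop("AB1 trace format not enabled: convert to a position/A/C/G/T TSV first",
             call. = FALSE)
    if (!file.exists(path))
        stop("trace table not found: ", path, call. = FALSE)
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("position", .CHANNELS)
    missing <- setdiff(need, names(df))
    if (length(missing))
        stop("trace table is missing columns: ",
             paste(missing, collapse = ", "), call. = FALSE)
    for (col in need)
        if (!is.numeric(df[[col]])) {
            badRow <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1L]
            stop(sprintf(
                "malformed trace table at data line %d: non-numeric '%s'",
                badRow, col), call. = FALSE)
        }
    df <- df[order(df$position), , drop = FALSE]
    heights <- as.matrix(df[, .CHANNELS])
    rownames(heights) <- NULL
    Trace(if (is.null(templateId)) basename(path) else templateId, heights)
}

#' Write a trace to a tab-separated table
#'
#' @param trace a [Trace-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTraceTable <- function(trace, path) {
    stopifnot(is(trace, "Trace"))
    df <- data.frame(position = seq_len(nrow(trace@heights)),
                     trace@heights, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
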