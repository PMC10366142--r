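#' Rank-size curve of genomic domain sizes
#'
#' Sorts the sizes ascending (stable sort, ties keep input order), normalizes
#' ranks to [0, 1] as (i - 1)/(n - 1) and sizes to [0, 1] by min-max
#' scaling, and computes the slope of the tangent at each pair of adjacent
#' points. This is the diagnostic curve on which the large-domain cutoff is
#' found: small domains form a flat body and the largest domains a steep
#' tail, so the tangent slope rises with rank.
#'
#' @param sizes numeric vector of domain sizes (bp), length >= 12, not all
#'   equal.
#' @return a \linkS4class{RankCurve}.
#' @seealso \code{\link{slidingSlopeCutoff}}
#' @examples
#' rankSizeCurve(seq(10, 1000, by = 10))
#' @export
rankSizeCurve <- function(sizes) {
    sizes <- as.numeric(sizes)
    n <- length(sizes)
    if (n < 12L) stop("need at least 12 domain sizes")
    if (any(!is.finite(sizes)) || any(sizes <= 0))
        stop("sizes must be positive and finite")
    if (max(sizes) == min(sizes))
        stop("degenerate normalization: all sizes are equal")
    s <- sizes[order(sizes)]           # order() is stable
    x <- (seq_len(n) - 1) / (n - 1)
    y <- (s - s[1]) / (s[n] - s[1])
    slopes <- diff(y) / diff(x)
    new("RankCurve", sizes = s, x = x, y = y, slopes = pmax(slopes, 0))
}

#' Sliding-window slope cutoff for large domains
#'
#' Scans windows of \code{window} consecutive tangent slopes in ascending
#' rank order and takes the first window whose mean slope reaches
#' \code{slopeThreshold} (default 1, the slope of the diagonal of the
#' normalized plot) as the crossing. The cutoff size is the domain size at
#' the chosen anchor of that window (default its first data point). When no
#' window qualifies the result carries status \code{"no_crossing"} rather
#' than an error.
#'
#' @param curve a \linkS4class{RankCurve}.
#' @param window number of consecutive slopes averaged (default 10).
#' @param slopeThreshold crossing threshold (default 1).
#' @param anchor which point of the qualifying window gives the cutoff:
#'   "first" (default), "center" or "last".
#' @return a \linkS4class{CutoffResult}.
#' @examples
#' cr <- slidingSlopeCutoff(rankSizeCurve(seq(10, 1000, by = 10)))
#' cutoffBp(cr)   # linear sizes: crossing at the first window
#' @export
slidingSlopeCutoff <- function(curve, window = 10, slopeThreshold = 1.0,
                               anchor = c("first", "center", "last")) {
    stopifnot(is(curve, "RankCurve"))
    anchor <- match.arg(anchor)
    W <- as.integer(window)
    t <- curve@slopes
    if (W < 1L || W > length(t))
        stop("'window' must lie in [1, number of slopes]")
    means <- as.numeric(stats::filter(t, rep(1 / W, W), sides = 1))
    means <- means[W:length(t)]        # means[i] = mean(t[i..i+W-1])
    # tolerance so the exact-equality case (all slopes 1) is not lost to
    # floating-point rounding
    hit <- which(means >= slopeThreshold - 1e-9)
    if (!length(hit))
        return(new("CutoffResult", cutoffBp = NA_real_,
                   crossingIndex = NA_real_, nLarge = 0,
                   status = "no_crossing", window = W,
                   slopeThreshold = slopeThreshold, windowMeans = means,
                   curve = curve))
    i <- hit[1L]
    pt <- switch(anchor, first = i, center = i + W %/% 2L, last = i + W - 1L)
    cutoff <- curve@sizes[pt]
    new("CutoffResult", cutoffBp = cutoff, crossingIndex = as.numeric(i),
        nLarge = sum(curve@sizes >= cutoff), status = "ok", window = W,
        slopeThreshold = slopeThreshold, windowMeans = means, curve = curve)
}

#' Partition domains into large and small
#'
#' Splits a set of genomic domains at a size cutoff obtained either from the
#' rank-slope crossing (\code{mode = "rank_slope"}) or from a fixed cutoff
#' (\code{mode = "fixed"}, default 96 kb, the previously reported megadomain
#' cutoff). The boundary is inclusive: a domain whose size equals the cutoff
#' counts as large.
#'
#' @param domains a \code{GRanges} of domains, or a numeric vector of sizes
#'   (bp).
#' @param mode "rank_slope" or "fixed".
#' @param fixedCutoffBp cutoff used in fixed mode (default 96000).
#' @param window,slopeThreshold,anchor passed to
#'   \code{\link{slidingSlopeCutoff}} in rank-slope mode.
#' @return a list with \code{large}, \code{small} (same class as the input),
#'   \code{cutoffBp}, and \code{cutoff} (a \linkS4class{CutoffResult} in
#'   rank-slope mode, otherwise the fixed value). In rank-slope mode with no
#'   crossing, all domains are classed small and \code{cutoffBp} is NA.
#' @examples
#' classifyLargeDomains(c(10e3, 96e3, 200e3), mode = "fixed")$large
#' @export
classifyLargeDomains <- function(domains, mode = c("rank_slope", "fixed"),
                                 fixedCutoffBp = 96000, window = 10,
                                 slopeThreshold = 1.0, anchor = "first") {
    mode <- match.arg(mode)
    sizes <- if (is(domains, "GRanges")) GenomicRanges::width(domains)
             else as.numeric(domains)
    if (mode == "fixed") {
        cutoff <- fixedCutoffBp
        detail <- fixedCutoffBp
    } else {
        detail <- slidingSlopeCutoff(rankSizeCurve(sizes), window = window,
                                     slopeThreshold = slopeThreshold,
                                     anchor = anchor)
        cutoff <- cutoffBp(detail)
    }
    isLarge <- if (is.na(cutoff)) rep(FALSE, length(sizes)) else sizes >= cutoff
    list(large = domains[isLarge], small = domains[!isLarge],
         cutoffBp = cutoff, cutoff = detail)
}

#' Overlap between two domain sets
#'
#' Counts, per direction, the domains of one set overlapping any domain of
#' the other by at least \code{minOverlapBp}, and computes the shared base
#' pairs and the base-pair-level Jaccard index of the two (reduced)
#' footprints. Coordinates follow the usual 0-based half-open BED convention
#' on import/export; internally GRanges 1-based closed intervals are used.
#'
#' @param setA,setB \code{GRanges} of domains.
#' @param minOverlapBp minimum overlap (bp) for a domain to count as
#'   overlapping (default 1).
#' @return a list with \code{nAOverlapping}, \code{nBOverlapping},
#'   \code{nA}, \code{nB}, \code{sharedBp}, \code{unionBp}, \code{jaccard}.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150))
#' domainOverlap(a, b)$jaccard   # 50 / 150
#' @export
domainOverlap <- function(setA, setB, minOverlapBp = 1) {
    stopifnot(is(setA, "GRanges"), is(setB, "GRanges"))
    lv <- union(GenomeInfoDb::seqlevels(setA), GenomeInfoDb::seqlevels(setB))
    GenomeInfoDb::seqlevels(setA) <- lv
    GenomeInfoDb::seqlevels(setB) <- lv
    nAov <- sum(GenomicRanges::countOverlaps(
        setA, setB, minoverlap = minOverlapBp) > 0)
    nBov <- sum(GenomicRanges::countOverlaps(
        setB, setA, minoverlap = minOverlapBp) > 0)
    ra <- GenomicRanges::reduce(setA)
    rb <- GenomicRanges::reduce(setB)
    shared <- sum(GenomicRanges::width(GenomicRanges::intersect(ra, rb)))
    unionBp <- sum(GenomicRanges::width(GenomicRanges::union(ra, rb)))
    list(nAOverlapping = nAov, nBOverlapping = nBov,
         nA = length(setA), nB = length(setB),
         sharedBp = shared, unionBp = unionBp,
         jaccard = if (unionBp > 0) shared / unionBp else 0)
}

#' Read and write domain BED files
#'
#' Minimal BED3 IO preserving the 0-based half-open convention: on reading,
#' start + 1 becomes the GRanges start; on writing, start - 1 is emitted.
#'
#' @param path file path.
#' @param domains a \code{GRanges}.
#' @return \code{readDomainsBed}: a \code{GRanges};
#'   \code{writeDomainsBed}: the path, invisibly.
#' @export
readDomainsBed <- function(path) {
    df <- read.table(path, sep = "\t", header = FALSE,
                     col.names = c("chrom", "start", "end"),
                     colClasses = c("character", "numeric", "numeric"))[, 1:3]
    if (any(df$end <= df$start)) stop("malformed interval: end <= start")
    GenomicRanges::GRanges(df$chrom,
                           IRanges::IRanges(df$start + 1, df$end))
}

#' @rdname readDomainsBed
#' @export
writeDomainsBed <- function(domains, path) {
    stopifnot(is(domains, "GRanges"))
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(domains)),
                     start = GenomicRanges::start(domains) - 1,
                     end = GenomicRanges::end(domains))
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Export the rank-slope diagnostic curve
#'
#' Writes one row per ranked domain: rank, size, normalized rank and size,
#' the tangent slope at that point (NA for the last) and the sliding window
#' mean starting at that slope (NA where the window does not fit), ready for
#' plotting.
#'
#' @param result a \linkS4class{CutoffResult}.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeCurveTsv <- function(result, path) {
    stopifnot(is(result, "CutoffResult"))
    cv <- result@curve
    n <- length(cv@sizes)
    wm <- rep(NA_real_, n)
    wm[seq_along(result@windowMeans)] <- result@windowMeans
    df <- data.frame(rank = seq_len(n), size_bp = cv@sizes,
                     rank_norm = cv@x, size_norm = cv@y,
                     slope = c(cv@slopes, NA), window_mean = wm)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
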