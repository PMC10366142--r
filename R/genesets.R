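#' Venn partition counts of two gene sets
#'
#' @param setA,setB character vectors of gene identifiers (duplicates are
#'   removed).
#' @return a named numeric vector with \code{nAOnly}, \code{nBOnly},
#'   \code{overlap}.
#' @examples
#' vennCounts(c("a", "b", "c"), c("b", "c", "d", "e"))   # 1, 2, 2
#' @export
vennCounts <- function(setA, setB) {
    a <- unique(as.character(setA)); b <- unique(as.character(setB))
    ov <- length(intersect(a, b))
    c(nAOnly = length(a) - ov, nBOnly = length(b) - ov, overlap = ov)
}

#' Randomized expected overlap of two gene sets
#'
#' Each iteration draws two sets of sizes \code{nA} and \code{nB}
#' independently, uniformly without replacement, from the universe and
#' records the size of their intersection; the default 20 iterations match
#' the randomly-generated-gene-pool procedure used for published Venn
#' expectations, and many more can be requested for convergence checks.
#'
#' @param nA,nB set sizes.
#' @param universe character vector of gene identifiers.
#' @param iters number of random draws (default 20).
#' @param seed integer seed.
#' @return a list with \code{mean}, \code{sd} and the per-iteration
#'   \code{samples}.
#' @examples
#' u <- sprintf("g%03d", 1:100)
#' expectedOverlapRandom(20, 30, u, iters = 50, seed = 1)$mean  # ~ 6
#' @export
expectedOverlapRandom <- function(nA, nB, universe, iters = 20, seed = 1L) {
    universe <- unique(as.character(universe))
    N <- length(universe)
    if (nA > N || nB > N) stop("set size exceeds the universe")
    if (iters < 1) stop("'iters' must be >= 1")
    samples <- withLocalSeed(seed, vapply(seq_len(iters), function(i) {
        length(intersect(sample(universe, nA), sample(universe, nB)))
    }, 0))
    list(mean = mean(samples),
         sd = if (iters > 1) sd(samples) else 0,
         samples = samples)
}

#' Representation factor
#'
#' The number of overlapping genes divided by the number expected when two
#' sets of the same sizes are drawn at random from independent groups.
#'
#' @param observed observed overlap count.
#' @param expected expected overlap (> 0).
#' @return observed / expected.
#' @examples
#' representationFactor(31, 1)   # 31
#' @export
representationFactor <- function(observed, expected) {
    if (observed < 0) stop("'observed' must be >= 0")
    if (expected <= 0)
        stop("undefined representation factor: expected overlap is 0")
    observed / expected
}

#' Hypergeometric enrichment p-value for a set overlap
#'
#' Upper-tail probability P(X >= observed) where X is the overlap of a
#' random set of size \code{nA} with a fixed set of size \code{nB} in a
#' universe of size \code{N} (hypergeometric with \code{nA} draws and
#' \code{nB} successes). Symmetric in \code{nA} and \code{nB}.
#'
#' @param observed observed overlap.
#' @param nA,nB set sizes.
#' @param N universe size.
#' @return p in (0, 1]; \code{observed = 0} gives exactly 1.
#' @examples
#' hypergeomPvalue(0, 5, 4, 10)   # 1
#' @export
hypergeomPvalue <- function(observed, nA, nB, N) {
    if (nA > N || nB > N) stop("set sizes must not exceed the universe")
    if (observed > min(nA, nB)) stop("overlap exceeds a set size")
    if (observed < 0) stop("'observed' must be >= 0")
    phyper(observed - 1, nB, N - nB, nA, lower.tail = FALSE)
}

#' Full gene-set overlap analysis
#'
#' Combines the Venn counts, the randomized expected overlap, the analytic
#' expectation nA * nB / N, the representation factor (observed over the
#' randomized expectation) and the hypergeometric enrichment p-value into a
#' single \linkS4class{OverlapResult}.
#'
#' @param setA,setB character vectors of gene identifiers.
#' @param universe character vector containing the gene universe.
#' @param iters randomization iterations (default 20).
#' @param seed integer seed for the randomization.
#' @return an \linkS4class{OverlapResult}.
#' @examples
#' gs <- simulateGeneSets(1000, 100, 50, 20, seed = 5)
#' geneSetOverlap(gs$setA, gs$setB, gs$universe, seed = 5)
#' @export
geneSetOverlap <- function(setA, setB, universe, iters = 20, seed = 1L) {
    a <- unique(as.character(setA)); b <- unique(as.character(setB))
    universe <- unique(as.character(universe))
    missing <- setdiff(c(a, b), universe)
    if (length(missing))
        stop(length(missing), " gene(s) not present in the universe")
    vc <- vennCounts(a, b)
    N <- length(universe)
    rnd <- expectedOverlapRandom(length(a), length(b), universe, iters, seed)
    rf <- if (rnd$mean > 0) vc[["overlap"]] / rnd$mean else NA_real_
    new("OverlapResult",
        nAOnly = vc[["nAOnly"]], nBOnly = vc[["nBOnly"]],
        observedOverlap = vc[["overlap"]],
        expectedRandomMean = rnd$mean, expectedRandomSD = rnd$sd,
        expectedAnalytic = length(a) * length(b) / N,
        representationFactor = rf,
        pValue = hypergeomPvalue(vc[["overlap"]], length(a), length(b), N),
        iters = iters, universeSize = N, seed = as.numeric(seed))
}

#' Read or write a one-identifier-per-line gene list
#'
#' @param path file path.
#' @param genes character vector.
#' @return \code{readGeneSet}: a character vector; \code{writeGeneSet}: the
#'   path, invisibly.
#' @export
readGeneSet <- function(path) {
    x <- readLines(path)
    x <- trimws(x)
    unique(x[nzchar(x)])
}

#' @rdname readGeneSet
#' @export
writeGeneSet <- function(genes, path) {
    writeLines(as.character(genes), path)
    invisible(path)
}
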