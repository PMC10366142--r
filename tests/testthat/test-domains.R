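library(GenomicRanges)

test_that("rank-size curve normalization and slopes", {
    sizes <- seq(10, 1000, by = 10)
    cv <- rankSizeCurve(sizes)
    expect_equal(cv@slopes, rep(1, 99))            # linear => unit slopes
    expect_equal(range(cv@x), c(0, 1))
    expect_equal(range(cv@y), c(0, 1))

    cv7 <- rankSizeCurve(sizes * 7)                # min-max scale invariance
    expect_equal(cv7@x, cv@x)
    expect_equal(cv7@y, cv@y)
    expect_equal(cv7@slopes, cv@slopes)

    set.seed(2)
    s <- round(rlnorm(500, 9, 1))
    cvl <- rankSizeCurve(s)
    expect_true(all(diff(cvl@x) > 0))
    expect_true(all(diff(cvl@y) >= 0))
    srt <- sort(s)   # independent finite differences
    ind <- diff((srt - min(srt)) / (max(srt) - min(srt))) /
        diff((seq_along(srt) - 1) / (length(srt) - 1))
    expect_equal(cvl@slopes, ind)

    expect_error(rankSizeCurve(1:11), "at least 12")
    expect_error(rankSizeCurve(rep(5, 20)), "degenerate")
})

test_that("sliding-slope cutoff finds the first qualifying window", {
    lin <- slidingSlopeCutoff(rankSizeCurve(seq(10, 1000, by = 10)))
    expect_equal(crossingIndex(lin), 1)
    expect_equal(cutoffBp(lin), 10)                # smallest size
    expect_equal(nLarge(lin), 100)

    for (sd in 1:6) {
        pw <- simulateDomainSizes(200, "piecewise",
                                  bodyIncrement = 10 * sd,
                                  tailIncrement = 2000 * sd,
                                  bodyFraction = 0.7 + 0.03 * sd)
        cr <- slidingSlopeCutoff(rankSizeCurve(pw$sizes))
        oracle <- bruteCrossing(pw$sizes)
        expect_equal(crossingIndex(cr), oracle$index)
        expect_equal(cutoffBp(cr), oracle$cutoff)
        expect_equal(nLarge(cr), sum(pw$sizes >= oracle$cutoff))
    }

    # no window reaches the threshold: since min-max normalization forces
    # the mean of all slopes to be exactly 1, a threshold of 1 always
    # crosses somewhere; a no-crossing outcome needs a higher threshold
    lin <- rankSizeCurve(seq(10, 1000, by = 10))     # every window mean = 1
    nc <- slidingSlopeCutoff(lin, window = 10, slopeThreshold = 2)
    expect_equal(nc@status, "no_crossing")
    expect_true(is.na(cutoffBp(nc)))
    expect_equal(nLarge(nc), 0)

    expect_error(slidingSlopeCutoff(rankSizeCurve(1:12), window = 30),
                 "window")
})

test_that("cutoff is scale-equivariant and permutation-invariant", {
    pw <- simulateDomainSizes(300, "piecewise")
    base <- slidingSlopeCutoff(rankSizeCurve(pw$sizes))
    for (c in c(0.5, 7.3, 1000)) {
        sc <- slidingSlopeCutoff(rankSizeCurve(pw$sizes * c))
        expect_equal(crossingIndex(sc), crossingIndex(base))
        expect_equal(cutoffBp(sc), cutoffBp(base) * c, tolerance = 1e-12)
    }
    set.seed(3)
    sh <- slidingSlopeCutoff(rankSizeCurve(sample(pw$sizes)))
    expect_equal(cutoffBp(sh), cutoffBp(base))

    # raising the slope threshold never moves the crossing earlier
    idx <- vapply(c(0.5, 1, 1.5, 2), function(th) {
        r <- slidingSlopeCutoff(rankSizeCurve(pw$sizes), slopeThreshold = th)
        if (r@status == "ok") crossingIndex(r) else Inf
    }, 0)
    expect_true(all(diff(idx) >= 0))
})

test_that("classifyLargeDomains partitions correctly in both modes", {
    sizes <- c(10e3, 96e3, 200e3, rep(20e3, 12))
    fx <- classifyLargeDomains(sizes, mode = "fixed")
    expect_setequal(fx$large, c(96e3, 200e3))      # boundary inclusive
    expect_equal(length(fx$large) + length(fx$small), length(sizes))

    allSmall <- classifyLargeDomains(rep(50e3, 15), mode = "fixed")
    expect_length(allSmall$large, 0)

    pw <- simulateDomainSizes(200, "piecewise")
    rs <- classifyLargeDomains(pw$sizes, mode = "rank_slope")
    oracle <- bruteCrossing(pw$sizes)
    expect_length(rs$large, sum(pw$sizes >= oracle$cutoff))

    gr <- GRanges("chr1", IRanges(start = seq(1, by = 300e3, length.out = 14),
                                  width = c(rep(10e3, 12), 96e3, 200e3)))
    fg <- classifyLargeDomains(gr, mode = "fixed")
    expect_equal(length(fg$large), 2L)
    expect_s4_class(fg$large, "GRanges")
})

test_that("interval overlap counts, shared bp and Jaccard", {
    a <- GRanges("chr1", IRanges(1, 100))
    b <- GRanges("chr1", IRanges(51, 150))
    ov <- domainOverlap(a, b)
    expect_equal(ov$sharedBp, 50)
    expect_equal(ov$jaccard, 50 / 150)
    expect_equal(ov$nAOverlapping, 1)

    ident <- domainOverlap(b, b)
    expect_equal(ident$jaccard, 1)
    expect_equal(ident$nAOverlapping, 1)

    disj <- domainOverlap(GRanges("chr1", IRanges(1, 100)),
                          GRanges("chr2", IRanges(1, 100)))
    expect_equal(disj$nAOverlapping, 0)
    expect_equal(disj$jaccard, 0)

    # minimum-overlap requirement
    touch <- domainOverlap(GRanges("chr1", IRanges(1, 100)),
                           GRanges("chr1", IRanges(91, 200)),
                           minOverlapBp = 20)
    expect_equal(touch$nAOverlapping, 0)
})

test_that("BED round trip preserves 0-based half-open coordinates", {
    gr <- GRanges(c("chrS", "chrS", "chr2"),
                  IRanges(start = c(1, 1001, 5001), end = c(100, 2000, 5100)))
    p <- tempfile(fileext = ".bed")
    writeDomainsBed(gr, p)
    txt <- read.table(p, sep = "\t")
    expect_equal(txt$V2, c(0, 1000, 5000))          # 0-based starts on disk
    back <- readDomainsBed(p)
    expect_equal(start(back), start(gr))
    expect_equal(width(back), width(gr))

    bad <- tempfile(fileext = ".bed")
    writeLines("chr1\t100\t50", bad)
    expect_error(readDomainsBed(bad), "malformed")
})
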