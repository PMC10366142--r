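test_that("filterNuclei applies the size gate and border rule", {
    lab <- drawDisk(400, 400, 200, 200, 50)                 # d = 100 px
    expect_equal(max(filterNuclei(lab, detectionParams())), 1L)

    border <- drawDisk(400, 400, 51, 200, 50, value = 1L)   # touches row 1
    expect_equal(max(filterNuclei(border, detectionParams())), 0L)
    keepBorder <- detectionParams(removeBorderNuclei = FALSE)
    expect_equal(max(filterNuclei(border, keepBorder)), 1L)

    three <- drawDisk(900, 900, 150, 150, 30)               # d = 60: too small
    three <- drawDisk(900, 900, 450, 450, 50, 2L, three)    # d = 100: kept
    three <- drawDisk(900, 900, 450, 750, 30, 3L, three)    # second small one
    big <- drawDisk(900, 900, 700, 250, 175, 4L)            # d = 350: too big
    three[big == 4L] <- 4L
    out <- filterNuclei(three, detectionParams())
    expect_equal(sort(unique(out[out > 0])), 1L)
    expect_equal(sum(out == 1L), sum(three == 2L))          # the 100-px disk

    expect_warning(filterNuclei(matrix(0L, 5, 5)), "empty")
})

test_that("enhanceSpeckles is a white top-hat with the stated behaviour", {
    expect_equal(enhanceSpeckles(matrix(7, 30, 30), 11), matrix(0, 30, 30))

    # bright disk of diameter 10 on flat background, feature 40
    m <- drawDisk(100, 100, 50, 50, 5, value = 1L) * 50 + 10
    enh <- enhanceSpeckles(m, 40)
    expect_equal(enh, bruteTopHat(m, 40))
    expect_gt(max(enh), 0.95 * 50)                 # contrast preserved

    # a smooth large-scale gradient is removed almost entirely; within one
    # structuring-element radius of the border the opening is necessarily
    # underestimated (any window containing an edge pixel of a ramp has its
    # minimum one half-width away), so the bound applies to the interior
    grad <- matrix(rep(seq(0, 100, length.out = 120), each = 120), 120, 120)
    enhG <- enhanceSpeckles(grad, 40)
    expect_equal(enhG, bruteTopHat(grad, 40))
    expect_lt(max(enhG[21:100, 21:100]), 0.05 * 100)
})

test_that("otsuThreshold equals the exhaustive between-class-variance scan", {
    v <- c(rep(10, 500), rep(200, 500))
    t <- otsuThreshold(v)
    expect_gt(t, 10); expect_lt(t, 200)

    set.seed(123)
    for (i in 1:10) {
        vals <- sample(0:255, 64 * 64, replace = TRUE)
        expect_identical(otsuThreshold(vals), bruteOtsu(vals))
    }

    # two well-separated Gaussian modes: the between-class variance is flat
    # across the empty inter-mode gap, and (like skimage) the first maximum
    # is taken, so the threshold lands at the gap's lower edge -- anywhere
    # strictly between the modes separates the classes identically
    set.seed(5)
    bimodal <- c(rnorm(3000, 50, 5), rnorm(3000, 150, 5))
    tb <- otsuThreshold(bimodal)
    expect_gt(tb, 50 + 3 * 5); expect_lt(tb, 150 - 3 * 5)
    expect_equal(tb, bruteOtsu(bimodal))

    expect_error(otsuThreshold(rep(3, 10)), "degenerate")
})

test_that("robustBackgroundThreshold implements trim-then-mean-plus-SD", {
    expect_equal(robustBackgroundThreshold(rep(5, 100)), 5)
    kept <- 5:94
    expect_equal(robustBackgroundThreshold(0:99, 0.05, 0.05, 2),
                 mean(kept) + 2 * sd(kept))
    expect_equal(robustBackgroundThreshold(0:99, 0.05, 0.05, 0), mean(kept))
    expect_error(robustBackgroundThreshold(1:4, 0.5, 0.5, 2), "trimmed")
    expect_error(robustBackgroundThreshold(numeric(0)), "empty")
})

plantedNucleusScene <- function(conds, nr = 200, nc = 200, noise = 20,
                                amp = 200, bg = 200, seed = 1,
                                nucR = 55) {
    set.seed(seed)
    nuc <- drawDisk(nr, nc, nr / 2, nc / 2, nucR)
    img <- bg * (nuc > 0)
    for (cn in conds) img <- addGauss(img, cn[1], cn[2], cn[3], amp)
    img <- img + matrix(rnorm(nr * nc, 0, noise), nr, nc)
    list(image = pmax(img, 0), nuclei = nuc)
}

test_that("two-round detection recovers planted condensates", {
    sc <- plantedNucleusScene(list(c(80, 80, 8), c(100, 120, 12),
                                   c(125, 90, 20)), seed = 3)
    enh <- enhanceSpeckles(sc$image, 40)
    det <- detectCondensates(enh, sc$nuclei, pixelSizeUm = 0.08)
    expect_equal(nrow(det$objects), 3L)
    truth <- data.frame(centroid_row = c(80, 100, 125),
                        centroid_col = c(80, 120, 90))
    expect_equal(matchCentroids(truth, det$objects, maxDist = 2), 3L)
    expect_true(all(det$objects$nucleus_id == 1L))

    # reported diameters always lie in the configured round-2 range
    p <- detectionParams()
    expect_true(all(det$objects$equiv_diameter_px >=
                        p@round2DiameterPxRange[1] &
                    det$objects$equiv_diameter_px <=
                        p@round2DiameterPxRange[2]))
    expect_true(all(det$objects$eccentricity >= 0 &
                    det$objects$eccentricity < 1))

    # centroid lies inside the assigned nucleus
    for (i in seq_len(nrow(det$objects)))
        expect_equal(sc$nuclei[round(det$objects$centroid_row[i]),
                               round(det$objects$centroid_col[i])], 1L)
})

test_that("noise-only nuclei yield no condensates", {
    sc <- plantedNucleusScene(list(), noise = 15, seed = 11)
    enh <- enhanceSpeckles(sc$image, 40)
    det <- detectCondensates(enh, sc$nuclei)
    expect_equal(nrow(det$objects), 0L)
})

test_that("round II splits neighbouring condensates merged in round I", {
    # two condensates whose connecting saddle sits above the lenient
    # adaptive threshold but below the stringent Otsu-based one
    sc <- plantedNucleusScene(list(c(95, 89.5, 10), c(95, 110.5, 10)),
                              noise = 3, seed = 4)
    enh <- enhanceSpeckles(sc$image, 40)
    det <- detectCondensates(enh, sc$nuclei, pixelSizeUm = 0.08)
    r1 <- regionProperties(det$round1Labels)
    expect_equal(nrow(r1), 1L)                 # merged by the lenient pass
    expect_equal(nrow(det$objects), 2L)        # split by the stringent pass
    truth <- data.frame(centroid_row = c(95, 95), centroid_col = c(89.5, 110.5))
    expect_equal(matchCentroids(truth, det$objects, maxDist = 3), 2L)
})

test_that("raising the Otsu correction factor never adds round-II objects", {
    sc <- plantedNucleusScene(list(c(70, 70, 10), c(100, 120, 14),
                                   c(130, 80, 18)), seed = 6)
    enh <- enhanceSpeckles(sc$image, 40)
    counts <- vapply(c(0.3, 0.5, 0.8, 1.2, 2), function(f) {
        det <- detectCondensates(enh, sc$nuclei,
                                 detectionParams(otsuCorrectionFactor = f))
        nrow(det$objects)
    }, 0L)
    expect_true(all(diff(counts) <= 0))
})

test_that("degenerate inputs are handled with warnings, not crashes", {
    expect_warning(det <- detectCondensates(matrix(1, 20, 20),
                                            matrix(0L, 20, 20)), "no nuclei")
    expect_equal(nrow(det$objects), 0L)
    expect_error(detectCondensates(matrix(1, 20, 20), matrix(0L, 10, 10)),
                 "identical dimensions")
    # constant image inside nuclei: adaptive pass finds nothing
    nuc <- drawDisk(100, 100, 50, 50, 30)
    det2 <- detectCondensates(matrix(5, 100, 100), nuc)
    expect_equal(nrow(det2$objects), 0L)
})

test_that("measureCondensates aggregates objects into cell summaries", {
    sc <- plantedNucleusScene(list(c(80, 80, 10), c(110, 110, 16)), seed = 8)
    enh <- enhanceSpeckles(sc$image, 40)
    det <- detectCondensates(enh, sc$nuclei, pixelSizeUm = 0.08)
    meas <- measureCondensates(micrograph(sc$image, 0.08), det$labels,
                               sc$nuclei)
    expect_equal(nrow(meas$cells), 1L)
    expect_equal(meas$cells$n_condensates, nrow(meas$objects))
    expect_equal(meas$cells$nucleus_area_px, sum(sc$nuclei > 0))
    expect_gt(meas$cells$mean_condensate_intensity,
              meas$cells$mean_nuclear_intensity)

    # objects outside any nucleus are dropped with a message
    stray <- det$labels
    stray[1:5, 1:5] <- max(stray) + 1L
    expect_message(m2 <- measureCondensates(sc$image, stray, sc$nuclei),
                   "outside any nucleus")
    expect_equal(nrow(m2$objects), nrow(meas$objects))
})

test_that("the large-condensate cell rule and expression gate behave as stated", {
    cells <- data.frame(nucleus_id = 1:4, nucleus_area_px = 100,
                        mean_nuclear_intensity = c(50, 100, 150, 500),
                        n_condensates = c(2, 1, 3, 2),
                        mean_condensate_intensity = 10)
    objects <- data.frame(
        nucleus_id = c(1, 1, 2, 3, 3, 3, 4, 4),
        equiv_diameter_um = c(1.5, 1.4,   # cell 1: two large -> positive
                              2.0,         # cell 2: one large -> negative
                              1.0, 1.0, 1.0,  # cell 3: none large -> negative
                              1.3, 1.26))  # cell 4: two large -> positive
    res <- callLargePositiveCells(cells, objects)
    expect_equal(res$cells$is_large_positive, c(TRUE, FALSE, FALSE, TRUE))
    expect_equal(res$fractionPositive, 0.5)

    gated <- callLargePositiveCells(cells, objects,
        detectionParams(expressionGateRange = c(75, 200)))
    expect_equal(gated$cells$nucleus_id, 2:3)       # cells 1 and 4 gated out
    expect_equal(gated$fractionPositive, 0)
    expect_warning(
        callLargePositiveCells(cells, objects,
            detectionParams(expressionGateRange = c(1e6, 2e6))),
        "excluded every cell")
})

test_that("Pearson colocalization over reference objects", {
    set.seed(10)
    a <- matrix(runif(100 * 100), 100, 100)
    lab <- drawDisk(100, 100, 50, 50, 40)
    expect_equal(pearsonColocalization(a, a, lab), 1)
    expect_equal(pearsonColocalization(a, 3 - a, lab), -1)
    b <- matrix(runif(100 * 100), 100, 100)
    expect_lt(abs(pearsonColocalization(a, b, lab)), 0.05)  # ~3/sqrt(n)
    expect_error(pearsonColocalization(a, matrix(1, 100, 100), lab),
                 "zero variance")
})

test_that("object overlap fractions and Dice", {
    A <- matrix(0L, 20, 20); A[1:10, 1:10] <- 1L
    expect_equal(objectOverlapFraction(A, A)$dice, 1)
    expect_equal(objectOverlapFraction(A, A)$perObject$overlap_fraction, 1)

    B <- matrix(0L, 20, 20); B[1:10, 1:5] <- 1L
    ov <- objectOverlapFraction(A, B)
    expect_equal(ov$perObject$overlap_fraction, 0.5)
    expect_equal(ov$dice, 2 * 50 / 150)

    C <- matrix(0L, 20, 20); C[15:18, 15:18] <- 1L
    ovd <- objectOverlapFraction(A, C)
    expect_equal(ovd$perObject$overlap_fraction, 0)
    expect_equal(ovd$dice, 0)

    expect_warning(z <- objectOverlapFraction(A, matrix(0L, 20, 20)),
                   "empty foreground")
    expect_equal(z$dice, 0)
})
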