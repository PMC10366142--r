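smallSpec <- function(seed = 5L, ...) {
    simImageSpec(widthPx = 200, heightPx = 200, pixelSizeUm = 0.08,
                 nNuclei = 1, nucleusDiameterPxRange = c(100, 120),
                 condensatesPerNucleus = 3,
                 condensateDiameterUmRange = c(0.8, 2.0), seed = seed, ...)
}

test_that("identical spec and seed give byte-identical renderings", {
    a <- simulateMicrograph(smallSpec())
    b <- simulateMicrograph(smallSpec())
    expect_identical(imageValues(a$raw), imageValues(b$raw))
    expect_identical(imageValues(a$empty), imageValues(b$empty))
    expect_identical(a$nucleusLabels, b$nucleusLabels)
    expect_identical(a$truth, b$truth)
    d <- simulateMicrograph(smallSpec(seed = 6L))
    expect_false(identical(imageValues(a$raw), imageValues(d$raw)))
})

test_that("zero nuclei gives offset-plus-noise only and empty truth", {
    spec <- simImageSpec(widthPx = 64, heightPx = 64, nNuclei = 0,
                         cameraOffset = 100, noiseSigma = 5, seed = 2)
    sim <- simulateMicrograph(spec)
    expect_equal(nrow(sim$truth$condensates), 0L)
    expect_equal(nrow(sim$truth$cells), 0L)
    expect_equal(max(sim$nucleusLabels), 0L)
    expect_equal(mean(imageValues(sim$raw)), 100, tolerance = 0.02)
})

test_that("planted condensate counts and ground-truth flags are consistent", {
    spec <- simImageSpec(widthPx = 680, heightPx = 680, pixelSizeUm = 0.08,
                         nNuclei = 10, nucleusDiameterPxRange = c(110, 140),
                         condensatesPerNucleus = 3,
                         condensateDiameterUmRange = c(0.8, 2.0), seed = 9)
    sim <- simulateMicrograph(spec)
    expect_equal(nrow(sim$truth$condensates), 30L)
    expect_equal(max(sim$nucleusLabels), 10L)
    # the large-positive flag is exactly (count of diameters > 1.25 um) >= 2
    for (k in sim$truth$cells$nucleus_id) {
        d <- sim$truth$condensates$diameter_um[
            sim$truth$condensates$nucleus_id == k]
        expect_equal(sim$truth$cells$n_large_true[k], sum(d > 1.25))
        expect_equal(sim$truth$cells$large_positive_true[k], sum(d > 1.25) >= 2)
    }
    # nuclei do not touch borders or each other by construction
    lab <- sim$nucleusLabels
    expect_true(all(lab[c(1, nrow(lab)), ] == 0) && all(lab[, c(1, ncol(lab))] == 0))
})

test_that("rendered condensates have the requested FWHM and SNR", {
    # noiseless rendering: area above half-max recovers the FWHM diameter;
    # one condensate per nucleus so half-max footprints cannot interleave
    spec <- simImageSpec(widthPx = 360, heightPx = 360, pixelSizeUm = 0.08,
                         nNuclei = 4, nucleusDiameterPxRange = c(110, 130),
                         condensatesPerNucleus = 1,
                         condensateDiameterUmRange = c(0.35, 2.0),
                         noiseSigma = 0, vignetteStrength = 0, seed = 31)
    sim <- simulateMicrograph(spec)
    scene <- imageValues(sim$raw) - spec@cameraOffset -
        spec@nuclearBackgroundIntensity * (sim$nucleusLabels > 0)
    expect_gte(nrow(sim$truth$condensates), 3)
    for (i in seq_len(nrow(sim$truth$condensates))) {
        tr <- sim$truth$condensates[i, ]
        if (tr$diameter_px < 4) next
        win <- ceiling(tr$diameter_px / 2) + 3
        rs <- (round(tr$centroid_row) - win):(round(tr$centroid_row) + win)
        cs <- (round(tr$centroid_col) - win):(round(tr$centroid_col) + win)
        patch <- scene[rs, cs]
        area <- sum(patch > tr$peak_intensity / 2)
        expect_equal(2 * sqrt(area / pi), tr$diameter_px,
                     tolerance = 1 / tr$diameter_px)
    }

    # noisy rendering: measured peak / background SD reproduces requested SNR
    specN <- simImageSpec(widthPx = 400, heightPx = 400, pixelSizeUm = 0.08,
                          nNuclei = 4, nucleusDiameterPxRange = c(110, 130),
                          condensatesPerNucleus = 3,
                          condensateDiameterUmRange = c(1.0, 2.0),
                          condensatePeakIntensity = 200, noiseSigma = 20,
                          vignetteStrength = 0, seed = 17)
    simN <- simulateMicrograph(specN)
    raw <- imageValues(simN$raw)
    sdBg <- sd(raw[simN$nucleusLabels == 0])          # off-nucleus: offset+noise
    # average a 3x3 patch at the centroid: a max over the patch would carry
    # the upward bias of the noise-maximum order statistic
    peaks <- vapply(seq_len(nrow(simN$truth$condensates)), function(i) {
        tr <- simN$truth$condensates[i, ]
        rs <- (round(tr$centroid_row) - 1):(round(tr$centroid_row) + 1)
        cs <- (round(tr$centroid_col) - 1):(round(tr$centroid_col) + 1)
        mean(raw[rs, cs]) - specN@cameraOffset - specN@nuclearBackgroundIntensity
    }, 0)
    snr <- mean(peaks) / sdBg
    expect_equal(snr, specN@condensatePeakIntensity / specN@noiseSigma,
                 tolerance = 0.1)
})

test_that("domain-size simulation regimes behave as stated", {
    lin <- simulateDomainSizes(100, "linear", baseSize = 10)
    expect_equal(lin$crossingIndex, 1L)
    expect_equal(lin$sizes, 10 * (1:100))

    pw <- simulateDomainSizes(250, "piecewise")
    expect_true(all(pw$sizes > 0))
    expect_equal(length(pw$sizes), 250L)
    expect_equal(pw$crossingIndex, bruteCrossing(pw$sizes)$index)

    ln1 <- simulateDomainSizes(100, "lognormal", seed = 3)
    ln2 <- simulateDomainSizes(100, "lognormal", seed = 3)
    expect_identical(ln1$sizes, ln2$sizes)
    expect_true(all(ln1$sizes >= 1))

    expect_error(simulateDomainSizes(11), "at least 12")
})

test_that("gene-set simulation plants the exact overlap", {
    gs <- simulateGeneSets(100, 20, 30, 5, seed = 2)
    expect_length(gs$setA, 20)
    expect_length(gs$setB, 30)
    expect_length(intersect(gs$setA, gs$setB), 5)
    expect_true(all(c(gs$setA, gs$setB) %in% gs$universe))

    all10 <- simulateGeneSets(10, 10, 10, 10, seed = 1)
    expect_setequal(all10$setA, all10$universe)
    expect_setequal(all10$setB, all10$universe)

    disj <- simulateGeneSets(100, 10, 10, 0, seed = 4)
    expect_length(intersect(disj$setA, disj$setB), 0)

    expect_error(simulateGeneSets(10, 8, 8, 2), "universe too small")
    expect_error(simulateGeneSets(100, 5, 10, 7), "exceeds a set size")

    same <- simulateGeneSets(100, 20, 30, 5, seed = 2)
    expect_identical(same, gs)
})
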