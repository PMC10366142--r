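# Ground-truthed synthetic data for every downstream stage: micrographs with
# known condensates and illumination field, heavy-tailed domain-size lists
# with a computable rank-slope crossing, and gene universes with planted
# overlaps.

# Run expr under a fully pinned RNG state and restore the caller's state.
withLocalSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
             sample.kind = "Rejection")
    expr
}

vignetteField <- function(nr, nc, strength) {
    cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
    r2 <- outer((seq_len(nr) - cr)^2, (seq_len(nc) - cc)^2, "+")
    1 - strength * r2 / max(r2)
}

fillEllipse <- function(labels, value, cr, cc, a, b, theta) {
    nr <- nrow(labels); nc <- ncol(labels)
    ext <- ceiling(max(a, b)) + 1L
    rows <- max(1L, floor(cr - ext)):min(nr, ceiling(cr + ext))
    cols <- max(1L, floor(cc - ext)):min(nc, ceiling(cc + ext))
    dr <- rows - cr
    dc <- cols - cc
    u <- outer(dr * cos(theta), dc * sin(theta), "+")
    v <- outer(-dr * sin(theta), dc * cos(theta), "+")
    inside <- (u / a)^2 + (v / b)^2 <= 1
    sub <- labels[rows, cols, drop = FALSE]
    sub[inside] <- value
    labels[rows, cols] <- sub
    labels
}

addGaussianSpot <- function(scene, cr, cc, fwhmPx, amplitude) {
    sg <- fwhmPx / (2 * sqrt(2 * log(2)))
    ext <- ceiling(4 * sg)
    nr <- nrow(scene); nc <- ncol(scene)
    rows <- max(1L, floor(cr - ext)):min(nr, ceiling(cr + ext))
    cols <- max(1L, floor(cc - ext)):min(nc, ceiling(cc + ext))
    g <- amplitude * exp(-(outer((rows - cr)^2, (cols - cc)^2, "+")) / (2 * sg^2))
    scene[rows, cols] <- scene[rows, cols] + g
    scene
}

#' Simulate a condensate micrograph with ground truth
#'
#' Renders the full acquisition described by a \linkS4class{SimImageSpec}:
#' non-overlapping elliptical nuclei (axis ratio drawn from [1, 1.3]) with a
#' uniform nuclear background, isotropic 2-D Gaussian condensates whose FWHM
#' equals the nominal diameter, a radial-vignette illumination field with
#' maximum 1, a camera offset and additive Gaussian read noise (optionally
#' Poisson shot noise). The three rendered images follow
#' \deqn{raw = offset + field \cdot scene + noise}
#' \deqn{empty = offset + noise}
#' \deqn{emptyFluorophore = offset + field \cdot level + noise}
#' where the uniform fluorophore level is background + peak intensity.
#' Identical spec (including seed) gives byte-identical outputs.
#'
#' @param spec a \linkS4class{SimImageSpec}.
#' @return a list with elements \code{raw}, \code{empty},
#'   \code{emptyFluorophore} (\linkS4class{Micrograph}s), \code{nucleusLabels}
#'   (integer label matrix), \code{field} (the planted illumination matrix),
#'   and \code{truth}: a list of two data.frames, \code{condensates} (one row
#'   per planted condensate: nucleus, centroid, FWHM diameter, peak) and
#'   \code{cells} (one row per nucleus, including \code{n_large_true}, the
#'   number of condensates with diameter > 1.25 um, and
#'   \code{large_positive_true}, TRUE when that count is >= 2).
#' @examples
#' sim <- simulateMicrograph(simImageSpec(widthPx = 128, heightPx = 128,
#'     nNuclei = 1, nucleusDiameterPxRange = c(60, 70), seed = 3))
#' nrow(sim$truth$condensates)
#' @export
simulateMicrograph <- function(spec) {
    stopifnot(is(spec, "SimImageSpec"))
    validObject(spec)
    withLocalSeed(spec@seed, {
        nr <- spec@heightPx; nc <- spec@widthPx
        fld <- vignetteField(nr, nc, spec@vignetteStrength)
        labels <- matrix(0L, nr, nc)
        cells <- list(); conds <- list()
        scene <- matrix(0, nr, nc)

        margin <- 3
        placed <- list()
        for (k in seq_len(spec@nNuclei)) {
            dMaj <- runif(1, spec@nucleusDiameterPxRange[1],
                          spec@nucleusDiameterPxRange[2])
            ratio <- runif(1, 1, 1.3)
            a <- dMaj / 2; b <- a / ratio
            theta <- runif(1, 0, pi)
            ok <- FALSE
            for (try in seq_len(300L)) {
                if (spec@allowBorderNuclei) {
                    cr <- runif(1, 1, nr); cc <- runif(1, 1, nc)
                } else {
                    if (2 * (a + margin) >= min(nr, nc))
                        stop("nucleus too large for the image")
                    cr <- runif(1, a + margin, nr - a - margin)
                    cc <- runif(1, a + margin, nc - a - margin)
                }
                clash <- FALSE
                for (p in placed)
                    if (sqrt((cr - p[1])^2 + (cc - p[2])^2) < a + p[3] + margin) {
                        clash <- TRUE; break
                    }
                if (!clash) { ok <- TRUE; break }
            }
            if (!ok)
                stop("could not place ", spec@nNuclei,
                     " non-overlapping nuclei after bounded retries")
            placed[[k]] <- c(cr, cc, a)
            labels <- fillEllipse(labels, k, cr, cc, a, b, theta)

            nCond <- if (spec@condensateCountModel == "fixed")
                as.integer(round(spec@condensatesPerNucleus))
            else rpois(1, spec@condensatesPerNucleus)
            phen <- if (!spec@phenotypeMix) "uniform"
                else if (runif(1) < spec@largeCellFraction) "large" else "small"
            dRange <- switch(phen,
                uniform = spec@condensateDiameterUmRange,
                small = spec@smallDiameterUmRange,
                large = spec@largeDiameterUmRange)
            placedCond <- list()
            for (j in seq_len(nCond)) {
                dUm <- runif(1, dRange[1], dRange[2])
                dPx <- dUm / spec@pixelSizeUm
                m <- dPx / 2 + 2
                aa <- max(a - m, 1); bb <- max(b - m, 1)
                posOk <- FALSE
                for (try in seq_len(100L)) {
                    ang <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1))
                    u <- aa * rad * cos(ang); v <- bb * rad * sin(ang)
                    pr <- cr + u * cos(theta) - v * sin(theta)
                    pc <- cc + u * sin(theta) + v * cos(theta)
                    # keep planted condensates individually resolvable:
                    # at least a diameter-sum of centre separation
                    sepOk <- TRUE
                    for (q in placedCond)
                        if (sqrt((pr - q$row)^2 + (pc - q$col)^2) <
                            (dPx + q$dPx) + 4) { sepOk <- FALSE; break }
                    if (sepOk) { posOk <- TRUE; break }
                }
                if (!posOk) next   # nucleus saturated; plant what fits
                placedCond[[length(placedCond) + 1L]] <-
                    list(row = pr, col = pc, dPx = dPx, dUm = dUm)
                scene <- addGaussianSpot(scene, pr, pc, dPx,
                                         spec@condensatePeakIntensity)
            }
            nLargeTrue <- sum(vapply(placedCond, function(q) q$dUm, 0) > 1.25)
            cells[[k]] <- data.frame(
                nucleus_id = k, centroid_row = cr, centroid_col = cc,
                phenotype = phen, n_condensates = length(placedCond),
                n_large_true = nLargeTrue,
                large_positive_true = nLargeTrue >= 2)
            if (length(placedCond))
                conds[[length(conds) + 1L]] <- data.frame(
                    nucleus_id = k,
                    centroid_row = vapply(placedCond, function(q) q$row, 0),
                    centroid_col = vapply(placedCond, function(q) q$col, 0),
                    diameter_um = vapply(placedCond, function(q) q$dUm, 0),
                    diameter_px = vapply(placedCond, function(q) q$dPx, 0),
                    peak_intensity = spec@condensatePeakIntensity)
        }
        scene <- scene + spec@nuclearBackgroundIntensity * (labels > 0L)

        noise <- function() if (spec@noiseSigma > 0)
            matrix(rnorm(nr * nc, 0, spec@noiseSigma), nr, nc)
        else matrix(0, nr, nc)
        offset <- matrix(spec@cameraOffset, nr, nc)
        illuminated <- fld * scene
        if (spec@shotNoise)
            illuminated <- matrix(rpois(nr * nc, illuminated), nr, nc)
        raw <- pmax(offset + illuminated + noise(), 0)
        empty <- pmax(offset + noise(), 0)
        level <- spec@nuclearBackgroundIntensity + spec@condensatePeakIntensity
        emptyFluor <- pmax(offset + fld * level + noise(), 0)

        emptyDf <- function(x) x[0, , drop = FALSE]
        condDf <- if (length(conds)) do.call(rbind, conds) else
            data.frame(nucleus_id = integer(0), centroid_row = numeric(0),
                       centroid_col = numeric(0), diameter_um = numeric(0),
                       diameter_px = numeric(0), peak_intensity = numeric(0))
        cellDf <- if (length(cells)) do.call(rbind, cells) else
            data.frame(nucleus_id = integer(0), centroid_row = numeric(0),
                       centroid_col = numeric(0), phenotype = character(0),
                       n_condensates = integer(0), n_large_true = integer(0),
                       large_positive_true = logical(0))
        rownames(condDf) <- rownames(cellDf) <- NULL
        list(raw = micrograph(raw, spec@pixelSizeUm),
             empty = micrograph(empty, spec@pixelSizeUm),
             emptyFluorophore = micrograph(emptyFluor, spec@pixelSizeUm),
             nucleusLabels = labels,
             field = fld,
             truth = list(condensates = condDf, cells = cellDf))
    })
}

#' Simulate a domain-size list with a known rank-slope crossing
#'
#' Generates \code{n} positive integer domain sizes (bp) under one of three
#' regimes. \code{"linear"} produces sizes proportional to rank, so every
#' normalized tangent slope is exactly 1 and the crossing sits at the first
#' window. \code{"piecewise"} produces a flat body of \code{bodyFraction * n}
#' sizes growing by \code{bodyIncrement} bp per rank followed by a steep tail
#' growing by \code{tailIncrement} bp per rank; for this regime the index at
#' which the mean of \code{window} consecutive normalized slopes first
#' reaches 1 has a closed form, returned as \code{crossingIndex}.
#' \code{"lognormal"} draws heavy-tailed sizes with no analytic crossing
#' (\code{crossingIndex} is NA).
#'
#' @param n number of domains, at least 12.
#' @param regime "piecewise", "linear" or "lognormal".
#' @param baseSize smallest body size (bp).
#' @param bodyIncrement,tailIncrement per-rank size increments (bp) of body
#'   and tail in the piecewise regime.
#' @param bodyFraction fraction of sizes in the body.
#' @param meanlog,sdlog lognormal parameters.
#' @param window sliding-window length used for the analytic crossing.
#' @param seed integer seed (used by the lognormal regime).
#' @return a list with \code{sizes} (length n), \code{crossingIndex},
#'   \code{regime} and \code{params}.
#' @examples
#' d <- simulateDomainSizes(100, "piecewise")
#' d$crossingIndex
#' @export
simulateDomainSizes <- function(n, regime = c("piecewise", "linear", "lognormal"),
                                baseSize = 5000, bodyIncrement = 20,
                                tailIncrement = 5000, bodyFraction = 0.8,
                                meanlog = 9, sdlog = 1, window = 10,
                                seed = 1L) {
    regime <- match.arg(regime)
    if (n < 12) stop("'n' must be at least 12 so that >= 10 slopes exist")
    params <- list(baseSize = baseSize, bodyIncrement = bodyIncrement,
                   tailIncrement = tailIncrement, bodyFraction = bodyFraction,
                   meanlog = meanlog, sdlog = sdlog, window = window)
    if (regime == "linear") {
        sizes <- baseSize * seq_len(n)
        crossing <- 1L
    } else if (regime == "piecewise") {
        m <- max(2L, min(n - 2L, round(bodyFraction * n)))
        sizes <- numeric(n)
        sizes[seq_len(m)] <- baseSize + bodyIncrement * seq_len(m)
        if (m < n)
            sizes[(m + 1L):n] <- sizes[m] + tailIncrement * seq_len(n - m)
        denom <- sizes[n] - sizes[1]
        tb <- bodyIncrement * (n - 1) / denom
        tt <- tailIncrement * (n - 1) / denom
        W <- as.integer(window)
        nTail <- n - m            # number of tail slopes (indices m .. n-1)
        crossing <- if (tb >= 1 - 1e-12) 1L else if (tt <= tb) NA_integer_
        else {
            k <- ceiling(W * (1 - tb) / (tt - tb) - 1e-9)
            if (k > min(W, nTail)) NA_integer_ else max(1L, m - W + as.integer(k))
        }
    } else {
        sizes <- withLocalSeed(seed, pmax(round(rlnorm(n, meanlog, sdlog)), 1))
        crossing <- NA_integer_
    }
    list(sizes = as.numeric(round(sizes)), crossingIndex = crossing,
         regime = regime, params = params)
}

#' Simulate gene sets with a planted overlap
#'
#' Draws two gene sets of sizes \code{nA} and \code{nB} from a synthetic
#' universe of \code{universeSize} identifiers such that their intersection
#' has exactly \code{plantedOverlap} members.
#'
#' @param universeSize number of genes in the universe.
#' @param nA,nB set sizes.
#' @param plantedOverlap exact intersection size.
#' @param seed integer seed.
#' @return a list with character vectors \code{universe}, \code{setA},
#'   \code{setB}.
#' @examples
#' gs <- simulateGeneSets(100, 20, 30, 5, seed = 2)
#' length(intersect(gs$setA, gs$setB))   # 5
#' @export
simulateGeneSets <- function(universeSize, nA, nB, plantedOverlap, seed = 1L) {
    N <- as.integer(universeSize)
    k <- as.integer(plantedOverlap)
    if (k > min(nA, nB)) stop("planted overlap exceeds a set size")
    if (nA > N || nB > N) stop("set sizes exceed the universe")
    if (nA + nB - k > N)
        stop("universe too small for the requested overlap structure")
    universe <- sprintf("G%06d", seq_len(N))
    withLocalSeed(seed, {
        shared <- sample(universe, k)
        restA <- sample(setdiff(universe, shared), nA - k)
        restB <- sample(setdiff(universe, c(shared, restA)), nB - k)
        list(universe = universe, setA = c(shared, restA),
             setB = c(shared, restB))
    })
}
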