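asImageMatrix <- function(image) {
    if (is(image, "Micrograph")) imageValues(image) else as.matrix(image)
}

#' Filter a nucleus label map by size and border contact
#'
#' Keeps nuclei whose equivalent diameter (2 * sqrt(area / pi)) lies within
#' the configured range (default 80--300 px) and, when
#' \code{removeBorderNuclei} is set, whose pixels do not touch any image
#' border. Survivors are relabelled compactly 1..k in ascending original
#' label order.
#'
#' @param labels integer nucleus label matrix (0 = background).
#' @param params a \linkS4class{DetectionParams}.
#' @return a filtered, compactly relabelled integer matrix.
#' @examples
#' lab <- matrix(0L, 50, 50); lab[20:30, 20:30] <- 1L  # ~12 px equiv diam
#' max(filterNuclei(lab, detectionParams(nucleusDiameterPxRange = c(5, 40))))
#' @export
filterNuclei <- function(labels, params = detectionParams()) {
    stopifnot(is.matrix(labels))
    storage.mode(labels) <- "integer"
    if (!any(labels > 0L)) {
        warning("empty nucleus label map")
        return(labels)
    }
    props <- regionProperties(labels)
    keep <- props$label[props$equiv_diameter_px >=
                            params@nucleusDiameterPxRange[1] &
                        props$equiv_diameter_px <=
                            params@nucleusDiameterPxRange[2]]
    if (params@removeBorderNuclei) {
        border <- unique(c(labels[1, ], labels[nrow(labels), ],
                           labels[, 1], labels[, ncol(labels)]))
        keep <- setdiff(keep, border)
    }
    out <- matrix(0L, nrow(labels), ncol(labels))
    if (length(keep)) {
        keep <- sort(keep)
        sel <- labels %in% keep
        out[sel] <- match(labels[sel], keep)
    }
    out
}

#' Enhance speckle-like features
#'
#' White top-hat transform: the image minus its morphological opening with a
#' disk of the given feature diameter. Features narrower than the disk
#' (condensates) are preserved while the smooth background and any
#' large-scale gradient are removed; the output is nonnegative.
#'
#' @param image \linkS4class{Micrograph} or numeric matrix.
#' @param featureDiameterPx structuring-element diameter in pixels (>= 1).
#' @return object of the same kind as \code{image} with enhanced values.
#' @examples
#' m <- matrix(10, 40, 40); m[20, 20] <- 50
#' max(enhanceSpeckles(m, 15))   # ~40: background removed, peak kept
#' @export
enhanceSpeckles <- function(image, featureDiameterPx = 40) {
    if (featureDiameterPx < 1) stop("'featureDiameterPx' must be >= 1")
    v <- asImageMatrix(image)
    out <- pmax(v - diskOpen(v, floor(featureDiameterPx / 2)), 0)
    if (is(image, "Micrograph"))
        micrograph(out, pixelSize(image), image@metadata)
    else out
}

#' Global Otsu threshold
#'
#' The threshold maximizing the between-class variance over a 256-bin
#' histogram of the sample range (min-max scaled). The returned value is on
#' the intensity scale of the input (a bin edge).
#'
#' @param values numeric vector of intensities with at least 2 distinct
#'   values.
#' @return a single threshold.
#' @examples
#' otsuThreshold(c(rep(10, 100), rep(200, 100)))
#' @export
otsuThreshold <- function(values) {
    values <- values[is.finite(values)]
    lo <- min(values); hi <- max(values)
    if (length(values) < 2L || hi <= lo)
        stop("degenerate Otsu threshold: need at least 2 distinct values")
    nb <- 256L
    h <- tabulate(pmin(pmax(floor((values - lo) / (hi - lo) * nb) + 1L, 1L),
                       nb), nbins = nb)
    p <- h / sum(h)
    centers <- lo + ((seq_len(nb) - 0.5) / nb) * (hi - lo)
    w1 <- cumsum(p)[-nb]
    w2 <- 1 - w1
    cs <- cumsum(p * centers)
    mu <- cs[nb]
    m1 <- cs[-nb] / w1
    m2 <- (mu - cs[-nb]) / w2
    bcv <- w1 * w2 * (m1 - m2)^2
    bcv[!is.finite(bcv)] <- -Inf
    t <- which.max(bcv)
    lo + (t / nb) * (hi - lo)
}

#' Robust Background threshold
#'
#' Discards the lowest \code{trimLow} and highest \code{trimHigh} fractions
#' of the sorted sample and returns mean + \code{nSD} * SD of the retained
#' values (SD with the usual n - 1 denominator; 0 for a single retained
#' value). This is the trimmed-background thresholding rule used for the
#' lenient first identification round.
#'
#' @param values nonempty numeric vector.
#' @param trimLow,trimHigh fractions trimmed from each end.
#' @param nSD standard-deviation multiplier.
#' @return a single threshold.
#' @examples
#' robustBackgroundThreshold(0:99)   # mean + 2 SD of 5..94
#' @export
robustBackgroundThreshold <- function(values, trimLow = 0.05,
                                      trimHigh = 0.05, nSD = 2.0) {
    values <- values[is.finite(values)]
    n <- length(values)
    if (n == 0L) stop("empty intensity sample")
    s <- sort(values)
    from <- floor(n * trimLow) + 1L
    to <- n - floor(n * trimHigh)
    if (from > to) stop("all values trimmed: reduce trim fractions")
    kept <- s[from:to]
    m <- mean(kept)
    sdv <- if (length(kept) > 1L) sd(kept) else 0
    m + nSD * sdv
}

# Adaptive threshold surface: Robust Background per tile of the nuclear
# region on a windowPx grid, bilinearly interpolated between tile centers.
adaptiveThresholdSurface <- function(values, nucMask, windowPx, trimLow,
                                     trimHigh, nSD, minTilePixels = 20L) {
    nr <- nrow(values); nc <- ncol(values)
    w <- max(1L, as.integer(round(windowPx)))
    rStarts <- seq(1L, nr, by = w)
    cStarts <- seq(1L, nc, by = w)
    G <- matrix(NA_real_, length(rStarts), length(cStarts))
    for (i in seq_along(rStarts)) {
        rs <- rStarts[i]:min(rStarts[i] + w - 1L, nr)
        for (j in seq_along(cStarts)) {
            cs <- cStarts[j]:min(cStarts[j] + w - 1L, nc)
            inNuc <- nucMask[rs, cs]
            if (sum(inNuc) >= minTilePixels)
                G[i, j] <- robustBackgroundThreshold(
                    values[rs, cs][inNuc], trimLow, trimHigh, nSD)
        }
    }
    if (all(is.na(G)))
        G[] <- robustBackgroundThreshold(values[nucMask], trimLow, trimHigh, nSD)
    # fill empty tiles from the global nuclear sample so interpolation is total
    if (anyNA(G))
        G[is.na(G)] <- robustBackgroundThreshold(values[nucMask], trimLow,
                                                 trimHigh, nSD)
    rowCenters <- pmin(rStarts + (w - 1) / 2, nr)
    colCenters <- pmin(cStarts + (w - 1) / 2, nc)
    interpolateTileGrid(G, rowCenters, colCenters, nr, nc)
}

sizeGate <- function(labels, diamRangePx) {
    if (!any(labels > 0L)) return(labels)
    props <- regionProperties(labels)
    keep <- props$label[props$equiv_diameter_px >= diamRangePx[1] &
                        props$equiv_diameter_px <= diamRangePx[2]]
    out <- matrix(0L, nrow(labels), ncol(labels))
    if (length(keep)) {
        sel <- labels %in% keep
        out[sel] <- match(labels[sel], sort(keep))
    }
    out
}

#' Two-round condensate identification
#'
#' Identifies condensates inside segmented nuclei in two rounds. Round I
#' (lenient): the nuclear region is tiled into
#' \code{round1AdaptiveWindowPx}-sized windows, a Robust Background
#' threshold is computed per tile and bilinearly interpolated into a
#' threshold surface; connected components (8-connectivity) of
#' above-surface nuclear pixels with equivalent diameter in
#' \code{round1DiameterPxRange} become the round-I footprint. Round II
#' (stringent): within that footprint, pixels above the global Otsu
#' threshold of the nuclear intensities multiplied by
#' \code{otsuCorrectionFactor} are relabelled; components with equivalent
#' diameter in \code{round2DiameterPxRange} are the final objects. The
#' stringent round recovers large-condensate shapes and splits neighbouring
#' condensates merged by the lenient round. Each object is assigned to the
#' nucleus containing its centroid.
#'
#' The image should normally be the speckle-enhanced, flat-field-corrected
#' channel (see \code{\link{enhanceSpeckles}}).
#'
#' @param image \linkS4class{Micrograph} or numeric matrix.
#' @param nuclei integer nucleus label matrix of the same dimensions.
#' @param params a \linkS4class{DetectionParams}.
#' @param pixelSizeUm micrometres per pixel; defaults to the image's own
#'   pixel size when a \linkS4class{Micrograph} is supplied.
#' @return a list with \code{labels} (final object label matrix),
#'   \code{objects} (data.frame of per-object measurements including
#'   \code{nucleus_id}), and \code{round1Labels} (diagnostic).
#' @seealso \code{\link{measureCondensates}},
#'   \code{\link{callLargePositiveCells}}
#' @export
detectCondensates <- function(image, nuclei, params = detectionParams(),
                              pixelSizeUm = NULL) {
    v <- asImageMatrix(image)
    if (is.null(pixelSizeUm))
        pixelSizeUm <- if (is(image, "Micrograph")) pixelSize(image) else NA_real_
    stopifnot(is.matrix(nuclei))
    if (!identical(dim(v), dim(nuclei)))
        stop("image and nucleus label map must have identical dimensions")
    storage.mode(nuclei) <- "integer"
    emptyResult <- function() {
        obj <- regionProperties(matrix(0L, 1, 1), v[1, 1, drop = FALSE],
                                pixelSizeUm)
        obj$nucleus_id <- integer(0)
        list(labels = matrix(0L, nrow(v), ncol(v)), objects = obj,
             round1Labels = matrix(0L, nrow(v), ncol(v)))
    }
    nucMask <- nuclei > 0L
    if (!any(nucMask)) {
        warning("no nuclei in label map; returning empty result")
        return(emptyResult())
    }

    ## Round I: adaptive Robust Background
    surf <- adaptiveThresholdSurface(v, nucMask, params@round1AdaptiveWindowPx,
                                     params@robustTrimLow, params@robustTrimHigh,
                                     params@robustNSD)
    bin1 <- nucMask & (v > surf)
    lab1 <- sizeGate(labelConnected(bin1, 8), params@round1DiameterPxRange)
    footprint <- lab1 > 0L
    if (!any(footprint)) {
        res <- emptyResult()
        res$round1Labels <- lab1
        return(res)
    }

    ## Round II: global Otsu x correction factor, within the round-I footprint
    nucVals <- v[nucMask]
    t2 <- tryCatch(otsuThreshold(nucVals) * params@otsuCorrectionFactor,
                   error = function(e) NA_real_)
    if (is.na(t2)) {
        warning("degenerate Otsu threshold; returning empty result")
        res <- emptyResult()
        res$round1Labels <- lab1
        return(res)
    }
    bin2 <- footprint & (v > t2)
    lab2 <- sizeGate(labelConnected(bin2, 8), params@round2DiameterPxRange)

    objects <- regionProperties(lab2, v, pixelSizeUm)
    objects$nucleus_id <- assignNucleus(objects, nuclei)
    outside <- is.na(objects$nucleus_id) | objects$nucleus_id == 0L
    if (any(outside)) {
        message(sum(outside), " object(s) outside any nucleus dropped")
        drop <- objects$label[outside]
        lab2[lab2 %in% drop] <- 0L
        lab2 <- relabelCompact(lab2)
        objects <- objects[!outside, , drop = FALSE]
        objects$label <- seq_len(nrow(objects))
        rownames(objects) <- NULL
    }
    list(labels = lab2, objects = objects, round1Labels = lab1)
}

assignNucleus <- function(objects, nuclei) {
    if (nrow(objects) == 0L) return(integer(0))
    r <- pmin(pmax(round(objects$centroid_row), 1L), nrow(nuclei))
    c <- pmin(pmax(round(objects$centroid_col), 1L), ncol(nuclei))
    nuclei[cbind(r, c)]
}

relabelCompact <- function(labels) {
    labs <- sort(unique(labels[labels > 0L]))
    if (!length(labs)) return(labels)
    out <- matrix(0L, nrow(labels), ncol(labels))
    sel <- labels > 0L
    out[sel] <- match(labels[sel], labs)
    out
}

#' Measure condensates and summarize per cell
#'
#' Computes per-object area, equivalent diameter (um), eccentricity of the
#' equal-second-moment ellipse, centroid, and mean/integrated intensity in
#' each supplied channel; objects are assigned to the nucleus containing
#' their centroid and objects outside any nucleus are dropped with a
#' message. Per-nucleus summaries aggregate nucleus area, mean nuclear
#' intensity (first channel), condensate count and mean condensate
#' intensity.
#'
#' @param images a \linkS4class{Micrograph}, numeric matrix, or named list
#'   of them (channels measured jointly on the same objects).
#' @param labels integer condensate label matrix.
#' @param nuclei integer nucleus label matrix.
#' @param pixelSizeUm micrometres per pixel (defaults to the first
#'   Micrograph's).
#' @return a list with data.frames \code{objects} and \code{cells}.
#' @export
measureCondensates <- function(images, labels, nuclei, pixelSizeUm = NULL) {
    if (!is.list(images)) images <- list(ch1 = images)
    if (is.null(names(images))) names(images) <- paste0("ch", seq_along(images))
    if (is.null(pixelSizeUm)) {
        mg <- Filter(function(x) is(x, "Micrograph"), images)
        pixelSizeUm <- if (length(mg)) pixelSize(mg[[1]]) else NA_real_
    }
    mats <- lapply(images, asImageMatrix)
    stopifnot(identical(dim(mats[[1]]), dim(labels)),
              identical(dim(mats[[1]]), dim(nuclei)))
    storage.mode(labels) <- "integer"
    storage.mode(nuclei) <- "integer"

    objects <- regionProperties(labels, mats, pixelSizeUm)
    objects$nucleus_id <- assignNucleus(objects, nuclei)
    outside <- is.na(objects$nucleus_id) | objects$nucleus_id == 0L
    if (any(outside)) {
        message(sum(outside), " object(s) outside any nucleus dropped")
        objects <- objects[!outside, , drop = FALSE]
        rownames(objects) <- NULL
    }

    nucProps <- regionProperties(nuclei, mats[1], pixelSizeUm)
    meanCol <- paste0("mean_intensity_", names(mats)[1])
    nCond <- table(factor(objects$nucleus_id, levels = nucProps$label))
    meanCondInt <- tapply(objects[[meanCol]],
                          factor(objects$nucleus_id, levels = nucProps$label),
                          mean)
    cells <- data.frame(
        nucleus_id = nucProps$label,
        nucleus_area_px = nucProps$area,
        mean_nuclear_intensity = nucProps[[meanCol]],
        n_condensates = as.integer(nCond),
        mean_condensate_intensity = as.numeric(meanCondInt))
    rownames(cells) <- NULL
    list(objects = objects, cells = cells)
}

#' Classify large-condensate-positive cells
#'
#' Applies the large-condensate rule: a cell is positive when at least
#' \code{largeCondensateMinCount} of its condensates have equivalent
#' diameter greater than \code{largeCondensateMinDiameterUm} (defaults: at
#' least 2 condensates larger than 1.25 um). When an expression gate is
#' configured, cells whose mean nuclear intensity falls outside the gate are
#' excluded from the returned summaries (and hence from the denominator of
#' the positive fraction), emulating stringent expression-level cutoffs on
#' the tag fluorescence.
#'
#' @param cells data.frame from \code{\link{measureCondensates}}.
#' @param objects data.frame of condensates with \code{nucleus_id} and
#'   \code{equiv_diameter_um}.
#' @param params a \linkS4class{DetectionParams}.
#' @return a list with \code{cells} (gated, with \code{n_large_condensates}
#'   and \code{is_large_positive}) and \code{fractionPositive}.
#' @export
callLargePositiveCells <- function(cells, objects, params = detectionParams()) {
    if (any(is.na(objects$equiv_diameter_um)) && nrow(objects))
        stop("pixel size unknown: object diameters are not in micrometres")
    isLarge <- objects$equiv_diameter_um > params@largeCondensateMinDiameterUm
    nLargeTab <- table(factor(objects$nucleus_id[isLarge],
                              levels = cells$nucleus_id))
    cells$n_large_condensates <- as.integer(nLargeTab)
    cells$is_large_positive <-
        cells$n_large_condensates >= params@largeCondensateMinCount
    gate <- params@expressionGateRange
    gated <- cells[cells$mean_nuclear_intensity >= gate[1] &
                   cells$mean_nuclear_intensity <= gate[2], , drop = FALSE]
    if (nrow(gated) == 0L && nrow(cells) > 0L)
        warning("expression gate excluded every cell")
    frac <- if (nrow(gated)) mean(gated$is_large_positive) else NA_real_
    rownames(gated) <- NULL
    list(cells = gated, fractionPositive = frac)
}

#' Pearson colocalization over reference objects
#'
#' Pearson correlation of two channels' intensities over the union of
#' reference-object pixels: one channel's objects serve as ground truth and
#' the other channel's intensities within them are compared to it.
#'
#' @param channelA,channelB \linkS4class{Micrograph}s or matrices of
#'   identical dimensions.
#' @param referenceObjects integer label matrix; pixels with label > 0 form
#'   the mask.
#' @return Pearson r in [-1, 1].
#' @examples
#' a <- matrix(runif(100), 10, 10); lab <- matrix(1L, 10, 10)
#' pearsonColocalization(a, a, lab)   # 1
#' @export
pearsonColocalization <- function(channelA, channelB, referenceObjects) {
    a <- asImageMatrix(channelA); b <- asImageMatrix(channelB)
    stopifnot(identical(dim(a), dim(b)),
              identical(dim(a), dim(referenceObjects)))
    mask <- referenceObjects > 0L
    if (sum(mask) < 2L)
        stop("reference mask must contain at least 2 pixels")
    x <- a[mask]; y <- b[mask]
    if (var(x) == 0 || var(y) == 0)
        stop("undefined correlation: zero variance in a channel over the mask")
    cor(x, y)
}

#' Object overlap fractions and Dice coefficient
#'
#' For each object of \code{labelsA}, the fraction of its pixels covered by
#' any object of \code{labelsB}, plus the global Dice coefficient
#' 2|A n B| / (|A| + |B|) of the two foregrounds.
#'
#' @param labelsA,labelsB integer label matrices of identical dimensions.
#' @return a list with \code{perObject} (data.frame label/area/
#'   overlap_fraction for A-objects), and \code{dice}.
#' @examples
#' A <- matrix(0L, 10, 10); A[1:10, 1:10] <- 1L
#' B <- matrix(0L, 10, 10); B[1:10, 1:5] <- 1L
#' objectOverlapFraction(A, B)$dice   # 2*50/150
#' @export
objectOverlapFraction <- function(labelsA, labelsB) {
    stopifnot(identical(dim(labelsA), dim(labelsB)))
    fgA <- labelsA > 0L; fgB <- labelsB > 0L
    if (!any(fgA) || !any(fgB)) {
        warning("empty foreground; overlap defined as 0")
        per <- regionProperties(labelsA)[, c("label", "area")]
        per$overlap_fraction <- if (nrow(per)) 0 else numeric(0)
        return(list(perObject = per, dice = 0))
    }
    labs <- sort(unique(labelsA[fgA]))
    g <- factor(labelsA[fgA], levels = labs)
    area <- as.integer(tabulate(g, nbins = length(labs)))
    cov <- rowsum(as.numeric(fgB[fgA]), g, reorder = FALSE)[, 1]
    inter <- sum(fgA & fgB)
    list(perObject = data.frame(label = labs, area = area,
                                overlap_fraction = cov / area),
         dice = 2 * inter / (sum(fgA) + sum(fgB)))
}
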