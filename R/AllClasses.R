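#' @import methods
#' @importFrom stats rnorm rpois runif sd var cor phyper rlnorm
#' @importFrom utils head tail read.csv write.csv read.table write.table
NULL

#' Micrograph: a single-channel intensity raster with a physical pixel size
#'
#' The elementary image container of the package. Values are a numeric
#' matrix (rows = image rows), nonnegative and finite; \code{pixelSize} is
#' the lateral sampling in micrometres per pixel. A free-form \code{metadata}
#' list carries provenance (e.g. the validity mask attached by
#' \code{\link{applyFlatField}}).
#'
#' @slot values numeric matrix of intensities.
#' @slot pixelSize micrometres per pixel, a single positive number.
#' @slot metadata list of auxiliary information.
#' @seealso \code{\link{micrograph}}, \code{\link{imageValues}},
#'   \code{\link{pixelSize}}
#' @exportClass Micrograph
setClass("Micrograph",
    representation(values = "matrix", pixelSize = "numeric",
                   metadata = "list"),
    prototype(values = matrix(0, 1L, 1L), pixelSize = 0.16,
              metadata = list()))

setValidity("Micrograph", function(object) {
    v <- object@values
    if (!is.numeric(v)) return("'values' must be a numeric matrix")
    if (nrow(v) < 1L || ncol(v) < 1L) return("both image dimensions must be >= 1")
    if (any(!is.finite(v))) return("image values must be finite")
    if (any(v < 0)) return("image values must be nonnegative")
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
        return("'pixelSize' must be a single positive number (um/px)")
    TRUE
})

#' IlluminationField: a smooth multiplicative illumination pattern
#'
#' A raster in (0, 1] with maximum exactly 1, produced by
#' \code{\link{computeIlluminationFunction}}. Values below the clamp floor
#' \code{floorFraction * max} are raised to the floor so that division by the
#' field never amplifies by more than \code{1/floorFraction}.
#'
#' @slot values numeric matrix in (0, 1], maximum exactly 1.
#' @slot smoothingSigmaPx Gaussian smoothing sigma (pixels) used to build it.
#' @slot floorFraction clamp floor as a fraction of the field maximum.
#' @exportClass IlluminationField
setClass("IlluminationField",
    representation(values = "matrix", smoothingSigmaPx = "numeric",
                   floorFraction = "numeric"),
    prototype(smoothingSigmaPx = 50, floorFraction = 1e-3))

setValidity("IlluminationField", function(object) {
    v <- object@values
    if (any(!is.finite(v))) return("field values must be finite")
    if (abs(max(v) - 1) > 1e-12) return("field maximum must be exactly 1")
    if (min(v) <= 0) return("field values must be strictly positive")
    if (object@floorFraction <= 0 || object@floorFraction >= 1)
        return("'floorFraction' must lie in (0, 1)")
    TRUE
})

#' DetectionParams: parameters of the two-round condensate identification
#'
#' Defaults follow the published pipeline: nuclei retained with equivalent
#' diameter 80--300 px and border-touching nuclei removed; speckle
#' enhancement with a 40-px feature; round I adaptive Robust Background
#' thresholding (50-px window, 5\%/5\% trim, mean + 2 SD) keeping objects of
#' 6--40 px equivalent diameter; round II global Otsu with a correction
#' factor of 0.5 keeping 8--40 px; a cell is large-condensate positive when
#' at least \code{largeCondensateMinCount} condensates exceed
#' \code{largeCondensateMinDiameterUm} in equivalent diameter.
#'
#' @slot nucleusDiameterPxRange length-2 numeric, nucleus equivalent-diameter
#'   gate in pixels.
#' @slot removeBorderNuclei drop nuclei touching any image border.
#' @slot speckleFeatureDiameterPx structuring-element diameter of the white
#'   top-hat used by \code{\link{enhanceSpeckles}}.
#' @slot round1DiameterPxRange,round2DiameterPxRange object equivalent-diameter
#'   gates (pixels) for the two identification rounds.
#' @slot round1AdaptiveWindowPx tile size of the adaptive threshold surface.
#' @slot robustTrimLow,robustTrimHigh,robustNSD Robust Background parameters.
#' @slot otsuCorrectionFactor multiplier applied to the global Otsu threshold
#'   in round II.
#' @slot largeCondensateMinDiameterUm,largeCondensateMinCount the
#'   large-condensate-positive cell rule.
#' @slot expressionGateRange optional length-2 numeric; cells whose mean
#'   nuclear intensity falls outside the interval are excluded (use
#'   \code{c(-Inf, Inf)} to disable).
#' @seealso \code{\link{detectionParams}}
#' @exportClass DetectionParams
setClass("DetectionParams",
    representation(
        nucleusDiameterPxRange = "numeric",
        removeBorderNuclei = "logical",
        speckleFeatureDiameterPx = "numeric",
        round1DiameterPxRange = "numeric",
        round1AdaptiveWindowPx = "numeric",
        robustTrimLow = "numeric",
        robustTrimHigh = "numeric",
        robustNSD = "numeric",
        round2DiameterPxRange = "numeric",
        otsuCorrectionFactor = "numeric",
        largeCondensateMinDiameterUm = "numeric",
        largeCondensateMinCount = "numeric",
        expressionGateRange = "numeric"),
    prototype(
        nucleusDiameterPxRange = c(80, 300),
        removeBorderNuclei = TRUE,
        speckleFeatureDiameterPx = 40,
        round1DiameterPxRange = c(6, 40),
        round1AdaptiveWindowPx = 50,
        robustTrimLow = 0.05,
        robustTrimHigh = 0.05,
        robustNSD = 2.0,
        round2DiameterPxRange = c(8, 40),
        otsuCorrectionFactor = 0.5,
        largeCondensateMinDiameterUm = 1.25,
        largeCondensateMinCount = 2,
        expressionGateRange = c(-Inf, Inf)))

setValidity("DetectionParams", function(object) {
    rng <- function(x) length(x) == 2L && !any(is.na(x)) && x[1] <= x[2]
    if (!rng(object@nucleusDiameterPxRange)) return("bad nucleus diameter range")
    if (!rng(object@round1DiameterPxRange)) return("bad round-1 diameter range")
    if (!rng(object@round2DiameterPxRange)) return("bad round-2 diameter range")
    if (!rng(object@expressionGateRange)) return("bad expression gate range")
    if (object@round1AdaptiveWindowPx < 1) return("adaptive window must be >= 1 px")
    if (object@otsuCorrectionFactor <= 0) return("Otsu correction factor must be > 0")
    if (object@robustTrimLow < 0 || object@robustTrimHigh < 0 ||
        object@robustTrimLow + object@robustTrimHigh >= 1)
        return("trim fractions must be nonnegative and sum to < 1")
    if (object@speckleFeatureDiameterPx < 1) return("feature diameter must be >= 1 px")
    if (object@largeCondensateMinCount < 0) return("minimum count must be >= 0")
    TRUE
})

#' SimImageSpec: the stated world of the micrograph simulator
#'
#' Describes a field of view with non-overlapping elliptical nuclei, each
#' carrying Gaussian-profile condensates (FWHM = nominal diameter), imaged
#' under a smooth radial-vignette illumination field with a camera offset and
#' additive Gaussian read noise. See \code{\link{simImageSpec}} for defaults
#' and \code{\link{simulateMicrograph}} for the rendering model.
#'
#' @slot widthPx,heightPx image dimensions in pixels.
#' @slot pixelSizeUm micrometres per pixel.
#' @slot nNuclei number of nuclei to place.
#' @slot nucleusDiameterPxRange length-2 range of nucleus major diameters (px).
#' @slot condensatesPerNucleus either a fixed count or a Poisson mean,
#'   according to \code{condensateCountModel}.
#' @slot condensateCountModel \code{"fixed"} or \code{"poisson"}.
#' @slot condensateDiameterUmRange length-2 range of condensate FWHM (um).
#' @slot largeCellFraction fraction of nuclei assigned the large-condensate
#'   phenotype when \code{phenotypeMix} is TRUE.
#' @slot phenotypeMix when TRUE, each nucleus is either a small-punctum cell
#'   (diameters from the lower sub-range \code{smallDiameterUmRange}) or a
#'   large-condensate cell (\code{largeDiameterUmRange}); when FALSE all
#'   diameters are uniform over \code{condensateDiameterUmRange}.
#' @slot smallDiameterUmRange,largeDiameterUmRange phenotype sub-ranges (um).
#' @slot condensatePeakIntensity peak amplitude above nuclear background (AU).
#' @slot nuclearBackgroundIntensity uniform in-nucleus background level (AU).
#' @slot cameraOffset additive camera offset (AU).
#' @slot vignetteStrength radial illumination falloff coefficient in [0, 1);
#'   the field is 1 - vignetteStrength * (r / rmax)^2.
#' @slot noiseSigma Gaussian read-noise standard deviation (AU).
#' @slot shotNoise when TRUE, Poisson shot noise is applied to the scene
#'   before read noise.
#' @slot allowBorderNuclei permit nuclei to touch image borders.
#' @slot seed integer seed making every rendering reproducible.
#' @exportClass SimImageSpec
setClass("SimImageSpec",
    representation(
        widthPx = "integer", heightPx = "integer", pixelSizeUm = "numeric",
        nNuclei = "integer", nucleusDiameterPxRange = "numeric",
        condensatesPerNucleus = "numeric", condensateCountModel = "character",
        condensateDiameterUmRange = "numeric",
        phenotypeMix = "logical", largeCellFraction = "numeric",
        smallDiameterUmRange = "numeric", largeDiameterUmRange = "numeric",
        condensatePeakIntensity = "numeric",
        nuclearBackgroundIntensity = "numeric", cameraOffset = "numeric",
        vignetteStrength = "numeric", noiseSigma = "numeric",
        shotNoise = "logical", allowBorderNuclei = "logical",
        seed = "integer"))

setValidity("SimImageSpec", function(object) {
    rng <- function(x) length(x) == 2L && all(is.finite(x)) && x[1] <= x[2]
    if (object@widthPx < 8L || object@heightPx < 8L)
        return("image must be at least 8 x 8 px")
    if (object@pixelSizeUm <= 0) return("'pixelSizeUm' must be > 0")
    if (object@nNuclei < 0L) return("'nNuclei' must be >= 0")
    if (!rng(object@nucleusDiameterPxRange) ||
        object@nucleusDiameterPxRange[1] <= 0)
        return("bad nucleus diameter range")
    if (!object@condensateCountModel %in% c("fixed", "poisson"))
        return("'condensateCountModel' must be 'fixed' or 'poisson'")
    if (object@condensatesPerNucleus < 0) return("condensate count must be >= 0")
    if (!rng(object@condensateDiameterUmRange) ||
        object@condensateDiameterUmRange[1] <= 0)
        return("bad condensate diameter range")
    if (object@phenotypeMix) {
        if (!rng(object@smallDiameterUmRange) || !rng(object@largeDiameterUmRange))
            return("bad phenotype diameter sub-ranges")
        if (object@largeCellFraction < 0 || object@largeCellFraction > 1)
            return("'largeCellFraction' must lie in [0, 1]")
    }
    if (object@vignetteStrength < 0 || object@vignetteStrength >= 1)
        return("'vignetteStrength' must lie in [0, 1)")
    if (object@noiseSigma < 0) return("'noiseSigma' must be >= 0")
    if (object@cameraOffset < 0) return("'cameraOffset' must be >= 0")
    TRUE
})

#' RankCurve: the normalized rank-size curve of a domain-size list
#'
#' Sizes sorted ascending (stable), ranks normalized to [0, 1] as
#' (i-1)/(n-1), sizes min-max normalized to [0, 1], and the slope of the
#' tangent at each pair of adjacent points.
#'
#' @slot sizes sorted domain sizes (bp).
#' @slot x normalized ranks, strictly increasing.
#' @slot y normalized sizes, nondecreasing.
#' @slot slopes adjacent-point tangent slopes, length n - 1, nonnegative.
#' @seealso \code{\link{rankSizeCurve}}, \code{\link{slidingSlopeCutoff}}
#' @exportClass RankCurve
setClass("RankCurve",
    representation(sizes = "numeric", x = "numeric", y = "numeric",
                   slopes = "numeric"))

setValidity("RankCurve", function(object) {
    n <- length(object@sizes)
    if (n < 12L) return("a rank curve needs at least 12 sizes")
    if (length(object@x) != n || length(object@y) != n ||
        length(object@slopes) != n - 1L)
        return("inconsistent component lengths")
    if (any(diff(object@x) <= 0)) return("'x' must be strictly increasing")
    if (any(diff(object@y) < -1e-12)) return("'y' must be nondecreasing")
    if (any(object@slopes < -1e-12)) return("slopes must be nonnegative")
    TRUE
})

#' CutoffResult: a rank-slope large-domain cutoff with diagnostics
#'
#' @slot cutoffBp the size (bp) at the crossing; NA when no window reaches
#'   the slope threshold.
#' @slot crossingIndex rank index of the first slope of the first qualifying
#'   window (NA when none).
#' @slot nLarge number of domains with size >= cutoff.
#' @slot status "ok" or "no_crossing".
#' @slot window,slopeThreshold parameters used.
#' @slot windowMeans sliding means of \code{window} consecutive slopes.
#' @slot curve the underlying \code{\linkS4class{RankCurve}}.
#' @exportClass CutoffResult
setClass("CutoffResult",
    representation(cutoffBp = "numeric", crossingIndex = "numeric",
                   nLarge = "numeric", status = "character",
                   window = "numeric", slopeThreshold = "numeric",
                   windowMeans = "numeric", curve = "RankCurve"))

#' OverlapResult: gene-set overlap statistics
#'
#' Venn counts, the randomized expected overlap (mean and SD over
#' \code{iters} draws of both sets from the universe), the analytic
#' expectation nA * nB / N, the representation factor (observed divided by
#' the randomized expected mean) and the hypergeometric upper-tail
#' enrichment p-value.
#'
#' @slot nAOnly,nBOnly,observedOverlap Venn partition counts.
#' @slot expectedRandomMean,expectedRandomSD randomization summary.
#' @slot expectedAnalytic nA * nB / N.
#' @slot representationFactor observed / expectedRandomMean (NA when the
#'   expectation is zero).
#' @slot pValue hypergeometric upper-tail probability of >= observed overlap.
#' @slot iters,universeSize,seed provenance of the randomization.
#' @seealso \code{\link{geneSetOverlap}}
#' @exportClass OverlapResult
setClass("OverlapResult",
    representation(nAOnly = "numeric", nBOnly = "numeric",
                   observedOverlap = "numeric",
                   expectedRandomMean = "numeric", expectedRandomSD = "numeric",
                   expectedAnalytic = "numeric",
                   representationFactor = "numeric", pValue = "numeric",
                   iters = "numeric", universeSize = "numeric",
                   seed = "numeric"))
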