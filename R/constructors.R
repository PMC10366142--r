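#' Construct a Micrograph
#'
#' @param values numeric matrix of nonnegative, finite intensities.
#' @param pixelSize micrometres per pixel (default 0.16, a typical 100x
#'   EM-CCD scale; always configurable, never assumed).
#' @param metadata optional list of auxiliary information.
#' @return a \linkS4class{Micrograph}.
#' @examples
#' micrograph(matrix(runif(64), 8, 8), pixelSize = 0.1)
#' @export
micrograph <- function(values, pixelSize = 0.16, metadata = list()) {
    new("Micrograph", values = as.matrix(values), pixelSize = pixelSize,
        metadata = metadata)
}

#' Construct detection parameters
#'
#' All arguments default to the published pipeline settings; see
#' \linkS4class{DetectionParams} for their meaning.
#'
#' @param nucleusDiameterPxRange nucleus equivalent-diameter gate (px).
#' @param removeBorderNuclei drop nuclei touching the image border.
#' @param speckleFeatureDiameterPx top-hat structuring-element diameter (px).
#' @param round1DiameterPxRange round-I object diameter gate (px).
#' @param round1AdaptiveWindowPx adaptive-threshold tile size (px).
#' @param robustTrimLow,robustTrimHigh,robustNSD Robust Background
#'   parameters: trimmed fractions and the SD multiplier.
#' @param round2DiameterPxRange round-II object diameter gate (px).
#' @param otsuCorrectionFactor multiplier on the global Otsu threshold.
#' @param largeCondensateMinDiameterUm,largeCondensateMinCount the
#'   large-condensate-positive cell rule (at least \code{count} condensates
#'   larger than \code{diameter} um).
#' @param expressionGateRange optional mean-nuclear-intensity bounds.
#' @return a \linkS4class{DetectionParams}.
#' @examples
#' detectionParams()
#' detectionParams(otsuCorrectionFactor = 0.8)
#' @export
detectionParams <- function(nucleusDiameterPxRange = c(80, 300),
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
                            expressionGateRange = c(-Inf, Inf)) {
    new("DetectionParams",
        nucleusDiameterPxRange = as.numeric(nucleusDiameterPxRange),
        removeBorderNuclei = isTRUE(removeBorderNuclei),
        speckleFeatureDiameterPx = as.numeric(speckleFeatureDiameterPx),
        round1DiameterPxRange = as.numeric(round1DiameterPxRange),
        round1AdaptiveWindowPx = as.numeric(round1AdaptiveWindowPx),
        robustTrimLow = as.numeric(robustTrimLow),
        robustTrimHigh = as.numeric(robustTrimHigh),
        robustNSD = as.numeric(robustNSD),
        round2DiameterPxRange = as.numeric(round2DiameterPxRange),
        otsuCorrectionFactor = as.numeric(otsuCorrectionFactor),
        largeCondensateMinDiameterUm = as.numeric(largeCondensateMinDiameterUm),
        largeCondensateMinCount = as.numeric(largeCondensateMinCount),
        expressionGateRange = as.numeric(expressionGateRange))
}

#' Construct a micrograph simulation specification
#'
#' The defaults describe a plausible spinning-disk confocal acquisition of
#' induced cells: a 512 x 512 field at 0.16 um/px with a handful of
#' non-overlapping nuclei, Gaussian-profile condensates whose FWHM defines
#' their nominal diameter, a radial vignette illumination field, a camera
#' offset and Gaussian read noise. When \code{phenotypeMix} is TRUE each
#' nucleus is assigned one of two phenotypes -- small-punctum cells versus
#' large-condensate cells -- mirroring cell lines that do or do not form
#' large condensates.
#'
#' @param widthPx,heightPx image dimensions (px).
#' @param pixelSizeUm micrometres per pixel.
#' @param nNuclei number of nuclei.
#' @param nucleusDiameterPxRange nucleus major-diameter range (px).
#' @param condensatesPerNucleus fixed count or Poisson mean, per
#'   \code{condensateCountModel}.
#' @param condensateCountModel \code{"fixed"} or \code{"poisson"}.
#' @param condensateDiameterUmRange condensate FWHM range (um) used when
#'   \code{phenotypeMix} is FALSE.
#' @param phenotypeMix assign per-nucleus phenotypes (see Details).
#' @param largeCellFraction fraction of large-condensate cells.
#' @param smallDiameterUmRange,largeDiameterUmRange phenotype FWHM
#'   sub-ranges (um).
#' @param condensatePeakIntensity condensate peak amplitude above the
#'   nuclear background (AU).
#' @param nuclearBackgroundIntensity in-nucleus background level (AU).
#' @param cameraOffset additive offset present even in empty wells (AU).
#' @param vignetteStrength radial falloff coefficient in [0, 1).
#' @param noiseSigma Gaussian read-noise SD (AU).
#' @param shotNoise apply Poisson shot noise to the scene.
#' @param allowBorderNuclei permit nuclei to touch the borders.
#' @param seed integer seed.
#' @return a \linkS4class{SimImageSpec}.
#' @examples
#' simImageSpec(nNuclei = 3, seed = 7)
#' @export
simImageSpec <- function(widthPx = 512, heightPx = 512, pixelSizeUm = 0.16,
                         nNuclei = 5,
                         nucleusDiameterPxRange = c(90, 140),
                         condensatesPerNucleus = 3,
                         condensateCountModel = c("fixed", "poisson"),
                         condensateDiameterUmRange = c(0.8, 2.0),
                         phenotypeMix = FALSE,
                         largeCellFraction = 0.5,
                         smallDiameterUmRange = c(0.8, 0.9),
                         largeDiameterUmRange = c(1.5, 2.0),
                         condensatePeakIntensity = 200,
                         nuclearBackgroundIntensity = 200,
                         cameraOffset = 100,
                         vignetteStrength = 0.3,
                         noiseSigma = 20,
                         shotNoise = FALSE,
                         allowBorderNuclei = FALSE,
                         seed = 1L) {
    condensateCountModel <- match.arg(condensateCountModel)
    new("SimImageSpec",
        widthPx = as.integer(widthPx), heightPx = as.integer(heightPx),
        pixelSizeUm = as.numeric(pixelSizeUm), nNuclei = as.integer(nNuclei),
        nucleusDiameterPxRange = as.numeric(nucleusDiameterPxRange),
        condensatesPerNucleus = as.numeric(condensatesPerNucleus),
        condensateCountModel = condensateCountModel,
        condensateDiameterUmRange = as.numeric(condensateDiameterUmRange),
        phenotypeMix = isTRUE(phenotypeMix),
        largeCellFraction = as.numeric(largeCellFraction),
        smallDiameterUmRange = as.numeric(smallDiameterUmRange),
        largeDiameterUmRange = as.numeric(largeDiameterUmRange),
        condensatePeakIntensity = as.numeric(condensatePeakIntensity),
        nuclearBackgroundIntensity = as.numeric(nuclearBackgroundIntensity),
        cameraOffset = as.numeric(cameraOffset),
        vignetteStrength = as.numeric(vignetteStrength),
        noiseSigma = as.numeric(noiseSigma),
        shotNoise = isTRUE(shotNoise),
        allowBorderNuclei = isTRUE(allowBorderNuclei),
        seed = as.integer(seed))
}
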