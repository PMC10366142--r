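#' Accessors for image and result classes
#'
#' \code{imageValues} returns the raw intensity matrix of a
#' \linkS4class{Micrograph} (or the raster of an
#' \linkS4class{IlluminationField}); \code{pixelSize} returns the lateral
#' sampling in micrometres per pixel.
#'
#' @param x a \linkS4class{Micrograph} or \linkS4class{IlluminationField}.
#' @return \code{imageValues}: a numeric matrix; \code{pixelSize}: a single
#'   positive number.
#' @examples
#' img <- micrograph(matrix(1:4, 2, 2), pixelSize = 0.16)
#' imageValues(img)
#' pixelSize(img)
#' @export
setGeneric("imageValues", function(x) standardGeneric("imageValues"))

#' @rdname imageValues
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname imageValues
setMethod("imageValues", "Micrograph", function(x) x@values)

#' @rdname imageValues
setMethod("imageValues", "IlluminationField", function(x) x@values)

#' @rdname imageValues
setMethod("pixelSize", "Micrograph", function(x) x@pixelSize)

#' Accessors for rank-slope cutoff results
#'
#' @param x a \linkS4class{CutoffResult}.
#' @return \code{cutoffBp}: the domain-size cutoff in bp (NA when no window
#'   reached the slope threshold); \code{crossingIndex}: the rank index of
#'   the first slope of the first qualifying window; \code{nLarge}: the
#'   number of domains at least as large as the cutoff.
#' @export
setGeneric("cutoffBp", function(x) standardGeneric("cutoffBp"))

#' @rdname cutoffBp
#' @export
setGeneric("crossingIndex", function(x) standardGeneric("crossingIndex"))

#' @rdname cutoffBp
#' @export
setGeneric("nLarge", function(x) standardGeneric("nLarge"))

#' @rdname cutoffBp
setMethod("cutoffBp", "CutoffResult", function(x) x@cutoffBp)

#' @rdname cutoffBp
setMethod("crossingIndex", "CutoffResult", function(x) x@crossingIndex)

#' @rdname cutoffBp
setMethod("nLarge", "CutoffResult", function(x) x@nLarge)

setMethod("show", "Micrograph", function(object) {
    d <- dim(object@values)
    cat(sprintf("Micrograph: %d x %d px, %.3g um/px, range [%.4g, %.4g]\n",
                d[1], d[2], object@pixelSize,
                min(object@values), max(object@values)))
})

setMethod("show", "IlluminationField", function(object) {
    d <- dim(object@values)
    cat(sprintf(
        "IlluminationField: %d x %d px, min %.4f, smoothing sigma %.1f px\n",
        d[1], d[2], min(object@values), object@smoothingSigmaPx))
})

setMethod("show", "DetectionParams", function(object) {
    cat("DetectionParams\n")
    cat(sprintf("  nuclei: diameter %g-%g px, remove border: %s\n",
                object@nucleusDiameterPxRange[1],
                object@nucleusDiameterPxRange[2], object@removeBorderNuclei))
    cat(sprintf("  round I: diameter %g-%g px, adaptive window %g px, trim %g/%g, %g SD\n",
                object@round1DiameterPxRange[1], object@round1DiameterPxRange[2],
                object@round1AdaptiveWindowPx, object@robustTrimLow,
                object@robustTrimHigh, object@robustNSD))
    cat(sprintf("  round II: diameter %g-%g px, Otsu x %g\n",
                object@round2DiameterPxRange[1], object@round2DiameterPxRange[2],
                object@otsuCorrectionFactor))
    cat(sprintf("  large cell: >= %g condensates > %g um\n",
                object@largeCondensateMinCount,
                object@largeCondensateMinDiameterUm))
})

setMethod("show", "CutoffResult", function(object) {
    if (object@status == "ok")
        cat(sprintf(
            "CutoffResult: cutoff %.0f bp at rank index %d (n = %d, %d large)\n",
            object@cutoffBp, as.integer(object@crossingIndex),
            length(object@curve@sizes), as.integer(object@nLarge)))
    else
        cat(sprintf("CutoffResult: no crossing (n = %d, window %d, threshold %g)\n",
                    length(object@curve@sizes), as.integer(object@window),
                    object@slopeThreshold))
})

setMethod("show", "OverlapResult", function(object) {
    cat(sprintf(
        "OverlapResult: A-only %d | overlap %d | B-only %d (universe %d)\n",
        as.integer(object@nAOnly), as.integer(object@observedOverlap),
        as.integer(object@nBOnly), as.integer(object@universeSize)))
    cat(sprintf("  expected overlap: %.3f random (sd %.3f, %d iters), %.3f analytic\n",
                object@expectedRandomMean, object@expectedRandomSD,
                as.integer(object@iters), object@expectedAnalytic))
    cat(sprintf("  representation factor %.3g, p = %.3g\n",
                object@representationFactor, object@pValue))
})

setMethod("show", "SimImageSpec", function(object) {
    cat(sprintf("SimImageSpec: %d x %d px (%.3g um/px), %d nuclei, seed %d\n",
                object@heightPx, object@widthPx, object@pixelSizeUm,
                object@nNuclei, object@seed))
})
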