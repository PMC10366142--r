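#' Estimate the illumination function from reference images
#'
#' Implements the illumination-calibration steps of the quantification
#' pipeline: the empty-well background image is subtracted from the
#' empty-well fluorophore reference (negatives clipped to zero), the
#' difference is smoothed with a large-sigma Gaussian to obtain a smooth
#' estimate of the spatial illumination pattern, and the result is rescaled
#' by division by its maximum so that the field maximum is exactly 1.
#' Values below \code{floorFraction} of the maximum are clamped to the floor
#' to bound noise amplification when images are later divided by the field.
#'
#' @param emptyFluorophoreImage \linkS4class{Micrograph} of an empty well
#'   containing dilute fluorophore (uniform fluorescent layer).
#' @param emptyImage \linkS4class{Micrograph} of an empty well with buffer
#'   only (camera offset + noise).
#' @param smoothingSigmaPx Gaussian sigma in pixels (default 50; the
#'   illumination pattern varies on a scale much larger than any object).
#' @param floorFraction clamp floor as a fraction of the field maximum.
#' @return an \linkS4class{IlluminationField}.
#' @seealso \code{\link{applyFlatField}}
#' @examples
#' ramp <- matrix(seq(0.5, 1, length.out = 32), 32, 32)
#' fl <- micrograph(ramp + 100); em <- micrograph(matrix(100, 32, 32))
#' f <- computeIlluminationFunction(fl, em, smoothingSigmaPx = 0)
#' max(imageValues(f))   # 1
#' @export
computeIlluminationFunction <- function(emptyFluorophoreImage, emptyImage,
                                        smoothingSigmaPx = 50,
                                        floorFraction = 1e-3) {
    stopifnot(is(emptyFluorophoreImage, "Micrograph"),
              is(emptyImage, "Micrograph"))
    a <- imageValues(emptyFluorophoreImage)
    b <- imageValues(emptyImage)
    if (!identical(dim(a), dim(b)))
        stop("reference images must have identical dimensions")
    if (smoothingSigmaPx < 0) stop("'smoothingSigmaPx' must be >= 0")
    diffImg <- pmax(a - b, 0)
    if (max(diffImg) <= 0)
        stop("degenerate illumination field: no fluorophore signal above background")
    sm <- gaussianSmooth(diffImg, smoothingSigmaPx)
    fld <- sm / max(sm)
    fld[fld < floorFraction] <- floorFraction
    new("IlluminationField", values = fld,
        smoothingSigmaPx = smoothingSigmaPx, floorFraction = floorFraction)
}

#' Flat-field correct a micrograph
#'
#' Subtracts the empty-well background from the image (negatives clipped to
#' zero) and divides by the illumination field, removing spatial
#' illumination bias. Pixels where the field sits at its clamp floor are
#' unreliable (the division there is bounded artificially); they are flagged
#' FALSE in a logical validity mask stored in the result's metadata as
#' \code{metadata(x)$valid}.
#'
#' @param image \linkS4class{Micrograph} to correct.
#' @param emptyImage \linkS4class{Micrograph} empty-well background.
#' @param field an \linkS4class{IlluminationField} from
#'   \code{\link{computeIlluminationFunction}}.
#' @return a corrected \linkS4class{Micrograph}; the validity mask is in
#'   \code{@metadata$valid}.
#' @examples
#' img <- micrograph(matrix(200, 16, 16)); em <- micrograph(matrix(50, 16, 16))
#' f <- new("IlluminationField", values = matrix(1, 16, 16),
#'          smoothingSigmaPx = 0, floorFraction = 1e-3)
#' range(imageValues(applyFlatField(img, em, f)))   # 150 everywhere
#' @export
applyFlatField <- function(image, emptyImage, field) {
    stopifnot(is(image, "Micrograph"), is(emptyImage, "Micrograph"),
              is(field, "IlluminationField"))
    a <- imageValues(image)
    b <- imageValues(emptyImage)
    f <- field@values
    if (!identical(dim(a), dim(b)) || !identical(dim(a), dim(f)))
        stop("image, empty image and field must have identical dimensions")
    corrected <- pmax(a - b, 0) / f
    valid <- f > field@floorFraction
    micrograph(corrected, pixelSize = pixelSize(image),
               metadata = c(image@metadata, list(valid = valid)))
}
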