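#' Accessors for ImageField and friends
#'
#' \code{imgData} returns the raw intensity array; \code{pixelSize} the
#' per-axis physical pixel size (um, absolute); \code{expansionFactor} the
#' linear expansion state E; \code{channelLabel} the channel annotation.
#'
#' @param x an \linkS4class{ImageField} (or \linkS4class{Mask} for
#'   \code{imgData}).
#' @return The corresponding slot value.
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("expansionFactor", function(x) standardGeneric("expansionFactor"))

#' @rdname accessors
#' @export
setGeneric("channelLabel", function(x) standardGeneric("channelLabel"))

#' @rdname accessors
#' @export
setMethod("imgData", "ImageField", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("imgData", "Mask", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("pixelSize", "ImageField", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setMethod("expansionFactor", "ImageField", function(x) x@expansionFactor)

#' @rdname accessors
#' @export
setMethod("channelLabel", "ImageField", function(x) x@channelLabel)

#' @describeIn accessors image dimensions (z, y, x) or (y, x)
#' @export
setMethod("dim", "ImageField", function(x) dim(x@data))

setMethod("show", "ImageField", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageField %s [%s px], pixel %s um, E = %.3g%s\n",
              if (length(d) == 2) "2D (y,x)" else "3D (z,y,x)",
              paste(d, collapse = " x "),
              paste(signif(object@pixelSize, 4), collapse = " x "),
              object@expansionFactor,
              if (nzchar(object@channelLabel))
                paste0(", channel '", object@channelLabel, "'") else ""))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "Mask", function(object) {
  cat(sprintf("Mask (%s) [%s px], %d true pixels\n", object@role,
              paste(dim(object@data), collapse = " x "), sum(object@data)))
})

setMethod("show", "RigidSimilarity", function(object) {
  cat(sprintf(
    "RigidSimilarity: scale %.4f, theta %.3f deg, t = (%.2f, %.2f) px, NCC %.4f\n",
    object@scale, object@theta * 180 / pi,
    object@translation[1], object@translation[2], object@metric))
})

setMethod("show", "DeformationResult", function(object) {
  mag <- sqrt(object@fieldY^2 + object@fieldX^2)[object@mask@data]
  cat(sprintf(
    "DeformationResult [%s px], |d| median %.3f um (max %.3f), NCC %.4f\n",
    paste(dim(object@fieldY), collapse = " x "),
    stats::median(mag), max(mag), object@metric))
  show(object@rigid)
})

setMethod("show", "RoiBox3D", function(object) {
  cat(sprintf("RoiBox3D '%s' [%s] - [%s]\n", object@label,
              paste(object@minCorner, collapse = ","),
              paste(object@maxCorner, collapse = ",")))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: canvas %s um, E = %.3g, sigmaD %.3g um, ell %.3g um, %d puncta, seed %d\n",
    paste(object@canvasUm, collapse = " x "), object@eTrue, object@sigmaD,
    object@ell, object@nPuncta, as.integer(object@seed)))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf(
    "PhantomTruth: %d puncta, %d spots in %d cells, midline %.1f -> %.1f um\n",
    nrow(object@punctaPre), nrow(object@spots), nrow(object@cellCounts),
    object@midlineLengthPre, object@midlineLengthPost))
})
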