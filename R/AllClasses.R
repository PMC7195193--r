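#' @import methods
NULL

#' ImageField: an intensity grid with physical metadata
#'
#' The universal carrier between pipeline stages: a 2D (y, x) or 3D
#' (z, y, x) grid of non-negative intensities together with the physical
#' pixel size per axis (micrometres, post-expansion "absolute" units) and
#' the specimen's linear expansion factor E. Biological (pre-expansion)
#' lengths are obtained by dividing absolute lengths by E.
#'
#' @slot data numeric array, 2D (y, x) or 3D (z, y, x); finite, >= 0.
#' @slot pixelSize numeric, physical length per pixel per axis (um),
#'   one value per array dimension, in the same axis order as \code{data}.
#' @slot expansionFactor numeric scalar > 0; 1 means pre-expansion.
#' @slot channelLabel free-text channel annotation.
#'
#' @exportClass ImageField
setClass("ImageField",
  representation(data = "array", pixelSize = "numeric",
                 expansionFactor = "numeric", channelLabel = "character"),
  validity = function(object) {
    d <- object@data
    if (!(length(dim(d)) %in% c(2L, 3L)))
      return("data must be a 2D (y,x) or 3D (z,y,x) array")
    if (any(!is.finite(d))) return("intensities must be finite")
    if (any(d < 0)) return("intensities must be >= 0")
    if (length(object@pixelSize) != length(dim(d)))
      return("pixelSize must have one entry per image axis")
    if (any(object@pixelSize <= 0)) return("pixelSize must be > 0 on every axis")
    if (length(object@expansionFactor) != 1 || object@expansionFactor <= 0)
      return("expansionFactor must be a positive scalar")
    TRUE
  })

#' Mask: a boolean grid congruent with a parent image
#'
#' @slot data logical array with the same shape as its parent image.
#' @slot role one of "signal", "background", "foreground".
#' @exportClass Mask
setClass("Mask",
  representation(data = "array", role = "character"),
  validity = function(object) {
    if (!is.logical(object@data)) return("mask data must be logical")
    if (!(object@role %in% c("signal", "background", "foreground")))
      return("role must be signal, background or foreground")
    TRUE
  })

#' RoiBox3D: an axis-aligned 3D bounding box assigning spots to a cell
#'
#' Integer voxel coordinates, 0-based, inclusive of both corners, in
#' (z, y, x) axis order.
#'
#' @slot minCorner,maxCorner integer vectors of length 3 (z, y, x).
#' @slot label cell identity.
#' @exportClass RoiBox3D
setClass("RoiBox3D",
  representation(minCorner = "numeric", maxCorner = "numeric", label = "character"),
  validity = function(object) {
    if (length(object@minCorner) != 3 || length(object@maxCorner) != 3)
      return("corners must have 3 coordinates (z, y, x)")
    if (any(object@minCorner > object@maxCorner))
      return("minCorner must be <= maxCorner on every axis")
    TRUE
  })

#' RigidSimilarity: isotropic scale + rotation + translation (2D)
#'
#' Maps pre-image pixel coordinates p (0-based, (y, x), in pixels) into the
#' post image as s * R(theta) p + t. The recovered scale estimates the raw
#' expansion factor between the two images.
#'
#' @slot scale isotropic scale s > 0.
#' @slot theta rotation angle (radians).
#' @slot translation length-2 numeric (y, x), pixels of the post frame.
#' @slot metric value of the similarity metric (normalized cross-correlation)
#'   at the optimum.
#' @exportClass RigidSimilarity
setClass("RigidSimilarity",
  representation(scale = "numeric", theta = "numeric",
                 translation = "numeric", metric = "numeric"),
  validity = function(object) {
    if (object@scale <= 0) return("scale must be > 0")
    if (length(object@translation) != 2) return("translation must be length 2")
    TRUE
  })

#' DeformationResult: output of non-rigid registration
#'
#' @slot rigid the rigid similarity recovered upstream.
#' @slot fieldY,fieldX dense residual displacement per pre-frame pixel,
#'   in biological micrometres.
#' @slot mask foreground \linkS4class{Mask} on the pre frame.
#' @slot metric similarity metric value (NCC inside the mask).
#' @slot pixelSize pre-frame pixel size (um), per axis (y, x).
#' @exportClass DeformationResult
setClass("DeformationResult",
  representation(rigid = "RigidSimilarity", fieldY = "matrix", fieldX = "matrix",
                 mask = "Mask", metric = "numeric", pixelSize = "numeric"),
  validity = function(object) {
    if (!all(dim(object@fieldY) == dim(object@fieldX)))
      return("field components must be congruent")
    if (!all(dim(object@fieldY) == dim(object@mask@data)))
      return("mask must be congruent with the field")
    m <- object@mask@data
    if (any(!is.finite(object@fieldY[m])) || any(!is.finite(object@fieldX[m])))
      return("residual field must be finite inside the mask")
    TRUE
  })

#' GroundTruthDeformation: the phantom generator's deformation model
#'
#' Global similarity (scale eTrue, rotation, translation) composed with a
#' smooth residual displacement field d(x) built by Gaussian-filtering
#' white noise on a coarse grid (spacing ell/2), normalized to a
#' per-component standard deviation sigmaD and mean ~ 0. The forward map of
#' a pre-expansion point p (biological um) is
#' T(p) = eTrue * R(theta) (p + d(p)) + t, so d acts on the biological
#' (pre-expansion) scale, matching how measurement error is reported.
#'
#' @slot eTrue global linear scale.
#' @slot theta rotation (radians).
#' @slot translation length-2 (y, x), absolute um in the post frame.
#' @slot gridY,gridX coarse-grid displacement components (um, biological).
#' @slot gridOrigin,gridSpacing coarse grid geometry (um, pre frame).
#' @slot sigmaD,ell field amplitude (per-component sd, um) and correlation
#'   length (um).
#' @exportClass GroundTruthDeformation
setClass("GroundTruthDeformation",
  representation(eTrue = "numeric", theta = "numeric", translation = "numeric",
                 gridY = "matrix", gridX = "matrix",
                 gridOrigin = "numeric", gridSpacing = "numeric",
                 sigmaD = "numeric", ell = "numeric"))

#' PhantomSpec: parameters of the synthetic worm phantom
#'
#' Defaults emulate the study conditions of whole-animal expansion
#' microscopy of C. elegans: a curved tubular body with two pharyngeal
#' bulbs, a bright nerve ring, dark ellipsoidal nuclei of 2-3 um length
#' scale, synaptic puncta along a ventral cord with a minimum spacing,
#' perinuclear FISH spots, a global expansion around 3-4x, and a smooth
#' residual deformation field.
#'
#' @slot canvasUm canvas extent (y, x), biological um.
#' @slot pixelSize pre-frame pixel size (um).
#' @slot midline control points of the body midline (n x 2, (y, x), um).
#' @slot bodyRadius nominal body radius (um).
#' @slot bulge pharyngeal bulb amplitude as a fraction of bodyRadius.
#' @slot nerveRingS arc-length fraction (0-1) of the nerve ring position.
#' @slot nerveRingBrightness peak intensity of the nerve ring band
#'   relative to body intensity.
#' @slot bodyIntensity,backgroundIntensity intensity levels (arbitrary units).
#' @slot nNuclei number of dark nuclei.
#' @slot nucleusAxes semi-axis range (um) of the nuclear ellipses.
#' @slot nucleusDepth fractional intensity drop inside nuclei (0-1).
#' @slot nPuncta,punctaMinSpacing,punctaAmplitude synaptic puncta count,
#'   minimum pairwise spacing (um) and amplitude range.
#' @slot psfSigma PSF sigma (um) per axis of the rendered frame.
#' @slot eTrue,thetaPost,translationPost global similarity of the post frame.
#' @slot sigmaD,ell residual deformation amplitude and correlation length (um).
#' @slot textureAmplitude,textureEll multiplicative tissue texture
#'   (relative sd, correlation length um); deforms with the specimen.
#' @slot noiseGain Poisson gain (photons per intensity unit; 0 = off).
#' @slot noiseSigmaRead Gaussian read-noise sd (intensity units; 0 = off).
#' @slot seed integer seed; fully determines the phantom. Geometry and noise
#'   use two sub-streams so noise can vary at fixed geometry.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(canvasUm = "numeric", pixelSize = "numeric", midline = "matrix",
                 bodyRadius = "numeric", bulge = "numeric", nerveRingS = "numeric",
                 nerveRingBrightness = "numeric", bodyIntensity = "numeric",
                 backgroundIntensity = "numeric", nNuclei = "numeric",
                 nucleusAxes = "numeric", nucleusDepth = "numeric",
                 nPuncta = "numeric", punctaMinSpacing = "numeric",
                 punctaAmplitude = "numeric", psfSigma = "numeric",
                 eTrue = "numeric", thetaPost = "numeric", translationPost = "numeric",
                 sigmaD = "numeric", ell = "numeric",
                 textureAmplitude = "numeric", textureEll = "numeric",
                 noiseGain = "numeric", noiseSigmaRead = "numeric", seed = "numeric"),
  validity = function(object) {
    geom <- c(object@canvasUm, object@pixelSize, object@bodyRadius,
              object@nucleusAxes, object@punctaMinSpacing, object@ell)
    if (any(geom <= 0)) return("geometric parameters must be positive")
    if (object@sigmaD < 0) return("sigmaD must be >= 0")
    if (object@eTrue <= 0) return("eTrue must be > 0")
    if (nrow(object@midline) < 3) return("midline needs >= 3 control points")
    TRUE
  })

#' PhantomTruth: ground truth emitted with each phantom
#'
#' @slot deformation \linkS4class{GroundTruthDeformation}.
#' @slot punctaPre,punctaPost puncta coordinates (n x 2, (y, x) um;
#'   pre in biological um, post in absolute post-frame um).
#' @slot foregroundMask,nucleiMask,signalMask,backgroundMask masks on the
#'   pre-frame grid.
#' @slot midlineLengthPre,midlineLengthPost worm midline arc lengths (um).
#' @slot gelContourPre,gelContourPost gel contour lengths (um).
#' @slot spots per-spot truth table (data.frame) for 3D FISH phantoms.
#' @slot cellCounts per-cell truth counts (data.frame).
#' @exportClass PhantomTruth
setClass("PhantomTruth",
  representation(deformation = "GroundTruthDeformation",
                 punctaPre = "matrix", punctaPost = "matrix",
                 foregroundMask = "Mask", nucleiMask = "Mask",
                 signalMask = "Mask", backgroundMask = "Mask",
                 midlineLengthPre = "numeric", midlineLengthPost = "numeric",
                 gelContourPre = "numeric", gelContourPost = "numeric",
                 spots = "data.frame", cellCounts = "data.frame"))
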