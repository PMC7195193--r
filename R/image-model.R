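#' Construct an ImageField
#'
#' @param data numeric matrix (y, x) or 3D array (z, y, x) of non-negative
#'   intensities.
#' @param pixelSize physical pixel size in micrometres (absolute,
#'   post-expansion units). Either one value per axis or a scalar that is
#'   recycled; confocal stacks routinely have a coarser z step than xy.
#' @param expansionFactor linear expansion state E (> 0); 1 = pre-expansion.
#' @param channelLabel free-text channel annotation.
#' @return An \linkS4class{ImageField}.
#' @examples
#' img <- imageField(matrix(0, 64, 64), pixelSize = 0.1625)
#' pixelSize(img)
#' @export
imageField <- function(data, pixelSize, expansionFactor = 1, channelLabel = "") {
  data <- as.array(data)
  if (length(pixelSize) == 1) pixelSize <- rep(pixelSize, length(dim(data)))
  new("ImageField", data = data, pixelSize = as.numeric(pixelSize),
      expansionFactor = as.numeric(expansionFactor),
      channelLabel = as.character(channelLabel))
}

#' Construct a Mask congruent with a parent image
#'
#' @param data logical array.
#' @param role one of "signal", "background", "foreground".
#' @param parent optional \linkS4class{ImageField}; shape is checked.
#' @return A \linkS4class{Mask}.
#' @export
mask <- function(data, role = c("foreground", "signal", "background"),
                 parent = NULL) {
  role <- match.arg(role)
  data <- as.array(data)
  if (!is.null(parent) && !identical(dim(data), dim(imgData(parent))))
    stop("mask shape must match the parent image")
  new("Mask", data = data, role = role)
}

#' Construct a 3D ROI bounding box
#'
#' Coordinates are 0-based voxel indices in (z, y, x) order; both corners
#' are inside the box (inclusive bounds, matching "bounding box enclosing"
#' semantics).
#'
#' @param minCorner,maxCorner length-3 integer vectors (z, y, x).
#' @param label cell identity string.
#' @return A \linkS4class{RoiBox3D}.
#' @export
roiBox3D <- function(minCorner, maxCorner, label = "") {
  new("RoiBox3D", minCorner = as.numeric(minCorner),
      maxCorner = as.numeric(maxCorner), label = as.character(label))
}

#' Read a TIFF image into an ImageField
#'
#' Reads single- or multi-page TIFF (uint8/uint16/float32). Multi-page
#' files become 3D arrays in (z, y, x) order. Integer data are returned on
#' their native scale (not normalized).
#'
#' @param path TIFF file path.
#' @param pixelSize,expansionFactor,channelLabel metadata attached to the
#'   result; see \code{\link{imageField}}. The expansion factor is carried
#'   as metadata and never inferred from the image.
#' @return An \linkS4class{ImageField}.
#' @export
readImageField <- function(path, pixelSize, expansionFactor = 1,
                           channelLabel = "") {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  if (any(pixelSize <= 0) || expansionFactor <= 0)
    stop("pixelSize and expansionFactor must be positive")
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  ## integer TIFFs (8/16 bit) arrive scaled to [0, 1]; restore the native
  ## scale. 32-bit pages are floating point and pass through unchanged.
  pages <- lapply(pages, function(p) {
    bps <- attr(p, "bits.per.sample")
    if (is.null(bps)) bps <- 16
    if (bps < 32) p <- round(p * (2^bps - 1))
    attributes(p) <- list(dim = dim(p))
    p
  })
  if (length(pages) == 1) {
    data <- pages[[1]]
  } else {
    data <- array(0, c(length(pages), dim(pages[[1]])))
    for (i in seq_along(pages)) data[i, , ] <- pages[[i]]
  }
  imageField(data, pixelSize = pixelSize, expansionFactor = expansionFactor,
             channelLabel = channelLabel)
}

#' Write an ImageField to TIFF
#'
#' 3D images are written as multi-page TIFF (one page per z plane).
#'
#' @param img an \linkS4class{ImageField}.
#' @param path output path.
#' @param bitsPerSample 8 or 16 for integer data, 32 for float32.
#' @return \code{path}, invisibly.
#' @export
writeImageField <- function(img, path, bitsPerSample = 16) {
  a <- imgData(img)
  if (bitsPerSample == 32) {
    scale <- 1
  } else {
    scale <- 2^bitsPerSample - 1
    if (max(a) > scale || any(a != round(a)))
      stop("integer TIFF output needs integer intensities within range; ",
           "use bitsPerSample = 32 for float data")
  }
  toPage <- function(m) m / scale
  if (length(dim(a)) == 2) {
    tiff::writeTIFF(toPage(a), path, bits.per.sample = bitsPerSample)
  } else {
    pages <- lapply(seq_len(dim(a)[1]), function(z) toPage(a[z, , ]))
    tiff::writeTIFF(pages, path, bits.per.sample = bitsPerSample)
  }
  invisible(path)
}

#' Convert a pixel length to biological micrometres
#'
#' Biological (pre-expansion) length of a pixel span: pixel count times the
#' physical pixel size divided by the expansion factor, the convention used
#' throughout expansion microscopy ("post-expansion lengths are divided by
#' the expansion factor").
#'
#' @param lengthPx pixel count (>= 0), vectorized.
#' @param img an \linkS4class{ImageField} supplying pixel size and E.
#' @param axis which axis's pixel size to use ("x", "y" or "z").
#' @return length in micrometres on the pre-expansion scale.
#' @examples
#' img <- imageField(matrix(0, 8, 8), pixelSize = 0.2, expansionFactor = 4)
#' toBiologicalUnits(100, img)  # 5 um
#' @export
toBiologicalUnits <- function(lengthPx, img, axis = "x") {
  stopifnot(all(lengthPx >= 0))
  nd <- length(dim(imgData(img)))
  ax <- match(axis, if (nd == 3) c("z", "y", "x") else c("y", "x"))
  if (is.na(ax)) stop("unknown axis '", axis, "' for this image")
  lengthPx * pixelSize(img)[ax] / expansionFactor(img)
}

## Read an ROI table (label, zmin, ymin, xmin, zmax, ymax, xmax; 0-based,
## inclusive) into a list of RoiBox3D.
#' Read 3D ROI boxes from a CSV table
#'
#' Expects columns label, zmin, ymin, xmin, zmax, ymax, xmax with 0-based,
#' inclusive voxel coordinates.
#'
#' @param path CSV path.
#' @return list of \linkS4class{RoiBox3D}.
#' @export
readRoiCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "zmin", "ymin", "xmin", "zmax", "ymax", "xmax")
  if (!all(need %in% names(df)))
    stop("ROI table must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    roiBox3D(c(df$zmin[i], df$ymin[i], df$xmin[i]),
             c(df$zmax[i], df$ymax[i], df$xmax[i]), df$label[i]))
}
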