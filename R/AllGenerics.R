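#' Channel names of a MultiplexImage
#' @param x a [MultiplexImage-class].
#' @return character vector of channel names.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Extract one channel as a matrix
#' @param x a [MultiplexImage-class].
#' @param name channel name.
#' @return numeric matrix of intensities.
#' @export
setGeneric("getChannel", function(x, name) standardGeneric("getChannel"))

#' Physical pixel size in micrometres
#' @param x an object with a pixel size.
#' @return numeric scalar (micrometres per pixel).
#' @export
setGeneric("pixelSizeUm", function(x) standardGeneric("pixelSizeUm"))

#' Name of the nuclei counterstain channel
#' @param x a [MultiplexImage-class].
#' @return character scalar.
#' @export
setGeneric("nucleiChannel", function(x) standardGeneric("nucleiChannel"))

#' Ground-truth components of a synthetic phantom
#' @param x a [TissuePhantom-class].
#' @param what one of "nuclei", "cells", "islets", "cellTruth",
#'   "intensities", "params".
#' @return the requested component.
#' @export
setGeneric("groundTruth", function(x, what) standardGeneric("groundTruth"))

#' Invert a spatial transform
#' @param x a [RigidTransform-class].
#' @return the inverse transform.
#' @export
setGeneric("invertTransform", function(x) standardGeneric("invertTransform"))

#' @describeIn MultiplexImage-class channel names
#' @param x a MultiplexImage.
#' @export
setMethod("channelNames", "MultiplexImage", function(x) names(x@channels))

#' @describeIn MultiplexImage-class extract one channel matrix
#' @param name channel name.
#' @export
setMethod("getChannel", "MultiplexImage", function(x, name) {
  if (!name %in% names(x@channels))
    stop("unknown channel: ", name)
  x@channels[[name]]
})

#' @describeIn MultiplexImage-class pixel size in micrometres
#' @export
setMethod("pixelSizeUm", "MultiplexImage", function(x) x@pixelSizeUm)

#' @describeIn MultiplexImage-class nuclei channel name
#' @export
setMethod("nucleiChannel", "MultiplexImage", function(x) x@nucleiChannel)

#' @describeIn MultiplexImage-class image dimensions (rows, cols)
#' @export
setMethod("dim", "MultiplexImage", function(x) dim(x@channels[[1]]))

setMethod("show", "MultiplexImage", function(object) {
  d <- dim(object)
  cat("MultiplexImage '", object@roundId, "': ", d[1], " x ", d[2],
      " px (", signif(object@pixelSizeUm, 4), " um/px)\n", sep = "")
  cat("  channels (", length(object@channels), "): ",
      paste(names(object@channels), collapse = ", "), "\n", sep = "")
  cat("  nuclei channel: ", object@nucleiChannel, "\n", sep = "")
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf(
    "RigidTransform: theta = %.4f deg, t = (%.3f, %.3f) px, scale = %.4f\n",
    object@thetaRad * 180 / pi, object@tyPx, object@txPx, object@scale))
})

setMethod("show", "DeformationGrid", function(object) {
  cat(sprintf(
    "DeformationGrid: %d x %d nodes, step %g px, max |d| = %.3f px\n",
    nrow(object@dy), ncol(object@dy), object@stepPx,
    max(sqrt(object@dy^2 + object@dx^2))))
})

setMethod("show", "TissuePhantom", function(object) {
  cat("TissuePhantom:", nrow(object@cellTruth), "cells,",
      max(object@isletLabels), "islets\n")
  show(object@image)
})

#' @describeIn TissuePhantom-class extract ground-truth components
#' @param what component name.
#' @export
setMethod("groundTruth", "TissuePhantom", function(x, what = c(
    "nuclei", "cells", "islets", "cellTruth", "intensities", "params")) {
  what <- match.arg(what)
  switch(what,
    nuclei = x@nucleusLabels,
    cells = x@cellLabels,
    islets = x@isletLabels,
    cellTruth = x@cellTruth,
    intensities = x@intensities,
    params = x@params
  )
})

#' @describeIn RigidTransform-class inverse transform (scale 1 only when the
#'   forward scale is 1)
#' @export
setMethod("invertTransform", "RigidTransform", function(x) {
  # p' = s R (p - c) + c + t  =>  p = R' (p' - c - t) / s + c
  s <- 1 / x@scale
  th <- -x@thetaRad
  # express inverse in the same parametric form: rotate by -theta, scale 1/s,
  # translation chosen so that composing the two gives the identity
  tv <- c(x@tyPx, x@txPx)
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  tinv <- -s * (rot %*% tv)
  RigidTransform(thetaRad = th, tyPx = tinv[1], txPx = tinv[2], scale = s)
})
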