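#' @import methods
NULL

#' MultiplexImage: one imaging round of a multiplexed acquisition
#'
#' Container for the named 2D intensity channels of a single imaging round,
#' together with the physical pixel size and the name of the nuclei
#' (counterstain) channel used for registration and segmentation.
#'
#' @slot roundId character scalar identifying the round.
#' @slot channels named list of numeric matrices, all with identical
#'   dimensions; values are non-negative intensities in arbitrary units.
#' @slot pixelSizeUm positive numeric scalar, physical size of one pixel in
#'   micrometres (default acquisition setting is 0.65).
#' @slot nucleiChannel name of the channel holding the nuclei counterstain
#'   (DAPI or equivalent); must be one of `names(channels)`.
#'
#' @seealso [MultiplexImage()], [readMultiplexImage()], [getChannel()]
#' @export
setClass("MultiplexImage",
  representation(
    roundId = "character",
    channels = "list",
    pixelSizeUm = "numeric",
    nucleiChannel = "character"
  )
)

setValidity("MultiplexImage", function(object) {
  ch <- object@channels
  if (length(ch) == 0) return("at least one channel is required")
  if (is.null(names(ch)) || any(!nzchar(names(ch))) || anyDuplicated(names(ch)))
    return("channels must have unique non-empty names")
  if (!all(vapply(ch, is.matrix, logical(1))))
    return("every channel must be a 2D matrix")
  dims <- vapply(ch, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    return("all channels must share identical height x width")
  if (length(object@pixelSizeUm) != 1 || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    return("pixelSizeUm must be a single positive number")
  if (length(object@nucleiChannel) != 1 ||
      !(object@nucleiChannel %in% names(ch)))
    return("nucleiChannel must name one of the channels")
  TRUE
})

#' Construct a MultiplexImage
#'
#' @param channels named list of equally sized numeric matrices.
#' @param pixelSizeUm physical pixel size in micrometres.
#' @param nucleiChannel name of the nuclei counterstain channel; defaults to
#'   the first channel.
#' @param roundId identifier for the imaging round.
#' @return A [MultiplexImage-class] object.
#' @examples
#' img <- MultiplexImage(
#'   channels = list(DAPI = matrix(runif(64), 8, 8),
#'                   CY3  = matrix(runif(64), 8, 8)),
#'   pixelSizeUm = 0.65
#' )
#' channelNames(img)
#' @export
MultiplexImage <- function(channels, pixelSizeUm = 0.65,
                           nucleiChannel = names(channels)[1],
                           roundId = "round1") {
  channels <- lapply(channels, function(m) {
    storage.mode(m) <- "double"
    m
  })
  new("MultiplexImage", roundId = roundId, channels = channels,
      pixelSizeUm = as.numeric(pixelSizeUm),
      nucleiChannel = nucleiChannel)
}

#' RigidTransform: global rigid alignment parameters
#'
#' A rotation about the image centre, a translation and an optional isotropic
#' scale (used when aligning modalities acquired at different pixel sizes).
#' The transform maps 0-based (row, col) coordinates `p` of the fixed frame to
#' sampling positions in the moving frame:
#' `scale * Rot(theta) (p - c) + c + (ty, tx)` with `c` the image centre.
#'
#' @slot thetaRad rotation angle in radians.
#' @slot txPx,tyPx translation in pixels (column and row direction).
#' @slot scale isotropic scale ratio (1 for same-resolution rounds).
#' @export
setClass("RigidTransform",
  representation(thetaRad = "numeric", txPx = "numeric", tyPx = "numeric",
                 scale = "numeric"),
  prototype(thetaRad = 0, txPx = 0, tyPx = 0, scale = 1)
)

setValidity("RigidTransform", function(object) {
  v <- c(object@thetaRad, object@txPx, object@tyPx, object@scale)
  if (length(v) != 4 || any(!is.finite(v))) return("parameters must be finite scalars")
  if (object@scale <= 0) return("scale must be > 0")
  TRUE
})

#' @rdname RigidTransform-class
#' @param thetaRad,txPx,tyPx,scale transform parameters.
#' @return A [RigidTransform-class] object.
#' @export
RigidTransform <- function(thetaRad = 0, txPx = 0, tyPx = 0, scale = 1) {
  new("RigidTransform", thetaRad = as.numeric(thetaRad), txPx = as.numeric(txPx),
      tyPx = as.numeric(tyPx), scale = as.numeric(scale))
}

#' DeformationGrid: coarse grid of 2D displacements defining a smooth warp
#'
#' Displacements are stored at nodes of a regular grid (spacing `stepPx`,
#' origin at pixel (0, 0)); the dense field is obtained by bilinear
#' interpolation between nodes with clamped extrapolation beyond the last
#' node. A zero grid is the identity warp.
#'
#' @slot stepPx grid spacing in pixels (whole-slide default 500).
#' @slot dy,dx numeric matrices of per-node displacements (rows x cols of the
#'   node grid), in pixels.
#' @export
setClass("DeformationGrid",
  representation(stepPx = "numeric", dy = "matrix", dx = "matrix")
)

setValidity("DeformationGrid", function(object) {
  if (length(object@stepPx) != 1 || object@stepPx <= 0)
    return("stepPx must be a single positive number")
  if (!identical(dim(object@dy), dim(object@dx)))
    return("dy and dx node grids must have identical dimensions")
  if (any(!is.finite(object@dy)) || any(!is.finite(object@dx)))
    return("displacements must be finite")
  TRUE
})

#' @rdname DeformationGrid-class
#' @param stepPx grid spacing in pixels.
#' @param dy,dx matrices of node displacements (row and column components).
#' @return A [DeformationGrid-class] object.
#' @export
DeformationGrid <- function(stepPx = 500, dy, dx) {
  new("DeformationGrid", stepPx = as.numeric(stepPx),
      dy = as.matrix(dy), dx = as.matrix(dx))
}

#' TissuePhantom: synthetic tissue image with complete ground truth
#'
#' Output of [simulateTissue()]: a rendered [MultiplexImage-class] plus the
#' exact label maps, per-cell truth table and planted parameters against
#' which every downstream stage can be validated.
#'
#' @slot image the rendered multichannel image (one round).
#' @slot nucleusLabels,cellLabels,isletLabels integer label matrices
#'   (0 = background) for nuclei, tessellated cells and islets.
#' @slot cellTruth data.frame with one row per cell: `cell_id`, centroid
#'   (`y`, `x`, 0-based pixels), `cluster_id`, `subtype`, `compartment`.
#' @slot intensities numeric matrix (cells x markers) of the true per-cell
#'   marker intensities before rendering noise.
#' @slot params list of the generator parameters actually used.
#' @export
setClass("TissuePhantom",
  representation(
    image = "MultiplexImage",
    nucleusLabels = "matrix",
    cellLabels = "matrix",
    isletLabels = "matrix",
    cellTruth = "data.frame",
    intensities = "matrix",
    params = "list"
  )
)

setValidity("TissuePhantom", function(object) {
  ids <- sort(unique(as.vector(object@nucleusLabels)))
  ids <- ids[ids > 0]
  cids <- sort(unique(as.vector(object@cellLabels)))
  cids <- cids[cids > 0]
  if (!identical(ids, cids))
    return("every cell id must appear in both nucleus and cell label maps")
  if (nrow(object@cellTruth) != length(ids))
    return("cellTruth must have one row per labelled cell")
  TRUE
})
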