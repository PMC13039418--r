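# Nuclei-based cross-round registration: global rigid alignment estimated on
# down-sampled images, then local grid-based deformable registration on the
# full-resolution images (grid step 500 px by default).
#
# Transform convention: an estimated (rigid, deformation) pair aligns the
# moving image onto the fixed frame via
#     aligned(p) = moving( R(p + D(p)) ),
# where p are 0-based (row, col) pixel coordinates of the fixed frame, D is
# the bilinearly interpolated displacement field and
# R(q) = scale * Rot(theta) (q - c) + c + t about the image centre c.

rotMat <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# map 0-based (y, x) through a RigidTransform, centre from `shape`
mapRigid <- function(y, x, rigid, shape) {
  cy <- (shape[1] - 1) / 2
  cx <- (shape[2] - 1) / 2
  ct <- cos(rigid@thetaRad)
  st <- sin(rigid@thetaRad)
  dy <- y - cy
  dx <- x - cx
  list(
    y = rigid@scale * (ct * dy - st * dx) + cy + rigid@tyPx,
    x = rigid@scale * (st * dy + ct * dx) + cx + rigid@txPx
  )
}

# evaluate a DeformationGrid at 0-based (y, x) points (clamped extrapolation)
evalDeformation <- function(deform, y, x) {
  gy <- pmin(pmax(y / deform@stepPx, 0), nrow(deform@dy) - 1)
  gx <- pmin(pmax(x / deform@stepPx, 0), ncol(deform@dy) - 1)
  list(
    dy = bilinearSample(deform@dy, gy, gx),
    dx = bilinearSample(deform@dx, gy, gx)
  )
}

zeroDeformation <- function(shape, stepPx = 500) {
  nNodes <- function(n) floor((n - 1) / stepPx) + 1
  DeformationGrid(stepPx,
                  matrix(0, nNodes(shape[1]), nNodes(shape[2])),
                  matrix(0, nNodes(shape[1]), nNodes(shape[2])))
}

# raster-level warp: sample `img` at R(p + D(p)) for all target pixels
warpRaster <- function(img, rigid = NULL, deform = NULL, fill = 0) {
  shape <- dim(img)
  if (is.null(rigid)) rigid <- RigidTransform()
  resampleGrid(img, shape, function(y, x) {
    if (!is.null(deform)) {
      d <- evalDeformation(deform, y, x)
      y <- y + d$dy
      x <- x + d$dx
    }
    mapRigid(y, x, rigid, shape)
  }, fill = fill)
}

#' Rescale an image to a target physical pixel size
#'
#' Used before cross-modality registration so that both images share a common
#' pixel grid. Interpolation is bilinear; the output extent covers the same
#' physical field of view.
#'
#' @param image a [MultiplexImage-class].
#' @param targetUm desired pixel size in micrometres.
#' @return A [MultiplexImage-class] with `pixelSizeUm = targetUm`.
#' @export
rescaleToPixelSize <- function(image, targetUm) {
  stopifnot(is(image, "MultiplexImage"))
  if (!is.finite(targetUm) || targetUm <= 0) stop("targetUm must be positive")
  if (targetUm == image@pixelSizeUm) return(image)
  ratio <- targetUm / image@pixelSizeUm
  shape <- dim(image)
  newShape <- c(max(1, round(shape[1] / ratio)), max(1, round(shape[2] / ratio)))
  chans <- lapply(image@channels, function(m) {
    resampleGrid(m, newShape, function(y, x) {
      list(y = pmin(y * ratio, shape[1] - 1), x = pmin(x * ratio, shape[2] - 1))
    })
  })
  MultiplexImage(chans, pixelSizeUm = targetUm,
                 nucleiChannel = image@nucleiChannel, roundId = image@roundId)
}

# rotate about the image centre (no translation) and cross-correlate:
# used for the rotation search in estimateRigid
rotationScore <- function(fixed, moving, theta, maxShift) {
  mrot <- warpRaster(moving, RigidTransform(thetaRad = theta))
  pk <- xcorrPeak(fixed, mrot, maxShift)
  if (is.null(pk)) return(list(score = -Inf))
  list(score = pk$ncc, dy = pk$dy, dx = pk$dx)
}

#' Estimate the global rigid transform between two nuclei images
#'
#' A coarse rotation search (±`maxRotationDeg`, step 0.25°) with
#' cross-correlation translation scoring is run on block-down-sampled images,
#' refined by a finer rotation pass at a quarter of the down-sampling, and
#' finished with a translation-only correlation at full resolution with
#' sub-pixel (parabolic) peak interpolation.
#'
#' @param fixed,moving numeric matrices (nuclei channel), same pixel size.
#' @param downsample integer down-sampling factor for the coarse search.
#' @param maxRotationDeg half-width of the rotation search range (degrees).
#' @param coarseStepDeg,fineStepDeg rotation search steps (degrees).
#' @param maxShiftPx largest translation magnitude considered, full-res px.
#' @return A [RigidTransform-class] mapping the fixed frame onto the moving
#'   image (use with [applyTransform()] to align the moving image).
#' @export
estimateRigid <- function(fixed, moving, downsample = 10,
                          maxRotationDeg = 10, coarseStepDeg = 0.25,
                          fineStepDeg = 0.05, maxShiftPx = 80) {
  if (stats::sd(fixed) == 0 || stats::sd(moving) == 0)
    stop("cannot estimate a rigid transform from a constant image")
  if (!identical(dim(fixed), dim(moving)))
    stop("fixed and moving images must have the same dimensions")
  dsc <- max(1L, as.integer(downsample))
  fds <- blockDownsize(fixed, dsc)
  mds <- blockDownsize(moving, dsc)
  msc <- max(3, ceiling(maxShiftPx / dsc))
  coarse <- seq(-maxRotationDeg, maxRotationDeg, by = coarseStepDeg) * pi / 180
  scores <- vapply(coarse, function(th)
    rotationScore(fds, mds, th, msc)$score, numeric(1))
  theta0 <- coarse[which.max(scores)]
  # fine rotation pass at a finer scale around the coarse optimum
  dsf <- max(1L, as.integer(round(dsc / 2.5)))
  ffs <- blockDownsize(fixed, dsf)
  mfs <- blockDownsize(moving, dsf)
  msf <- max(3, ceiling(maxShiftPx / dsf))
  fine <- seq(theta0 - 2 * coarseStepDeg * pi / 180,
              theta0 + 2 * coarseStepDeg * pi / 180,
              by = fineStepDeg * pi / 180)
  fineScores <- vapply(fine, function(th)
    rotationScore(ffs, mfs, th, msf)$score, numeric(1))
  ib <- which.max(fineScores)
  theta <- fine[ib]
  # parabolic refinement over the rotation score
  if (ib > 1 && ib < length(fine)) {
    den <- fineScores[ib - 1] - 2 * fineScores[ib] + fineScores[ib + 1]
    if (den < 0) {
      off <- 0.5 * (fineScores[ib - 1] - fineScores[ib + 1]) / den
      theta <- theta + max(-1, min(1, off)) * fineStepDeg * pi / 180
    }
  }
  # translation-only refinement at full resolution
  mrot <- warpRaster(moving, RigidTransform(thetaRad = theta))
  pk <- xcorrPeak(fixed, mrot, maxShiftPx)
  if (is.null(pk)) stop("translation refinement failed (degenerate overlap)")
  tvec <- rotMat(theta) %*% c(pk$dy, pk$dx)
  RigidTransform(thetaRad = theta, tyPx = tvec[1], txPx = tvec[2], scale = 1)
}

#' Estimate a grid deformation field between pre-aligned images
#'
#' For every node of a regular grid (spacing `stepPx`) a window of side
#' `windowPx` centred on the node is cross-correlated between the fixed and
#' the rigid-aligned moving image; the sub-pixel correlation peak gives the
#' node displacement. Nodes whose normalised correlation peak falls below
#' `minNcc` (featureless tiles) inherit the interpolated value of their valid
#' neighbours rather than an unstable vector.
#'
#' Because the correlation window spans the whole inter-node spacing, a
#' single pass measures a window-averaged displacement; the estimate is
#' therefore refined iteratively (warp by the current field, re-measure the
#' per-node residual, update) until the node updates fall below 0.05 px or
#' `iterations` passes have run.
#'
#' @param fixed,movingAligned numeric matrices, already rigidly aligned.
#' @param stepPx grid spacing (>= 64; whole-slide default 500).
#' @param windowPx correlation window side (default `stepPx`).
#' @param maxShiftPx largest per-node displacement searched.
#' @param minNcc confidence floor on the normalised correlation peak.
#' @param iterations maximum number of refinement passes.
#' @return A [DeformationGrid-class].
#' @export
estimateDeformation <- function(fixed, movingAligned, stepPx = 500,
                                windowPx = stepPx, maxShiftPx = 32,
                                minNcc = 0.3, iterations = 4) {
  if (!identical(dim(fixed), dim(movingAligned)))
    stop("images must have the same dimensions")
  if (stepPx < 64) stop("stepPx must be >= 64")
  nr <- nrow(fixed)
  nc <- ncol(fixed)
  if (nr < windowPx / 2 || nc < windowPx / 2)
    stop("image is smaller than one correlation tile")
  ys <- seq(0, nr - 1, by = stepPx)
  xs <- seq(0, nc - 1, by = stepPx)
  grid <- DeformationGrid(stepPx,
                          matrix(0, length(ys), length(xs)),
                          matrix(0, length(ys), length(xs)))
  warped <- movingAligned
  for (pass in seq_len(max(1, iterations))) {
    res <- deformationPass(fixed, warped, ys, xs, windowPx, maxShiftPx, minNcc)
    if (pass == 1) {
      valid <- res$valid  # confidence of the direct (unwarped) measurement
    }
    grid <- DeformationGrid(stepPx, grid@dy + res$dy, grid@dx + res$dx)
    if (max(abs(c(res$dy, res$dx))) < 0.05) break
    if (pass < iterations)
      warped <- warpRaster(movingAligned, deform = grid)
  }
  dy <- grid@dy
  dx <- grid@dx
  dy[!valid] <- NA_real_
  dx[!valid] <- NA_real_
  dy <- fillInvalidNodes(dy)
  dx <- fillInvalidNodes(dx)
  DeformationGrid(stepPx = stepPx, dy = dy, dx = dx)
}

# one sweep of per-node windowed cross-correlation
deformationPass <- function(fixed, moving, ys, xs, windowPx, maxShiftPx,
                            minNcc) {
  nr <- nrow(fixed)
  nc <- ncol(fixed)
  dy <- matrix(0, length(ys), length(xs))
  dx <- dy
  valid <- matrix(FALSE, length(ys), length(xs))
  half <- floor(windowPx / 2)
  for (i in seq_along(ys)) {
    for (j in seq_along(xs)) {
      r0 <- max(0, ys[i] - half)
      r1 <- min(nr - 1, ys[i] + half)
      c0 <- max(0, xs[j] - half)
      c1 <- min(nc - 1, xs[j] + half)
      fw <- fixed[(r0 + 1):(r1 + 1), (c0 + 1):(c1 + 1), drop = FALSE]
      mw <- moving[(r0 + 1):(r1 + 1), (c0 + 1):(c1 + 1), drop = FALSE]
      pk <- xcorrPeak(fw, mw, min(maxShiftPx, floor(min(dim(fw)) / 3)))
      if (!is.null(pk) && pk$ncc >= minNcc) {
        # fixed(p) ~ moving(p + d): the node displacement is d
        dy[i, j] <- pk$dy
        dx[i, j] <- pk$dx
        valid[i, j] <- TRUE
      }
    }
  }
  list(dy = dy, dx = dx, valid = valid)
}

# replace NA nodes by iterated 4-neighbour averages of valid nodes
fillInvalidNodes <- function(g) {
  if (!anyNA(g)) return(g)
  if (all(is.na(g))) {
    g[] <- 0
    return(g)
  }
  nr <- nrow(g)
  nc <- ncol(g)
  for (iter in seq_len(nr * nc)) {
    nas <- which(is.na(g), arr.ind = TRUE)
    if (nrow(nas) == 0) break
    filledAny <- FALSE
    for (k in seq_len(nrow(nas))) {
      i <- nas[k, 1]
      j <- nas[k, 2]
      nb <- c(
        if (i > 1) g[i - 1, j], if (i < nr) g[i + 1, j],
        if (j > 1) g[i, j - 1], if (j < nc) g[i, j + 1]
      )
      nb <- nb[!is.na(nb)]
      if (length(nb)) {
        g[i, j] <- mean(nb)
        filledAny <- TRUE
      }
    }
    if (!filledAny) break
  }
  g[is.na(g)] <- 0
  g
}

#' Canonicalise a rigid + deformable transform pair
#'
#' The split between a rigid transform and a displacement grid is not unique:
#' a mean displacement is indistinguishable from translation and the
#' infinitesimal-rotation component of a smooth field from rigid rotation.
#' This helper makes the decomposition canonical by fitting the small-angle
#' rigid model `d(p) = t + w J (p - c)` to the dense displacement field,
#' folding the fitted translation/rotation into the rigid transform and
#' leaving a rigid-free residual grid. Estimated registrations are
#' canonicalised this way so their rigid parameters are directly comparable
#' across methods (the phantom generator plants rigid-free fields by the
#' same projection).
#'
#' @param rigid a [RigidTransform-class].
#' @param deformation a [DeformationGrid-class].
#' @param shape integer (rows, cols) of the image the transforms act on.
#' @return list with the adjusted `rigid` and `deformation`.
#' @export
canonicalizeTransforms <- function(rigid, deformation, shape) {
  qy <- rep(seq(0, shape[1] - 1, length.out = 64), times = 64)
  qx <- rep(seq(0, shape[2] - 1, length.out = 64), each = 64)
  d <- evalDeformation(deformation, qy, qx)
  cy <- (shape[1] - 1) / 2
  cx <- (shape[2] - 1) / 2
  ry <- qy - cy
  rx <- qx - cx
  w <- sum(ry * d$dx - rx * d$dy) / sum(ry^2 + rx^2)
  ty <- mean(d$dy + w * rx)
  tx <- mean(d$dx - w * ry)
  ny <- nrow(deformation@dy)
  nx <- ncol(deformation@dy)
  nodeY <- matrix(seq(0, by = deformation@stepPx, length.out = ny),
                  ny, nx) - cy
  nodeX <- matrix(seq(0, by = deformation@stepPx, length.out = nx),
                  ny, nx, byrow = TRUE) - cx
  resid <- DeformationGrid(deformation@stepPx,
                           deformation@dy - ty + w * nodeX,
                           deformation@dx - tx - w * nodeY)
  # fold the fitted component into the rigid parameters (first order in w)
  rot <- rotMat(rigid@thetaRad)
  tnew <- c(rigid@tyPx, rigid@txPx) + rot %*% c(ty, tx)
  list(
    rigid = RigidTransform(thetaRad = rigid@thetaRad + w,
                           tyPx = tnew[1], txPx = tnew[2],
                           scale = rigid@scale),
    deformation = resid
  )
}

#' Apply a rigid plus deformable transform to all channels of an image
#'
#' All channels are warped identically (`aligned(p) = moving(R(p + D(p)))`);
#' intensity interpolation is bilinear and out-of-domain pixels are 0.
#'
#' @param image a [MultiplexImage-class] (the moving image).
#' @param rigid a [RigidTransform-class] (or `NULL` for identity).
#' @param deformation a [DeformationGrid-class] (or `NULL` for none).
#' @return The aligned [MultiplexImage-class].
#' @export
applyTransform <- function(image, rigid = NULL, deformation = NULL) {
  stopifnot(is(image, "MultiplexImage"))
  chans <- lapply(image@channels, warpRaster, rigid = rigid,
                  deform = deformation)
  MultiplexImage(chans, pixelSizeUm = image@pixelSizeUm,
                 nucleiChannel = image@nucleiChannel,
                 roundId = image@roundId)
}

#' Register imaging rounds to a reference round
#'
#' For each non-reference round: rescale to the reference pixel size if
#' needed, estimate the global rigid transform on the nuclei channels,
#' estimate the residual grid deformation at full resolution, and warp all
#' channels. Errors in any stage are re-thrown with the offending round id.
#'
#' @param reference the reference [MultiplexImage-class].
#' @param others list of further [MultiplexImage-class] rounds.
#' @param stepPx deformation grid step (px).
#' @param downsample down-sampling factor of the coarse rigid search.
#' @param ... further arguments to [estimateRigid()].
#' @return list with elements `aligned` (list of aligned images) and
#'   `transforms` (per round: `list(rigid =, deformation =)`).
#' @export
registerRounds <- function(reference, others, stepPx = 500, downsample = 10,
                           ...) {
  stopifnot(is(reference, "MultiplexImage"))
  out <- list(aligned = list(), transforms = list())
  fnuc <- getChannel(reference, nucleiChannel(reference))
  for (i in seq_along(others)) {
    mv <- others[[i]]
    rid <- mv@roundId
    res <- tryCatch({
      if (mv@pixelSizeUm != reference@pixelSizeUm)
        mv <- rescaleToPixelSize(mv, reference@pixelSizeUm)
      mnuc <- getChannel(mv, nucleiChannel(mv))
      rigid <- estimateRigid(fnuc, mnuc, downsample = downsample, ...)
      mAligned <- warpRaster(mnuc, rigid)
      deform <- estimateDeformation(fnuc, mAligned, stepPx = stepPx)
      can <- canonicalizeTransforms(rigid, deform, dim(fnuc))
      list(aligned = applyTransform(mv, can$rigid, can$deformation),
           rigid = can$rigid, deformation = can$deformation)
    }, error = function(e) {
      stop("registration of round '", rid, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    out$aligned[[rid]] <- res$aligned
    out$transforms[[rid]] <- list(rigid = res$rigid,
                                  deformation = res$deformation)
  }
  out
}

#' Serialise / restore transforms as a structured text file
#'
#' @param transforms the `transforms` element of [registerRounds()] output.
#' @param path YAML file path.
#' @return `writeTransforms` returns `path` invisibly; `readTransforms`
#'   returns the transform list.
#' @export
writeTransforms <- function(transforms, path) {
  ser <- lapply(transforms, function(tr) list(
    rigid = list(thetaRad = tr$rigid@thetaRad, tyPx = tr$rigid@tyPx,
                 txPx = tr$rigid@txPx, scale = tr$rigid@scale),
    deformation = if (is.null(tr$deformation)) NULL else list(
      stepPx = tr$deformation@stepPx,
      nrow = nrow(tr$deformation@dy),
      dy = as.numeric(tr$deformation@dy),
      dx = as.numeric(tr$deformation@dx))
  ))
  yaml::write_yaml(ser, path, precision = 15L)
  invisible(path)
}

#' @rdname writeTransforms
#' @export
readTransforms <- function(path) {
  ser <- yaml::read_yaml(path)
  lapply(ser, function(tr) list(
    rigid = RigidTransform(tr$rigid$thetaRad, tr$rigid$txPx, tr$rigid$tyPx,
                           tr$rigid$scale),
    deformation = if (is.null(tr$deformation)) NULL else DeformationGrid(
      tr$deformation$stepPx,
      matrix(tr$deformation$dy, nrow = tr$deformation$nrow),
      matrix(tr$deformation$dx, nrow = tr$deformation$nrow))
  ))
}
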