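# Synthetic tissue phantoms with complete ground truth.
#
# The generator renders a multichannel fluorescence round from known
# primitives — non-overlapping elliptical nuclei, bounded-expansion cell
# regions, disk-shaped islets, per-cell marker intensities drawn from
# mixture profiles, a smooth low-frequency background field and shot-like
# noise applied last — and returns the exact label maps, cluster identities
# and planted parameters alongside the image.

#' Default mixture profiles of the image phantom
#'
#' Acinar (exocrine) cells are mostly marker-low with a 53BP1-enriched
#' subpopulation; islet (endocrine) cells are an insulin+/glucagon+/SST-28+
#' mixture with elevated P16 and 53BP1, mirroring the compartment structure
#' of pancreatic tissue.
#'
#' @return list with `markers`, `localization`, `acinar` and `islet`
#'   profile lists (each profile: `name`, `subtype`, `mean`, `sd`, `weight`).
#' @export
defaultPhantomProfiles <- function() {
  markers <- c("INS", "GCG", "SST", "P16", "53BP1")
  mk <- function(...) {
    v <- c(...)
    stats::setNames(v, markers)
  }
  list(
    markers = markers,
    localization = c(INS = "cytosolic", GCG = "cytosolic", SST = "cytosolic",
                     P16 = "cytosolic", `53BP1` = "nuclear"),
    acinar = list(
      list(name = "acinar_low", subtype = "negative",
           mean = mk(5, 5, 5, 8, 10), sd = mk(2, 2, 2, 3, 4), weight = 0.7),
      list(name = "acinar_53BP1", subtype = "negative",
           mean = mk(5, 5, 5, 8, 80), sd = mk(2, 2, 2, 3, 12), weight = 0.3)
    ),
    islet = list(
      list(name = "beta", subtype = "Insulin+",
           mean = mk(150, 12, 12, 40, 60), sd = mk(20, 4, 4, 10, 10),
           weight = 0.55),
      list(name = "alpha", subtype = "Glucagon+",
           mean = mk(12, 150, 12, 40, 60), sd = mk(4, 20, 4, 10, 10),
           weight = 0.30),
      list(name = "delta", subtype = "SST-28+",
           mean = mk(12, 12, 150, 40, 60), sd = mk(4, 4, 20, 10, 10),
           weight = 0.15)
    )
  )
}

#' Configuration of the tissue phantom generator
#'
#' @param imageSizePx integer (rows, cols) of the rendered image.
#' @param nCells number of cells to place.
#' @param pixelSizeUm physical pixel size (µm).
#' @param nucleusRadiusRangeUm range of nucleus semi-major axes (µm).
#' @param expansionUm cell-boundary expansion used for the ground-truth cell
#'   tessellation (µm).
#' @param profiles marker panel and mixture profiles
#'   (see [defaultPhantomProfiles()]).
#' @param nIslets number of disk-shaped islets to place (ignored when
#'   `islets` is given).
#' @param isletRadiusRangeUm range of islet radii (µm).
#' @param islets optional data.frame (`y`, `x`, `radius_um`) of explicit
#'   islet placements, 0-based pixel centres.
#' @param isletCellDensityFactor relative cell density inside islets versus
#'   the surrounding tissue. Islets are compact clusters of endocrine
#'   cells, so their cell density is substantially higher than the acinar
#'   background; this also makes the rendered hormone staining contiguous.
#' @param backgroundAmplitude peak amplitude of the smooth autofluorescence
#'   background field (intensity units; 0 disables it).
#' @param backgroundScalePx correlation length of the background field (px).
#' @param noiseSd base standard deviation of the shot-like noise (the
#'   per-pixel SD is `noiseSd * sqrt(1 + I / shotScale)`; 0 disables noise).
#' @param shotScale intensity scale of the shot-noise variance growth.
#' @param nucleiIntensityRange per-nucleus counterstain brightness range.
#' @param plantedIsletCorrelation optional target Pearson r between islet
#'   area and the per-islet `correlationMarker` mean level.
#' @param correlationMarker marker carrying the planted islet-level
#'   correlation (default P16).
#' @param seed random seed; all generator randomness derives from it.
#' @return a validated list of class `TissuePhantomConfig`.
#' @export
phantomConfig <- function(imageSizePx = c(512L, 512L),
                          nCells = 250L,
                          pixelSizeUm = 0.65,
                          nucleusRadiusRangeUm = c(2.5, 4.5),
                          expansionUm = 4.5,
                          profiles = defaultPhantomProfiles(),
                          nIslets = 2L,
                          isletRadiusRangeUm = c(35, 60),
                          islets = NULL,
                          isletCellDensityFactor = 8,
                          backgroundAmplitude = 8,
                          backgroundScalePx = 128,
                          noiseSd = 2,
                          shotScale = 50,
                          nucleiIntensityRange = c(120, 250),
                          plantedIsletCorrelation = NULL,
                          correlationMarker = "P16",
                          seed = 1L) {
  cfg <- list(
    imageSizePx = as.integer(imageSizePx), nCells = as.integer(nCells),
    pixelSizeUm = pixelSizeUm, nucleusRadiusRangeUm = nucleusRadiusRangeUm,
    expansionUm = expansionUm, profiles = profiles, nIslets = as.integer(nIslets),
    isletRadiusRangeUm = isletRadiusRangeUm, islets = islets,
    isletCellDensityFactor = isletCellDensityFactor,
    backgroundAmplitude = backgroundAmplitude,
    backgroundScalePx = backgroundScalePx, noiseSd = noiseSd,
    shotScale = shotScale, nucleiIntensityRange = nucleiIntensityRange,
    plantedIsletCorrelation = plantedIsletCorrelation,
    correlationMarker = correlationMarker, seed = as.integer(seed)
  )
  if (is.null(profiles)) {
    # nuclei-only phantom (registration benchmarks): no marker channels
    profiles <- list(markers = character(0), localization = character(0),
                     acinar = list(), islet = list())
    cfg$profiles <- profiles
  }
  if (length(profiles$acinar)) {
    w <- vapply(profiles$acinar, `[[`, numeric(1), "weight")
    if (abs(sum(w) - 1) > 1e-8)
      stop("acinar profile mixture weights must sum to 1")
  }
  if (length(profiles$islet)) {
    wi <- vapply(profiles$islet, `[[`, numeric(1), "weight")
    if (abs(sum(wi) - 1) > 1e-8)
      stop("islet profile mixture weights must sum to 1")
  }
  if (cfg$nCells < 0) stop("nCells must be >= 0")
  if (any(nucleusRadiusRangeUm <= 0)) stop("nucleus radii must be positive")
  if (pixelSizeUm <= 0) stop("pixelSizeUm must be positive")
  class(cfg) <- "TissuePhantomConfig"
  cfg
}

# rasterise one ellipse; returns linear indices into an nr x nc matrix
ellipseIndices <- function(cy, cx, a, b, phi, nr, nc) {
  r <- ceiling(a)
  ys <- max(0, floor(cy - r)):min(nr - 1, ceiling(cy + r))
  xs <- max(0, floor(cx - r)):min(nc - 1, ceiling(cx + r))
  yy <- rep(ys, times = length(xs))
  xx <- rep(xs, each = length(ys))
  dy <- yy - cy
  dx <- xx - cx
  u <- dy * cos(phi) + dx * sin(phi)
  v <- -dy * sin(phi) + dx * cos(phi)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  (xx[inside]) * nr + yy[inside] + 1
}

# non-overlapping placement with a coarse grid hash; bounded retries.
# When an islet table and a sampling probability are given, that share of
# candidate positions is drawn uniformly inside a (area-weighted) random
# islet disk, giving islets their characteristic high cell density.
placeNuclei <- function(n, nr, nc, rRange, margin, maxTries = 200L,
                        isletDf = NULL, pIslet = 0) {
  if (n == 0)
    return(data.frame(y = numeric(0), x = numeric(0), a = numeric(0),
                      b = numeric(0), phi = numeric(0)))
  rmax <- rRange[2]
  binSize <- 2 * rmax + 2
  nby <- max(1, ceiling(nr / binSize))
  nbx <- max(1, ceiling(nc / binSize))
  bins <- vector("list", nby * nbx)
  ys <- xs <- as <- bs <- phis <- numeric(n)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > maxTries * n)
      stop("could not place ", n, " non-overlapping nuclei (capacity error)")
    a <- stats::runif(1, rRange[1], rRange[2])
    b <- a * stats::runif(1, 0.65, 1)
    if (!is.null(isletDf) && nrow(isletDf) && stats::runif(1) < pIslet) {
      w <- isletDf$radius_px^2
      k <- sample.int(nrow(isletDf), 1, prob = w / sum(w))
      rr <- (isletDf$radius_px[k] - 1) * sqrt(stats::runif(1))
      ang <- stats::runif(1, 0, 2 * pi)
      y <- min(max(isletDf$y[k] + rr * sin(ang), margin), nr - 1 - margin)
      x <- min(max(isletDf$x[k] + rr * cos(ang), margin), nc - 1 - margin)
    } else {
      y <- stats::runif(1, margin, nr - 1 - margin)
      x <- stats::runif(1, margin, nc - 1 - margin)
    }
    by <- min(nby, max(1, ceiling((y + 1) / binSize)))
    bx <- min(nbx, max(1, ceiling((x + 1) / binSize)))
    ok <- TRUE
    for (jy in max(1, by - 1):min(nby, by + 1)) {
      for (jx in max(1, bx - 1):min(nbx, bx + 1)) {
        for (i in bins[[(jx - 1) * nby + jy]]) {
          if ((ys[i] - y)^2 + (xs[i] - x)^2 < (as[i] + a + 1)^2) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
      if (!ok) break
    }
    if (!ok) next
    placed <- placed + 1L
    ys[placed] <- y
    xs[placed] <- x
    as[placed] <- a
    bs[placed] <- b
    phis[placed] <- stats::runif(1, 0, pi)
    bins[[(bx - 1) * nby + by]] <- c(bins[[(bx - 1) * nby + by]], placed)
  }
  data.frame(y = ys, x = xs, a = as, b = bs, phi = phis)
}

# smooth low-frequency field in [lo, hi] * amplitude via a coarse random
# grid upsampled bilinearly
smoothField <- function(shape, scalePx, amplitude) {
  nn <- pmax(2L, ceiling(shape / scalePx) + 1L)
  coarse <- matrix(stats::runif(prod(nn), 0.2, 1), nn[1], nn[2]) * amplitude
  blockUpsize(coarse, shape, scalePx)
}

#' Generate a synthetic tissue phantom with full ground truth
#'
#' Deterministic given `config$seed`. Nuclei are non-overlapping ellipses;
#' the ground-truth cell map is the bounded expansion tessellation of the
#' nuclei; islets are disks; each cell's marker vector is drawn from its
#' compartment's mixture profile and rendered into the nucleus (nuclear
#' markers) or the cytosolic annulus between nucleus and cell boundary
#' (cytosolic markers); the smooth background field is added and shot-like
#' noise is applied last, so the ground truth is exact for the noiseless
#' image.
#'
#' @param config a `TissuePhantomConfig` from [phantomConfig()].
#' @return A [TissuePhantom-class].
#' @examples
#' ph <- simulateTissue(phantomConfig(imageSizePx = c(256, 256),
#'                                    nCells = 60, seed = 7))
#' ph
#' @export
simulateTissue <- function(config) {
  stopifnot(inherits(config, "TissuePhantomConfig"))
  set.seed(config$seed)
  nr <- config$imageSizePx[1]
  nc <- config$imageSizePx[2]
  px <- config$pixelSizeUm
  rRangePx <- config$nucleusRadiusRangeUm / px
  expPx <- as.integer(floor(config$expansionUm / px + 0.5))
  margin <- ceiling(rRangePx[2] + expPx + 2)
  markers <- config$profiles$markers
  loc <- config$profiles$localization
  # islet placement
  islets <- config$islets
  if (is.null(islets) && config$nIslets > 0) {
    rads <- stats::runif(config$nIslets, config$isletRadiusRangeUm[1],
                         config$isletRadiusRangeUm[2]) / px
    ctr <- matrix(NA_real_, 0, 2)
    guard <- 0
    while (nrow(ctr) < config$nIslets && guard < 1000 * config$nIslets) {
      guard <- guard + 1
      r <- rads[nrow(ctr) + 1]
      if (nr - 2 * (r + margin) <= 0 || nc - 2 * (r + margin) <= 0) break
      y <- stats::runif(1, r + margin, nr - 1 - r - margin)
      x <- stats::runif(1, r + margin, nc - 1 - r - margin)
      if (nrow(ctr) == 0 ||
          all((ctr[, 1] - y)^2 + (ctr[, 2] - x)^2 >
              (rads[seq_len(nrow(ctr))] + r + 4)^2))
        ctr <- rbind(ctr, c(y, x))
    }
    islets <- data.frame(y = ctr[, 1], x = ctr[, 2],
                         radius_um = rads[seq_len(nrow(ctr))] * px)
  }
  if (is.null(islets))
    islets <- data.frame(y = numeric(0), x = numeric(0), radius_um = numeric(0))
  isletLabels <- matrix(0L, nr, nc)
  if (nrow(islets)) {
    for (i in seq_len(nrow(islets))) {
      idx <- ellipseIndices(islets$y[i], islets$x[i],
                            islets$radius_um[i] / px, islets$radius_um[i] / px,
                            0, nr, nc)
      isletLabels[idx] <- i
    }
  }
  # nuclei: oversample islet interiors by the configured density factor
  pIslet <- 0
  isletDf <- NULL
  if (nrow(islets)) {
    isletDf <- data.frame(y = islets$y, x = islets$x,
                          radius_px = islets$radius_um / px)
    fA <- min(sum(pi * isletDf$radius_px^2) / (nr * nc), 0.9)
    k <- max(config$isletCellDensityFactor, 1)
    pIslet <- min(k * fA / (k * fA + (1 - fA)), 0.9)
  }
  nucDf <- placeNuclei(config$nCells, nr, nc, rRangePx, margin,
                       isletDf = isletDf, pIslet = pIslet)
  nucleusLabels <- matrix(0L, nr, nc)
  nucChan <- matrix(0, nr, nc)
  bright <- stats::runif(config$nCells, config$nucleiIntensityRange[1],
                         config$nucleiIntensityRange[2])
  for (i in seq_len(nrow(nucDf))) {
    idx <- ellipseIndices(nucDf$y[i], nucDf$x[i], nucDf$a[i], nucDf$b[i],
                          nucDf$phi[i], nr, nc)
    nucleusLabels[idx] <- i
    nucChan[idx] <- bright[i]
  }
  cellLabels <- expandCells(nucleusLabels, expPx)
  # compartment and cluster assignment
  compartment <- rep("acinar", config$nCells)
  isletOf <- rep(0L, config$nCells)
  if (config$nCells > 0 && nrow(islets)) {
    ci <- round(nucDf$x) * nr + round(nucDf$y) + 1
    isletOf <- isletLabels[ci]
    compartment[isletOf > 0] <- "islet"
  }
  profAc <- config$profiles$acinar
  profIs <- config$profiles$islet
  nAc <- length(profAc)
  clusterId <- integer(config$nCells)
  subtype <- rep("negative", config$nCells)
  profileOf <- vector("list", config$nCells)
  if (config$nCells > 0 && (nAc + length(profIs)) > 0) {
    wAc <- vapply(profAc, `[[`, numeric(1), "weight")
    wIs <- vapply(profIs, `[[`, numeric(1), "weight")
    isIslet <- compartment == "islet" & length(profIs) > 0
    pick <- integer(config$nCells)
    if (any(!isIslet) && nAc > 0)
      pick[!isIslet] <- sample.int(nAc, sum(!isIslet), replace = TRUE, prob = wAc)
    if (any(isIslet))
      pick[isIslet] <- nAc + sample.int(length(profIs), sum(isIslet),
                                        replace = TRUE, prob = wIs)
    clusterId <- pick
    allProf <- c(profAc, profIs)
    subtype <- vapply(pick, function(p)
      if (p > 0) allProf[[p]]$subtype else "negative", character(1))
    profileOf <- lapply(pick, function(p) if (p > 0) allProf[[p]] else NULL)
  }
  # per-islet shift of the correlation marker, bivariate-normal construction
  isletShift <- rep(1, max(1, nrow(islets)))
  if (!is.null(config$plantedIsletCorrelation) && nrow(islets) > 1) {
    r <- config$plantedIsletCorrelation
    if (abs(r) >= 1) stop("|plantedIsletCorrelation| must be < 1")
    areas <- (islets$radius_um)^2
    za <- as.numeric(scale(areas))
    eps <- stats::rnorm(nrow(islets))
    isletShift <- 1 + 0.35 * (r * za + sqrt(1 - r^2) * eps)
    isletShift <- pmax(isletShift, 0.1)
  }
  # draw per-cell marker intensities
  intens <- matrix(0, config$nCells, length(markers),
                   dimnames = list(NULL, markers))
  for (i in seq_len(if (length(markers)) config$nCells else 0L)) {
    p <- profileOf[[i]]
    if (is.null(p)) next
    mu <- p$mean[markers]
    if (isletOf[i] > 0 && config$correlationMarker %in% markers)
      mu[config$correlationMarker] <-
        mu[config$correlationMarker] * isletShift[isletOf[i]]
    intens[i, ] <- pmax(stats::rnorm(length(markers), mu, p$sd[markers]), 0)
  }
  # render channels
  chans <- vector("list", 1 + length(markers))
  names(chans) <- c("DAPI", markers)
  chans[["DAPI"]] <- nucChan
  nucIdx <- which(nucleusLabels > 0)
  nucLab <- nucleusLabels[nucIdx]
  cytoIdx <- which(cellLabels > 0 & nucleusLabels == 0)
  cytoLab <- cellLabels[cytoIdx]
  for (mk in markers) {
    m <- matrix(0, nr, nc)
    if (config$nCells > 0) {
      if (identical(loc[[mk]], "cytosolic")) {
        m[cytoIdx] <- intens[cytoLab, mk]
      } else {
        m[nucIdx] <- intens[nucLab, mk]
      }
    }
    chans[[mk]] <- m
  }
  # background field, then noise last
  if (config$backgroundAmplitude > 0) {
    for (ch in names(chans))
      chans[[ch]] <- chans[[ch]] +
        smoothField(c(nr, nc), config$backgroundScalePx,
                    config$backgroundAmplitude)
  }
  if (config$noiseSd > 0) {
    for (ch in names(chans)) {
      sdpix <- config$noiseSd * sqrt(1 + chans[[ch]] / config$shotScale)
      chans[[ch]] <- pmax(chans[[ch]] +
        stats::rnorm(nr * nc, 0, as.vector(sdpix)), 0)
    }
  }
  img <- MultiplexImage(chans, pixelSizeUm = px, nucleiChannel = "DAPI",
                        roundId = "round1")
  cellTruth <- data.frame(
    cell_id = seq_len(config$nCells),
    y = nucDf$y, x = nucDf$x,
    cluster_id = clusterId,
    subtype = if (config$nCells) subtype else character(0),
    compartment = if (config$nCells) compartment else character(0),
    islet_id = isletOf
  )
  new("TissuePhantom",
    image = img, nucleusLabels = nucleusLabels, cellLabels = cellLabels,
    isletLabels = isletLabels, cellTruth = cellTruth, intensities = intens,
    params = list(config = config, islets = islets, expansionPx = expPx,
                  isletShift = isletShift))
}

#' Generate per-cell expression profiles without rendering an image
#'
#' Samples marker vectors from a mixture of Gaussian profiles — by default
#' six mutually exclusive single-marker-enriched clusters plus a diffuse
#' low-expression mass holding ~30% of cells, the structure seen in healthy
#' parenchyma. Useful for testing the clustering workflow at scale.
#'
#' @param nCells number of cells.
#' @param profiles list of profiles (`name`, `mean`, `sd`, `weight`;
#'   weights must sum to 1). Default: [defaultExpressionProfiles()].
#' @param seed random seed.
#' @return list with `expr` (markers x cells matrix), `clusterId` (true
#'   mixture component per cell) and `profiles`.
#' @export
simulateExpressionProfiles <- function(nCells = 5000L,
                                       profiles = defaultExpressionProfiles(),
                                       seed = 1L) {
  w <- vapply(profiles, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-8) stop("mixture weights must sum to 1")
  markers <- names(profiles[[1]]$mean)
  set.seed(seed)
  pick <- sample.int(length(profiles), nCells, replace = TRUE, prob = w)
  expr <- matrix(0, length(markers), nCells,
                 dimnames = list(markers, seq_len(nCells)))
  for (j in seq_len(nCells)) {
    p <- profiles[[pick[j]]]
    expr[, j] <- pmax(stats::rnorm(length(markers), p$mean[markers],
                                   p$sd[markers]), 0)
  }
  list(expr = expr, clusterId = pick, profiles = profiles)
}

#' Default expression-profile mixture: six exclusive clusters plus a
#' diffuse low-expression mass
#'
#' Six senescence-panel markers; each enriched cluster is high for exactly
#' one marker (mean 10, SD 1.5) and low elsewhere (mean 1, SD 0.3); the
#' diffuse mass (weight 0.3) is low for every marker. High-expressing
#' populations get the larger absolute spread, as observed in fluorescence
#' intensity data.
#'
#' @return list of profile lists suitable for
#'   [simulateExpressionProfiles()].
#' @export
defaultExpressionProfiles <- function() {
  markers <- c("P53", "P21", "P16", "53BP1", "LMNB1", "HMGB1")
  base <- stats::setNames(rep(1, 6), markers)
  sdLow <- stats::setNames(rep(0.3, 6), markers)
  profs <- list(list(name = "diffuse_low", mean = base, sd = sdLow,
                     weight = 0.3))
  for (mk in markers) {
    mu <- base
    mu[mk] <- 10
    sd <- sdLow
    sd[mk] <- 1.5
    profs[[length(profs) + 1]] <- list(name = paste0(mk, "_high"), mean = mu,
                                       sd = sd, weight = 0.7 / 6)
  }
  profs
}

#' Generate a misaligned round pair with known transforms
#'
#' Builds (or takes) a fixed image and derives the moving round by warping
#' it with the inverse of a known alignment transform, so the stored rigid
#' transform and deformation grid are exactly what [estimateRigid()] /
#' [estimateDeformation()] should recover. The random deformation grid is
#' smooth (one node per `stepPx`) and mean-centred per component, since a
#' nonzero mean displacement is indistinguishable from rigid translation.
#'
#' @param fixed a [MultiplexImage-class] (e.g. `simulateTissue(...)@image`).
#' @param rigid the true aligning [RigidTransform-class].
#' @param deformAmplitudePx peak node displacement of the random smooth
#'   field; must be smaller than `stepPx / 4`.
#' @param stepPx deformation grid step.
#' @param seed seed for the random deformation field.
#' @return list with `fixed`, `moving` (both [MultiplexImage-class]),
#'   `rigid` and `deformation` (the true aligning transforms).
#' @export
simulateRoundPair <- function(fixed, rigid = RigidTransform(),
                              deformAmplitudePx = 0, stepPx = 500,
                              seed = 1L) {
  stopifnot(is(fixed, "MultiplexImage"))
  if (abs(deformAmplitudePx) >= stepPx / 4)
    stop("deformAmplitudePx must be smaller than stepPx / 4")
  shape <- dim(fixed)
  deform <- zeroDeformation(shape, stepPx)
  if (deformAmplitudePx > 0) {
    set.seed(seed)
    nd <- dim(deform@dy)
    dy <- matrix(stats::runif(prod(nd), -deformAmplitudePx,
                              deformAmplitudePx), nd[1], nd[2])
    dx <- matrix(stats::runif(prod(nd), -deformAmplitudePx,
                              deformAmplitudePx), nd[1], nd[2])
    if (prod(nd) > 1) {
      # plant a rigid-free field: the rigid component of a smooth grid
      # (mean displacement, infinitesimal rotation) is indistinguishable
      # from the rigid transform, so it is projected out — the same
      # canonical decomposition applied to estimated registrations
      proj <- canonicalizeTransforms(RigidTransform(),
                                     DeformationGrid(stepPx, dy, dx), shape)
      dy <- proj$deformation@dy
      dx <- proj$deformation@dx
    }
    # keep the planted field inside the stated amplitude after centring
    mx <- max(abs(c(dy, dx)), 1e-12)
    if (mx > deformAmplitudePx) {
      dy <- dy * deformAmplitudePx / mx
      dx <- dx * deformAmplitudePx / mx
    }
    deform <- DeformationGrid(stepPx, dy, dx)
  }
  inv <- invertTransform(rigid)
  hasDeform <- max(abs(c(deform@dy, deform@dx))) > 0
  identityRigid <- rigid@thetaRad == 0 && rigid@tyPx == 0 &&
    rigid@txPx == 0 && rigid@scale == 1
  movingChans <- lapply(fixed@channels, function(m) {
    if (!hasDeform && identityRigid) return(m)
    resampleGrid(m, shape, function(y, x) {
      # solve R(q + D(q)) = (y, x) for q by fixed-point iteration
      q <- mapRigid(y, x, inv, shape)
      if (hasDeform) {
        qy <- q$y
        qx <- q$x
        for (it in 1:4) {
          d <- evalDeformation(deform, qy, qx)
          qy <- q$y - d$dy
          qx <- q$x - d$dx
        }
        q <- list(y = qy, x = qx)
      }
      q
    })
  })
  moving <- MultiplexImage(movingChans, pixelSizeUm = fixed@pixelSizeUm,
                           nucleiChannel = fixed@nucleiChannel,
                           roundId = "round2")
  list(fixed = fixed, moving = moving, rigid = rigid, deformation = deform)
}

#' Islet population with an exactly planted area-marker correlation
#'
#' Bivariate-normal construction: with standard normal `z1`, `z2`,
#' `area = muA + sdA * z1` and
#' `marker = muM + sdM * (r * z1 + sqrt(1 - r^2) * z2)`, so the population
#' Pearson correlation between area and marker level is exactly `r` and the
#' sample correlation converges to it as n grows.
#'
#' @param nIslets number of islets (>= 3).
#' @param rTarget target population correlation, |r| < 1.
#' @param seed random seed.
#' @param areaMeanUm2,areaSdUm2 islet-area distribution (µm²).
#' @param markerMean,markerSd marker-level distribution (arbitrary units).
#' @return data.frame with `islet_id`, `area_um2`, `marker_mean`.
#' @export
simulateIsletPopulation <- function(nIslets, rTarget, seed = 1L,
                                    areaMeanUm2 = 2000, areaSdUm2 = 400,
                                    markerMean = 100, markerSd = 25) {
  if (!is.finite(rTarget) || abs(rTarget) >= 1)
    stop("|rTarget| must be < 1")
  if (nIslets < 3) stop("nIslets must be >= 3")
  set.seed(seed)
  z1 <- stats::rnorm(nIslets)
  z2 <- stats::rnorm(nIslets)
  data.frame(
    islet_id = seq_len(nIslets),
    area_um2 = areaMeanUm2 + areaSdUm2 * z1,
    marker_mean = markerMean + markerSd * (rTarget * z1 +
                                             sqrt(1 - rTarget^2) * z2)
  )
}
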