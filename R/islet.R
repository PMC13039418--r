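# Segmentation of islets of Langerhans from the endocrine-marker channels
# and islet-level feature extraction and association statistics.

#' Segment islets from insulin and glucagon channels
#'
#' A binary map of endocrine-positive tissue is built as
#' `(insulin > t1) | (glucagon > t2)`, refined by morphological closing then
#' opening with a disk structuring element, holes fully enclosed by positive
#' tissue are filled, connected components are labelled, and components
#' smaller than `minAreaUm2` are discarded (the area rule is applied to the
#' final, hole-filled regions). With the defaults, 400 µm² at 0.65 µm/px is a
#' 947-pixel cutoff.
#'
#' @param insulin,glucagon numeric matrices of identical shape.
#' @param thresholds numeric length-2 manual thresholds (insulin, glucagon);
#'   `NA` entries fall back to Otsu on the corresponding channel.
#' @param minAreaUm2 smallest retained islet area (µm²).
#' @param pixelSizeUm physical pixel size (µm).
#' @param structRadiusPx disk radius for closing/opening (px).
#' @return integer islet label matrix (0 = background).
#' @export
segmentIslets <- function(insulin, glucagon, thresholds = c(NA, NA),
                          minAreaUm2 = 400, pixelSizeUm = 0.65,
                          structRadiusPx = 3L) {
  if (!identical(dim(insulin), dim(glucagon)))
    stop("insulin and glucagon channels must have the same shape")
  t1 <- thresholds[1]
  t2 <- thresholds[2]
  if (is.na(t1)) t1 <- otsuThreshold(as.vector(insulin))
  if (is.na(t2)) t2 <- otsuThreshold(as.vector(glucagon))
  if (t1 < 0 || t2 < 0) stop("thresholds must be non-negative")
  binary <- (insulin > t1) | (glucagon > t2)
  refined <- refineIsletMask(binary, structRadiusPx)
  lab <- EBImage::bwlabel(matrix(as.numeric(refined), nrow(refined),
                                 ncol(refined)))
  lab <- matrix(as.integer(lab), nrow(refined), ncol(refined))
  minPx <- ceiling(minAreaUm2 / pixelSizeUm^2)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], max(lab))
    drop <- which(areas < minPx)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  relabelSequential(lab)
}

# closing then opening with a disk, then fill enclosed holes
refineIsletMask <- function(binary, structRadiusPx = 3L) {
  m <- matrix(as.numeric(binary), nrow(binary), ncol(binary))
  if (structRadiusPx > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(structRadiusPx) + 1L,
                                shape = "disc")
    m <- EBImage::opening(EBImage::closing(m, brush), brush)
  }
  m <- EBImage::fillHull(m)
  matrix(as.logical(m > 0), nrow(binary), ncol(binary))
}

#' Islet-level morphology, intensity and cell-composition features
#'
#' Per islet: area (px and µm²), second-moment aspect ratio, Crofton
#' circularity, solidity (area over convex-hull area), per-channel mean and
#' total intensity over the islet mask, and — when a cell table with
#' positivity calls is supplied — per-subtype cell counts and fractions.
#' Cells belong to the islet whose mask contains their nucleus centroid.
#'
#' @param islets integer islet label matrix.
#' @param image an aligned [MultiplexImage-class] (intensities are summarised
#'   as provided; pass background-corrected channels for corrected summaries).
#' @param cells optional cell feature table (needs `cell_id`, `y`, `x`).
#' @param positivity optional data.frame of per-cell calls as returned by
#'   [callPositivity()]`$calls` (logical columns per marker, plus `subtype`).
#' @return data.frame with one row per islet.
#' @export
isletFeatures <- function(islets, image, cells = NULL, positivity = NULL) {
  stopifnot(is(image, "MultiplexImage"))
  if (!identical(dim(islets), dim(image)))
    stop("islet label map and image must share dimensions")
  px <- pixelSizeUm(image)
  ids <- sort(unique(islets[islets > 0]))
  if (length(ids) == 0) {
    out <- data.frame(islet_id = integer(0), area_px = numeric(0),
                      area_um2 = numeric(0), aspect_ratio = numeric(0),
                      circularity = numeric(0), solidity = numeric(0),
                      n_cells = integer(0))
    for (ch in channelNames(image)) {
      out[[paste0(ch, "_mean")]] <- numeric(0)
      out[[paste0(ch, "_total")]] <- numeric(0)
    }
    return(out)
  }
  nr <- nrow(islets)
  idx <- which(islets > 0)
  lab <- islets[idx]
  y0 <- (idx - 1) %% nr
  x0 <- (idx - 1) %/% nr
  n <- max(ids)
  area <- tabulate(lab, n)[ids]
  sy <- rowsum(y0, lab)[, 1]
  sx <- rowsum(x0, lab)[, 1]
  syy <- rowsum(y0^2, lab)[, 1]
  sxx <- rowsum(x0^2, lab)[, 1]
  sxy <- rowsum(y0 * x0, lab)[, 1]
  ax <- momentAxes(sy, sx, syy, sxx, sxy, area)
  shp <- vapply(ids, function(L) {
    w <- which(lab == L)
    rs <- range(y0[w])
    cs <- range(x0[w])
    m <- matrix(FALSE, rs[2] - rs[1] + 1, cs[2] - cs[1] + 1)
    m[cbind(y0[w] - rs[1] + 1, x0[w] - cs[1] + 1)] <- TRUE
    p <- croftonPerimeter(m)
    # solidity: pixel area over the area of the convex hull of pixel centres
    pts <- cbind(y0[w], x0[w])
    hullArea <- convexHullArea(pts)
    c(perimeter = p, hull = hullArea)
  }, numeric(2))
  circ <- pmin(4 * pi * area / shp["perimeter", ]^2, 1)
  solidity <- pmin(area / pmax(shp["hull", ], area), 1)
  out <- data.frame(
    islet_id = ids,
    area_px = area,
    area_um2 = area * px^2,
    aspect_ratio = ax$aspect,
    circularity = circ,
    solidity = solidity
  )
  for (ch in channelNames(image)) {
    vv <- as.vector(getChannel(image, ch))
    tot <- rep(0, n)
    rs <- rowsum(vv[idx], lab)
    tot[as.integer(rownames(rs))] <- rs[, 1]
    out[[paste0(ch, "_mean")]] <- tot[ids] / area
    out[[paste0(ch, "_total")]] <- tot[ids]
  }
  # cell membership and subtype composition
  if (!is.null(cells) && nrow(cells)) {
    ci <- pmin(pmax(round(cells$y), 0), nr - 1) + 1 +
      pmin(pmax(round(cells$x), 0), ncol(islets) - 1) * nr
    memb <- islets[ci]
    out$n_cells <- as.integer(tabulate(memb[memb > 0], n)[ids])
    if (!is.null(positivity)) {
      # align calls to the cell table by id: cells without a call (e.g.
      # outside the analysis ROIs) count as uncalled, not positive
      pidx <- match(cells$cell_id, positivity$cell_id)
      markers <- setdiff(names(positivity),
                         c("cell_id", "subtype", "senescence_group"))
      for (mk in markers) {
        pos <- positivity[[mk]][pidx]
        pos[is.na(pos)] <- FALSE
        posCount <- rep(0L, n)
        t <- tabulate(memb[memb > 0 & pos], n)
        posCount[seq_along(t)] <- t
        out[[paste0(mk, "_pos_n")]] <- posCount[ids]
        out[[paste0(mk, "_pos_frac")]] <-
          ifelse(out$n_cells > 0, posCount[ids] / out$n_cells, NA_real_)
      }
      if (!is.null(positivity$subtype)) {
        stv <- positivity$subtype[pidx]
        stv[is.na(stv)] <- "uncalled"
        for (st in c("Insulin+", "Glucagon+", "SST-28+", "negative")) {
          cnt <- rep(0L, n)
          t <- tabulate(memb[memb > 0 & stv == st], n)
          cnt[seq_along(t)] <- t
          key <- sub("\\+$", "", sub("-", "", st))
          out[[paste0("subtype_", key, "_n")]] <- cnt[ids]
          out[[paste0("subtype_", key, "_frac")]] <-
            ifelse(out$n_cells > 0, cnt[ids] / out$n_cells, NA_real_)
        }
      }
    }
  } else {
    out$n_cells <- 0L
  }
  rownames(out) <- NULL
  out
}

# area of the convex hull of a 2D point set (0 for degenerate sets)
convexHullArea <- function(pts) {
  if (nrow(pts) < 3) return(nrow(pts))
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hp <- pts[h, , drop = FALSE]
  i2 <- c(2:nrow(hp), 1)
  abs(sum(hp[, 1] * hp[i2, 2] - hp[i2, 1] * hp[, 2])) / 2
}

#' Pairwise Pearson correlations between islet-level variables
#'
#' Symmetric matrix of Pearson r with two-tailed p-values from the
#' t-distribution with n - 2 degrees of freedom. Zero-variance variables
#' yield `NA` for their pairs.
#'
#' @param table islet feature data.frame.
#' @param variables character vector of numeric column names.
#' @return list with matrices `r` and `p` (unit diagonal, `p` 0 on the
#'   diagonal) and the number of islets `n`.
#' @export
isletCorrelationMatrix <- function(table, variables) {
  missing <- setdiff(variables, names(table))
  if (length(missing)) stop("unknown variables: ", paste(missing, collapse = ", "))
  x <- as.matrix(table[, variables, drop = FALSE])
  n <- nrow(x)
  if (n < 3) stop("at least 3 islets are required")
  sds <- apply(x, 2, stats::sd)
  r <- suppressWarnings(stats::cor(x))
  r[sds == 0, ] <- NA
  r[, sds == 0] <- NA
  diag(r) <- ifelse(sds == 0, NA, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- ifelse(sds == 0, NA, 0)
  list(r = r, p = p, n = n)
}

#' Subtype occurrence as a function of islet size
#'
#' Islets are split into `nBins` equal-count area bins; the mean and SD of a
#' per-islet subtype fraction is reported per bin together with the overall
#' Pearson correlation between fraction and area.
#'
#' @param table islet feature data.frame (needs `area_um2`).
#' @param fractionColumn name of the per-islet fraction column.
#' @param nBins number of equal-count bins.
#' @return list with `bins` (data.frame: bin, n, area_mean, fraction_mean,
#'   fraction_sd) and `r` (Pearson r of fraction vs area).
#' @export
occurrenceVsSize <- function(table, fractionColumn, nBins = 5) {
  if (!fractionColumn %in% names(table))
    stop("unknown column: ", fractionColumn)
  ok <- is.finite(table$area_um2) & is.finite(table[[fractionColumn]])
  area <- table$area_um2[ok]
  frac <- table[[fractionColumn]][ok]
  if (nBins > length(area)) stop("more bins than islets")
  ord <- order(area)
  bin <- ceiling(seq_along(ord) / (length(ord) / nBins))
  bin <- pmin(bin, nBins)
  b <- integer(length(area))
  b[ord] <- bin
  bins <- data.frame(
    bin = seq_len(nBins),
    n = as.integer(tabulate(b, nBins)),
    area_mean = as.numeric(tapply(area, factor(b, levels = seq_len(nBins)), mean)),
    fraction_mean = as.numeric(tapply(frac, factor(b, levels = seq_len(nBins)), mean)),
    fraction_sd = as.numeric(tapply(frac, factor(b, levels = seq_len(nBins)), stats::sd))
  )
  r <- if (stats::sd(area) > 0 && stats::sd(frac) > 0)
    stats::cor(area, frac) else NA_real_
  list(bins = bins, r = r)
}
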