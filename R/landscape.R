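# Single-cell expression landscape: ROI selection, expression-matrix
# construction, z-score -> PCA -> k-means clustering, positivity calling and
# co-occurrence statistics.

#' ClusterModel: fitted z-score/PCA/k-means expression-landscape model
#'
#' @slot center,scale per-marker z-score parameters (means and SDs).
#' @slot rotation PCA loading matrix (markers x retained components).
#' @slot nComponents number of retained principal components: the minimal
#'   number whose cumulative explained variance reaches `varFrac`.
#' @slot varFrac requested variance fraction.
#' @slot varExplained cumulative explained variance at `nComponents`.
#' @slot centers k-means centroids in the reduced space (k x components).
#' @slot k number of clusters.
#' @slot seed random seed used for initialisation.
#' @export
setClass("ClusterModel",
  representation(
    center = "numeric", scale = "numeric", rotation = "matrix",
    nComponents = "integer", varFrac = "numeric", varExplained = "numeric",
    centers = "matrix", k = "integer", seed = "integer"
  )
)

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf(
    "ClusterModel: %d markers -> %d components (%.1f%% variance), k = %d\n",
    length(object@center), object@nComponents, 100 * object@varExplained,
    object@k))
})

#' Select non-overlapping square ROIs inside an image
#'
#' Deterministic greedy packing: candidate top-left corners are scanned
#' row-major on a grid of stride `roiSizePx` (with a seeded random jitter of
#' the grid phase), and a candidate is accepted when the ROI lies fully
#' inside the image, does not intersect the artifact mask, and does not
#' overlap a previously accepted ROI.
#'
#' @param shape integer (rows, cols) of the image.
#' @param nRois number of ROIs required.
#' @param roiSizePx ROI side length in pixels (2000 px is ~1.3 mm at
#'   0.65 µm/px).
#' @param artifactMask optional logical matrix, `TRUE` where tissue artifacts
#'   (folds, debris) must be avoided.
#' @param seed seed for the grid-phase jitter.
#' @return data.frame with columns `roi`, `y0`, `x0`, `y1`, `x1` (0-based,
#'   inclusive bounds).
#' @export
selectROIs <- function(shape, nRois, roiSizePx = 2000L, artifactMask = NULL,
                       seed = 1L) {
  nr <- shape[1]
  nc <- shape[2]
  s <- as.integer(roiSizePx)
  if (s > nr || s > nc) stop("image too small for a single ROI")
  if (!is.null(artifactMask) && !all(dim(artifactMask) == c(nr, nc)))
    stop("artifact mask shape differs from the image shape")
  set.seed(seed)
  phase <- c(sample.int(s, 1) - 1L, sample.int(s, 1) - 1L)
  gridStarts <- function(p, lim) {
    v <- if (p <= lim) seq(p, lim, by = s) else numeric(0)
    sort(unique(c(v, 0, lim)))
  }
  ys <- gridStarts(phase[1] %% s, nr - s)
  xs <- gridStarts(phase[2] %% s, nc - s)
  cum <- NULL
  if (!is.null(artifactMask)) {
    # summed-area table for O(1) mask queries
    cum <- apply(apply(artifactMask * 1, 2, cumsum), 1, cumsum)
    cum <- t(cum)
  }
  maskSum <- function(y0, x0) {
    if (is.null(cum)) return(0)
    y1 <- y0 + s
    x1 <- x0 + s
    a <- cum[y1, x1]
    b <- if (y0 > 0) cum[y0, x1] else 0
    d <- if (x0 > 0) cum[y1, x0] else 0
    e <- if (y0 > 0 && x0 > 0) cum[y0, x0] else 0
    a - b - d + e
  }
  acc <- matrix(numeric(0), 0, 2)
  for (y0 in sort(ys)) {
    for (x0 in sort(xs)) {
      if (nrow(acc) >= nRois) break
      if (y0 + s > nr || x0 + s > nc) next
      if (maskSum(y0, x0) > 0) next
      if (nrow(acc)) {
        ov <- abs(acc[, 1] - y0) < s & abs(acc[, 2] - x0) < s
        if (any(ov)) next
      }
      acc <- rbind(acc, c(y0, x0))
    }
  }
  if (nrow(acc) < nRois)
    stop(sprintf("could only place %d of %d requested ROIs", nrow(acc), nRois))
  data.frame(roi = seq_len(nRois), y0 = acc[, 1], x0 = acc[, 2],
             y1 = acc[, 1] + s - 1, x1 = acc[, 2] + s - 1)
}

#' Build the per-cell marker expression matrix
#'
#' One column per configured marker, one row per cell. Nuclear markers use
#' the nuclear mean intensity; cytosolic markers (such as P16) use the
#' whole-cell mean, following the convention that cytosolic staining is
#' quantified over the expanded cell region. Cells are restricted to the
#' supplied ROIs (if any) and tagged with their ROI id.
#'
#' @param cells cell feature table from [extractFeatures()].
#' @param markers character vector of marker (channel) names.
#' @param localization named character vector per marker, `"nuclear"` or
#'   `"cytosolic"`; markers not listed default to nuclear.
#' @param rois optional ROI data.frame from [selectROIs()].
#' @return A [SingleCellExperiment::SingleCellExperiment] with assay
#'   `"expr"` (markers x cells), and `cell_id`, `roi` in `colData`.
#' @export
buildExpressionMatrix <- function(cells, markers, localization = character(0),
                                  rois = NULL) {
  cols <- vapply(markers, function(mk) {
    loc <- if (mk %in% names(localization)) localization[[mk]] else "nuclear"
    suffix <- if (identical(loc, "cytosolic")) "_cell_mean" else "_nuc_mean"
    col <- paste0(mk, suffix)
    if (!col %in% names(cells))
      stop("marker channel not present in the cell table: ", mk)
    col
  }, character(1))
  roiId <- rep(NA_integer_, nrow(cells))
  if (!is.null(rois) && nrow(cells)) {
    for (k in seq_len(nrow(rois))) {
      inside <- cells$y >= rois$y0[k] & cells$y <= rois$y1[k] &
        cells$x >= rois$x0[k] & cells$x <= rois$x1[k]
      roiId[inside & is.na(roiId)] <- rois$roi[k]
    }
  }
  keep <- if (is.null(rois)) seq_len(nrow(cells)) else which(!is.na(roiId))
  m <- t(as.matrix(cells[keep, cols, drop = FALSE]))
  rownames(m) <- markers
  colnames(m) <- as.character(cells$cell_id[keep])
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(expr = m),
    colData = S4Vectors::DataFrame(
      cell_id = cells$cell_id[keep],
      roi = roiId[keep]
    )
  )
  S4Vectors::metadata(sce)$localization <-
    vapply(markers, function(mk)
      if (mk %in% names(localization)) localization[[mk]] else "nuclear",
      character(1))
  sce
}

# k-means++ seeding followed by Lloyd iterations; best of nInit restarts
kmeansPlusPlus <- function(x, k, nInit = 10, iterMax = 100) {
  n <- nrow(x)
  if (k == 1) {
    ctr <- matrix(colMeans(x), 1, ncol(x))
    return(list(cluster = rep(1L, n), centers = ctr,
                tot.withinss = sum(sweep(x, 2, ctr)^2)))
  }
  best <- NULL
  for (rep in seq_len(nInit)) {
    centers <- matrix(NA_real_, k, ncol(x))
    centers[1, ] <- x[sample.int(n, 1), ]
    d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
    if (k > 1) {
      for (j in 2:k) {
        p <- d2 / sum(d2)
        if (!all(is.finite(p)) || sum(d2) == 0)
          idx <- sample.int(n, 1)
        else
          idx <- sample.int(n, 1, prob = p)
        centers[j, ] <- x[idx, ]
        dj <- rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
        d2 <- pmin(d2, dj)
      }
    }
    fit <- suppressWarnings(
      stats::kmeans(x, centers = centers, iter.max = iterMax,
                    algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' Cluster cells into expression subtypes
#'
#' The standard expression-landscape workflow: per-marker z-scoring, PCA retaining the
#' minimal number of components whose cumulative explained variance reaches
#' `varFrac` (95% by default), and k-means (k-means++ initialisation,
#' `nInit` restarts, best within-cluster sum of squares kept) in the reduced
#' space. Deterministic given `seed`.
#'
#' @param x a SingleCellExperiment from [buildExpressionMatrix()] or a
#'   numeric matrix (markers x cells).
#' @param k number of clusters (default 20).
#' @param varFrac PCA variance fraction to retain, in (0, 1].
#' @param seed random seed.
#' @param nInit number of k-means restarts.
#' @return list with `model` (a [ClusterModel-class]), `assignments`
#'   (integer cluster per cell), `profiles` (k x markers matrix of mean
#'   z-scored expression per cluster — heatmap input), `occurrence`
#'   (cluster occurrence fractions, summing to 1) and, when the input was a
#'   SingleCellExperiment, `sce` with `cluster` in `colData` and the
#'   reduced coordinates in `reducedDim(sce, "PCA")`.
#' @export
clusterCells <- function(x, k = 20L, varFrac = 0.95, seed = 1L, nInit = 10L) {
  sce <- NULL
  if (is(x, "SingleCellExperiment")) {
    sce <- x
    m <- SummarizedExperiment::assay(x, "expr")
  } else {
    m <- x
  }
  if (varFrac <= 0 || varFrac > 1) stop("varFrac must be in (0, 1]")
  xm <- t(m)  # cells x markers
  n <- nrow(xm)
  if (n < k) stop("fewer cells than clusters (k)")
  ctr <- colMeans(xm)
  scl <- apply(xm, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  z <- sweep(sweep(xm, 2, ctr), 2, scl, "/")
  pca <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  ve <- pca$sdev^2 / sum(pca$sdev^2)
  nComp <- which(cumsum(ve) >= varFrac - 1e-12)[1]
  if (is.na(nComp)) nComp <- length(ve)
  red <- pca$x[, seq_len(nComp), drop = FALSE]
  set.seed(seed)
  fit <- kmeansPlusPlus(red, k, nInit = nInit)
  assignments <- fit$cluster
  prof <- rowsum(z, assignments) / as.vector(table(assignments))
  colnames(prof) <- rownames(m)
  occ <- as.vector(table(factor(assignments, levels = seq_len(k)))) / n
  model <- new("ClusterModel",
    center = ctr, scale = scl,
    rotation = pca$rotation[, seq_len(nComp), drop = FALSE],
    nComponents = as.integer(nComp), varFrac = varFrac,
    varExplained = cumsum(ve)[nComp],
    centers = fit$centers, k = as.integer(k), seed = as.integer(seed))
  out <- list(model = model, assignments = assignments, profiles = prof,
              occurrence = occ)
  if (!is.null(sce)) {
    SummarizedExperiment::colData(sce)$cluster <- assignments
    SingleCellExperiment::reducedDim(sce, "PCA") <- red
    out$sce <- sce
  }
  out
}

#' 2D embedding of the reduced expression features for visualisation
#'
#' Uses UMAP (via the `uwot` package) when it is installed; otherwise falls
#' back to the first two principal axes with a logged message, which
#' preserves the coordinates' interpretability if not their non-linear
#' structure.
#'
#' @param reduced numeric matrix of PCA-reduced features (cells x components).
#' @param seed random seed for UMAP.
#' @return numeric matrix (cells x 2) of embedding coordinates; the attribute
#'   `"method"` records which embedding was used.
#' @export
embedCells <- function(reduced, seed = 1L) {
  reduced <- as.matrix(reduced)
  if (requireNamespace("uwot", quietly = TRUE) && nrow(reduced) > 15) {
    set.seed(seed)
    em <- uwot::umap(reduced, n_components = 2)
    attr(em, "method") <- "umap"
    return(em)
  }
  message("uwot not available; using the first two principal axes")
  em <- reduced[, seq_len(min(2, ncol(reduced))), drop = FALSE]
  if (ncol(em) == 1) em <- cbind(em, 0)
  colnames(em) <- c("dim1", "dim2")
  attr(em, "method") <- "pca"
  em
}

# resolve one positivity threshold spec against a marker's values
resolveThreshold <- function(values, spec) {
  if (is.numeric(spec) && length(spec) == 1) spec <- list(mode = "manual", value = spec)
  if (!is.list(spec) || is.null(spec$mode))
    stop("threshold spec must be list(mode=, ...) or a single number")
  switch(spec$mode,
    manual = {
      if (is.null(spec$value)) stop("manual threshold needs a value")
      spec$value
    },
    quantile = {
      if (is.null(spec$q)) stop("quantile threshold needs q")
      as.numeric(stats::quantile(values, spec$q))
    },
    otsu = {
      # bimodal split on log intensities
      exp(otsuThreshold(log(values + 1))) - 1
    },
    stop("unknown threshold mode: ", spec$mode)
  )
}

#' Call per-marker positivity and derive endocrine subtypes
#'
#' A cell is positive for a marker when its expression value exceeds the
#' marker's threshold. Thresholds can be manual values, quantiles, or
#' automatic bimodal splits (Otsu on log intensities, the default).
#' Endocrine subtype is the positive marker among insulin / glucagon /
#' SST-28 with the highest z-score when several are positive, and
#' `"negative"` when none is.
#'
#' @param x SingleCellExperiment from [buildExpressionMatrix()] or a numeric
#'   markers x cells matrix.
#' @param thresholds named list of per-marker specs (see
#'   [PipelineConfig-class]); markers without a spec use Otsu.
#' @param endocrineMarkers length-3 character vector naming the insulin,
#'   glucagon and somatostatin-28 markers (those present in `x` are used).
#' @param senescenceMarkers markers combined into the `senescence_group`
#'   label (e.g. P16/53BP1), taken from those present in `x`.
#' @return list with `calls` (data.frame: `cell_id`, one logical column per
#'   marker, `subtype`, `senescence_group`) and `thresholds` (named numeric
#'   vector of the thresholds used).
#' @export
callPositivity <- function(x, thresholds = list(),
                           endocrineMarkers = c("INS", "GCG", "SST"),
                           senescenceMarkers = c("P16", "BP53_1", "53BP1")) {
  if (is(x, "SingleCellExperiment")) {
    m <- SummarizedExperiment::assay(x, "expr")
    ids <- SummarizedExperiment::colData(x)$cell_id
  } else {
    m <- x
    ids <- seq_len(ncol(m))
  }
  markers <- rownames(m)
  thr <- vapply(markers, function(mk) {
    spec <- if (mk %in% names(thresholds)) thresholds[[mk]] else list(mode = "otsu")
    resolveThreshold(m[mk, ], spec)
  }, numeric(1))
  calls <- data.frame(cell_id = ids)
  for (mk in markers) calls[[mk]] <- m[mk, ] > thr[[mk]]
  endo <- intersect(endocrineMarkers, markers)
  if (length(endo)) {
    zs <- t(apply(m[endo, , drop = FALSE], 1, function(v) {
      s <- stats::sd(v)
      if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
    }))
    subtypeNames <- c(INS = "Insulin+", GCG = "Glucagon+", SST = "SST-28+")
    subtype <- rep("negative", ncol(m))
    for (i in seq_len(ncol(m))) {
      pos <- endo[vapply(endo, function(mk) calls[[mk]][i], logical(1))]
      if (length(pos)) {
        zbest <- pos[which.max(zs[pos, i])]
        subtype[i] <- if (zbest %in% names(subtypeNames))
          subtypeNames[[zbest]] else paste0(zbest, "+")
      }
    }
    calls$subtype <- subtype
  }
  sen <- intersect(senescenceMarkers, markers)
  if (length(sen) >= 1) {
    lab <- vapply(seq_len(ncol(m)), function(i) {
      paste(vapply(sen, function(mk)
        paste0(mk, if (calls[[mk]][i]) "+" else "-"), character(1)),
        collapse = "/")
    }, character(1))
    calls$senescence_group <- lab
  }
  list(calls = calls, thresholds = thr)
}

#' Co-occurrence fraction and 2x2 group means
#'
#' Computes the fraction of `markerX`-positive cells that are also
#' `markerY`-positive, with a Wilson 95% confidence interval, and optionally
#' the mean of a quantitative marker across the four (x±, y±) groups.
#'
#' @param calls positivity data.frame from [callPositivity()]`$calls`.
#' @param markerX,markerY marker column names.
#' @param quantValues optional numeric vector (one value per cell, e.g.
#'   background-corrected insulin intensity) for the group means.
#' @return list with `fraction`, `ci` (length-2 Wilson interval), `nX`
#'   (number of x-positive cells), and when `quantValues` is given a
#'   `groups` data.frame (group, n, mean). With no x-positive cells the
#'   fraction is `NA` and `nX` is 0.
#' @export
cooccurrenceStats <- function(calls, markerX, markerY, quantValues = NULL) {
  for (mk in c(markerX, markerY))
    if (!mk %in% names(calls)) stop("no positivity call for marker: ", mk)
  xp <- calls[[markerX]]
  yp <- calls[[markerY]]
  nX <- sum(xp)
  if (nX == 0) {
    res <- list(fraction = NA_real_, ci = c(NA_real_, NA_real_), nX = 0L)
  } else {
    nXY <- sum(xp & yp)
    # Wilson score interval = prop.test without continuity correction
    ci <- suppressWarnings(
      stats::prop.test(nXY, nX, correct = FALSE)$conf.int)
    res <- list(fraction = nXY / nX, ci = as.numeric(ci), nX = as.integer(nX))
  }
  if (!is.null(quantValues)) {
    if (length(quantValues) != nrow(calls))
      stop("quantValues must have one value per cell")
    grp <- paste0(markerX, ifelse(xp, "+", "-"), "/",
                  markerY, ifelse(yp, "+", "-"))
    lev <- c(paste0(markerX, "-/", markerY, "-"),
             paste0(markerX, "+/", markerY, "-"),
             paste0(markerX, "-/", markerY, "+"),
             paste0(markerX, "+/", markerY, "+"))
    gf <- factor(grp, levels = lev)
    res$groups <- data.frame(
      group = lev,
      n = as.integer(table(gf)),
      mean = as.numeric(tapply(quantValues, gf, mean))
    )
  }
  res
}
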