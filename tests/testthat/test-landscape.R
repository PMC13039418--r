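test_that("ROI selection respects bounds, masks and disjointness", {
  one <- selectROIs(c(3000, 3000), 1, roiSizePx = 2000L, seed = 2)
  expect_identical(nrow(one), 1L)
  expect_true(one$y1 < 3000 && one$x1 < 3000)
  # ROI side in physical units: 2000 px at 0.65 um/px is 1.3 mm
  expect_equal((one$y1 - one$y0 + 1) * 0.65 / 1000, 1.3)

  mask <- matrix(FALSE, 1200, 1200)
  mask[, 1:600] <- TRUE
  rois <- selectROIs(c(1200, 1200), 2, roiSizePx = 256L,
                     artifactMask = mask, seed = 3)
  expect_true(all(rois$x0 >= 600))
  # pairwise disjoint
  for (i in seq_len(nrow(rois) - 1)) {
    for (j in (i + 1):nrow(rois)) {
      expect_true(abs(rois$y0[i] - rois$y0[j]) >= 256 ||
                    abs(rois$x0[i] - rois$x0[j]) >= 256)
    }
  }
  expect_error(selectROIs(c(500, 500), 1, roiSizePx = 2000L), "too small")
  expect_error(selectROIs(c(1200, 1200), 50, roiSizePx = 512L,
                          artifactMask = mask, seed = 1),
               "could only place")
})

test_that("expression matrix routes nuclear vs cytosolic summaries", {
  ph <- noiselessPhantom(n = 25, size = 224, seed = 27)
  f <- extractFeatures(groundTruth(ph, "nuclei"), groundTruth(ph, "cells"),
                       ph@image, correctBackground = FALSE)
  sce <- buildExpressionMatrix(
    f, markers = c("53BP1", "P16"),
    localization = c(P16 = "cytosolic", `53BP1` = "nuclear"))
  m <- SummarizedExperiment::assay(sce, "expr")
  expect_identical(unname(m["53BP1", ]), f[["53BP1_nuc_mean"]])
  expect_identical(unname(m["P16", ]), f[["P16_cell_mean"]])
  expect_error(buildExpressionMatrix(f, "ABSENT"), "not present")
  # ROI restriction and the empty case
  rois <- data.frame(roi = 1L, y0 = 0, x0 = 0, y1 = 10, x1 = 10)
  sce2 <- buildExpressionMatrix(f, "P16", rois = rois)
  expect_true(ncol(sce2) <= nrow(f))
  expect_s4_class(sce2, "SingleCellExperiment")
})

test_that("clustering recovers planted structure and honours k = 1", {
  sim <- simulateExpressionProfiles(400, list(
    list(name = "lo", mean = c(A = 1, B = 1), sd = c(A = 0.3, B = 0.3),
         weight = 0.5),
    list(name = "hi", mean = c(A = 12, B = 12), sd = c(A = 0.3, B = 0.3),
         weight = 0.5)), seed = 5)
  one <- clusterCells(sim$expr, k = 1, varFrac = 0.95, seed = 1)
  expect_identical(unique(one$assignments), 1L)
  expect_equal(one$occurrence, 1)
  two <- clusterCells(sim$expr, k = 2, varFrac = 0.95, seed = 1)
  expect_equal(mclust::adjustedRandIndex(two$assignments, sim$clusterId), 1)
  expect_equal(sum(two$occurrence), 1)
  expect_error(clusterCells(sim$expr, k = 500), "fewer cells")
})

test_that("clustering is invariant to marker order and affine rescaling", {
  sim <- simulateExpressionProfiles(600, seed = 8)
  base <- clusterCells(sim$expr, k = 7, seed = 3)
  perm <- clusterCells(sim$expr[rev(rownames(sim$expr)), ], k = 7, seed = 3)
  expect_equal(mclust::adjustedRandIndex(base$assignments, perm$assignments),
               1)
  resc <- sim$expr
  resc["P16", ] <- resc["P16", ] * 40 + 1000
  scaled <- clusterCells(resc, k = 7, seed = 3)
  expect_equal(mclust::adjustedRandIndex(base$assignments,
                                         scaled$assignments), 1)
})

test_that("the retained-component rule is minimal for the variance target", {
  sim <- simulateExpressionProfiles(800, seed = 12)
  cl <- clusterCells(sim$expr, k = 5, varFrac = 0.95, seed = 2)
  m <- cl$model
  # oracle: recompute the spectrum with prcomp on the z-scored matrix
  z <- scale(t(sim$expr))
  ve <- stats::prcomp(z, center = FALSE)$sdev^2
  cum <- cumsum(ve) / sum(ve)
  expect_gte(cum[m@nComponents], 0.95)
  if (m@nComponents > 1) expect_lt(cum[m@nComponents - 1], 0.95)
  expect_equal(m@varExplained, cum[m@nComponents], tolerance = 1e-9)
})

test_that("2D embedding returns coordinates, falling back to the PCA plane", {
  red <- matrix(stats::rnorm(30), 10, 3)
  em <- suppressMessages(embedCells(red[1:3, , drop = FALSE]))
  expect_identical(dim(em), c(3L, 2L))
  if (!requireNamespace("uwot", quietly = TRUE)) {
    expect_message(em2 <- embedCells(red), "principal axes")
    expect_identical(attr(em2, "method"), "pca")
    expect_equal(unname(em2), unname(red[, 1:2]))
  }
})

test_that("positivity calling separates planted bimodal mixtures", {
  set.seed(13)
  n <- 4000
  v <- c(stats::rnorm(n / 2, 1, 0.5), stats::rnorm(n / 2, 10, 0.5))
  m <- matrix(pmax(v, 0), 1, dimnames = list("P16", NULL))
  auto <- callPositivity(m)
  truth <- rep(c(FALSE, TRUE), each = n / 2)
  expect_lt(mean(auto$calls$P16 != truth), 0.01)
  # all values below a manual threshold -> everybody negative
  man <- callPositivity(m, thresholds = list(P16 = list(mode = "manual",
                                                        value = 1e6)))
  expect_false(any(man$calls$P16))
  qt <- callPositivity(m, thresholds = list(P16 = list(mode = "quantile",
                                                       q = 0.5)))
  expect_equal(mean(qt$calls$P16), 0.5, tolerance = 0.01)
  expect_error(callPositivity(m, thresholds = list(P16 = list(mode = "??"))),
               "unknown threshold mode")
})

test_that("endocrine subtypes follow the positive-marker routing", {
  m <- rbind(INS = c(10, 0, 0, 8), GCG = c(0, 10, 0, 9), SST = c(0, 0, 10, 0))
  colnames(m) <- paste0("c", 1:4)
  thr <- list(INS = list(mode = "manual", value = 5),
              GCG = list(mode = "manual", value = 5),
              SST = list(mode = "manual", value = 5))
  calls <- callPositivity(m, thresholds = thr)$calls
  expect_identical(calls$subtype[1:3], c("Insulin+", "Glucagon+", "SST-28+"))
  # double positive resolved toward the higher z-score
  expect_identical(calls$subtype[4], "Glucagon+")
  low <- callPositivity(m * 0 + 1, thresholds = thr)$calls
  expect_true(all(low$subtype == "negative"))
})

test_that("co-occurrence fractions carry Wilson intervals and group means", {
  calls <- data.frame(cell_id = 1:8,
                      X = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
                      Y = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
  sub <- cooccurrenceStats(calls, "X", "Y")
  expect_equal(sub$fraction, 1)        # X+ is a subset of Y+
  expect_identical(sub$nX, 4L)

  set.seed(17)
  n <- 1e4
  big <- data.frame(cell_id = seq_len(n), X = rep(TRUE, n),
                    Y = stats::runif(n) < 0.3)
  ind <- cooccurrenceStats(big, "X", "Y")
  expect_gt(ind$fraction, 0.28)
  expect_lt(ind$fraction, 0.32)
  expect_true(ind$ci[1] < 0.3 && ind$ci[2] > 0.28)

  none <- cooccurrenceStats(data.frame(cell_id = 1, X = FALSE, Y = TRUE),
                            "X", "Y")
  expect_true(is.na(none$fraction))
  expect_identical(none$nX, 0L)
  expect_error(cooccurrenceStats(calls, "X", "Z"), "no positivity call")
})

test_that("planted 2x2 group shifts in a quantitative marker are recovered", {
  set.seed(19)
  n <- 6000
  x <- stats::runif(n) < 0.5
  y <- stats::runif(n) < 0.5
  mu <- ifelse(x & y, 3.0, ifelse(!x & !y, 2.0, 2.5))
  vals <- stats::rnorm(n, mu, 0.5)
  calls <- data.frame(cell_id = seq_len(n), P16 = x, `53BP1` = y,
                      check.names = FALSE)
  st <- cooccurrenceStats(calls, "P16", "53BP1", quantValues = vals)
  g <- st$groups
  both <- g$mean[g$group == "P16+/53BP1+"]
  neither <- g$mean[g$group == "P16-/53BP1-"]
  semB <- 0.5 / sqrt(g$n[g$group == "P16+/53BP1+"])
  semN <- 0.5 / sqrt(g$n[g$group == "P16-/53BP1-"])
  expect_lt(abs(both - 3.0), 3 * semB)
  expect_lt(abs(neither - 2.0), 3 * semN)
  expect_identical(sum(g$n), 6000L)
})
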