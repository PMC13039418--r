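test_that("nucleus detection handles blank, clean and touching inputs", {
  expect_identical(max(detectNuclei(matrix(0, 64, 64))), 0L)
  expect_identical(max(detectNuclei(matrix(5, 64, 64))), 0L)

  ph <- simulateTissue(phantomConfig(imageSizePx = c(448, 448), nCells = 50,
                                     nIslets = 0, backgroundAmplitude = 0,
                                     noiseSd = 0, seed = 51))
  lab <- detectNuclei(getChannel(ph@image, "DAPI"))
  expect_identical(max(lab), 50L)
  # centroids match ground truth within 1 px after nearest matching
  truth <- groundTruth(ph, "cellTruth")
  idx <- which(lab > 0)
  cy <- tapply((idx - 1) %% 448, lab[idx], mean)
  cx <- tapply((idx - 1) %/% 448, lab[idx], mean)
  for (k in seq_along(cy)) {
    d <- sqrt((truth$y - cy[k])^2 + (truth$x - cx[k])^2)
    expect_lt(min(d), 1)
  }

  # two touching blobs with distinct cores are split by the watershed
  img <- matrix(0, 64, 64)
  img[diskMask(64, 64, 32, 24, 9)] <- 100
  img[diskMask(64, 64, 32, 41, 9)] <- 100
  lab2 <- detectNuclei(img, correctBackground = FALSE, smoothSigma = 1)
  expect_identical(max(lab2), 2L)

  # pluggable detector interface
  ext <- function(channel) matrix(rep(c(0L, 7L), each = 32 * 64), 64, 64)
  expect_identical(sort(unique(as.vector(detectNuclei(img, detector = ext)))),
                   c(0L, 1L))
})

test_that("expandCells reproduces the disk and midpoint geometry", {
  nuc <- matrix(0L, 41, 41)
  nuc[21, 21] <- 1L
  # single-pixel nucleus, expansion 7: the discrete Euclidean disk
  cell <- expandCells(nuc, 7L)
  expect_identical(sum(cell == 1L), sum(diskMask(41, 41, 21, 21, 7)))

  # an isolated disk nucleus of radius r grows to (the discrete version of)
  # the disk of radius r + 7: bracketed by the lattice disks of radius
  # r + 7 - 1 and r + 7, with the area within a few percent of pi (r+7)^2
  nuc2 <- matrix(0L, 61, 61)
  nuc2[diskMask(61, 61, 31, 31, 5)] <- 1L
  cell2 <- expandCells(nuc2, 7L) == 1L
  expect_true(all(cell2[diskMask(61, 61, 31, 31, 11)]))
  expect_true(all(diskMask(61, 61, 31, 31, 12)[cell2]))
  expect_lt(abs(sum(cell2) - pi * 12^2) / (pi * 12^2), 0.05)

  # two nuclei 10 px apart: each extends at most 5 px toward the other
  nuc3 <- matrix(0L, 41, 61)
  nuc3[21, 21] <- 1L
  nuc3[21, 31] <- 2L
  cell3 <- expandCells(nuc3, 7L)
  expect_identical(cell3[21, 26], 1L)  # equidistant -> smaller label
  expect_identical(cell3[21, 27], 2L)
  expect_true(all(cell3[, 28:31][cell3[, 28:31] > 0] == 2L))
  expect_error(expandCells(nuc3, -1), "non-negative")
  expect_identical(expandCells(nuc3, 0L), nuc3)
})

test_that("expandCells equals the brute-force oracle on random instances", {
  for (s in 1:8) {
    ph <- simulateTissue(phantomConfig(
      imageSizePx = c(128, 128), nCells = sample(3:12, 1), nIslets = 0,
      profiles = NULL, expansionUm = 0, noiseSd = 0,
      backgroundAmplitude = 0, seed = 60 + s))
    nuc <- groundTruth(ph, "nuclei")
    expect_identical(expandCells(nuc, 7L), tessellationOracle(nuc, 7L))
  }
})

test_that("the tessellation is monotone in the expansion distance", {
  ph <- simulateTissue(phantomConfig(imageSizePx = c(128, 128), nCells = 10,
                                     nIslets = 0, profiles = NULL,
                                     expansionUm = 0, seed = 70))
  nuc <- groundTruth(ph, "nuclei")
  prev <- expandCells(nuc, 0L)
  for (e in c(2L, 4L, 7L, 10L)) {
    cur <- expandCells(nuc, e)
    # pixels assigned at a smaller expansion keep exactly that label
    expect_true(all(cur[prev > 0] == prev[prev > 0]))
    prev <- cur
  }
})

test_that("background estimation removes small structures, keeps ramps", {
  cst <- matrix(7, 100, 100)
  expect_identical(estimateBackground(cst), cst)

  set.seed(8)
  img <- matrix(120, 300, 300)
  for (k in 1:25) {
    y <- sample(5:295, 1)
    x <- sample(5:295, 1)
    img[y:(y + 2), x:(x + 2)] <- 1200
  }
  bg <- estimateBackground(img)
  interior <- bg[41:260, 41:260]
  expect_lt(max(abs(interior - 120)) / 120, 0.01)

  ramp <- matrix(seq(0, 100, length.out = 200), 200, 200)
  bgr <- estimateBackground(ramp)
  expect_lt(max(abs(bgr[41:160, 41:160] - ramp[41:160, 41:160])), 2)

  expect_error(estimateBackground(matrix(0, 5, 5), downsize = 10),
               "smaller than")
  expect_error(estimateBackground(cst, windowPx = 4), "odd")
})

test_that("background subtraction clamps at zero", {
  ch <- matrix(stats::runif(64, 0, 10), 8, 8)
  expect_identical(subtractBackground(ch, ch), matrix(0, 8, 8))
  expect_equal(subtractBackground(ch + 10, ch), matrix(10, 8, 8))
  hi <- ch + 5
  expect_true(all(subtractBackground(ch, hi) == 0))
  expect_error(subtractBackground(ch, matrix(0, 4, 4)), "shapes differ")
})

test_that("morphology features follow the discretisation oracles", {
  nuc <- matrix(0L, 41, 41)
  nuc[diskMask(41, 41, 21, 21, 10)] <- 1L
  img <- MultiplexImage(list(M = matrix(2, 41, 41)), pixelSizeUm = 0.65)
  f <- extractFeatures(nuc, nuc, img, correctBackground = FALSE)
  expect_lt(abs(f$equivalent_radius_px - 10) / 10, 0.02)
  expect_gte(f$circularity, 0.85)
  expect_lte(f$circularity, 1)
  expect_lt(abs(f$aspect_ratio - 1), 0.05)
  expect_equal(f$nucleus_area_um2, f$nucleus_area_px * 0.65^2)
})

test_that("feature extraction on ground-truth labels is exact without noise", {
  ph <- noiselessPhantom(n = 30, size = 256, seed = 15)
  nuc <- groundTruth(ph, "nuclei")
  cells <- groundTruth(ph, "cells")
  tr <- groundTruth(ph, "intensities")
  f <- extractFeatures(nuc, cells, ph@image, correctBackground = FALSE)
  # nuclear marker: nuclear mean equals the drawn intensity
  expect_equal(f[["53BP1_nuc_mean"]], unname(tr[f$cell_id, "53BP1"]),
               tolerance = 1e-12)
  # cytosolic marker: whole-cell total over the annulus area is exact
  annulus <- f$cell_area_px - f$nucleus_area_px
  expect_equal(f[["INS_cell_total"]] / annulus, unname(tr[f$cell_id, "INS"]),
               tolerance = 1e-12)
  # algebraic identity: total = mean * pixel count, every cell and channel
  for (ch in channelNames(ph@image)) {
    expect_equal(f[[paste0(ch, "_nuc_total")]],
                 f[[paste0(ch, "_nuc_mean")]] * f$nucleus_area_px,
                 tolerance = 1e-9)
    expect_equal(f[[paste0(ch, "_cell_total")]],
                 f[[paste0(ch, "_cell_mean")]] * f$cell_area_px,
                 tolerance = 1e-9)
  }
  # tessellation sanity asserted per run
  expect_lte(sum(f$cell_area_px), prod(dim(nuc)))
  expect_error(extractFeatures(nuc, cells + 1L, ph@image), "absent")
})
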