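test_that("phantom generation is bit-reproducible for a fixed seed", {
  cfg <- phantomConfig(imageSizePx = c(128, 128), nCells = 25, seed = 9)
  a <- simulateTissue(cfg)
  b <- simulateTissue(cfg)
  expect_identical(a@nucleusLabels, b@nucleusLabels)
  expect_identical(a@cellLabels, b@cellLabels)
  expect_identical(a@intensities, b@intensities)
  for (ch in channelNames(a@image))
    expect_identical(getChannel(a@image, ch), getChannel(b@image, ch))
})

test_that("an empty phantom is background plus noise with empty label maps", {
  ph <- simulateTissue(phantomConfig(imageSizePx = c(64, 64), nCells = 0,
                                     nIslets = 0, seed = 1))
  expect_identical(max(ph@nucleusLabels), 0L)
  expect_identical(max(ph@cellLabels), 0L)
  expect_equal(nrow(groundTruth(ph, "cellTruth")), 0)
  expect_true(all(getChannel(ph@image, "DAPI") >= 0))
})

test_that("noiseless construction renders configured intensities exactly", {
  ph <- noiselessPhantom(n = 25, size = 192, seed = 13)
  nuc <- groundTruth(ph, "nuclei")
  tr <- groundTruth(ph, "intensities")
  # nuclear marker: mean over the nucleus mask equals the drawn value
  ch <- getChannel(ph@image, "53BP1")
  for (L in unique(nuc[nuc > 0])) {
    expect_equal(mean(ch[nuc == L]), unname(tr[L, "53BP1"]), tolerance = 1e-12)
  }
  # cytosolic marker: constant on the annulus between nucleus and cell edge
  cells <- groundTruth(ph, "cells")
  ins <- getChannel(ph@image, "INS")
  L <- unique(nuc[nuc > 0])[1]
  annulus <- cells == L & nuc == 0
  expect_equal(mean(ins[annulus]), unname(tr[L, "INS"]), tolerance = 1e-12)
  expect_true(all(ins[nuc == L] == 0))
})

test_that("nuclei are non-overlapping and labels are consistent", {
  for (s in 1:5) {
    ph <- simulateTissue(phantomConfig(imageSizePx = c(160, 160),
                                       nCells = 30, seed = 20 + s))
    nuc <- groundTruth(ph, "nuclei")
    cel <- groundTruth(ph, "cells")
    ids <- sort(unique(nuc[nuc > 0]))
    expect_identical(ids, sort(unique(cel[cel > 0])))
    expect_identical(ids, seq_len(30))
    # nucleus pixels keep their label in the cell map
    expect_true(all(cel[nuc > 0] == nuc[nuc > 0]))
  }
})

test_that("impossible packing raises a capacity error", {
  expect_error(
    simulateTissue(phantomConfig(imageSizePx = c(64, 64), nCells = 500,
                                 seed = 1)),
    "capacity")
})

test_that("per-cluster empirical marker means match configured profiles", {
  profiles <- defaultPhantomProfiles()
  cfg <- phantomConfig(imageSizePx = c(820, 820), nCells = 500,
                       nIslets = 1, isletRadiusRangeUm = c(80, 90),
                       backgroundAmplitude = 0, noiseSd = 0, seed = 31)
  ph <- simulateTissue(cfg)
  truth <- groundTruth(ph, "cellTruth")
  intens <- groundTruth(ph, "intensities")
  allProf <- c(profiles$acinar, profiles$islet)
  for (cl in unique(truth$cluster_id)) {
    rows <- truth$cluster_id == cl
    if (sum(rows) < 10) next
    p <- allProf[[cl]]
    for (mk in c("INS", "53BP1")) {
      sem <- p$sd[[mk]] / sqrt(sum(rows))
      expect_lt(abs(mean(intens[rows, mk]) - p$mean[[mk]]),
                3 * sem + 1e-9)
    }
  }
})

test_that("round pair with identity transform is pixel-identical", {
  ph <- noiselessPhantom(n = 15, size = 128, nIslets = 0)
  rp <- simulateRoundPair(ph@image, RigidTransform(), 0)
  for (ch in channelNames(ph@image))
    expect_identical(getChannel(rp$moving, ch), getChannel(ph@image, ch))
  expect_equal(rp$rigid@tyPx, 0)
  expect_identical(max(abs(c(rp$deformation@dy, rp$deformation@dx))), 0)
})

test_that("round pair stores the planted transform it was given", {
  ph <- noiselessPhantom(n = 15, size = 128, nIslets = 0)
  tr <- RigidTransform(txPx = 12, tyPx = -7)
  rp <- simulateRoundPair(ph@image, tr, 0)
  expect_equal(rp$rigid@txPx, 12)
  expect_equal(rp$rigid@tyPx, -7)
  expect_error(simulateRoundPair(ph@image, tr, deformAmplitudePx = 200,
                                 stepPx = 500),
               "smaller than")
})

test_that("the planted warp is invertible on the image interior", {
  ph <- simulateTissue(phantomConfig(imageSizePx = c(300, 300), nCells = 80,
                                     nIslets = 0, profiles = NULL,
                                     expansionUm = 0, seed = 7))
  rigid <- RigidTransform(thetaRad = 3 * pi / 180, txPx = 3, tyPx = -2)
  rp <- simulateRoundPair(ph@image, rigid, deformAmplitudePx = 4,
                          stepPx = 100, seed = 8)
  # forward map of the alignment, then the generator's numeric inverse,
  # must return interior points to within 0.1 px
  def <- rp$deformation
  pts <- expand.grid(y = seq(60, 240, by = 30), x = seq(60, 240, by = 30))
  d <- mplexquant:::evalDeformation(def, pts$y, pts$x)
  fwd <- mplexquant:::mapRigid(pts$y + d$dy, pts$x + d$dx, rigid, c(300, 300))
  inv <- invertTransform(rigid)
  q <- mplexquant:::mapRigid(fwd$y, fwd$x, inv, c(300, 300))
  qy <- q$y
  qx <- q$x
  for (i in 1:6) {
    dd <- mplexquant:::evalDeformation(def, qy, qx)
    qy <- q$y - dd$dy
    qx <- q$x - dd$dx
  }
  expect_lt(max(abs(qy - pts$y)), 0.1)
  expect_lt(max(abs(qx - pts$x)), 0.1)
})

test_that("planted islet populations hit their target correlation", {
  pop0 <- simulateIsletPopulation(1e4, 0, seed = 2)
  expect_lt(abs(stats::cor(pop0$area_um2, pop0$marker_mean)), 0.05)
  pop4 <- simulateIsletPopulation(1e4, 0.4, seed = 3)
  r <- stats::cor(pop4$area_um2, pop4$marker_mean)
  expect_gt(r, 0.37)
  expect_lt(r, 0.43)
  expect_error(simulateIsletPopulation(1e4, 1), "rTarget")
  expect_error(simulateIsletPopulation(2, 0.5), ">= 3")
})

test_that("expression-profile mixtures are seeded and weighted correctly", {
  sim <- simulateExpressionProfiles(2000, seed = 4)
  sim2 <- simulateExpressionProfiles(2000, seed = 4)
  expect_identical(sim$expr, sim2$expr)
  expect_equal(dim(sim$expr), c(6, 2000))
  # diffuse mass holds ~30% of cells
  expect_lt(abs(mean(sim$clusterId == 1) - 0.3), 0.04)
  badProfiles <- defaultExpressionProfiles()
  badProfiles[[1]]$weight <- 0.5
  expect_error(simulateExpressionProfiles(10, badProfiles), "sum to 1")
})
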