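test_that("rescaling to a common pixel size follows the size arithmetic", {
  img <- MultiplexImage(list(DAPI = matrix(stats::runif(100 * 100), 100, 100)),
                        pixelSizeUm = 0.65)
  expect_identical(rescaleToPixelSize(img, 0.65), img)
  half <- rescaleToPixelSize(img, 1.30)
  expect_identical(dim(half), c(50L, 50L))
  expect_equal(pixelSizeUm(half), 1.30)
  cst <- MultiplexImage(list(DAPI = matrix(4.2, 80, 80)), pixelSizeUm = 1)
  out <- rescaleToPixelSize(cst, 1.7)
  expect_true(all(abs(getChannel(out, "DAPI") - 4.2) < 1e-12))
  expect_error(rescaleToPixelSize(img, -1), "positive")
})

test_that("registering an image to itself recovers the identity", {
  ph <- simulateTissue(phantomConfig(imageSizePx = c(512, 512), nCells = 220,
                                     nIslets = 0, profiles = NULL,
                                     expansionUm = 0, seed = 41))
  nuc <- getChannel(ph@image, "DAPI")
  est <- estimateRigid(nuc, nuc)
  expect_lt(sqrt(est@tyPx^2 + est@txPx^2), 0.5)
  expect_lt(abs(est@thetaRad) * 180 / pi, 0.2)
  def <- estimateDeformation(nuc, nuc, stepPx = 128)
  expect_lt(max(sqrt(def@dy^2 + def@dx^2)), 0.5)
  expect_error(estimateRigid(matrix(1, 64, 64), matrix(1, 64, 64)),
               "constant")
})

test_that("planted translations and rotations are recovered", {
  ph <- simulateTissue(phantomConfig(imageSizePx = c(512, 512), nCells = 220,
                                     nIslets = 0, profiles = NULL,
                                     expansionUm = 0, seed = 42))
  nuc <- getChannel(ph@image, "DAPI")
  # pure translation (12, -7)
  rp <- simulateRoundPair(ph@image, RigidTransform(txPx = -7, tyPx = 12), 0)
  est <- estimateRigid(nuc, getChannel(rp$moving, "DAPI"))
  expect_lt(sqrt((est@tyPx - 12)^2 + (est@txPx + 7)^2), 0.5)
  expect_lt(abs(est@thetaRad) * 180 / pi, 0.5)
  # rotation 5 degrees plus shift
  tr <- RigidTransform(thetaRad = 5 * pi / 180, txPx = 6, tyPx = -9)
  rp2 <- simulateRoundPair(ph@image, tr, 0)
  est2 <- estimateRigid(nuc, getChannel(rp2$moving, "DAPI"))
  expect_lt(sqrt((est2@tyPx + 9)^2 + (est2@txPx - 6)^2), 0.5)
  expect_lt(abs(est2@thetaRad - tr@thetaRad) * 180 / pi, 0.5)
})

test_that("featureless tiles inherit interpolated neighbour displacements", {
  set.seed(6)
  fixed <- mplexquant:::gaussianSmooth(matrix(stats::rnorm(384 * 384),
                                              384, 384), 1.5)
  # uniform planted shift of (2, 1): every confident node should see it
  moving <- matrix(0, 384, 384)
  moving[3:384, 2:384] <- fixed[1:382, 1:383]
  blank <- 61:201  # covers the whole window of the node at (128, 128)
  fixed[blank, blank] <- 0
  moving[blank, blank] <- 0
  def <- estimateDeformation(fixed, moving, stepPx = 128, windowPx = 128,
                             iterations = 1)
  expect_lt(max(abs(def@dy - 2)), 0.5)
  expect_lt(max(abs(def@dx - 1)), 0.5)
  expect_error(estimateDeformation(fixed, moving, stepPx = 32), ">= 64")
  expect_error(estimateDeformation(fixed, moving[1:100, 1:100], 128),
               "same dimensions")
})

test_that("applyTransform is exact for identity and conserves intensity", {
  ph <- noiselessPhantom(n = 20, size = 160, nIslets = 0)
  out <- applyTransform(ph@image, RigidTransform(),
                        mplexquant:::zeroDeformation(c(160, 160), 80))
  for (ch in channelNames(ph@image))
    expect_identical(getChannel(out, ch), getChannel(ph@image, ch))
  # constant image stays constant on the interior under a real warp
  cst <- MultiplexImage(list(DAPI = matrix(3, 160, 160)), 0.65)
  w <- applyTransform(cst, RigidTransform(thetaRad = 0.05, txPx = 2,
                                          tyPx = -3))
  expect_true(all(abs(getChannel(w, "DAPI")[40:120, 40:120] - 3) < 1e-9))
  # compactly supported blob: total intensity conserved within 1%
  blob <- matrix(0, 160, 160)
  blob[70:90, 70:90] <- outer(stats::dnorm(seq(-2, 2, length.out = 21)),
                              stats::dnorm(seq(-2, 2, length.out = 21)))
  bi <- MultiplexImage(list(DAPI = blob), 0.65)
  wb <- applyTransform(bi, RigidTransform(thetaRad = 0.1, txPx = 5.3,
                                          tyPx = -4.7))
  expect_lt(abs(sum(getChannel(wb, "DAPI")) - sum(blob)) / sum(blob), 0.01)
})

test_that("warp-then-estimate closes to a small residual", {
  ph <- simulateTissue(phantomConfig(imageSizePx = c(384, 384), nCells = 140,
                                     nIslets = 0, profiles = NULL,
                                     expansionUm = 0, seed = 44))
  nuc <- getChannel(ph@image, "DAPI")
  rigid <- RigidTransform(thetaRad = 2 * pi / 180, txPx = 5, tyPx = -4)
  rp <- simulateRoundPair(ph@image, rigid, deformAmplitudePx = 3,
                          stepPx = 128, seed = 45)
  est <- estimateRigid(nuc, getChannel(rp$moving, "DAPI"))
  aligned <- applyTransform(rp$moving, est,
                            estimateDeformation(nuc,
                              mplexquant:::warpRaster(
                                getChannel(rp$moving, "DAPI"), est),
                              stepPx = 128))
  resid <- estimateDeformation(nuc, getChannel(aligned, "DAPI"),
                               stepPx = 128, iterations = 1)
  inner <- 2:(nrow(resid@dy) - 1)
  expect_lt(max(sqrt(resid@dy[inner, inner]^2 + resid@dx[inner, inner]^2)), 1)
})

test_that("registerRounds handles empty input and self-registration", {
  ph <- simulateTissue(phantomConfig(imageSizePx = c(384, 384), nCells = 150,
                                     nIslets = 0, profiles = NULL,
                                     expansionUm = 0, seed = 46))
  empty <- registerRounds(ph@image, list(), stepPx = 128)
  expect_length(empty$aligned, 0)
  res <- registerRounds(ph@image, list(ph@image), stepPx = 128)
  tr <- res$transforms[[1]]
  expect_lt(sqrt(tr$rigid@tyPx^2 + tr$rigid@txPx^2), 0.5)
  expect_lt(abs(tr$rigid@thetaRad) * 180 / pi, 0.2)
  expect_lt(max(sqrt(tr$deformation@dy^2 + tr$deformation@dx^2)), 0.5)
})

test_that("transforms survive the text serialisation round trip", {
  tr <- list(r2 = list(
    rigid = RigidTransform(thetaRad = 0.02, txPx = 3.5, tyPx = -1.25),
    deformation = DeformationGrid(128, matrix(stats::rnorm(9), 3, 3),
                                  matrix(stats::rnorm(9), 3, 3))))
  dir <- withr::local_tempdir()
  f <- file.path(dir, "tf.yaml")
  writeTransforms(tr, f)
  back <- readTransforms(f)
  expect_equal(back$r2$rigid@thetaRad, 0.02)
  expect_equal(back$r2$rigid@txPx, 3.5)
  expect_equal(back$r2$deformation@dy, tr$r2$deformation@dy,
               tolerance = 1e-12)
})
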