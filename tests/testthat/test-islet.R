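test_that("islet segmentation applies threshold, refinement and area rule", {
  z <- matrix(0, 300, 300)
  expect_identical(max(segmentIslets(z, z, thresholds = c(10, 10))), 0L)

  # 500 um2 disk retained, 300 um2 disk removed (0.65 um pixels)
  r500 <- sqrt(500 / pi) / 0.65   # ~19.4 px
  r300 <- sqrt(300 / pi) / 0.65   # ~15.0 px
  ins <- matrix(0, 300, 300)
  ins[diskMask(300, 300, 80, 80, r500)] <- 100
  ins[diskMask(300, 300, 80, 220, r300)] <- 100
  lab <- segmentIslets(ins, z, thresholds = c(50, 50))
  expect_identical(max(lab), 1L)
  expect_gt(sum(lab[1:150, 1:150] > 0), 0)
  expect_identical(sum(lab[, 151:300] > 0), 0L)

  # a hole below threshold inside a stained region is filled
  ins2 <- matrix(0, 200, 200)
  ins2[diskMask(200, 200, 100, 100, 40)] <- 100
  ins2[diskMask(200, 200, 100, 100, 10)] <- 0
  lab2 <- segmentIslets(ins2, matrix(0, 200, 200), thresholds = c(50, 50))
  expect_true(all(lab2[diskMask(200, 200, 100, 100, 9)] == 1L))
  expect_error(segmentIslets(ins2, z, thresholds = c(1, 1)), "same shape")
})

test_that("morphological refinement is idempotent on its own output", {
  set.seed(77)
  for (s in 1:5) {
    m <- matrix(stats::runif(150 * 150) > 0.6, 150, 150)
    once <- mplexquant:::refineIsletMask(m, 3L)
    twice <- mplexquant:::refineIsletMask(once, 3L)
    expect_identical(twice, once)
  }
})

test_that("islet features report exact intensities and compositions", {
  ph <- noiselessPhantom(n = 50, size = 320, seed = 19)
  islets <- groundTruth(ph, "islets")
  tab <- isletFeatures(islets, ph@image)
  # noiseless: islet mean of a channel equals the direct mask mean
  ins <- getChannel(ph@image, "INS")
  expect_equal(tab$INS_mean[1], mean(ins[islets == 1]), tolerance = 1e-12)
  expect_equal(tab$INS_total[1], sum(ins[islets == 1]), tolerance = 1e-9)
  # rasterised circular islet: circularity >= 0.9, aspect ratio ~ 1
  expect_gte(tab$circularity[1], 0.9)
  expect_lt(abs(tab$aspect_ratio[1] - 1), 0.1)
  expect_equal(tab$area_um2, tab$area_px * 0.65^2)

  # composition: 10 member cells, 4 called positive -> fraction 0.4
  cells <- data.frame(cell_id = 1:10,
                      y = rep(tab$area_px[1]^0, 10) * 0,  # placeholder
                      x = numeric(10))
  ctr <- which(islets == 1, arr.ind = TRUE)
  cells$y <- ctr[seq_len(10), 1] - 1
  cells$x <- ctr[seq_len(10), 2] - 1
  calls <- data.frame(cell_id = 1:10, P16 = rep(c(TRUE, FALSE), c(4, 6)),
                      subtype = rep("negative", 10))
  tab2 <- isletFeatures(islets, ph@image, cells = cells, positivity = calls)
  expect_identical(tab2$n_cells[1], 10L)
  expect_equal(tab2$P16_pos_frac[1], 0.4)
  expect_equal(tab2$subtype_negative_frac[1], 1)
})

test_that("correlation matrices have the Pearson/t-test structure", {
  x <- stats::rnorm(50)
  tab <- data.frame(a = x, b = -x, c = stats::rnorm(50), d = rep(1, 50))
  cm <- isletCorrelationMatrix(tab, c("a", "b", "c", "d"))
  expect_equal(cm$r["a", "a"], 1)
  expect_equal(cm$p["a", "a"], 0)
  expect_equal(cm$r["a", "b"], -1)
  expect_true(isSymmetric(cm$r[1:3, 1:3]))
  expect_true(all(abs(cm$r[1:3, 1:3]) <= 1))
  expect_true(all(is.na(cm$r["d", ])))   # zero variance -> missing
  # p-value agrees with cor.test (independent route)
  ct <- stats::cor.test(tab$a, tab$c)
  expect_equal(cm$p["a", "c"], ct$p.value, tolerance = 1e-12)
  expect_error(isletCorrelationMatrix(tab[1:2, ], c("a", "b")), "3 islets")
  expect_error(isletCorrelationMatrix(tab, "nope"), "unknown")
})

test_that("planted islet-level correlation is recovered through the matrix", {
  pop <- simulateIsletPopulation(1e4, 0.4, seed = 23)
  cm <- isletCorrelationMatrix(pop, c("area_um2", "marker_mean"))
  expect_gt(cm$r["area_um2", "marker_mean"], 0.37)
  expect_lt(cm$r["area_um2", "marker_mean"], 0.43)
  expect_lt(cm$p["area_um2", "marker_mean"], 1e-10)
})

test_that("occurrence-vs-size profiles detect planted monotone trends", {
  set.seed(31)
  n <- 1000
  area <- stats::runif(n, 500, 5000)
  tab <- data.frame(area_um2 = area,
                    flat = rep(0.25, n),
                    rising = area / max(area) +
                      stats::rnorm(n, 0, 0.05))
  flat <- occurrenceVsSize(tab, "flat", nBins = 5)
  expect_true(all(abs(flat$bins$fraction_mean - 0.25) < 1e-12))
  expect_true(is.na(flat$r) || abs(flat$r) < 0.05)
  up <- occurrenceVsSize(tab, "rising", nBins = 5)
  expect_gte(up$r, 0.9)
  expect_true(all(diff(up$bins$fraction_mean) > 0))
  one <- occurrenceVsSize(tab, "rising", nBins = 1)
  expect_identical(nrow(one$bins), 1L)
  expect_error(occurrenceVsSize(tab[1:3, ], "rising", nBins = 5),
               "more bins")
  expect_error(occurrenceVsSize(tab, "nope"), "unknown column")
})
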