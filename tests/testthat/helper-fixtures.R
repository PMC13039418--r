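# shared fixtures and independent oracles

# brute-force nearest-nucleus-pixel tessellation: for every nucleus, scan
# all pixels of its padded bounding box against every nucleus pixel
# (mechanism independent of the offset-scan used by expandCells)
tessellationOracle <- function(nuclei, expansionPx) {
  nr <- nrow(nuclei)
  nc <- ncol(nuclei)
  best <- matrix(Inf, nr, nc)
  lab <- matrix(0L, nr, nc)
  ids <- sort(unique(nuclei[nuclei > 0]))
  r <- expansionPx
  for (L in ids) {
    pix <- which(nuclei == L, arr.ind = TRUE)
    y0 <- max(1, min(pix[, 1]) - r)
    y1 <- min(nr, max(pix[, 1]) + r)
    x0 <- max(1, min(pix[, 2]) - r)
    x1 <- min(nc, max(pix[, 2]) + r)
    ys <- y0:y1
    xs <- x0:x1
    subD <- matrix(Inf, length(ys), length(xs))
    for (k in seq_len(nrow(pix)))
      subD <- pmin(subD, outer((ys - pix[k, 1])^2, (xs - pix[k, 2])^2, "+"))
    curD <- best[ys, xs]
    curL <- lab[ys, xs]
    take <- subD <= r^2 &
      (subD < curD | (subD == curD & (curL == 0 | L < curL)))
    curD[take] <- subD[take]
    curL[take] <- L
    best[ys, xs] <- curD
    lab[ys, xs] <- curL
  }
  lab[nuclei > 0] <- nuclei[nuclei > 0]
  lab
}

# filled disk as a logical matrix (1-based centre)
diskMask <- function(nr, nc, cy, cx, r) {
  yy <- matrix(seq_len(nr), nr, nc)
  xx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}

# small noiseless phantom shared by feature-identity tests
noiselessPhantom <- function(n = 40, size = 256, seed = 5, nIslets = 1) {
  simulateTissue(phantomConfig(
    imageSizePx = c(size, size), nCells = n, nIslets = nIslets,
    isletRadiusRangeUm = c(30, 45),
    backgroundAmplitude = 0, noiseSd = 0, seed = seed))
}

quietly <- function(expr) suppressMessages(expr)
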