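# Internal raster helpers shared by registration, segmentation and background
# estimation. All coordinates are 0-based (row, col), origin top-left.

#' Bilinear sampling of a raster at fractional coordinates
#'
#' @param img numeric matrix.
#' @param y,x numeric vectors of 0-based sample coordinates (row, col).
#' @param fill value for samples outside the image domain.
#' @return numeric vector of sampled values, same length as `y`.
#' @noRd
bilinearSample <- function(img, y, x, fill = 0) {
  nr <- nrow(img)
  nc <- ncol(img)
  out <- rep(as.numeric(fill), length(y))
  ok <- y >= 0 & y <= nr - 1 & x >= 0 & x <= nc - 1 & is.finite(y) & is.finite(x)
  if (!any(ok)) return(out)
  yy <- y[ok]
  xx <- x[ok]
  y0 <- pmin(floor(yy), nr - 2)
  x0 <- pmin(floor(xx), nc - 2)
  if (nr == 1) y0 <- rep(0, length(yy))
  if (nc == 1) x0 <- rep(0, length(xx))
  fy <- yy - y0
  fx <- xx - x0
  # column-major linear indices (1-based)
  i00 <- y0 + 1 + x0 * nr
  i10 <- i00 + as.numeric(nr > 1)
  i01 <- i00 + nr * as.numeric(nc > 1)
  i11 <- i01 + as.numeric(nr > 1)
  v <- (1 - fy) * (1 - fx) * img[i00] + fy * (1 - fx) * img[i10] +
    (1 - fy) * fx * img[i01] + fy * fx * img[i11]
  out[ok] <- v
  out
}

#' Sample a raster on the full pixel grid at mapped coordinates
#'
#' `coords` is a function(y, x) returning list(y =, x =) of source coordinates
#' for each 0-based target pixel; returns a matrix the same shape as `shape`.
#' @noRd
resampleGrid <- function(img, shape, coords, fill = 0) {
  nr <- shape[1]
  nc <- shape[2]
  yy <- rep(seq_len(nr) - 1, times = nc)
  xx <- rep(seq_len(nc) - 1, each = nr)
  cc <- coords(yy, xx)
  matrix(bilinearSample(img, cc$y, cc$x, fill = fill), nr, nc)
}

#' Block-average downsizing by an integer factor
#'
#' Edge blocks smaller than `factor` are averaged over the pixels present, so
#' no part of the image is discarded.
#' @noRd
blockDownsize <- function(img, factor) {
  factor <- as.integer(factor)
  if (factor < 1) stop("downsize factor must be >= 1")
  if (factor == 1) return(img)
  nr <- nrow(img)
  nc <- ncol(img)
  ro <- ceiling(nr / factor)
  co <- ceiling(nc / factor)
  ridx <- rep(seq_len(ro), each = factor, length.out = nr)
  cidx <- rep(seq_len(co), each = factor, length.out = nc)
  sums <- rowsum(img, ridx)          # ro x nc
  sums <- t(rowsum(t(sums), cidx))   # ro x co
  cnt <- tabulate(ridx, ro) %o% tabulate(cidx, co)
  sums / cnt
}

#' Bilinear upscaling of a block-downsized raster back to an original shape
#'
#' Block b (1-based) has center (b - 1) * factor + (factor - 1) / 2 in the
#' original 0-based frame; interpolation is between block centers with
#' clamped extrapolation at the borders.
#' @noRd
blockUpsize <- function(small, shape, factor) {
  nr <- shape[1]
  nc <- shape[2]
  resampleGrid(small, shape, function(y, x) {
    gy <- (y - (factor - 1) / 2) / factor
    gx <- (x - (factor - 1) / 2) / factor
    list(
      y = pmin(pmax(gy, 0), nrow(small) - 1),
      x = pmin(pmax(gx, 0), ncol(small) - 1)
    )
  })
}

#' Exact 2D median filter with replicate padding
#'
#' Direct sorted-window implementation; intended for the small down-sized
#' rasters used in background estimation.
#' @noRd
medianFilter2D <- function(img, window) {
  window <- as.integer(window)
  if (window %% 2L != 1L || window < 1L) stop("median window must be odd and >= 1")
  if (window == 1L) return(img)
  h <- (window - 1L) %/% 2L
  nr <- nrow(img)
  nc <- ncol(img)
  # replicate-pad
  ri <- pmin(pmax(seq(1 - h, nr + h), 1), nr)
  ci <- pmin(pmax(seq(1 - h, nc + h), 1), nc)
  pad <- img[ri, ci, drop = FALSE]
  n <- nr * nc
  stack <- matrix(0, n, window * window)
  k <- 0L
  for (dc in 0:(window - 1L)) {
    for (dr in 0:(window - 1L)) {
      k <- k + 1L
      stack[, k] <- pad[dr + seq_len(nr), dc + seq_len(nc)]
    }
  }
  med <- apply(stack, 1, stats::median)
  matrix(med, nr, nc)
}

#' Cyclic FFT cross-correlation peak between two equally sized rasters
#'
#' Finds the integer shift d (within `maxShift`) maximising
#' sum_x a(x) * b(x + d) after mean removal, then refines it by a separable
#' parabolic fit around the peak. The returned `ncc` is the peak correlation
#' normalised by the L2 norms of the mean-removed images (1 for identical
#' images at zero shift).
#'
#' @return list(dy, dx, ncc) or NULL if either input is constant.
#' @noRd
xcorrPeak <- function(a, b, maxShift = NULL) {
  a <- a - mean(a)
  b <- b - mean(b)
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NULL)
  nr <- nrow(a)
  nc <- ncol(a)
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE)) / (nr * nc)
  # cc[1 + ((dy) mod nr), 1 + ((dx) mod nc)] = sum_x a(x) b(x + (dy,dx))
  if (is.null(maxShift)) maxShift <- floor(min(nr, nc) / 2) - 1
  ms <- min(maxShift, floor((min(nr, nc) - 1) / 2))
  sh <- c(0:ms, if (ms >= 1) (-ms):(-1))
  ridx <- 1 + (sh %% nr)
  cidx <- 1 + (sh %% nc)
  sub <- cc[ridx, cidx, drop = FALSE]
  pk <- arrayInd(which.max(sub), dim(sub))
  dy <- sh[pk[1]]
  dx <- sh[pk[2]]
  val <- sub[pk[1], pk[2]]
  # separable parabolic sub-pixel refinement on the cyclic correlation surface
  pidx <- function(d, n) 1 + (d %% n)
  cm <- cc[pidx(dy - 1, nr), pidx(dx, nc)]
  cp <- cc[pidx(dy + 1, nr), pidx(dx, nc)]
  den <- cm - 2 * val + cp
  sy <- if (den < 0) 0.5 * (cm - cp) / den else 0
  cm <- cc[pidx(dy, nr), pidx(dx - 1, nc)]
  cp <- cc[pidx(dy, nr), pidx(dx + 1, nc)]
  den <- cm - 2 * val + cp
  sx <- if (den < 0) 0.5 * (cm - cp) / den else 0
  list(
    dy = dy + max(-0.5, min(0.5, sy)),
    dx = dx + max(-0.5, min(0.5, sx)),
    ncc = val / (na * nb)
  )
}

#' Otsu threshold of a numeric vector (256-bin histogram)
#' @noRd
otsuThreshold <- function(v, nbins = 256L) {
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1)
  h <- as.numeric(tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins))
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  mt <- m[nbins]
  n <- w[nbins]
  wb <- w[-nbins]
  wf <- n - wb
  valid <- wb > 0 & wf > 0
  mb <- m[-nbins] / wb
  mf <- (mt - m[-nbins]) / wf
  between <- wb * wf * (mb - mf)^2
  between[!valid] <- -Inf
  mids[which.max(between)]
}

#' Crofton 4-direction perimeter estimate of a binary mask
#'
#' Counts foreground/background crossings along rows, columns and both
#' diagonals; diagonal counts are weighted by the 1/sqrt(2) line spacing.
#' @noRd
croftonPerimeter <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- as.integer(mask)
  nh <- sum(abs(m[, -1] - m[, -ncol(m)]))
  nv <- sum(abs(m[-1, ] - m[-nrow(m), ]))
  nd1 <- sum(abs(m[-1, -1] - m[-nrow(m), -ncol(m)]))
  nd2 <- sum(abs(m[-1, -ncol(m)] - m[-nrow(m), -1]))
  (pi / 8) * (nh + nv + (nd1 + nd2) / sqrt(2))
}

#' Gaussian 2D smoothing by separable convolution (replicate padding)
#' @noRd
gaussianSmooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  h <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-h:h, sd = sigma)
  k <- k / sum(k)
  smooth1 <- function(m) {
    nr <- nrow(m)
    ri <- pmin(pmax(seq(1 - h, nr + h), 1), nr)
    pad <- m[ri, , drop = FALSE]
    out <- matrix(0, nr, ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * pad[(i - 1) + seq_len(nr), , drop = FALSE]
    out
  }
  t(smooth1(t(smooth1(img))))
}

#' Relabel a label map so labels are contiguous 1..N
#'
#' Preserves the numeric order of the input labels.
#' @noRd
relabelSequential <- function(labels) {
  u <- unique(as.vector(labels))
  u <- sort(u[u > 0])
  if (length(u) == 0) return(labels)
  lut <- integer(max(u))
  lut[u] <- seq_along(u)
  out <- labels
  pos <- labels > 0
  out[pos] <- lut[labels[pos]]
  out
}
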