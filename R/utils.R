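# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed
#'
#' Child seeds are produced by a small multiplicative hash so that independent
#' pipeline stages / subjects get decorrelated but fully reproducible RNG
#' streams. Result always lies in [1, 2^31 - 2].
#'
#' @param master integer master seed.
#' @param index non-negative integer stream index.
#' @return integer seed.
#' @export
child_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  x <- (abs(as.double(master)) %% 2147483647) + 1
  for (i in seq_len(index %% 64L + 1L)) {
    x <- (x * 48271) %% 2147483647
  }
  x <- (x + 9973 * as.double(index)) %% 2147483646
  as.integer(x + 1)
}

# Evaluate expr with a local RNG state seeded by `seed`, restoring the caller's
# RNG afterwards, so package functions never disturb the global stream.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Centered moving average with odd window, edges handled by shrinking window.
moving_average <- function(x, window) {
  n <- length(x)
  window <- max(1L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  h <- window %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Complex circular white noise array with per-row (depth) RMS amplitude `amp`
# (vector of length dim[1]).
complex_noise <- function(dims, amp) {
  n <- prod(dims)
  sd_row <- amp / sqrt(2)
  sds <- array(rep(sd_row, times = prod(dims[-1])), dim = dims)
  array(complex(real = rnorm(n, sd = sds), imaginary = rnorm(n, sd = sds)),
        dim = dims)
}

# Precompute the padded-FFT machinery for repeated "same"-size 2D
# cross-correlations of images of a fixed size with a fixed kernel.
xcorr2_plan <- function(di, kernel) {
  dk <- dim(kernel)
  stopifnot(all(dk %% 2L == 1L))
  nz <- stats::nextn(di[1] + dk[1] - 1L, c(2, 3, 5))
  nx <- stats::nextn(di[2] + dk[2] - 1L, c(2, 3, 5))
  pk <- matrix(0, nz, nx); pk[seq_len(dk[1]), seq_len(dk[2])] <- kernel
  hz <- dk[1] %/% 2L; hx <- dk[2] %/% 2L
  list(di = di, nz = nz, nx = nx, kfft = Conj(fftwtools::fftw2d(pk)),
       rows = ((seq_len(di[1]) - 1L - hz) %% nz) + 1L,
       cols = ((seq_len(di[2]) - 1L - hx) %% nx) + 1L)
}

# Execute a planned correlation; `img_fft` may be passed if already computed
# on the plan's padded grid.
xcorr2_exec <- function(plan, img = NULL, img_fft = NULL) {
  if (is.null(img_fft)) {
    pi_ <- matrix(0, plan$nz, plan$nx)
    pi_[seq_len(plan$di[1]), seq_len(plan$di[2])] <- img
    img_fft <- fftwtools::fftw2d(pi_)
  }
  full <- Re(fftwtools::fftw2d(img_fft * plan$kfft, inverse = 1)) /
    (plan$nz * plan$nx)
  full[plan$rows, plan$cols]
}

# One-shot "same"-size cross-correlation of img with kernel.
xcorr2_same <- function(img, kernel) {
  xcorr2_exec(xcorr2_plan(dim(img), kernel), img)
}

# Rasterize the segment between two (row, col) integer pixel pairs; returns a
# two-column matrix of pixels visited (inclusive), supercover-style Bresenham.
raster_segment <- function(p0, p1) {
  dz <- p1[1] - p0[1]; dx <- p1[2] - p0[2]
  n <- max(abs(dz), abs(dx))
  if (n == 0L) return(matrix(p0, ncol = 2L))
  t <- seq(0, 1, length.out = n + 1L)
  cbind(round(p0[1] + t * dz), round(p0[2] + t * dx))
}

# Even-odd (ray casting) point-in-polygon test, vectorized over query points.
# poly: matrix (n x 2) closed or open (closure implied).
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1L)]; ye <- ys[c(2:n, 1L)]
  inside <- logical(length(px))
  for (i in seq_len(n)) {
    x1 <- xs[i]; y1 <- ys[i]; x2 <- xe[i]; y2 <- ye[i]
    if (y1 == y2) next
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py[crosses] - y1) / (y2 - y1) * (x2 - x1)
      flip <- xint > px[crosses]
      idx <- which(crosses)[flip]
      inside[idx] <- !inside[idx]
    }
  }
  inside
}

# Test whether two segments (a1-a2, b1-b2) properly intersect (excluding
# shared endpoints).
segments_intersect <- function(a1, a2, b1, b2, eps = 1e-12) {
  cross <- function(o, p, q) (p[1] - o[1]) * (q[2] - o[2]) - (p[2] - o[2]) * (q[1] - o[1])
  d1 <- cross(b1, b2, a1); d2 <- cross(b1, b2, a2)
  d3 <- cross(a1, a2, b1); d4 <- cross(a1, a2, b2)
  (((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
     ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps)))
}

fmt_num <- function(x) format(x, digits = 10, scientific = FALSE, trim = TRUE)
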