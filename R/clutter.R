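#' Spatiotemporal SVD clutter filter
#'
#' Reshapes the IQ stack into its columnized Casorati matrix, removes the
#' low-order singular components that carry the spatiotemporally coherent
#' tissue signal, and reshapes back to the original dimensions. The cutoff is
#' either a fixed integer k (components 1..k zeroed) or chosen adaptively from
#' the singular-value decay curve (see [adaptive_cutoff()]); on realistic
#' scenes this typically removes the first 10-20 components. Optionally a
#' high-order (noise) truncation can be applied as well.
#'
#' @param stack an [iq_stack()] with at least 2 frames and finite values.
#' @param cutoff `"adaptive"` or a fixed non-negative integer.
#' @param clamp inclusive clamp for the adaptive cutoff.
#' @param upper_cutoff optional index above which (exclusive) trailing
#'   components are zeroed too; `NULL` (default) keeps them.
#' @param keep_factors keep the SVD factors on the result (needed by
#'   [noise_equalization()]; costs memory).
#' @return list with `stack` (filtered [iq_stack()]), `spectrum` (a
#'   `singular_spectrum`: singular values `sigma`, chosen `k`) and, if
#'   requested, `factors` (`u`, `d`, `v`).
#' @export
svd_filter <- function(stack, cutoff = "adaptive", clamp = c(5L, 30L),
                       upper_cutoff = NULL, keep_factors = TRUE) {
  stopifnot(inherits(stack, "iq_stack"))
  d3 <- dim(stack$iq)
  if (d3[3] < 2) stop("need at least 2 frames")
  if (any(!is.finite(Re(stack$iq))) || any(!is.finite(Im(stack$iq)))) {
    stop("stack contains non-finite values")
  }
  x <- casorati(stack)
  sv <- La.svd(x)                 # x = u %*% diag(d) %*% vt
  k <- if (identical(cutoff, "adaptive")) {
    adaptive_cutoff(sv$d, clamp = clamp)
  } else {
    as.integer(cutoff)
  }
  if (k >= d3[3]) stop("cutoff k = ", k, " >= frame count; nothing would remain")
  if (k < 0) stop("cutoff must be non-negative")
  dk <- sv$d
  if (k > 0) dk[seq_len(k)] <- 0
  if (!is.null(upper_cutoff)) {
    upper_cutoff <- as.integer(upper_cutoff)
    if (upper_cutoff <= k) stop("upper_cutoff must exceed the low-order cutoff")
    if (upper_cutoff < length(dk)) dk[(upper_cutoff + 1L):length(dk)] <- 0
  }
  nzc <- which(dk > 0)
  filt <- if (length(nzc)) {
    sv$u[, nzc, drop = FALSE] %*% (dk[nzc] * sv$vt[nzc, , drop = FALSE])
  } else {
    matrix(complex(real = 0), nrow(x), ncol(x))
  }
  spectrum <- structure(list(sigma = sv$d, k = k), class = "singular_spectrum")
  out <- list(stack = uncasorati(filt, stack), spectrum = spectrum)
  if (keep_factors) out$factors <- list(u = sv$u, d = sv$d, vt = sv$vt)
  out
}

#' @export
print.singular_spectrum <- function(x, ...) {
  cat(sprintf("singular_spectrum: %d values, sigma1 = %.4g, low-order cutoff k = %d\n",
              length(x$sigma), x$sigma[1], x$k))
  invisible(x)
}

#' Adaptive low-order singular-value cutoff
#'
#' Chooses the tissue cutoff from the elbow of the log10 singular-value decay
#' curve. The elbow is located at the maximum positive (convex) discrete
#' curvature of `log10(sigma)` versus component index - the corner at the
#' bottom of the tissue "cliff" - and the cutoff k is one less than that
#' index, i.e. the number of components forming the cliff. k is clamped to
#' `clamp`. A flat decay curve (no convex elbow, e.g. exactly geometric decay)
#' yields the lower clamp with a warning.
#'
#' @param sigma non-increasing singular values (>= 10 of them).
#' @param clamp inclusive integer range for k, default `c(5, 30)`.
#' @return integer cutoff k (components 1..k are zeroed by [svd_filter()]).
#' @export
adaptive_cutoff <- function(sigma, clamp = c(5L, 30L)) {
  stopifnot(length(sigma) >= 10, all(diff(sigma) <= 1e-8 * sigma[1]))
  y <- log10(pmax(sigma, .Machine$double.xmin))
  n <- length(y)
  i <- 2:(n - 1)
  ypp <- y[i - 1] - 2 * y[i] + y[i + 1]
  yp <- (y[i + 1] - y[i - 1]) / 2
  kappa <- ypp / (1 + yp^2)^1.5
  if (max(kappa) < 1e-8) {
    warning("flat singular-value decay: no convex elbow; using lower clamp")
    return(as.integer(clamp[1]))
  }
  k <- i[which.max(kappa)] - 1L
  as.integer(min(max(k, clamp[1]), clamp[2]))
}

#' Depth-dependent noise equalization
#'
#' Estimates a per-depth noise amplitude profile and divides the stack
#' row-wise by it (profile normalized to unit mean, so the global scale is
#' preserved); the profile is returned for audit. Equalization acts on
#' amplitude; the power profile is its square.
#'
#' Two noise surrogates are available. `"row_quantile"` (default) takes a low
#' quantile (default the 10th percentile) of the absolute amplitude per depth
#' row of the clutter-filtered stack itself: after clutter removal the rows
#' are dominated by the noise floor, and a low quantile stays on the floor
#' even when bubbles and their point-spread tails cover most of a row (a
#' vessel running along a row would contaminate the row median). Because the
#' profile is normalized to unit mean, using a quantile instead of the mean
#' only rescales it, not its shape. `"svd_tail"` reconstructs the
#' lowest-energy 10% of singular components and averages their absolute
#' amplitude per row; it needs no assumption of bubble sparsity, but for
#' strongly depth-colored noise the trailing subspace under-represents the
#' high-noise rows and the estimated gradient is compressed. Both profiles
#' are smoothed with a centered moving window spanning 10% of the depth rows.
#'
#' @param filtered result of [svd_filter()] (with `keep_factors = TRUE` for
#'   the `"svd_tail"` method), or an [iq_stack()].
#' @param method `"row_quantile"` (default) or `"svd_tail"`.
#' @param row_quantile quantile of per-row amplitudes used by the default
#'   surrogate.
#' @param tail_fraction fraction of trailing singular components used by the
#'   `"svd_tail"` surrogate.
#' @param smooth_fraction moving-window span as a fraction of depth rows.
#' @return list with `stack` (equalized [iq_stack()]) and `profile` (linear
#'   amplitude gain per depth row, unit mean).
#' @export
noise_equalization <- function(filtered, method = c("row_quantile", "svd_tail"),
                               row_quantile = 0.10, tail_fraction = 0.10,
                               smooth_fraction = 0.10) {
  method <- match.arg(method)
  if (inherits(filtered, "iq_stack")) {
    filtered <- list(stack = filtered, factors = NULL)
  }
  stk <- filtered$stack
  d3 <- dim(stk$iq)
  if (method == "row_quantile") {
    prof <- apply(Mod(stk$iq), 1, stats::quantile, probs = row_quantile,
                  names = FALSE)
  } else {
    if (is.null(filtered$factors)) {
      filtered$factors <- with(La.svd(casorati(stk)), list(u = u, d = d, vt = vt))
    }
    f <- filtered$factors
    nsv <- length(f$d)
    tail_idx <- (nsv - max(1L, ceiling(tail_fraction * nsv)) + 1L):nsv
    surrogate <- f$u[, tail_idx, drop = FALSE] %*%
      (f$d[tail_idx] * f$vt[tail_idx, , drop = FALSE])
    prof <- apply(array(Mod(surrogate), dim = d3), 1, mean)
  }
  prof <- moving_average(prof, max(3L, round(smooth_fraction * d3[1])))
  if (any(prof <= 0)) stop("noise profile contains non-positive entries")
  prof <- prof / mean(prof)
  eq <- stk$iq / array(rep(prof, times = d3[2] * d3[3]), dim = d3)
  list(stack = iq_stack(eq, stk$params), profile = prof)
}
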