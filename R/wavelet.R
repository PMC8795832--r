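## Orthonormal scaling filters (Daubechies extremal-phase family).
## "dbK" here names the K-tap member: db2 = Haar, db4 = 4-tap (2 vanishing
## moments), db8 = 8-tap (4 vanishing moments).
.wavelet_filters <- list(
  haar = c(1, 1) / sqrt(2),
  db2  = c(1, 1) / sqrt(2),
  db4  = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
  db8  = c(0.230377813308855, 0.714846570552542, 0.630880767929590,
           -0.027983769416984, -0.187034811718881, 0.030841381835987,
           0.032883011666983, -0.010597401784997)
)

#' Multiscale (wavelet-domain) ramp filter description
#'
#' Describes the per-view filter of the wavelet-multiscale filtered
#' back-projection: projections are taken to the wavelet domain, hard
#' universal thresholding is (optionally) applied there, and the
#' conventional FBP ramp filter \eqn{|\omega|} acts on the signal path. The
#' wavelet-domain form of the composite filter (conjugating the ramp matrix
#' by the orthonormal transform) is realized as operator composition, which
#' is algebraically identical and avoids dense \code{t_b x t_b} matrices.
#'
#' @param wavelet One of \code{"haar"}, \code{"db2"}, \code{"db4"},
#'   \code{"db8"} (the number is the filter tap count).
#' @param levels Decomposition depth; \code{NULL} (default) chooses
#'   \code{max(1, floor(log2(t_b)) - 2)} at the length seen.
#' @return An object of class \code{multiscale_filter}.
#' @export
multiscale_filter <- function(wavelet = "db4", levels = NULL) {
  wavelet <- match.arg(wavelet, names(.wavelet_filters))
  if (!is.null(levels) && levels < 1L) stop("levels must be >= 1")
  structure(list(wavelet = wavelet, h = .wavelet_filters[[wavelet]],
                 levels = if (is.null(levels)) NULL else as.integer(levels)),
            class = "multiscale_filter")
}

filter_levels <- function(filter, n) {
  if (!is.null(filter$levels)) filter$levels
  else max(1L, as.integer(floor(log2(n))) - 2L)
}

## ---- periodized orthogonal DWT -------------------------------------------
## The analysis operator is orthonormal, so synthesis is its transpose;
## inputs are zero-padded to the next power of two and truncated back.

next_pow2 <- function(n) 2L^as.integer(ceiling(log2(n)))

dwt_step <- function(x, h) {
  L <- length(x)
  g <- rev(h) * (-1)^(seq_along(h) - 1)  # quadrature mirror highpass
  k <- seq_len(L / 2)
  idx <- outer(2 * (k - 1), seq_along(h) - 1, "+") %% L + 1
  Xm <- matrix(x[idx], nrow = L / 2)
  list(approx = as.vector(Xm %*% h), detail = as.vector(Xm %*% g))
}

idwt_step <- function(approx, detail, h) {
  L <- 2L * length(approx)
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  x <- numeric(L)
  k <- seq_along(approx)
  for (n in seq_along(h)) {
    pos <- (2 * (k - 1) + (n - 1)) %% L + 1
    contrib <- approx * h[n] + detail * g[n]
    ## positions can repeat across k only when L < 2*length(h); accumulate
    for (i in seq_along(pos)) x[pos[i]] <- x[pos[i]] + contrib[i]
  }
  x
}

#' Periodized 1-D discrete wavelet transform
#'
#' Forward pyramid transform of a numeric vector, zero-padded internally to
#' a power-of-two length. The analysis operator is orthonormal, so
#' [idwt_1d()] reconstructs the input exactly (to machine precision).
#'
#' @param x Numeric vector (nonzero length).
#' @param filter A [multiscale_filter()].
#' @return A list of class \code{dwt_1d}: \code{approx} (coarsest scaling
#'   coefficients), \code{details} (list, finest level first), \code{n}
#'   (original length), \code{wavelet}.
#' @export
dwt_1d <- function(x, filter = multiscale_filter()) {
  if (length(x) == 0L) stop("zero-length input")
  n <- length(x)
  L <- max(next_pow2(n), 2L * length(filter$h))
  xp <- c(x, numeric(L - n))
  levels <- min(filter_levels(filter, n),
                as.integer(log2(L / length(filter$h))) + 1L)
  levels <- max(1L, levels)
  details <- vector("list", levels)
  a <- xp
  for (j in seq_len(levels)) {
    s <- dwt_step(a, filter$h)
    details[[j]] <- s$detail
    a <- s$approx
  }
  structure(list(approx = a, details = details, n = n,
                 wavelet = filter$wavelet), class = "dwt_1d")
}

#' @rdname dwt_1d
#' @param w A \code{dwt_1d} object.
#' @return \code{idwt_1d}: the reconstructed numeric vector of the original
#'   length.
#' @export
idwt_1d <- function(w, filter = multiscale_filter(w$wavelet)) {
  a <- w$approx
  for (j in rev(seq_along(w$details)))
    a <- idwt_step(a, w$details[[j]], filter$h)
  a[seq_len(w$n)]
}

#' Hard universal (VisuShrink) threshold
#'
#' Applies the universal threshold \eqn{\lambda = \hat\sigma \sqrt{2\ln m}}
#' with the robust noise estimate \eqn{\hat\sigma =
#' \mathrm{median}(|d_1|)/0.6745} taken from the finest-detail
#' coefficients. Thresholding is hard: coefficients with \eqn{|c| \le
#' \lambda} are zeroed, all others pass unchanged.
#'
#' @param coeffs Numeric coefficient vector (\code{m = length(coeffs)}).
#' @param finest Finest-detail coefficients used for the noise estimate;
#'   defaults to \code{coeffs} itself.
#' @return Thresholded vector, with the threshold used in attribute
#'   \code{threshold}.
#' @export
universal_threshold <- function(coeffs, finest = coeffs) {
  if (length(coeffs) == 0L) stop("empty coefficient vector")
  sigma <- median(abs(finest)) / 0.6745
  lambda <- sigma * sqrt(2 * log(length(coeffs)))
  out <- ifelse(abs(coeffs) <= lambda, 0, coeffs)
  attr(out, "threshold") <- lambda
  out
}

## threshold the detail coefficients of a decomposition (approximation
## band kept; noise scale from the finest level)
threshold_dwt <- function(w) {
  all_details <- unlist(w$details)
  thr <- universal_threshold(all_details, finest = w$details[[1L]])
  lambda <- attr(thr, "threshold")
  pos <- 0L
  for (j in seq_along(w$details)) {
    len <- length(w$details[[j]])
    w$details[[j]] <- thr[pos + seq_len(len)]
    pos <- pos + len
  }
  attr(w, "threshold") <- lambda
  w
}

## circular frequency-domain ramp filter |omega| on the native detector
## length; the DC response is exactly zero, so constant projections are
## annihilated (the detector already pads the object support by sqrt(2))
ramp_filter_apply <- function(v) {
  m <- length(v)
  freqs <- (seq_len(m) - 1) / m
  freqs <- pmin(freqs, 1 - freqs)   # |omega| on the circular grid
  Re(fft(fft(v) * freqs, inverse = TRUE)) / m
}

#' Wavelet-multiscale filtering of one projection
#'
#' One view's path through the multiscale filtered back-projection: the
#' projection is wavelet-transformed, optionally hard-thresholded
#' (universal threshold, noise scale from the finest detail band),
#' inverse-transformed, and ramp-filtered. With thresholding off the map is
#' linear and coincides with conventional ramp filtering.
#'
#' @param p Projection vector (length \code{t_b}).
#' @param filter A [multiscale_filter()].
#' @param threshold_on Apply the universal threshold to the detail
#'   coefficients.
#' @return Filtered projection \eqn{\xi_\theta}, with the threshold used in
#'   attribute \code{threshold} (0 when off).
#' @export
wavelet_filter_view <- function(p, filter = multiscale_filter(),
                                threshold_on = TRUE) {
  if (length(p) == 0L) stop("zero-length projection")
  w <- dwt_1d(p, filter)
  lambda <- 0
  if (threshold_on) {
    w <- threshold_dwt(w)
    lambda <- attr(w, "threshold")
  }
  out <- ramp_filter_apply(idwt_1d(w, filter))
  attr(out, "threshold") <- lambda
  out
}

## back-project filtered projections over an n x n grid with linear
## interpolation along the detector, averaged over views
backproject_linear <- function(xi, angles, side, n_bins) {
  pc <- pixel_centers(side)
  acc <- numeric(side^2)
  center <- (n_bins - 1) / 2
  for (m in seq_along(angles)) {
    t <- pc$x * cos(angles[m]) + pc$y * sin(angles[m]) + center + 1
    lo <- floor(t)
    frac <- t - lo
    v <- numeric(side^2)
    ok <- lo >= 1L & lo <= n_bins
    v[ok] <- xi[lo[ok], m] * (1 - frac[ok])
    ok2 <- lo + 1 >= 1L & lo + 1 <= n_bins
    v[ok2] <- v[ok2] + xi[lo[ok2] + 1, m] * frac[ok2]
    acc <- acc + v
  }
  matrix(acc / length(angles), side, side)
}

## shared finalization of back-projected estimates: min-max normalize to
## [0, 1] (constant rasters map to 0), clip, optionally quantize
finalize_recon <- function(raw, normalize = TRUE, levels = NULL) {
  if (normalize) {
    rng <- range(raw)
    raw <- if (rng[2] > rng[1]) (raw - rng[1]) / (rng[2] - rng[1])
           else matrix(0, nrow(raw), ncol(raw))
  }
  raw <- pmin(pmax(raw, 0), 1)
  if (!is.null(levels)) raw <- quantize_levels(raw, levels)
  structure(raw, class = c("image_grid", class(raw)))
}

#' Wavelet-multiscale FBP initialization template
#'
#' Builds the starting estimate for the annealer: every view of the
#' sinogram is wavelet-filtered ([wavelet_filter_view()]) and the filtered
#' projections are back-projected with linear interpolation, averaged over
#' views, min-max normalized, clipped to \[0, 1\], and quantized. With
#' thresholding off this reduces exactly to conventional filtered
#' back-projection.
#'
#' @param sino A [sinogram] object.
#' @param side Side of the reconstruction grid.
#' @param filter A [multiscale_filter()].
#' @param threshold_on Apply universal thresholding per view.
#' @param quantize Quantization level count for the output (NULL to skip).
#' @return A list of class \code{template_result}: \code{image} (the
#'   template, \code{image_grid}), \code{thresholds} (per-view threshold
#'   used).
#' @export
build_template <- function(sino, side, filter = multiscale_filter(),
                           threshold_on = TRUE, quantize = 256L) {
  stopifnot(inherits(sino, "sinogram"))
  if (side < 2L) stop("side incompatible with geometry")
  nb <- nrow(sino$values)
  xi <- matrix(0, nb, ncol(sino$values))
  thr <- numeric(ncol(sino$values))
  for (m in seq_len(ncol(sino$values))) {
    f <- wavelet_filter_view(sino$values[, m], filter, threshold_on)
    xi[, m] <- f
    thr[m] <- attr(f, "threshold")
  }
  raw <- backproject_linear(xi, sino$geometry$angles, side, nb)
  img <- finalize_recon(raw, normalize = TRUE, levels = quantize)
  structure(list(image = img, thresholds = thr), class = "template_result")
}
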