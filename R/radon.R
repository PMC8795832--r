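#' Parallel-beam projection geometry
#'
#' Describes how a square image of side \code{side} is sampled by \code{M}
#' parallel-beam views uniformly distributed over \eqn{[0, \pi)}, with
#' detector bins of one pixel unit centered on the grid center.
#'
#' The default bin count is the smallest odd integer at least
#' \eqn{\sqrt{2}\,\mathrm{side}}, so that diagonal rays never clip; a
#' tighter detector (for example \code{n_bins = side}) can be requested
#' explicitly as long as every pixel still maps to a valid bin.
#'
#' @param side Image side length (pixels), at least 2.
#' @param n_views Number of views \code{M}; view angles are
#'   \eqn{\theta_i = i\pi/M}, \eqn{i = 0, \dots, M-1}.
#' @param n_bins Number of detector bins \code{t_b}; default as above.
#' @return An object of class \code{projection_geometry} with fields
#'   \code{side}, \code{n_views}, \code{n_bins}, \code{angles}.
#' @export
projection_geometry <- function(side, n_views, n_bins = NULL) {
  side <- as.integer(side); n_views <- as.integer(n_views)
  if (side < 1L) stop("side must be >= 1")
  if (n_views < 1L) stop("n_views must be >= 1")
  if (is.null(n_bins)) {
    n_bins <- as.integer(ceiling(sqrt(2) * side))
    if (n_bins %% 2L == 0L) n_bins <- n_bins + 1L
  }
  n_bins <- as.integer(n_bins)
  if (n_bins < side) stop("n_bins must be at least side")
  structure(list(side = side, n_views = n_views, n_bins = n_bins,
                 angles = (seq_len(n_views) - 1) * pi / n_views),
            class = "projection_geometry")
}

#' @export
print.projection_geometry <- function(x, ...) {
  cat(sprintf("<projection_geometry side=%d views=%d bins=%d>\n",
              x$side, x$n_views, x$n_bins))
  invisible(x)
}

new_sinogram <- function(values, geometry) {
  structure(list(values = values, geometry = geometry), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram %d bins x %d views, sum %.4g>\n",
              nrow(x$values), ncol(x$values), sum(x$values)))
  invisible(x)
}

## pixel centers in detector units, measured from the grid center:
## x = col - (n-1)/2 (0-indexed columns), y = (n-1)/2 - row
pixel_centers <- function(side) {
  half <- (side - 1) / 2
  cols <- rep(seq_len(side) - 1, each = side)  # column-major pixel order
  rows <- rep(seq_len(side) - 1, times = side)
  list(x = cols - half, y = half - rows)
}

## nearest-bin assignment of every pixel for one angle; 1-based bin index
bin_index_for_angle <- function(side, theta, n_bins) {
  pc <- pixel_centers(side)
  t <- pc$x * cos(theta) + pc$y * sin(theta)
  if (n_bins %% 2L == 1L) {
    idx <- round_half_away(t) + (n_bins - 1L) %/% 2L + 1L
  } else {
    idx <- floor(t + (n_bins - 1) / 2 + 0.5) + 1L
  }
  if (any(idx < 1L | idx > n_bins))
    stop("geometry error: detector too small (a ray falls outside the bins); ",
         "increase n_bins")
  as.integer(idx)
}

#' Pixel-to-bin assignment table of a projection geometry
#'
#' For each view, every pixel contributes its full value to exactly one
#' detector bin (the nearest-bin reading of the discrete forward model's
#' binary indicator). The table drives the forward projector, the
#' algebraic-reconstruction system, and the annealer's incremental
#' sinogram updates.
#'
#' @param geom A [projection_geometry()].
#' @return An integer \code{side^2 x n_views} matrix of 1-based bin
#'   indices, pixels in column-major order.
#' @export
radon_bin_indices <- function(geom) {
  matrix(vapply(geom$angles,
                function(th) bin_index_for_angle(geom$side, th, geom$n_bins),
                integer(geom$side^2)),
         nrow = geom$side^2)
}

#' Discrete Radon forward projection
#'
#' Computes the sinogram \eqn{P(t, \theta)} of an image under the discrete
#' line-sum model: for each view, pixel values are accumulated into the
#' nearest detector bin along \eqn{t = x\cos\theta + y\sin\theta}. Because
#' every pixel lands in exactly one bin per view, each view conserves the
#' total image mass: \eqn{\sum_t P(t,\theta) = \sum_{x,y} f(x,y)}.
#'
#' @param img Square numeric matrix (the cross-section f(x, y)).
#' @param geom A [projection_geometry()] consistent with \code{nrow(img)}.
#' @return A \code{sinogram} object (fields \code{values}: \code{n_bins x
#'   n_views} matrix; \code{geometry}).
#' @examples
#' ph <- generate_lung_phantom(phantom_spec(8, seed = 1))
#' g <- projection_geometry(8, n_views = 18)
#' s <- radon_forward(ph, g)
#' colSums(s$values) # every view sums to sum(ph)
#' @export
radon_forward <- function(img, geom) {
  if (nrow(img) != ncol(img)) stop("img must be square")
  if (nrow(img) != geom$side) stop("geometry side does not match image")
  B <- radon_bin_indices(geom)
  f <- as.vector(unclass(img))
  vals <- vapply(seq_len(geom$n_views), function(m) {
    v <- numeric(geom$n_bins)
    acc <- rowsum(f, B[, m])
    v[as.integer(rownames(acc))] <- acc
    v
  }, numeric(geom$n_bins))
  new_sinogram(vals, geom)
}

#' Single-view projection
#'
#' The line-integral profile \eqn{P_\theta(t)} of an image at one view
#' angle, consistent with the corresponding column of [radon_forward()].
#'
#' @param img Square numeric matrix.
#' @param theta View angle in radians, in \eqn{[0, \pi)}.
#' @param geom A [projection_geometry()] (its angle list is ignored; only
#'   the detector layout is used).
#' @return Numeric vector of length \code{geom$n_bins}.
#' @export
single_view <- function(img, theta, geom) {
  if (!is.finite(theta) || theta < 0 || theta >= pi)
    stop("theta must lie in [0, pi)")
  if (nrow(img) != geom$side) stop("geometry side does not match image")
  idx <- bin_index_for_angle(geom$side, theta, geom$n_bins)
  v <- numeric(geom$n_bins)
  acc <- rowsum(as.vector(unclass(img)), idx)
  v[as.integer(rownames(acc))] <- acc
  v
}
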