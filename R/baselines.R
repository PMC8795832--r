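#' Filtered back-projection reconstruction
#'
#' Conventional FBP: every view is ramp-filtered in the frequency domain
#' and back-projected with linear interpolation along the detector; the
#' raw estimate is min-max normalized and clipped to \[0, 1\]. Set
#' \code{normalize = FALSE} to obtain the raw (linear-in-the-data)
#' back-projection.
#'
#' @param sino A [sinogram] object.
#' @param side Side of the reconstruction grid.
#' @param normalize Min-max normalize and clip the output (default TRUE).
#' @return An \code{image_grid} matrix (raw numeric matrix when
#'   \code{normalize = FALSE}).
#' @export
fbp_reconstruct <- function(sino, side, normalize = TRUE) {
  stopifnot(inherits(sino, "sinogram"))
  if (length(sino$values) == 0L) stop("empty sinogram")
  xi <- apply(sino$values, 2L, ramp_filter_apply)
  raw <- backproject_linear(xi, sino$geometry$angles, side,
                            nrow(sino$values))
  if (!normalize) return(raw)
  finalize_recon(raw, normalize = TRUE)
}

#' Algebraic reconstruction (Kaczmarz row action)
#'
#' Solves the binary projection system of the discrete forward model by
#' cyclic Kaczmarz sweeps: every (bin, view) equation relaxes the current
#' estimate toward consistency with its measured line sum, and the
#' estimate is projected onto non-negativity after each sweep.
#'
#' @param sino A [sinogram] object.
#' @param side Side of the reconstruction grid.
#' @param sweeps Number of full passes over all equations (>= 1).
#' @param relaxation Relaxation factor in (0, 1].
#' @return An \code{image_grid} matrix clipped to \[0, 1\].
#' @export
art_reconstruct <- function(sino, side, sweeps = 20L, relaxation = 0.25) {
  stopifnot(inherits(sino, "sinogram"))
  if (sweeps < 1L) stop("sweeps must be >= 1")
  if (relaxation <= 0 || relaxation > 1)
    stop("relaxation must lie in (0, 1]")
  geom <- sino$geometry
  if (geom$side != side) stop("geometry side does not match requested side")
  B <- radon_bin_indices(geom)
  ## row index sets: pixels hitting each bin, per view
  rows <- lapply(seq_len(geom$n_views), function(m)
    split(seq_len(side^2), B[, m]))
  f <- numeric(side^2)
  for (s in seq_len(sweeps)) {
    for (m in seq_len(geom$n_views)) {
      vm <- sino$values[, m]
      for (bname in names(rows[[m]])) {
        px <- rows[[m]][[bname]]
        b <- as.integer(bname)
        r <- vm[b] - sum(f[px])
        f[px] <- f[px] + relaxation * r / length(px)
      }
    }
    f[f < 0] <- 0
  }
  finalize_recon(matrix(pmin(f, 1), side, side), normalize = FALSE)
}
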