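#' Peak signal-to-noise ratio
#'
#' \eqn{10\log_{10}(1/\mathrm{MSE})} for images on \[0, 1\] (peak value 1).
#' Identical images give \code{Inf}.
#'
#' @param ref,est Square numeric matrices of the same size with values in
#'   \[0, 1\].
#' @return PSNR in dB.
#' @export
psnr <- function(ref, est) {
  check_same_size(ref, est)
  mse <- mean((ref - est)^2)
  if (mse == 0) Inf else 10 * log10(1 / mse)
}

#' Relative Euclidean error
#'
#' \eqn{\|ref - est\|_2 / \|ref\|_2}: 0 for a perfect reconstruction, 1
#' for an all-zero estimate.
#'
#' @inheritParams psnr
#' @return Dimensionless relative error.
#' @export
euclidean_error <- function(ref, est) {
  check_same_size(ref, est)
  den <- sqrt(sum(ref^2))
  if (den == 0) stop("reference image is all zero")
  sqrt(sum((ref - est)^2)) / den
}

#' Weighted peak signal-to-noise ratio
#'
#' PSNR with the squared error weighted by a noise-visibility map of the
#' reference: \eqn{w = 1/(1 + \sigma^2_{local}/\sigma^2_{global})}, where
#' \eqn{\sigma^2_{local}} is the 3x3 local variance of \code{ref}
#' (windows truncated at the borders) and \eqn{\sigma^2_{global}} its
#' global variance. Flat regions, where the eye notices noise most, weigh
#' errors fully; textured regions are discounted. For a constant reference
#' all weights are equal and WPSNR reduces to PSNR exactly.
#'
#' @inheritParams psnr
#' @return WPSNR in dB.
#' @export
wpsnr <- function(ref, est) {
  check_same_size(ref, est)
  w <- nvf_weights(ref)
  wmse <- sum(w * (ref - est)^2) / sum(w)
  if (wmse == 0) Inf else 10 * log10(1 / wmse)
}

## noise-visibility weights from the 3x3 local-variance map of ref
nvf_weights <- function(ref) {
  s2g <- mean((ref - mean(ref))^2)
  if (s2g == 0) return(matrix(1, nrow(ref), ncol(ref)))
  1 / (1 + local_variance_3x3(ref) / s2g)
}

## population variance over the 3x3 neighborhood of each pixel, truncated
## at the image borders; computed from summed-area style shifts
local_variance_3x3 <- function(img) {
  n <- nrow(img); m <- ncol(img)
  s <- matrix(0, n, m); s2 <- matrix(0, n, m); cnt <- matrix(0, n, m)
  for (dr in -1:1) for (dc in -1:1) {
    r_src <- intersect(seq_len(n), seq_len(n) - dr)
    c_src <- intersect(seq_len(m), seq_len(m) - dc)
    r_dst <- r_src + dr; c_dst <- c_src + dc
    v <- img[r_src, c_src, drop = FALSE]
    s[r_dst, c_dst] <- s[r_dst, c_dst] + v
    s2[r_dst, c_dst] <- s2[r_dst, c_dst] + v^2
    cnt[r_dst, c_dst] <- cnt[r_dst, c_dst] + 1
  }
  s2 / cnt - (s / cnt)^2
}

#' Reconstruction quality report
#'
#' Convenience wrapper computing the three quality measures of a
#' reconstruction against its reference.
#'
#' @inheritParams psnr
#' @return A list of class \code{quality_report} with fields \code{psnr},
#'   \code{eue}, \code{wpsnr}.
#' @export
quality_report <- function(ref, est) {
  structure(list(psnr = psnr(ref, est), eue = euclidean_error(ref, est),
                 wpsnr = wpsnr(ref, est)), class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("PSNR %.2f dB | EuE %.4f | WPSNR %.2f dB\n",
              x$psnr, x$eue, x$wpsnr))
  invisible(x)
}

check_same_size <- function(ref, est) {
  if (!all(dim(ref) == dim(est))) stop("images differ in size")
  invisible(TRUE)
}
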