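#' Specification for a procedural lung phantom
#'
#' Bundles the parameters of the seeded phantom generator. Identical specs
#' produce bit-identical phantoms, so a spec is a complete, reproducible
#' description of a test image.
#'
#' @param side Image side length in pixels (square grid), at least 2.
#' @param seed Integer seed driving all random choices (branch angle jitter,
#'   ground-glass blob placement).
#' @param branching_depth Recursion depth of the bronchial-tree branching
#'   (0 disables the airway tree).
#' @param ggo_count Number of ground-glass-opacity blobs placed in the
#'   peripheral lung zones (0 for the plain phantom).
#' @param intensity_levels Number of uniform quantization levels on
#'   \[0, 1\]; every pixel of the generated phantom lies on the
#'   \code{k / (intensity_levels - 1)} lattice.
#' @return An object of class \code{phantom_spec}.
#' @seealso [generate_lung_phantom()]
#' @export
phantom_spec <- function(side, seed = 1L, branching_depth = 4L,
                         ggo_count = 0L, intensity_levels = 256L) {
  side <- as.integer(side)
  if (is.na(side) || side < 2L)
    stop("invalid phantom spec: side must be an integer >= 2")
  if (branching_depth < 0L) stop("invalid phantom spec: branching_depth < 0")
  if (ggo_count < 0L) stop("invalid phantom spec: ggo_count < 0")
  if (intensity_levels < 2L) stop("invalid phantom spec: intensity_levels < 2")
  structure(list(side = side, seed = as.integer(seed),
                 branching_depth = as.integer(branching_depth),
                 ggo_count = as.integer(ggo_count),
                 intensity_levels = as.integer(intensity_levels)),
            class = "phantom_spec")
}

#' Generate a seeded lung-like test phantom
#'
#' Draws a 2-D axial-slice analogue of a thoracic cross-section: a bright
#' body ellipse enclosing two darker lung fields, a recursively bifurcating
#' bright airway tree inside each lung, and (optionally) peripheral
#' ground-glass blobs mimicking the COVID-19 CT appearance. All absorption
#' values lie in \[0, 1\] and are quantized to the spec's intensity lattice.
#' The generator is fully deterministic given the spec.
#'
#' @param spec A [phantom_spec()], or an integer side length (remaining
#'   parameters taken from the spec defaults).
#' @param ... When \code{spec} is a side length, further arguments passed to
#'   [phantom_spec()].
#' @return A numeric \code{side x side} matrix of class \code{image_grid}
#'   with attribute \code{lung_mask} (logical matrix marking the lung
#'   fields as laid out by the generator's own geometry).
#' @examples
#' ph <- generate_lung_phantom(phantom_spec(side = 16, seed = 1))
#' range(ph)
#' @export
generate_lung_phantom <- function(spec, ...) {
  if (!inherits(spec, "phantom_spec")) spec <- phantom_spec(spec, ...)
  with_seed(spec$seed, function() phantom_draw(spec))
}

## intensity palette of the slice analogue (soft tissue bright, aerated lung
## dark, airway walls intermediate)
.phantom_int <- list(body = 0.85, lung = 0.15, branch = 0.7, ggo = 0.3)

phantom_draw <- function(spec) {
  n <- spec$side
  ## pixel centers in normalized [-1, 1] coordinates, x right, y down
  ax <- (2 * (seq_len(n) - 0.5) - n) / n
  X <- matrix(ax, n, n, byrow = TRUE)   # column coordinate
  Y <- matrix(ax, n, n)                 # row coordinate
  img <- matrix(0, n, n)

  in_ellipse <- function(cx, cy, a, b) ((X - cx) / a)^2 + ((Y - cy) / b)^2 <= 1

  body <- in_ellipse(0, 0, 0.92, 0.75)
  img[body] <- .phantom_int$body

  lung_a <- 0.30; lung_b <- 0.50
  lungs <- in_ellipse(-0.42, 0.02, lung_a, lung_b) |
           in_ellipse( 0.42, 0.02, lung_a, lung_b)
  lungs <- lungs & body
  img[lungs] <- .phantom_int$lung

  ## recursive bifurcating airway tree inside each lung field
  if (spec$branching_depth > 0L) {
    for (cx in c(-0.42, 0.42)) {
      img <- phantom_branch(img, X, Y, lungs,
                            x0 = cx, y0 = 0.02 - lung_b * 0.8,
                            angle = pi / 2,            # pointing down
                            len = lung_b * 0.55, width = 0.10,
                            depth = spec$branching_depth)
    }
  }

  ## peripheral ground-glass blobs (seeded Gaussian bumps, additive)
  if (spec$ggo_count > 0L) {
    for (i in seq_len(spec$ggo_count)) {
      cx <- sample(c(-0.42, 0.42), 1L)
      phi <- runif(1, 0, 2 * pi)
      r <- runif(1, 0.55, 0.9)          # peripheral zone of the lung ellipse
      gx <- cx + r * lung_a * cos(phi)
      gy <- 0.02 + r * lung_b * sin(phi)
      sig <- runif(1, 0.05, 0.10)
      bump <- .phantom_int$ggo * exp(-(((X - gx)^2 + (Y - gy)^2) / (2 * sig^2)))
      img[lungs] <- img[lungs] + bump[lungs]
    }
  }

  img <- pmin(pmax(img, 0), 1)
  img <- quantize_levels(img, spec$intensity_levels)
  structure(img, class = c("image_grid", class(img)), lung_mask = lungs)
}

## draw one airway segment as a thick line, then recurse into two sprouts
## with seeded angle jitter; geometry decays by 0.7 per generation
phantom_branch <- function(img, X, Y, mask, x0, y0, angle, len, width, depth) {
  x1 <- x0 + len * cos(angle)
  y1 <- y0 + len * sin(angle)
  ## distance from every pixel center to the segment
  dx <- x1 - x0; dy <- y1 - y0
  L2 <- dx * dx + dy * dy
  tt <- pmin(pmax(((X - x0) * dx + (Y - y0) * dy) / L2, 0), 1)
  d2 <- (X - (x0 + tt * dx))^2 + (Y - (y0 + tt * dy))^2
  hit <- d2 <= (width / 2)^2 & mask
  img[hit] <- .phantom_int$branch
  if (depth > 1L) {
    spread <- 0.55
    for (s in c(-1, 1)) {
      jit <- runif(1, -0.25, 0.25)
      img <- phantom_branch(img, X, Y, mask, x1, y1,
                            angle + s * spread + jit,
                            len * 0.7, width * 0.7, depth - 1L)
    }
  }
  img
}

quantize_levels <- function(img, levels) {
  round(img * (levels - 1)) / (levels - 1)
}

#' Block-mean downsampling of a square image
#'
#' Reduces an image to \code{target_side} by averaging non-overlapping
#' square blocks. The global mean is preserved exactly, and values stay in
#' \[0, 1\] when the input does. This is how high-resolution source images
#' are reduced to the small grids that the annealer reconstructs.
#'
#' @param img Square numeric matrix.
#' @param target_side Side length of the result; must divide \code{nrow(img)}.
#' @return A \code{target_side x target_side} matrix of class \code{image_grid}.
#' @export
downsample <- function(img, target_side) {
  n <- nrow(img)
  if (n != ncol(img)) stop("img must be square")
  target_side <- as.integer(target_side)
  if (target_side < 1L || n %% target_side != 0L)
    stop("target_side must be a positive divisor of the image side")
  f <- n %/% target_side
  ## average f x f blocks: collapse rows, then columns
  grp <- rep(seq_len(target_side), each = f)
  m <- rowsum(unclass(img), grp) / f
  m <- t(rowsum(t(m), grp) / f)
  dimnames(m) <- NULL
  structure(m, class = c("image_grid", class(m)))
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid %d x %d, range [%.4g, %.4g], mean %.4g>\n",
              nrow(x), ncol(x), min(x), max(x), mean(x)))
  invisible(x)
}
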