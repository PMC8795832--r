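## shared small fixtures, built in code

fixture_phantom8 <- function(seed = 1) {
  generate_lung_phantom(phantom_spec(8, seed = seed))
}

fixture_case8 <- function(seed = 1, n_views = 18) {
  ph <- fixture_phantom8(seed)
  geom <- projection_geometry(8, n_views)
  list(phantom = ph, geom = geom, sino = radon_forward(ph, geom))
}

## independent brute-force projector: enumerate pixels, assign each to the
## detector bin whose center is nearest to t = x cos(theta) + y sin(theta)
## (half-away-from-zero on ties, the stated convention)
brute_projection <- function(img, theta, n_bins) {
  n <- nrow(img)
  half <- (n - 1) / 2
  centers <- seq_len(n_bins) - 1 - (n_bins - 1) / 2
  v <- numeric(n_bins)
  for (r in seq_len(n)) for (cl in seq_len(n)) {
    x <- (cl - 1) - half
    y <- half - (r - 1)
    t <- x * cos(theta) + y * sin(theta)
    d <- abs(centers - t)
    cand <- which(d - min(d) < 1e-12)
    bin <- if (length(cand) > 1) {      # tie: pick the bin away from zero
      cand[which.max(abs(centers[cand]))]
    } else cand
    v[bin] <- v[bin] + img[r, cl]
  }
  v
}
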