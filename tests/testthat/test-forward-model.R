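test_that("projection geometry defaults pad the detector to sqrt(2) * side, odd", {
  g <- projection_geometry(8, 18)
  expect_identical(g$n_bins, 13L)
  expect_identical(g$n_views, 18L)
  expect_equal(g$angles, (0:17) * pi / 18)
  expect_true(all(diff(g$angles) > 0) && max(g$angles) < pi)
  g512 <- projection_geometry(512, 18, n_bins = 512)
  expect_identical(g512$n_bins, 512L)
  expect_error(projection_geometry(8, 18, n_bins = 4), "n_bins")
})

test_that("a corner pixel lands in a single bin with its full mass", {
  img <- matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE)
  g <- projection_geometry(2, 1, n_bins = 3)
  s <- radon_forward(img, g)
  expect_equal(sum(s$values != 0), 1)
  expect_equal(sum(s$values), 1.0)
  ## convention: t = -0.5 rounds away from zero into the lower bin
  expect_equal(s$values[1, 1], 1.0)
})

test_that("forward projection matches the brute-force nearest-bin oracle", {
  set.seed(10)
  for (side in c(2, 5, 8)) {
    img <- matrix(runif(side^2), side, side)
    g <- projection_geometry(side, 7)
    s <- radon_forward(img, g)
    for (m in seq_along(g$angles))
      expect_equal(s$values[, m],
                   brute_projection(img, g$angles[m], g$n_bins),
                   tolerance = 1e-12)
  }
})

test_that("axis-aligned views sum columns (theta = 0) and rows (theta = pi/2)", {
  img <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2, byrow = TRUE) # [[a,b],[c,d]]
  g <- projection_geometry(2, 4, n_bins = 3)
  v0 <- single_view(img, 0, g)
  ## x = -0.5 for column 1 (bins 1), +0.5 for column 2 (bin 3)
  expect_equal(v0, c(0.1 + 0.3, 0, 0.2 + 0.4))
  v90 <- single_view(img, pi / 2, g)
  ## y = +0.5 for row 1 (bin 3), -0.5 for row 2 (bin 1)
  expect_equal(v90, c(0.3 + 0.4, 0, 0.1 + 0.2))
})

test_that("single_view agrees with the matching radon_forward column", {
  cs <- fixture_case8()
  for (m in c(1L, 7L, 18L))
    expect_identical(single_view(cs$phantom, cs$geom$angles[m], cs$geom),
                     cs$sino$values[, m])
  expect_error(single_view(cs$phantom, pi, cs$geom), "theta")
  expect_error(single_view(cs$phantom, -0.1, cs$geom), "theta")
})

test_that("every view conserves total image mass", {
  set.seed(11)
  for (rep in 1:20) {
    side <- sample(c(4, 8, 16), 1)
    img <- matrix(runif(side^2), side, side)
    g <- projection_geometry(side, 18)
    s <- radon_forward(img, g)
    expect_equal(colSums(s$values), rep(sum(img), 18), tolerance = 1e-12)
  }
  expect_true(all(radon_forward(matrix(0, 8, 8),
                                projection_geometry(8, 18))$values == 0))
})

test_that("the projector is linear", {
  set.seed(12)
  f <- matrix(runif(64), 8, 8); h <- matrix(runif(64), 8, 8)
  g <- projection_geometry(8, 9)
  lhs <- radon_forward(2.5 * f - 0.5 * h, g)$values
  rhs <- 2.5 * radon_forward(f, g)$values - 0.5 * radon_forward(h, g)$values
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("projections commute with quarter-turn rotation on odd grids", {
  ## odd side keeps ray offsets integral, away from rounding ties
  set.seed(13)
  img <- matrix(runif(81), 9, 9)
  rot90ccw <- function(m) t(m)[nrow(m):1, ]
  g <- projection_geometry(9, 8)
  for (th in g$angles[g$angles < pi / 2 - 1e-9])
    expect_equal(single_view(img, th, g),
                 single_view(rot90ccw(img), th + pi / 2, g))
})

test_that("an undersized detector raises a geometry error", {
  img <- matrix(1, 8, 8)
  g <- projection_geometry(8, 4, n_bins = 8)  # diagonal views clip
  expect_error(radon_forward(img, g), "detector too small")
})
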