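test_that("per-view costs reproduce their closed-form values", {
  expect_equal(view_cost("MAE", c(1, 3), c(2, 5)), 1.5)
  expect_equal(view_cost("RMSE", c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(view_cost("RSE", c(1, 3), c(2, 5)), 2.5)
  expect_equal(view_cost("RAE", c(1, 3), c(2, 5)), 1.5)
  set.seed(30)
  p <- runif(16, 0.1, 2)
  expect_equal(view_cost("UIQI", p, p), 1)
  expect_equal(view_cost("SSIM", p, p), 1)
  expect_equal(view_cost("RMSLE", p, p), 0)
})

test_that("UIQI equals its single-factor algebraic form", {
  set.seed(31)
  for (rep in 1:5) {
    x <- runif(32, 0, 3); y <- x + rnorm(32, sd = 0.3)
    sx <- sd(x); sy <- sd(y)
    sxy <- sum((x - mean(x)) * (y - mean(y))) / 31
    ref <- 4 * sxy * mean(x) * mean(y) /
      ((sx^2 + sy^2) * (mean(x)^2 + mean(y)^2))
    expect_equal(view_cost("UIQI", x, y), ref, tolerance = 1e-10)
  }
})

test_that("symmetry of the bank: reference-free costs symmetric, others not", {
  set.seed(32)
  x <- runif(24, 0.2, 2); y <- runif(24, 0.2, 2)
  ## UIQI is symmetric by construction (its single-factor form shows it);
  ## SSIM is not, through the stabilizers drawn from the measured range
  for (id in c("MAE", "RMSE", "RMSLE", "UIQI"))
    expect_equal(view_cost(id, x, y), view_cost(id, y, x))
  for (id in c("RSE", "RAE", "SSIM"))
    expect_false(isTRUE(all.equal(view_cost(id, x, y),
                                  view_cost(id, y, x))))
})

test_that("RMSE dominates MAE on random pairs", {
  set.seed(33)
  for (rep in 1:200) {
    x <- runif(13, 0, 3); y <- runif(13, 0, 3)
    expect_gte(view_cost("RMSE", x, y), view_cost("MAE", x, y))
  }
})

test_that("degenerate and invalid inputs are rejected", {
  cst <- rep(1, 8); v <- seq_len(8) / 2
  expect_error(view_cost("RSE", cst, v), "degenerate")
  expect_error(view_cost("RAE", cst, v), "degenerate")
  expect_error(view_cost("RMSLE", v, -v), "domain")
  expect_error(view_cost("MAE", 1:3, 1:4), "length")
  expect_error(view_cost("XYZ", v, v), "unknown cost")
  expect_error(view_cost("MAE", c(1, NA), c(1, 2)), "finite")
})

test_that("the aggregate objective is zero at equality and orientation-wrapped", {
  cs <- fixture_case8()
  for (id in cost_function_ids)
    expect_equal(aggregate_cost(id, cs$sino, cs$sino), 0)

  ## single-view sinogram reduces exactly to view_cost for error ids
  g1 <- projection_geometry(8, 1)
  a <- radon_forward(cs$phantom, g1)
  b <- radon_forward(generate_lung_phantom(phantom_spec(8, seed = 2)), g1)
  for (id in c("MAE", "RMSE", "RMSLE", "RSE", "RAE"))
    expect_identical(aggregate_cost(id, a, b),
                     view_cost(id, a$values[, 1], b$values[, 1]))

  ## positive whenever the sinograms differ
  for (id in cost_function_ids)
    expect_gt(aggregate_cost(id, cs$sino, radon_forward(
      generate_lung_phantom(phantom_spec(8, seed = 5)), cs$geom)), 0)

  g2 <- projection_geometry(8, 9)
  expect_error(aggregate_cost("MAE", cs$sino,
                              radon_forward(cs$phantom, g2)), "mismatch")
})
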