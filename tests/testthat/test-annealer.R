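test_that("the cooling profile hits T0, approaches TN, and steps by slab", {
  cfg <- anneal_config(t0 = 0.1, tn = 1e-6, n_iter = 2e5L, slab = 1000L)
  expect_identical(temperature_at(0L, cfg), 0.1)
  tN <- temperature_at(cfg$n_iter, cfg)
  expect_equal(tN, 1.00799e-5, tolerance = 1e-4)   # (T0-TN)/cosh(10) + TN
  expect_lt(abs(tN - cfg$tn), 1.1e-5)
  ## constant within a slab, strictly decreasing across slab boundaries
  expect_identical(temperature_at(1500L, cfg), temperature_at(1999L, cfg))
  boundaries <- temperature_at(seq(0L, 2e5L, by = 1000L), cfg)
  expect_true(all(diff(boundaries) < 0))
  expect_error(temperature_at(cfg$n_iter + 1L, cfg), "outside")
  expect_error(anneal_config(t0 = 0.1, tn = 0.2), "tn < t0")
})

test_that("proposals are uniform over pixels and the intensity lattice", {
  cs <- fixture_case8()
  cfg <- anneal_config(cost = "RMSE", n_iter = 1000L, slab = 100L, seed = 5)
  st <- sa_state_init(cs$sino, build_template(cs$sino, 8)$image, cfg)
  set.seed(5)
  moves <- replicate(10000, propose_move(st), simplify = FALSE)
  pix <- vapply(moves, function(m) (m$col - 1L) * 8L + m$row, integer(1))
  counts <- tabulate(pix, 64)
  p <- 1 / 64
  bound <- 5 * sqrt(10000 * p * (1 - p))
  expect_true(all(abs(counts - 10000 * p) <= bound))
  levels <- vapply(moves, `[[`, integer(1), "level")
  expect_true(all(levels >= 0L & levels <= 255L))
  vals <- vapply(moves, `[[`, numeric(1), "value")
  expect_equal(vals, levels / 255)
  ## same seed, same stream
  set.seed(5)
  moves2 <- replicate(10000, propose_move(st), simplify = FALSE)
  expect_identical(moves, moves2)
})

test_that("incremental sinogram updates match full recomputation", {
  cs <- fixture_case8()
  cfg <- anneal_config(cost = "RMSE", n_iter = 1000L, slab = 100L, seed = 6)
  st <- sa_state_init(cs$sino, build_template(cs$sino, 8)$image, cfg)

  ## zero-change move leaves everything untouched
  mv0 <- list(row = 2L, col = 3L, level = st$f[2, 3],
              value = st$f[2, 3] / 255)
  app0 <- apply_move(st, mv0)
  expect_identical(app0$pp, st$pp)
  expect_identical(app0$d_cost, 0)

  ## last level wins when the same pixel moves twice
  mvA <- list(row = 1L, col = 1L, level = 10L, value = 10 / 255)
  mvB <- list(row = 1L, col = 1L, level = 200L, value = 200 / 255)
  commit_move(st, mvA, apply_move(st, mvA))
  commit_move(st, mvB, apply_move(st, mvB))
  expect_identical(st$f[1, 1], 200L)
  expect_equal(st$pp, radon_forward(st$f / 255, cs$geom)$values,
               tolerance = 1e-12)

  ## a long stream of committed random moves stays consistent
  set.seed(6)
  for (i in 1:1000) {
    mv <- propose_move(st)
    commit_move(st, mv, apply_move(st, mv))
  }
  expect_lt(max(abs(st$pp - radon_forward(st$f / 255, cs$geom)$values)),
            1e-10)
  expect_equal(st$cost, aggregate_cost("RMSE", cs$sino,
                                       radon_forward(st$f / 255, cs$geom)))
})

test_that("the Metropolis rule accepts downhill always and uphill by exp(-dC/T)", {
  set.seed(7)
  expect_true(all(replicate(50, metropolis_accept(-0.5, 1e-9))))
  expect_true(all(replicate(50, metropolis_accept(0, 1e-9))))
  freq <- mean(replicate(10000, metropolis_accept(0.02, 0.02)))
  expect_lt(abs(freq - exp(-1)), 0.02)
  expect_error(metropolis_accept(0.1, 0), "positive")
})

test_that("compiled and reference engines produce identical runs", {
  ph <- generate_lung_phantom(phantom_spec(16, seed = 3))
  g <- projection_geometry(16, 18)
  s <- radon_forward(ph, g)
  tpl <- build_template(s, 16)$image
  for (cost in c("RMSE", "RMSLE")) {
    cfg <- anneal_config(cost = cost, n_iter = 2000L, slab = 500L,
                         stop_tolerance = 0, seed = 11)
    a <- run_sa(s, cfg, template = tpl, engine = "cpp")
    b <- run_sa(s, cfg, template = tpl, engine = "r")
    expect_identical(unclass(a$final), unclass(b$final))
    expect_identical(unclass(a$estimate), unclass(b$estimate))
    expect_identical(a$accepted, b$accepted)
    expect_equal(a$trace, b$trace, tolerance = 1e-9)
  }
})

test_that("annealing is deterministic, monotone in best cost, and self-consistent", {
  cs <- fixture_case8()
  cfg <- anneal_config(cost = "RMSE", n_iter = 2e5L, stop_tolerance = 0,
                       seed = 42)
  rec <- run_sa(cs$sino, cfg)
  rec2 <- run_sa(cs$sino, cfg)
  expect_identical(unclass(rec$estimate), unclass(rec2$estimate))

  expect_true(all(diff(rec$trace$best_cost) <= 0))
  tpl_cost <- rec$trace$cost[1]
  expect_lt(rec$best_cost, tpl_cost)

  ## the engine's internal sinogram equals a fresh forward projection
  expect_equal(fitted(rec)$values,
               radon_forward(rec$estimate, cs$geom)$values,
               tolerance = 1e-12)
  expect_equal(rec$best_cost,
               aggregate_cost("RMSE", cs$sino, fitted(rec)),
               tolerance = 1e-9)

  ## the anneal recovers far more of the phantom than its template
  tpl <- build_template(cs$sino, 8)$image
  expect_gte(psnr(cs$phantom, rec$estimate), psnr(cs$phantom, tpl) + 5)

  ## residuals shrink with the fit
  expect_lt(sqrt(mean(residuals(rec)^2)),
            sqrt(mean((cs$sino$values -
                       radon_forward(tpl, cs$geom)$values)^2)))
})

test_that("the slab-improvement rule stops the chain early when enabled", {
  cs <- fixture_case8()
  cfg <- anneal_config(cost = "RMSE", n_iter = 2e5L, stop_tolerance = 0.5,
                       seed = 3)
  rec <- run_sa(cs$sino, cfg)
  expect_lt(rec$iterations, cfg$n_iter)
})

test_that("degenerate cost configurations are rejected up front", {
  flat <- matrix(0.5, 8, 8)
  s <- radon_forward(matrix(0, 8, 8), projection_geometry(8, 18))
  expect_error(run_sa(s, anneal_config(cost = "RSE"), template = flat),
               "configuration error")
  expect_error(run_sa(s, anneal_config(cost = "RAE"), template = flat),
               "configuration error")
})
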