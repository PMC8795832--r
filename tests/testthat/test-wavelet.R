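test_that("periodized DWT reconstructs perfectly at arbitrary lengths", {
  set.seed(20)
  for (wv in c("haar", "db4", "db8")) {
    f <- multiscale_filter(wv)
    for (len in c(8, 13, 16, 33, 64)) {
      x <- rnorm(len)
      expect_equal(idwt_1d(dwt_1d(x, f), f), x, tolerance = 1e-10)
    }
  }
  expect_error(dwt_1d(numeric(0)), "zero-length")
})

test_that("universal threshold is hard and uses the stated lambda", {
  expect_equal(universal_threshold(numeric(16)), numeric(16),
               ignore_attr = TRUE)

  set.seed(21)
  x <- c(rnorm(31, sd = 0.01), 5)   # one huge coefficient among tiny noise
  out <- universal_threshold(x)
  lambda_ref <- median(abs(x)) / 0.6745 * sqrt(2 * log(length(x)))
  expect_equal(attr(out, "threshold"), lambda_ref)
  expect_identical(out[32], 5)       # survivor passes unchanged
  ## hard threshold: support shrinks, survivors unmodified, energy drops
  expect_true(all(out == 0 | out == x))
  expect_true(all(which(out != 0) %in% which(x != 0)))
  expect_lte(sum(out^2), sum(x^2))
})

test_that("wavelet view filtering is linear without thresholding and kills DC", {
  f <- multiscale_filter("db4")
  expect_error(wavelet_filter_view(numeric(0), f), "zero-length")
  expect_equal(wavelet_filter_view(numeric(13), f, threshold_on = FALSE),
               numeric(13), ignore_attr = TRUE)

  set.seed(22)
  p <- runif(13); q <- runif(13)
  lhs <- wavelet_filter_view(3 * p - 2 * q, f, threshold_on = FALSE)
  rhs <- 3 * wavelet_filter_view(p, f, threshold_on = FALSE) -
         2 * wavelet_filter_view(q, f, threshold_on = FALSE)
  expect_equal(as.vector(lhs), as.vector(rhs), tolerance = 1e-10)

  const <- wavelet_filter_view(rep(7, 16), f, threshold_on = FALSE)
  expect_lt(max(abs(const)), 1e-6 * 7)
})

test_that("template building handles zero input and centers a point source", {
  g <- projection_geometry(9, 18)
  zero <- radon_forward(matrix(0, 9, 9), g)
  expect_true(all(build_template(zero, 9)$image == 0))

  d <- matrix(0, 9, 9); d[5, 5] <- 1
  tpl <- build_template(radon_forward(d, g), 9)$image
  expect_identical(which.max(tpl), 41L)  # the center pixel
})

test_that("the template beats a flat image as a starting estimate", {
  ph <- generate_lung_phantom(phantom_spec(16, seed = 4))
  s <- radon_forward(ph, projection_geometry(16, 18))
  tpl <- build_template(s, 16)$image
  flat <- matrix(mean(ph), 16, 16)
  expect_gt(psnr(ph, tpl), psnr(ph, flat))
})

test_that("with thresholding off the multiscale template equals plain FBP", {
  ph <- generate_lung_phantom(phantom_spec(16, seed = 3))
  s <- radon_forward(ph, projection_geometry(16, 18))
  fb <- fbp_reconstruct(s, 16)
  for (wv in c("haar", "db4")) {
    tpl <- build_template(s, 16, multiscale_filter(wv),
                          threshold_on = FALSE, quantize = NULL)$image
    expect_equal(unclass(tpl), unclass(fb), tolerance = 1e-6)
  }
})
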