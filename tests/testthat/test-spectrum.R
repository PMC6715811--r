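test_that("kernel columns are proper component CDFs", {
  r <- seq(0.01, 6, length.out = 80)
  Rg <- exp(seq(log(0.1), log(3), length.out = 15))
  K <- build_kernel(r, Rg, family = "rdc")
  expect_identical(dim(K), c(80L, 15L))
  expect_true(all(K >= 0 & K <= 1))
  expect_true(all(apply(K, 2, function(col) all(diff(col) >= 0))))
  # column matches quadrature of the component density
  j <- which.min(abs(Rg - 0.5))
  for (i in round(seq(1, 80, length.out = 10))) {
    expect_equal(K[i, j], quad_rdc_cdf(r[i], Rg[j], 1, 5 / 4), tolerance = 1e-8)
  }
  # a one-component spectrum reproduces that column exactly
  expect_equal(as.numeric(K %*% c(rep(0, j - 1), 1, rep(0, 15 - j))), K[, j])
})

test_that("identity kernel with alpha = 0 returns the data exactly", {
  w_true <- c(0.1, 0, 0.4, 0.2, 0.3)
  sol <- solve_nonneg_tikhonov(diag(5), w_true, alpha = 0)
  expect_equal(sol$raw_weights, w_true, tolerance = 1e-12)
  expect_equal(sol$weights, w_true / sum(w_true), tolerance = 1e-12)
  expect_false(sol$degenerate)
})

test_that("nonnegativity and normalisation hold; residual grows with alpha", {
  set.seed(21)
  Rg <- exp(seq(log(0.05), log(4), length.out = 40))
  r <- seq(0.02, 5, length.out = 120)
  K <- build_kernel(r, Rg, family = "rdc")
  w_true <- numeric(40); w_true[c(10, 30)] <- c(0.5, 0.5)
  y <- as.numeric(K %*% w_true) + rnorm(120, sd = 0.005)
  res_norm <- vapply(c(1e-4, 1e-2, 1, 100), function(a) {
    sol <- solve_nonneg_tikhonov(K, y, alpha = a)
    expect_true(all(sol$weights >= 0))
    if (!sol$degenerate) expect_equal(sum(sol$weights), 1, tolerance = 1e-9)
    sqrt(sum(sol$residual^2))
  }, numeric(1))
  expect_true(all(diff(res_norm) >= -1e-12))
})

test_that("a two-spike spectrum is recovered from its noiseless CDF", {
  Rg <- exp(seq(log(0.05), log(5), length.out = 60))
  i1 <- which.min(abs(Rg - 0.3)); i2 <- which.min(abs(Rg - 1.2))
  w_true <- numeric(60); w_true[i1] <- 0.4; w_true[i2] <- 0.6
  r <- seq(0.01, 6, length.out = 200)
  K <- build_kernel(r, Rg, family = "rdc")
  y <- as.numeric(K %*% w_true)
  sp <- deconvolve_spectrum(tibble::tibble(r = r, cdf = y), family = "rdc",
                            alpha = 1e-3, R_grid = Rg)
  s <- spectrum_summaries(sp)
  expect_identical(s$n_peaks, 2L)
  # recovered modes within one grid step of the generating spikes
  top2 <- order(sp$weights, decreasing = TRUE)[1:2]
  expect_true(min(abs(top2 - i1)) <= 1)
  expect_true(min(abs(top2 - i2)) <= 1)
  # CV close to the generating spectrum CV
  mu_t <- sum(w_true * Rg); cv_t <- sqrt(sum(w_true * (Rg - mu_t)^2)) / mu_t
  expect_equal(s$cv, cv_t, tolerance = 0.1)
  # forward-inverse residual small at mild regularisation
  expect_lt(sp$residual_max, 1e-3)
})

test_that("spectrum summaries have the right closed-form special cases", {
  one <- list(R_grid = c(0.2, 0.5, 1), weights = c(0, 1, 0))
  s1 <- spectrum_summaries(one)
  expect_equal(s1$cv, 0)
  expect_identical(s1$n_peaks, 1L)
  # equal masses at R and 3R: mu = 2R, sigma = R, CV = 1/2
  two <- list(R_grid = c(0.4, 0.8, 1.2), weights = c(0.5, 0, 0.5))
  s2 <- spectrum_summaries(two)
  expect_equal(s2$mu, 0.8)
  expect_equal(s2$sigma, 0.4)
  expect_equal(s2$cv, 0.5)
  expect_identical(s2$n_peaks, 2L)
})

test_that("spectrum of sampled single-population data is near-homogeneous", {
  d <- sample_distances(mixture_model(1, 0.8, 0.8, family = "rdc"),
                        n_cells = 3000, seed = 9)
  sp <- deconvolve_spectrum(d, family = "rdc")
  s <- spectrum_summaries(sp)
  expect_equal(s$mu, 0.8, tolerance = 0.08)
  expect_lt(s$cv, 0.25)
})

test_that("mixture-generated data yields peaks near R1 and R2", {
  m <- mixture_model(0.4, 0.3, 1.2, family = "rdc")
  d <- sample_distances(m, n_cells = 4000, seed = 13)
  sp <- deconvolve_spectrum(d, family = "rdc", alpha = 1e-2)
  tw <- tidy(sp)
  # mass concentrates near the two generating components
  near1 <- sum(tw$weight[abs(log(tw$R / 0.3)) < log(1.5)])
  near2 <- sum(tw$weight[abs(log(tw$R / 1.2)) < log(1.5)])
  expect_gt(near1, 0.2)
  expect_gt(near2, 0.3)
  expect_gt(near1 + near2, 0.8)
})

test_that("predicted_cdf reproduces the fit and single components", {
  Rg <- exp(seq(log(0.1), log(2), length.out = 30))
  r <- seq(0.02, 3, length.out = 90)
  K <- build_kernel(r, Rg, family = "chi")
  w <- numeric(30); w[12] <- 1
  y <- as.numeric(K %*% w)
  sp <- deconvolve_spectrum(tibble::tibble(r = r, cdf = y), family = "chi",
                            alpha = 1e-4, R_grid = Rg)
  pc <- predicted_cdf(sp)
  expect_equal(pc$cdf, sp$fitted)
  expect_lt(max(abs(pc$residual)), 1e-3)
  # evaluation on a fresh grid equals the single-component CDF
  r2 <- seq(0.1, 2, length.out = 20)
  pc2 <- predicted_cdf(sp, r2)
  expect_equal(pc2$cdf, chi_cdf(r2, sigma_from_mean(Rg[12])), tolerance = 5e-3)
})

test_that("alpha scan reports monotone solution norms", {
  d <- sample_distances(mixture_model(0.5, 0.4, 1.4, family = "rdc"),
                        n_cells = 800, seed = 30)
  sc <- scan_alpha(d, alphas = c(1e-3, 1e-1, 10), family = "rdc", n_grid = 40)
  expect_identical(nrow(sc), 3L)
  expect_true(all(diff(sc$solution_norm) <= 1e-9))
})
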