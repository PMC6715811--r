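test_that("chi density is a proper distribution with the Gaussian-chain mean", {
  expect_equal(chi_pdf(0, sigma = 0.5), 0)
  norm <- integrate(chi_pdf, 0, Inf, sigma = 0.3, rel.tol = 1e-10)$value
  expect_equal(norm, 1, tolerance = 1e-8)
  m <- integrate(function(r) r * chi_pdf(r, 1), 0, Inf, rel.tol = 1e-10)$value
  expect_equal(m, 2 * sqrt(2 / pi), tolerance = 1e-8)
  expect_equal(m, 1.595769, tolerance = 1e-6)
  expect_error(chi_pdf(0.1, sigma = -1), "sigma")
  expect_error(chi_pdf(-0.1, sigma = 1), "r")
})

test_that("contact probability equals quadrature of the chi density", {
  expect_equal(contact_prob_chi(0.3, 0.02), 7.869843e-05, tolerance = 1e-6)
  set.seed(101)
  for (i in 1:50) {
    sigma <- runif(1, 0.05, 2)
    r_c <- runif(1, 0.005, 1.5)
    expect_equal(contact_prob_chi(sigma, r_c), quad_contact_prob(sigma, r_c),
                 tolerance = 1e-9)
  }
  # limits: full mass and zero mass
  expect_equal(contact_prob_chi(0.1, 100), 1, tolerance = 1e-12)
  expect_lt(contact_prob_chi(100, 1e-4), 1e-15)
})

test_that("the mean-distance parameterisation agrees with the sigma one", {
  set.seed(7)
  sig <- runif(20, 0.05, 3)
  rc <- runif(20, 0.01, 1)
  expect_equal(contact_prob_from_mean(mean_from_sigma(sig), rc),
               contact_prob_chi(sig, rc), tolerance = 1e-12)
  # strict monotone decrease in the mean distance
  R <- seq(0.05, 5, length.out = 80)
  P <- contact_prob_from_mean(R, r_c = 0.1)
  expect_true(all(diff(P) < 0))
})

test_that("inversion recovers mean distances and obeys the small-P power law", {
  # a contact probability of 1e-3 maps to ~0.2 um at r_c = 20 nm and ~0.3 um
  # at 30 nm: the r_c sensitivity of inferred FISH distances
  expect_equal(invert_contact_to_mean(1e-3, 0.02), 0.2, tolerance = 0.05)
  expect_equal(invert_contact_to_mean(1e-3, 0.03), 0.3, tolerance = 0.05)

  # round trip across eight decades of P
  P <- 10^seq(-6, log10(0.99), length.out = 40)
  R <- invert_contact_to_mean(P, r_c = 0.02)
  expect_equal(contact_prob_from_mean(R, 0.02), P, tolerance = 1e-8)

  # asymptote <R> -> r_c P^(-1/3) within 5% for small P
  small <- P <= 1e-3
  ratio <- R[small] * P[small]^(1 / 3) / 0.02
  expect_true(all(abs(ratio - 1) < 0.05))

  expect_error(invert_contact_to_mean(0, 0.02), "P")
  expect_error(invert_contact_to_mean(1, 0.02), "P")
})

test_that("RdC family is normalised with the imposed first moment", {
  p <- contact_params(r_c = 0.01, g = 1, delta = 5 / 4)
  norm <- integrate(rdc_pdf, 0, Inf, mean_distance = 0.5, params = p,
                    rel.tol = 1e-10)$value
  expect_equal(norm, 1, tolerance = 1e-8)
  m1 <- quad_rdc_moment(0.5, g = 1, delta = 5 / 4, power = 1)
  expect_equal(m1, 0.5, tolerance = 1e-8)
  # CDF endpoints and agreement with quadrature
  expect_equal(rdc_cdf(0, 0.5, p), 0)
  expect_equal(rdc_cdf(1e6, 0.5, p), 1)
  for (r in c(0.1, 0.35, 0.8, 2)) {
    expect_equal(rdc_cdf(r, 0.5, p), quad_rdc_cdf(r, 0.5, 1, 5 / 4),
                 tolerance = 1e-9)
  }
  # quantile inverts the CDF
  q <- rdc_quantile(c(0.1, 0.5, 0.9), 0.5, p)
  expect_equal(rdc_cdf(q, 0.5, p), c(0.1, 0.5, 0.9), tolerance = 1e-10)
})

test_that("RdC with (g, delta) = (0, 2) reduces to the chi family", {
  p <- contact_params(r_c = 0.02, g = 0, delta = 2)
  set.seed(11)
  for (i in 1:20) {
    R <- runif(1, 0.1, 3)
    r <- runif(1, 0.01, 4)
    sigma <- sigma_from_mean(R)
    expect_equal(rdc_pdf(r, R, p), chi_pdf(r, sigma), tolerance = 1e-10)
    expect_equal(rdc_cdf(r, R, p), chi_cdf(r, sigma), tolerance = 1e-10)
    rc <- runif(1, 0.005, 0.5)
    pr <- contact_params(r_c = rc, g = 0, delta = 2)
    expect_equal(rdc_contact_prob(R, pr), contact_prob_from_mean(R, rc),
                 tolerance = 1e-10)
  }
})

test_that("delta can be supplied through the Flory exponent", {
  p <- contact_params(r_c = 0.01, g = 1, nu = 0.2)
  expect_equal(p$delta, 1 / (1 - 0.2))
  expect_error(contact_params(0.01, delta = 2, nu = 0.5), "not both")
  expect_error(contact_params(-1), "r_c")
})

test_that("theory_curve tabulates the inverse relation and asymptote", {
  tc <- theory_curve(c(1e-4, 1e-3, 1e-2), r_c = 0.02)
  expect_s3_class(tc, "tbl_df")
  expect_equal(tc$asymptote, 0.02 * c(1e-4, 1e-3, 1e-2)^(-1 / 3))
  expect_equal(contact_prob_from_mean(tc$mean_distance, 0.02),
               tc$contact_prob, tolerance = 1e-8)
})
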