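# Quadrature oracles kept independent of the closed forms under test.

quad_contact_prob <- function(sigma, r_c) {
  integrate(function(r) sqrt(2 / pi) * r^2 / sigma^3 * exp(-r^2 / (2 * sigma^2)),
            0, r_c, rel.tol = 1e-12)$value
}

quad_rdc_moment <- function(mean_distance, g, delta, power = 1) {
  b <- gamma((4 + g) / delta) / (gamma((3 + g) / delta) * mean_distance)
  f <- function(r) {
    delta * b^(3 + g) / gamma((3 + g) / delta) * r^(2 + g) * exp(-(b * r)^delta)
  }
  integrate(function(r) r^power * f(r), 0, Inf, rel.tol = 1e-10)$value
}

quad_rdc_cdf <- function(r, mean_distance, g, delta) {
  b <- gamma((4 + g) / delta) / (gamma((3 + g) / delta) * mean_distance)
  f <- function(x) {
    delta * b^(3 + g) / gamma((3 + g) / delta) * x^(2 + g) * exp(-(b * x)^delta)
  }
  integrate(f, 0, r, rel.tol = 1e-10)$value
}

# Fig. 2-style two-population chi mixtures used across tests (sigmas in um)
fig2_pair1 <- function() mixture_model(0.4, mean_from_sigma(0.3), mean_from_sigma(0.8))
fig2_pair2 <- function() mixture_model(0.4, mean_from_sigma(0.4), mean_from_sigma(0.5))
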