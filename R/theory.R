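#' Distance-distribution family parameters
#'
#' Bundles the contact threshold `r_c` and the Redner-des Cloizeaux (RdC)
#' exponents `(g, delta)` describing the pair distance distribution of one
#' homogeneous population. The Gaussian-chain (GRMC) case is `g = 0,
#' delta = 2`; chromatin fits use `g = 1, delta = 5/4`. `delta` may instead
#' be supplied through the Flory exponent `nu`, via `delta = 1 / (1 - nu)`.
#'
#' @param r_c Contact threshold distance (> 0), in the same length units as
#'   the distances the parameters will be used with (um for imaging data,
#'   bond lengths `a` for simulations).
#' @param g Dimensionless contact exponent (>= 0). The small-distance
#'   behaviour of the distance distribution is `r^(2+g)`, so contact
#'   probability scales as `P ~ <R>^-(3+g)`.
#' @param delta Dimensionless decay exponent (> 0) of the stretched
#'   exponential tail `exp(-(b r)^delta)`.
#' @param nu Optional Flory scaling exponent; if given, `delta` is derived
#'   as `1 / (1 - nu)` and the `delta` argument must be left missing.
#'
#' @return An object of class `contact_params`: a list with elements
#'   `r_c`, `g`, `delta`.
#' @examples
#' contact_params(r_c = 0.02)                   # Gaussian chain, r_c = 20 nm
#' contact_params(r_c = 0.01, g = 1, delta = 5/4) # chromatin RdC exponents
#' contact_params(r_c = 0.01, g = 1, nu = 0.2)    # same via nu
#' @export
contact_params <- function(r_c, g = 0, delta = NULL, nu = NULL) {
  if (!is.null(delta) && !is.null(nu)) {
    abort("supply either `delta` or `nu`, not both")
  }
  if (is.null(delta)) {
    delta <- if (is.null(nu)) 2 else {
      if (nu >= 1 || nu <= 0) abort("`nu` must be in (0, 1)")
      1 / (1 - nu)
    }
  }
  if (!is.numeric(r_c) || length(r_c) != 1L || !is.finite(r_c) || r_c <= 0) {
    abort("`r_c` must be a single positive number")
  }
  if (g < 0) abort("`g` must be >= 0")
  if (delta <= 0) abort("`delta` must be > 0")
  structure(list(r_c = r_c, g = g, delta = delta), class = "contact_params")
}

#' @export
print.contact_params <- function(x, ...) {
  cat(sprintf("<contact_params> r_c = %g, g = %g, delta = %g\n",
              x$r_c, x$g, x$delta))
  invisible(x)
}

erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# Shared kernel of Eq.-1/Eq.-11 type contact integrals:
#   k(x) = erf(x) - (2/sqrt(pi)) x exp(-x^2),
# with x = r_c/(sqrt(2) sigma) = 2 r_c/(sqrt(pi) <R>).
# For small x the two terms cancel to O(x^3); switch to the series
#   (2/sqrt(pi)) sum_{n>=1} (-1)^(n+1) 2n x^(2n+1) / (n! (2n+1))
# to keep full relative accuracy down to P ~ 1e-18.
contact_kernel <- function(x) {
  out <- erf(x) - (2 / sqrt(pi)) * x * exp(-x^2)
  small <- x < 0.05
  if (any(small)) {
    xs <- x[small]
    n <- 1:6
    terms <- vapply(xs, function(xi) {
      sum((-1)^(n + 1) * 2 * n * xi^(2 * n + 1) / (factorial(n) * (2 * n + 1)))
    }, numeric(1))
    out[small] <- (2 / sqrt(pi)) * terms
  }
  out
}

#' Chi (GRMC) pair-distance density
#'
#' Density of the 3D distance between two loci of a Gaussian chain whose
#' per-axis displacement is normal with standard deviation `sigma`:
#' `sqrt(2/pi) r^2 / sigma^3 exp(-r^2 / (2 sigma^2))`. Its mean is
#' `2 sqrt(2/pi) sigma`.
#'
#' @param r Distance(s), >= 0.
#' @param sigma Per-axis standard deviation (> 0).
#' @return Density values, same length as `r`.
#' @examples
#' chi_pdf(0.3, sigma = 0.3)
#' @export
chi_pdf <- function(r, sigma) {
  check_sigma(sigma)
  if (any(r < 0)) abort("`r` must be >= 0")
  sqrt(2 / pi) * r^2 / sigma^3 * exp(-r^2 / (2 * sigma^2))
}

#' @rdname chi_pdf
#' @export
chi_cdf <- function(r, sigma) {
  check_sigma(sigma)
  if (any(r < 0)) abort("`r` must be >= 0")
  contact_kernel(r / (sqrt(2) * sigma))
}

check_sigma <- function(sigma) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    abort("`sigma` must be positive and finite")
  }
}

#' Contact probability of a homogeneous Gaussian-chain population
#'
#' `contact_prob_chi()` integrates the chi density over `[0, r_c]`, giving
#' the closed form `erf(r_c / (sqrt(2) sigma)) - sqrt(2/pi) exp(-r_c^2 /
#' (2 sigma^2)) r_c / sigma`. `contact_prob_from_mean()` is the same map
#' parameterised by the mean distance `<R> = 2 sqrt(2/pi) sigma`; as a
#' function of `<R>` it is the strictly decreasing relation
#' `P = erf(2 r_c / (sqrt(pi) <R>)) - (4/pi) (r_c/<R>) exp(-4 r_c^2 /
#' (pi <R>^2))`, the one-to-one Hi-C/FISH map for a homogeneous population.
#'
#' @inheritParams chi_pdf
#' @param r_c Contact threshold (> 0), same units as `sigma`.
#' @param mean_distance Mean 3D distance(s) `<R>` (> 0).
#' @return Contact probability in (0, 1).
#' @examples
#' contact_prob_chi(sigma = 0.3, r_c = 0.02)
#' contact_prob_from_mean(mean_distance = 0.5, r_c = 0.02)
#' @export
contact_prob_chi <- function(sigma, r_c) {
  check_sigma(sigma)
  if (any(r_c <= 0)) abort("`r_c` must be > 0")
  contact_kernel(r_c / (sqrt(2) * sigma))
}

#' @rdname contact_prob_chi
#' @export
contact_prob_from_mean <- function(mean_distance, r_c) {
  if (any(!is.finite(mean_distance)) || any(mean_distance <= 0)) {
    abort("`mean_distance` must be positive and finite")
  }
  if (any(r_c <= 0)) abort("`r_c` must be > 0")
  contact_kernel(2 * r_c / (sqrt(pi) * mean_distance))
}

#' Convert between sigma and mean distance of the chi family
#'
#' The GRMC identities `<R> = 2 sqrt(2/pi) sigma` and its inverse.
#'
#' @param sigma,mean_distance Positive lengths.
#' @return The converted length(s).
#' @export
mean_from_sigma <- function(sigma) 2 * sqrt(2 / pi) * sigma

#' @rdname mean_from_sigma
#' @export
sigma_from_mean <- function(mean_distance) mean_distance * sqrt(pi) / (2 * sqrt(2))

#' Invert the contact-probability relation to a mean distance
#'
#' Numerically solves `contact_prob_from_mean(<R>, r_c) = P` for the unique
#' mean distance `<R>`, the quantity a FISH experiment would report for a
#' homogeneous population whose Hi-C contact probability is `P`. For small
#' `P` the solution approaches the power law `r_c * P^(-1/3)`.
#'
#' @param P Contact probability(ies), strictly inside (0, 1).
#' @param r_c Contact threshold (> 0).
#' @param tol Absolute root tolerance passed to [stats::uniroot()].
#' @return Mean distance(s), same units as `r_c`.
#' @examples
#' invert_contact_to_mean(1e-3, r_c = 0.02)  # ~0.2 um
#' invert_contact_to_mean(1e-3, r_c = 0.03)  # ~0.3 um
#' @export
invert_contact_to_mean <- function(P, r_c, tol = 1e-12) {
  if (any(!is.finite(P)) || any(P <= 0) || any(P >= 1)) {
    abort("`P` must lie strictly inside (0, 1)")
  }
  if (any(r_c <= 0)) abort("`r_c` must be > 0")
  vapply(P, function(p) {
    lower <- r_c * 1e-3
    upper <- 10 * r_c * p^(-1 / 3)
    # guaranteed bracket by monotonicity; widen defensively if needed
    while (contact_prob_from_mean(lower, r_c) < p) lower <- lower / 10
    while (contact_prob_from_mean(upper, r_c) > p) upper <- upper * 10
    root <- uniroot(function(R) contact_prob_from_mean(R, r_c) - p,
                    lower = lower, upper = upper, tol = tol)
    if (abs(root$f.root) > 1e-6 * p) {
      abort(sprintf(
        "inversion did not converge: P = %g, r_c = %g, residual = %g",
        p, r_c, root$f.root))
    }
    root$root
  }, numeric(1))
}

#' Theory curve of mean distance versus contact probability
#'
#' Evaluates the inverse contact map on a grid of probabilities, returning a
#' tidy curve (useful for overlaying on simulated or fitted pair statistics).
#'
#' @param P Vector of contact probabilities in (0, 1).
#' @param r_c Contact threshold.
#' @return A tibble with columns `contact_prob`, `mean_distance` and the
#'   small-P asymptote `asymptote = r_c * P^(-1/3)`.
#' @export
theory_curve <- function(P, r_c) {
  tibble::tibble(
    contact_prob = P,
    mean_distance = invert_contact_to_mean(P, r_c),
    asymptote = r_c * P^(-1 / 3)
  )
}

# Tail-decay constant of the RdC density, fixed by the unit-mean constraint:
# f(r) = delta b^(3+g) / Gamma((3+g)/delta) r^(2+g) exp(-(b r)^delta) with
# b = Gamma((4+g)/delta) / (Gamma((3+g)/delta) <R>).
rdc_b <- function(mean_distance, g, delta) {
  gamma((4 + g) / delta) / (gamma((3 + g) / delta) * mean_distance)
}

check_rdc <- function(mean_distance, params) {
  if (!inherits(params, "contact_params")) {
    abort("`params` must be a `contact_params` object")
  }
  if (any(!is.finite(mean_distance)) || any(mean_distance <= 0)) {
    abort("`mean_distance` must be positive and finite")
  }
}

#' Redner-des Cloizeaux pair-distance distribution
#'
#' Generalized-gamma family for polymer pair distances,
#' `f(r) = delta b^(3+g) / Gamma((3+g)/delta) * r^(2+g) * exp(-(b r)^delta)`,
#' with `b` fixed so the first moment equals `mean_distance`. With
#' `(g, delta) = (0, 2)` it reduces exactly to the Gaussian-chain chi family;
#' `(1, 5/4)` is the chromatin parameterisation. The CDF is the regularised
#' lower incomplete gamma `P((3+g)/delta, (b r)^delta)`, so the contact
#' probability is simply `rdc_cdf(r_c, ...)`.
#'
#' @param r Distance(s) >= 0.
#' @param mean_distance Mean distance `<R>` (> 0).
#' @param params A [contact_params()] object supplying `g`, `delta` (and
#'   `r_c` for `rdc_contact_prob()`).
#' @return Density, cumulative probability, or contact probability.
#' @examples
#' p <- contact_params(r_c = 0.01, g = 1, delta = 5/4)
#' rdc_pdf(0.4, mean_distance = 0.5, params = p)
#' rdc_cdf(0.4, mean_distance = 0.5, params = p)
#' rdc_contact_prob(mean_distance = 0.5, params = p)
#' @export
rdc_pdf <- function(r, mean_distance, params) {
  check_rdc(mean_distance, params)
  if (any(r < 0)) abort("`r` must be >= 0")
  g <- params$g; delta <- params$delta
  b <- rdc_b(mean_distance, g, delta)
  delta * b^(3 + g) / gamma((3 + g) / delta) * r^(2 + g) * exp(-(b * r)^delta)
}

#' @rdname rdc_pdf
#' @export
rdc_cdf <- function(r, mean_distance, params) {
  check_rdc(mean_distance, params)
  if (any(r < 0)) abort("`r` must be >= 0")
  g <- params$g; delta <- params$delta
  b <- rdc_b(mean_distance, g, delta)
  pgamma((b * r)^delta, shape = (3 + g) / delta)
}

#' @rdname rdc_pdf
#' @export
rdc_contact_prob <- function(mean_distance, params) {
  rdc_cdf(params$r_c, mean_distance, params)
}

#' @rdname rdc_pdf
#' @param p Cumulative probability(ies) in [0, 1), for the quantile function.
#' @export
rdc_quantile <- function(p, mean_distance, params) {
  check_rdc(mean_distance, params)
  if (any(p < 0) || any(p >= 1)) abort("`p` must lie in [0, 1)")
  g <- params$g; delta <- params$delta
  b <- rdc_b(mean_distance, g, delta)
  qgamma(p, shape = (3 + g) / delta)^(1 / delta) / b
}
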