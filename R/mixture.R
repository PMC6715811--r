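#' Two-subpopulation mixture of pair-distance distributions
#'
#' Describes one locus pair measured across a heterogeneous cell population:
#' a fraction `eta` of cells has mean pair distance `R1` (e.g. the looped
#' subpopulation) and the remaining `1 - eta` has mean distance `R2`. The
#' component distance law is either the Gaussian-chain chi family or the
#' Redner-des Cloizeaux family with exponents `(g, delta)`. The population
#' mean distance is `eta * R1 + (1 - eta) * R2` and the population contact
#' probability is the same convex combination of component contact
#' probabilities — the two averages that FISH and Hi-C respectively probe.
#'
#' @param eta Fraction of cells in the first (closer) subpopulation, in
#'   \[0, 1\].
#' @param R1,R2 Component mean distances, `0 < R1 <= R2` after
#'   canonicalisation (a call with `R1 > R2` is relabelled by swapping the
#'   components and replacing `eta` with `1 - eta`).
#' @param family `"chi"` or `"rdc"`.
#' @param g,delta RdC exponents (ignored for `family = "chi"`, which is
#'   `(0, 2)`).
#' @return An object of class `mixture_model`.
#' @examples
#' mixture_model(eta = 0.4, R1 = mean_from_sigma(0.3), R2 = mean_from_sigma(0.8))
#' @export
mixture_model <- function(eta, R1, R2, family = c("chi", "rdc"),
                          g = 1, delta = 5 / 4) {
  family <- match.arg(family)
  if (!is.finite(eta) || eta < 0 || eta > 1) abort("`eta` must be in [0, 1]")
  if (!is.finite(R1) || R1 <= 0 || !is.finite(R2) || R2 <= 0) {
    abort("`R1` and `R2` must be positive")
  }
  if (R1 > R2) {
    tmp <- R1; R1 <- R2; R2 <- tmp
    eta <- 1 - eta
  }
  if (family == "chi") {
    g <- 0; delta <- 2
  }
  structure(list(eta = eta, R1 = R1, R2 = R2,
                 family = family, g = g, delta = delta),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf(
    "<mixture_model> family = %s (g = %g, delta = %g)\n  eta = %.4g, R1 = %.4g, R2 = %.4g, mean = %.4g\n",
    x$family, x$g, x$delta, x$eta, x$R1, x$R2, mixture_mean(x)))
  invisible(x)
}

model_params <- function(model) {
  contact_params(r_c = 1, g = model$g, delta = model$delta)
}

#' Mixture density, CDF, mean and contact probability
#'
#' Convex combinations of the component quantities of a [mixture_model()]:
#' `eta * f(r | R1) + (1 - eta) * f(r | R2)` for the density (and likewise
#' for the CDF), `eta * R1 + (1 - eta) * R2` for the mean, and
#' `eta * P(R1) + (1 - eta) * P(R2)` for the contact probability, where
#' `P(R)` is the component probability of the pair being within `r_c`.
#'
#' @param r Distance(s) >= 0.
#' @param model A [mixture_model()].
#' @param r_c Contact threshold (> 0), same units as `R1`, `R2`.
#' @return Numeric vector (density/CDF) or single probability.
#' @examples
#' m <- mixture_model(0.4, mean_from_sigma(0.3), mean_from_sigma(0.8))
#' mixture_contact_prob(m, r_c = 0.02)
#' @export
mixture_pdf <- function(r, model) {
  p <- model_params(model)
  model$eta * rdc_pdf(r, model$R1, p) + (1 - model$eta) * rdc_pdf(r, model$R2, p)
}

#' @rdname mixture_pdf
#' @export
mixture_cdf <- function(r, model) {
  p <- model_params(model)
  model$eta * rdc_cdf(r, model$R1, p) + (1 - model$eta) * rdc_cdf(r, model$R2, p)
}

#' @rdname mixture_pdf
#' @export
mixture_mean <- function(model) {
  model$eta * model$R1 + (1 - model$eta) * model$R2
}

#' @rdname mixture_pdf
#' @export
mixture_contact_prob <- function(model, r_c) {
  if (r_c <= 0) abort("`r_c` must be > 0")
  p <- contact_params(r_c = r_c, g = model$g, delta = model$delta)
  model$eta * rdc_contact_prob(model$R1, p) +
    (1 - model$eta) * rdc_contact_prob(model$R2, p)
}

#' Mean-distance and contact-probability maps over a grid of mixtures
#'
#' Evaluates, for a fixed looped fraction `eta`, the population mean distance
#' and contact probability of every mixture on the grid `R1_grid x R2_grid`.
#' At `eta = 0` both quantities depend on `R2` alone and are linked one to
#' one; at intermediate `eta` their contour lines cross, so cells exist where
#' one pair has both the larger mean distance and the larger contact
#' probability — the FISH-Hi-C paradox.
#'
#' @param eta Looped-population fraction.
#' @param R1_grid,R2_grid Vectors of component mean distances.
#' @param r_c Contact threshold.
#' @param family,g,delta Component family, as in [mixture_model()].
#' @return A tibble with one row per grid cell: `R1`, `R2`, `mean_distance`,
#'   `contact_prob`.
#' @examples
#' paradox_grid(0.3, seq(2, 20, 2), seq(20, 100, 10), r_c = 2)
#' @export
paradox_grid <- function(eta, R1_grid, R2_grid, r_c,
                         family = c("chi", "rdc"), g = 1, delta = 5 / 4) {
  family <- match.arg(family)
  if (any(R1_grid <= 0) || any(R2_grid <= 0)) abort("grids must be positive")
  grid <- tidyr::expand_grid(R1 = R1_grid, R2 = R2_grid)
  if (family == "chi") { g <- 0; delta <- 2 }
  p <- contact_params(r_c = r_c, g = g, delta = delta)
  grid |>
    dplyr::mutate(
      mean_distance = eta * .data$R1 + (1 - eta) * .data$R2,
      contact_prob = eta * rdc_contact_prob(.data$R1, p) +
        (1 - eta) * rdc_contact_prob(.data$R2, p)
    )
}

#' Locate paradoxical pairs on a mixture grid
#'
#' Searches the rows of a [paradox_grid()] result for pairs where one member
#' has strictly larger mean distance *and* strictly larger contact
#' probability than the other (a single ascending-P sweep with a running
#' distance minimum, equivalent to the exhaustive quadratic scan for
#' detecting whether any such pair exists).
#'
#' @param grid A tibble as returned by [paradox_grid()].
#' @param max_pairs Stop after collecting this many paradox pairs (the
#'   exhaustive scan is quadratic in grid size).
#' @return A tibble with columns `i`, `j` (row indices of `grid`) and the two
#'   pairs' `mean_distance` and `contact_prob` values; zero rows if no
#'   paradox exists.
#' @export
find_paradox_pairs <- function(grid, max_pairs = Inf) {
  R <- grid$mean_distance
  P <- grid$contact_prob
  ord <- order(P)                      # ascending P
  out_i <- integer(0); out_j <- integer(0)
  # paradox: P_i > P_j and R_i > R_j. Scan in ascending-P order, tracking the
  # running minimum of R; any later point with larger R than some earlier
  # point is paradoxical with it.
  run_min <- Inf; run_min_idx <- NA_integer_
  for (k in seq_along(ord)) {
    idx <- ord[k]
    if (is.finite(run_min) && R[idx] > run_min && P[idx] > P[run_min_idx]) {
      out_i <- c(out_i, idx); out_j <- c(out_j, run_min_idx)
      if (length(out_i) >= max_pairs) break
    }
    if (R[idx] < run_min) { run_min <- R[idx]; run_min_idx <- idx }
  }
  tibble::tibble(
    i = out_i, j = out_j,
    mean_distance_i = R[out_i], mean_distance_j = R[out_j],
    contact_prob_i = P[out_i], contact_prob_j = P[out_j]
  )
}

#' Relative contact frequencies across a set of locus pairs
#'
#' Hi-C reports contact counts, not probabilities, and the threshold `r_c`
#' is unknown; model and experiment are therefore compared on the scale-free
#' quantity `P_i / mean(P)`, each pair's value divided by the arithmetic mean
#' over the pair set.
#'
#' @param P Nonnegative contact probabilities or raw Hi-C counts (>= 2
#'   values).
#' @return Dimensionless relative frequencies averaging to 1.
#' @examples
#' relative_contact_frequencies(c(10, 20, 30))
#' @export
relative_contact_frequencies <- function(P) {
  if (length(P) < 2) abort("need at least 2 pairs")
  if (any(P < 0)) abort("values must be nonnegative")
  m <- mean(P)
  if (m == 0) abort("all values are zero")
  P / m
}

#' Correlate predicted and Hi-C relative contact frequencies
#'
#' @param predicted Model contact probabilities per pair.
#' @param counts Hi-C contact counts for the same pairs, same order.
#' @return Pearson correlation between the two sets of relative frequencies.
#' @export
compare_to_hic <- function(predicted, counts) {
  if (length(predicted) != length(counts)) {
    abort("`predicted` and `counts` must have equal length")
  }
  cor(relative_contact_frequencies(predicted),
      relative_contact_frequencies(counts))
}
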