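#' Discretised CDF kernel for subpopulation deconvolution
#'
#' The observed distance CDF of a heterogeneous population is a weighted
#' superposition of single-population CDFs over the distribution of mean
#' distances `P(<R>)`. Discretising that integral on a grid of candidate
#' means gives a linear system `K w = y` with
#' `K[i, j] = CDF(r_i | R_grid[j])` under the chosen distance family; each
#' column of `K` is a proper CDF sampled at the observation abscissae.
#'
#' @param r_grid Observation distances (ordered, >= 0).
#' @param R_grid Candidate mean distances (strictly increasing, > 0).
#' @param family,g,delta Component family as in [mixture_model()].
#' @return A `length(r_grid) x length(R_grid)` matrix with entries in
#'   \[0, 1\].
#' @export
build_kernel <- function(r_grid, R_grid, family = c("chi", "rdc"),
                         g = 1, delta = 5 / 4) {
  family <- match.arg(family)
  if (family == "chi") { g <- 0; delta <- 2 }
  if (any(r_grid < 0)) abort("`r_grid` must be >= 0")
  if (any(R_grid <= 0) || is.unsorted(R_grid, strictly = TRUE)) {
    abort("`R_grid` must be strictly increasing and positive")
  }
  params <- contact_params(r_c = 1, g = g, delta = delta)
  vapply(R_grid, function(R) rdc_cdf(r_grid, R, params),
         numeric(length(r_grid)))
}

#' Recover the subpopulation spectrum from a distance CDF
#'
#' Solves the discretised superposition `K w ~ y` for nonnegative weights by
#' Tikhonov-regularised nonnegative least squares:
#' `argmin ||K w - y||^2 + alpha^2 ||w||^2, w >= 0`, computed as ordinary
#' nonnegative least squares on the augmented system
#' `rbind(K, alpha * I) w = c(y, 0)` (Lawson-Hanson, via
#' [pracma::lsqnonneg()]). The weights are then normalised to sum to one,
#' giving the discrete spectrum of subpopulation mean distances `P(<R>)`.
#'
#' @param data Distances or CDF curve, as accepted by [fit_mixture()]; raw
#'   distances are converted to a right-continuous empirical CDF.
#' @param family,g,delta Component family.
#' @param alpha Regularisation strength (>= 0). The default `1e-2` is a
#'   mild ridge; see [scan_alpha()] for an L-curve style scan.
#' @param R_grid Candidate mean distances. Default: `n_grid` log-spaced
#'   points spanning `[min(r)/2, max(r)]` of the data.
#' @param n_grid Size of the default grid.
#' @param max_points When raw distances are given, the empirical CDF is
#'   evaluated at up to this many quantile-spaced points (keeps the solve
#'   cheap for large samples without changing the curve).
#' @return An object of class `subpop_spectrum`: list with `R_grid`,
#'   `weights` (nonnegative, summing to 1), `raw_weights` (pre-normalisation
#'   solution), `alpha`, `r`, `cdf` (the data curve used), `fitted` (K w on
#'   `r`), `residual_max` (max-norm residual), `degenerate` (TRUE if the
#'   solver returned the all-zero solution), and the family parameters.
#' @examples
#' set.seed(1)
#' m <- mixture_model(0.4, 0.3, 1.2, family = "rdc")
#' d <- sample_distances(m, n_cells = 1000)
#' sp <- deconvolve_spectrum(d, family = "rdc")
#' glance(sp)
#' @export
deconvolve_spectrum <- function(data, family = c("chi", "rdc"), g = 1,
                                delta = 5 / 4, alpha = 1e-2, R_grid = NULL,
                                n_grid = 100, max_points = 400) {
  family <- match.arg(family)
  if (alpha < 0) abort("`alpha` must be >= 0")
  grid <- as_cdf_grid(data)
  r <- grid$r; y <- grid$cdf
  if (length(r) > max_points) {
    idx <- unique(round(seq(1, length(r), length.out = max_points)))
    r <- r[idx]; y <- y[idx]
  }
  if (is.null(R_grid)) {
    rng <- range(r[r > 0])
    # cap the grid at the largest observed distance: components with larger
    # means are supported only by the extreme ECDF tail, where sampling noise
    # otherwise attracts spurious mass that inflates the spectrum mean
    R_grid <- exp(seq(log(rng[1] / 2), log(rng[2]), length.out = n_grid))
  }
  if (length(y) < length(R_grid) / 4) {
    abort("too few CDF points to identify the spectrum; coarsen `R_grid`")
  }
  K <- build_kernel(r, R_grid, family = family, g = g, delta = delta)
  sol <- solve_nonneg_tikhonov(K, y, alpha)
  if (sol$degenerate) {
    warn("deconvolution returned the all-zero solution; spectrum is degenerate")
  }
  structure(list(R_grid = R_grid, weights = sol$weights,
                 raw_weights = sol$raw_weights,
                 alpha = alpha, r = r, cdf = y, fitted = sol$fitted,
                 residual_max = max(abs(sol$fitted - y)),
                 degenerate = sol$degenerate,
                 family = family,
                 g = if (family == "chi") 0 else g,
                 delta = if (family == "chi") 2 else delta),
            class = "subpop_spectrum")
}

#' Nonnegative Tikhonov-regularised least squares
#'
#' Solves `argmin ||K w - y||^2 + alpha^2 ||w||^2` subject to `w >= 0` by
#' Lawson-Hanson nonnegative least squares on the augmented system
#' `rbind(K, alpha I) w = c(y, 0)`. This is the workhorse behind
#' [deconvolve_spectrum()] and is exposed for custom kernels.
#'
#' @param K Kernel matrix (rows = observations, columns = candidates).
#' @param y Observed values, `length(y) == nrow(K)`.
#' @param alpha Regularisation strength (>= 0).
#' @return A list with `weights` (normalised to sum 1 unless degenerate),
#'   `raw_weights` (unnormalised minimiser), `fitted` (`K %*% raw_weights`),
#'   `residual` (`fitted - y`) and `degenerate` (all-zero solution flag).
#' @export
solve_nonneg_tikhonov <- function(K, y, alpha = 1e-2) {
  K <- as.matrix(K)
  if (length(y) != nrow(K)) abort("`length(y)` must equal `nrow(K)`")
  if (alpha < 0) abort("`alpha` must be >= 0")
  ng <- ncol(K)
  A <- if (alpha > 0) rbind(K, alpha * diag(ng)) else K
  b <- if (alpha > 0) c(y, rep(0, ng)) else y
  w <- pracma::lsqnonneg(A, b)$x
  w[w < 0] <- 0
  degenerate <- sum(w) <= 0
  fitted <- as.numeric(K %*% w)
  list(weights = if (degenerate) w else w / sum(w),
       raw_weights = w, fitted = fitted, residual = fitted - y,
       degenerate = degenerate)
}

#' @export
print.subpop_spectrum <- function(x, ...) {
  s <- spectrum_summaries(x)
  cat(sprintf(
    "<subpop_spectrum> %d grid points on [%.3g, %.3g], alpha = %g\n  mu = %.4g, sigma = %.4g, CV = %.3g, peaks = %d, max residual = %.2g\n",
    length(x$R_grid), min(x$R_grid), max(x$R_grid), x$alpha,
    s$mu, s$sigma, s$cv, s$n_peaks, x$residual_max))
  invisible(x)
}

#' Moments, heterogeneity index and peak count of a spectrum
#'
#' Weighted summaries of the recovered distribution of subpopulation mean
#' distances: mean `mu(<R>)`, standard deviation `sigma(<R>)`, the
#' coefficient of variation `CV = sigma(<R>)/mu(<R>)` (near zero for a
#' homogeneous population), and the number of peaks (local maxima of the
#' weight vector with height at least `peak_threshold` of the tallest).
#'
#' @param spectrum A `subpop_spectrum`, or a list/tibble with `R_grid` and
#'   `weights`.
#' @param peak_threshold Relative height floor for counting a local maximum
#'   as a peak.
#' @return A tibble with columns `mu`, `sigma`, `cv`, `n_peaks`.
#' @export
spectrum_summaries <- function(spectrum, peak_threshold = 0.05) {
  R <- spectrum$R_grid; w <- spectrum$weights
  if (sum(w) <= 0) {
    return(tibble::tibble(mu = NA_real_, sigma = NA_real_, cv = NA_real_,
                          n_peaks = 0L))
  }
  w <- w / sum(w)
  mu <- sum(w * R)
  sigma <- sqrt(max(sum(w * (R - mu)^2), 0))
  tibble::tibble(mu = mu, sigma = sigma, cv = sigma / mu,
                 n_peaks = count_peaks(w, peak_threshold))
}

count_peaks <- function(w, threshold = 0.05) {
  n <- length(w)
  if (n == 0 || max(w) <= 0) return(0L)
  floor_h <- threshold * max(w)
  wpad <- c(-Inf, w, -Inf)
  peaks <- 0L
  i <- 2L
  while (i <= n + 1L) {
    if (wpad[i] > wpad[i - 1L]) {
      j <- i
      while (j < n + 1L && wpad[j + 1L] == wpad[j]) j <- j + 1L  # plateau
      if (wpad[j + 1L] < wpad[j] && wpad[i] >= floor_h) peaks <- peaks + 1L
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  peaks
}

#' Normalised spectrum over `<R>/mu(<R>)`
#'
#' Rescales the grid by the spectrum mean, the representation used to
#' compare heterogeneity across locus pairs with different length scales.
#'
#' @inheritParams spectrum_summaries
#' @return A tibble with `R_rel = R_grid / mu` and `weight`.
#' @export
normalized_spectrum <- function(spectrum) {
  s <- spectrum_summaries(spectrum)
  tibble::tibble(R_rel = spectrum$R_grid / s$mu, weight = spectrum$weights)
}

#' Reconstructed CDF implied by a spectrum
#'
#' Evaluates `K w` on a distance grid, with the kernel rebuilt under the
#' spectrum's family; used to inspect residuals against the data curve.
#'
#' @inheritParams spectrum_summaries
#' @param r_grid Distances at which to evaluate (defaults to the fitted
#'   data's abscissae).
#' @return A tibble with `r`, `cdf` and, when evaluated on the data grid,
#'   `residual` (fitted minus data).
#' @export
predicted_cdf <- function(spectrum, r_grid = NULL) {
  on_data <- is.null(r_grid)
  if (on_data) r_grid <- spectrum$r
  K <- build_kernel(r_grid, spectrum$R_grid, family = spectrum$family,
                    g = spectrum$g, delta = spectrum$delta)
  out <- tibble::tibble(r = r_grid, cdf = as.numeric(K %*% spectrum$raw_weights))
  if (on_data) out$residual <- out$cdf - spectrum$cdf
  out
}

#' L-curve style scan of the regularisation strength
#'
#' Re-solves the deconvolution over a grid of `alpha` values, reporting the
#' data-residual norm and the solution norm so a corner can be picked by eye.
#'
#' @inheritParams deconvolve_spectrum
#' @param alphas Values of the regularisation strength to scan.
#' @return A tibble with `alpha`, `residual_norm` (`||K w - y||`),
#'   `solution_norm` (`||w||`), `cv` and `n_peaks`.
#' @export
scan_alpha <- function(data, alphas = 10^seq(-4, 0, length.out = 9),
                       family = c("chi", "rdc"), g = 1, delta = 5 / 4,
                       R_grid = NULL, n_grid = 100) {
  family <- match.arg(family)
  purrr::map_dfr(alphas, function(a) {
    sp <- deconvolve_spectrum(data, family = family, g = g, delta = delta,
                              alpha = a, R_grid = R_grid, n_grid = n_grid)
    s <- spectrum_summaries(sp)
    tibble::tibble(alpha = a,
                   residual_norm = sqrt(sum((sp$fitted - sp$cdf)^2)),
                   solution_norm = sqrt(sum(sp$raw_weights^2)),
                   cv = s$cv, n_peaks = s$n_peaks)
  })
}

#' @rdname deconvolve_spectrum
#' @param x,object A `subpop_spectrum` object.
#' @param ... Unused.
#' @export
tidy.subpop_spectrum <- function(x, ...) {
  tibble::tibble(R = x$R_grid, weight = x$weights)
}

#' @rdname deconvolve_spectrum
#' @export
glance.subpop_spectrum <- function(x, ...) {
  dplyr::bind_cols(
    spectrum_summaries(x),
    tibble::tibble(alpha = x$alpha, residual_max = x$residual_max,
                   degenerate = x$degenerate, n_grid = length(x$R_grid),
                   family = x$family)
  )
}

#' @rdname deconvolve_spectrum
#' @export
autoplot.subpop_spectrum <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$R, y = .data$weight)) +
    ggplot2::geom_col(width = diff(range(df$R)) / length(df$R) * 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "subpopulation mean distance <R>", y = "weight") +
    ggplot2::theme_minimal()
}
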