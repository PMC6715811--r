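#' Fit a two-subpopulation mixture to FISH distance data
#'
#' Estimates `(eta, R1, R2)` by least squares between the model cumulative
#' distance distribution and the empirical CDF, the standard way FISH
#' distance data are summarised. With raw distances the residuals are taken
#' at the empirical jump points (CDF value `i/n` at the i-th order
#' statistic); with a pre-tabulated curve, at the supplied abscissae. An
#' explicit `r_grid` re-weights the fit: the empirical CDF is evaluated at
#' those distances instead, which up-weights sparsely sampled regions (a
#' uniform grid makes a small extended subpopulation's tail count far more
#' than the handful of cells it contributes at the jump points). The
#' objective is multimodal, so the optimiser (L-BFGS-B on
#' `(eta, log R1, log R2)`) is restarted from a deterministic grid of
#' quantile-based initial values and the best minimum kept. Fits are
#' canonicalised to `R1 <= R2` (swapping relabels `eta` as `1 - eta`).
#'
#' @param data Either a numeric vector of distances, or a data frame with a
#'   `distance` (or `distance_um`) column of per-cell distances, or a data
#'   frame with `r` (or `r_um`) and `cdf` columns giving an empirical CDF
#'   curve.
#' @param family,g,delta Component family as in [mixture_model()].
#' @param bounds Length-2 vector of admissible component mean distances
#'   (defaults to 1 nm to 100 um when distances are in um).
#' @param n_eta_starts Number of `eta` starting values (spread over (0, 1)).
#' @param r_grid Optional distances at which the empirical CDF of raw
#'   distance data is evaluated for the fit (ignored jump points); only
#'   valid with raw distances, not with a pre-tabulated curve.
#' @return An object of class `mixture_fit`: list with elements `model`
#'   ([mixture_model()]), `objective` (sum of squared CDF residuals),
#'   `convergence` (0 = converged), `n` (number of residual points),
#'   `ks` (Kolmogorov-Smirnov statistic of the fit), `degenerate` (TRUE when
#'   the data had < 3 distinct values and a single-population fallback was
#'   returned), and the fitting grid (`r`, `ecdf`).
#' @examples
#' set.seed(1)
#' d <- sample_distances(mixture_model(0.4, 0.5, 1.5), n_cells = 500)
#' fit <- fit_mixture(d)
#' tidy(fit)
#' @export
fit_mixture <- function(data, family = c("chi", "rdc"), g = 1, delta = 5 / 4,
                        bounds = c(1e-3, 100), n_eta_starts = 5,
                        r_grid = NULL) {
  family <- match.arg(family)
  if (family == "chi") { g <- 0; delta <- 2 }
  grid <- as_cdf_grid(data)
  if (!is.null(r_grid)) {
    if (!isTRUE(attr(grid, "step"))) {
      abort("`r_grid` applies to raw distances, not to a supplied CDF curve")
    }
    r_grid <- sort(r_grid[is.finite(r_grid) & r_grid >= 0])
    if (length(r_grid) < 3) abort("`r_grid` needs at least 3 points")
    grid <- tibble::tibble(r = r_grid, cdf = stats::ecdf(grid$r)(r_grid))
    attr(grid, "step") <- FALSE
  }
  r <- grid$r; y <- grid$cdf

  if (length(unique(r)) < 3) {
    # degenerate: not enough distinct distances to resolve two components
    R <- if (length(r)) mean(r) else abort("no distances supplied")
    model <- mixture_model(1, R, R, family = family, g = g, delta = delta)
    return(new_mixture_fit(model, r, y, objective = NA_real_,
                           convergence = 1L, degenerate = TRUE))
  }

  params <- contact_params(r_c = 1, g = g, delta = delta)
  obj <- function(par) {
    eta <- par[1]; R1 <- exp(par[2]); R2 <- exp(par[3])
    pred <- eta * rdc_cdf(r, R1, params) + (1 - eta) * rdc_cdf(r, R2, params)
    sum((pred - y)^2)
  }

  # deterministic multistart: eta grid x quantile-based (R1, R2) guesses,
  # with quantiles read off the (possibly pre-tabulated) empirical CDF
  qs <- vapply(c(0.1, 0.25, 0.5, 0.75, 0.9), function(p) {
    idx <- which(y >= p)[1]
    if (is.na(idx)) r[length(r)] else max(r[idx], bounds[1] * 1.01)
  }, numeric(1))
  qs <- pmin(pmax(qs, bounds[1] * 1.01), bounds[2] * 0.99)
  etas <- seq(0.1, 0.9, length.out = n_eta_starts)
  starts <- tidyr::expand_grid(
    eta = etas,
    R1 = unique(qs[1:2]),
    R2 = unique(qs[4:5])
  )
  starts <- dplyr::bind_rows(
    starts,
    tibble::tibble(eta = 1, R1 = qs[3], R2 = qs[3])  # single-population start
  )

  lower <- c(0, log(bounds[1]), log(bounds[1]))
  upper <- c(1, log(bounds[2]), log(bounds[2]))
  fits <- purrr::pmap(starts, function(eta, R1, R2) {
    tryCatch(
      optim(c(eta, log(R1), log(R2)), obj, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL
    )
  })
  fits <- purrr::compact(fits)
  if (!length(fits)) abort("all optimisation starts failed")
  best <- fits[[which.min(purrr::map_dbl(fits, "value"))]]

  model <- mixture_model(best$par[1], exp(best$par[2]), exp(best$par[3]),
                         family = family, g = g, delta = delta)
  new_mixture_fit(model, r, y, objective = best$value,
                  convergence = best$convergence, degenerate = FALSE,
                  step = isTRUE(attr(grid, "step")))
}

new_mixture_fit <- function(model, r, y, objective, convergence, degenerate,
                            step = TRUE) {
  f <- mixture_cdf(r, model)
  ks <- if (step) max(abs(f - y), abs(f - c(0, head(y, -1)))) else max(abs(f - y))
  structure(list(model = model, r = r, ecdf = y, objective = objective,
                 convergence = convergence, degenerate = degenerate,
                 n = length(r), ks = ks),
            class = "mixture_fit")
}

# Normalise the accepted input shapes to a tibble(r, cdf) of evaluation
# points: sorted jump points with right-continuous ECDF i/n for raw
# distances, or the curve as given.
as_cdf_grid <- function(data) {
  if (is.numeric(data)) {
    distances <- data
  } else if (is.data.frame(data)) {
    nm <- names(data)
    if (any(c("distance", "distance_um") %in% nm)) {
      distances <- data[[intersect(c("distance", "distance_um"), nm)[1]]]
    } else if (all(c("cdf", "r") %in% nm) || all(c("cdf", "r_um") %in% nm)) {
      r <- data[[intersect(c("r", "r_um"), nm)[1]]]
      y <- data$cdf
      if (is.unsorted(r)) { o <- order(r); r <- r[o]; y <- y[o] }
      if (any(diff(y) < -1e-9) || any(y < -1e-9) || any(y > 1 + 1e-9)) {
        abort("`cdf` must be nondecreasing within [0, 1]")
      }
      out <- tibble::tibble(r = r, cdf = pmin(pmax(y, 0), 1))
      attr(out, "step") <- FALSE
      return(out)
    } else {
      abort("data frame must have a `distance`/`distance_um` column or `r`(+`r_um`)/`cdf` columns")
    }
  } else {
    abort("`data` must be a numeric vector or data frame")
  }
  if (any(!is.finite(distances)) || any(distances < 0)) {
    abort("distances must be finite and >= 0")
  }
  r <- sort(distances)
  out <- tibble::tibble(r = r, cdf = seq_along(r) / length(r))
  attr(out, "step") <- TRUE
  out
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit>\n")
  print(x$model)
  cat(sprintf("  objective = %.4g, KS = %.4g, n = %d%s\n",
              x$objective, x$ks, x$n,
              if (x$degenerate) " [degenerate single-population fallback]" else ""))
  invisible(x)
}

#' Kolmogorov-Smirnov statistic between a mixture model and data
#'
#' The sup-norm distance between the model CDF and the empirical CDF, used
#' as the goodness-of-fit summary for fitted FISH distance distributions.
#' Accepts the same data shapes as [fit_mixture()].
#'
#' @param model A [mixture_model()].
#' @param data Distances or CDF curve (see [fit_mixture()]).
#' @return The KS statistic (dimensionless, in \[0, 1\]).
#' @export
ks_statistic <- function(model, data) {
  grid <- as_cdf_grid(data)
  f <- mixture_cdf(grid$r, model)
  if (isTRUE(attr(grid, "step"))) {
    # sup over both sides of each jump of the step ECDF
    max(abs(f - grid$cdf), abs(f - c(0, head(grid$cdf, -1))))
  } else {
    max(abs(f - grid$cdf))
  }
}

#' @rdname fit_mixture
#' @param x A `mixture_fit` object.
#' @param ... Unused.
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble::tibble(
    term = c("eta", "R1", "R2"),
    estimate = c(x$model$eta, x$model$R1, x$model$R2)
  )
}

#' @rdname fit_mixture
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble::tibble(
    eta = x$model$eta, R1 = x$model$R1, R2 = x$model$R2,
    mean_distance = mixture_mean(x$model),
    objective = x$objective, ks = x$ks, n = x$n,
    convergence = x$convergence, degenerate = x$degenerate,
    family = x$model$family, g = x$model$g, delta = x$model$delta
  )
}

#' @rdname fit_mixture
#' @param object A `mixture_fit` object.
#' @export
autoplot.mixture_fit <- function(object, ...) {
  df <- tibble::tibble(r = object$r, ecdf = object$ecdf,
                       fitted = mixture_cdf(object$r, object$model))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$ecdf, colour = "empirical")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted, colour = "fitted"),
                       linetype = "dashed") +
    ggplot2::labs(x = "distance", y = "CDF", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Fit mixtures to several locus pairs at once
#'
#' Applies [fit_mixture()] within each `pair_id` of a tidy FISH table and
#' returns one summary row per pair (the [glance()] columns plus the pair
#' id and, when `r_c` is given, the predicted contact probability).
#'
#' @param fish A data frame with columns `pair_id` and `distance_um` (or
#'   `distance`), one row per cell.
#' @param r_c Optional contact threshold; when supplied, a
#'   `predicted_contact_prob` column is added.
#' @inheritParams fit_mixture
#' @return A tibble with one row per pair.
#' @export
fit_mixture_pairs <- function(fish, family = c("chi", "rdc"), g = 1,
                              delta = 5 / 4, r_c = NULL) {
  family <- match.arg(family)
  if (!"pair_id" %in% names(fish)) abort("`fish` must have a `pair_id` column")
  fish |>
    dplyr::group_by(.data$pair_id) |>
    dplyr::group_modify(function(df, key) {
      fit <- fit_mixture(df, family = family, g = g, delta = delta)
      out <- glance(fit)
      if (!is.null(r_c)) {
        out$predicted_contact_prob <- mixture_contact_prob(fit$model, r_c)
      }
      out
    }) |>
    dplyr::ungroup()
}
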