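#' Sample FISH-style distances from a mixture or spectrum
#'
#' Draws i.i.d. per-cell 3D distances the way an imaging experiment would
#' report them: a subpopulation is chosen by its weight, then a distance is
#' drawn from that component's distance law by the exact inverse-CDF on its
#' generalised-gamma representation (`dist = G^(1/delta) / b` with
#' `G ~ Gamma((3+g)/delta)`), optionally blurred by additive Gaussian
#' measurement noise truncated at zero. Real FISH localisation error is not
#' modelled by default (`noise = 0`).
#'
#' @param model A [mixture_model()], or a `subpop_spectrum` / list with
#'   `R_grid` and `weights` describing an arbitrary discrete spectrum of
#'   subpopulation mean distances.
#' @param n_cells Number of cells (draws).
#' @param seed Optional integer seed (uses and advances R's RNG when set).
#' @param noise Measurement noise standard deviation, same units as the
#'   distances.
#' @param pair_id Label stored in the output.
#' @return A tibble with columns `pair_id`, `distance_um`.
#' @examples
#' sample_distances(mixture_model(0.4, 0.3, 1.2, family = "rdc"),
#'                  n_cells = 100, seed = 7)
#' @export
sample_distances <- function(model, n_cells, seed = NULL, noise = 0,
                             pair_id = "pair_1") {
  if (n_cells < 1) abort("`n_cells` must be >= 1")
  if (noise < 0) abort("`noise` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (inherits(model, "mixture_model")) {
    R <- c(model$R1, model$R2)
    w <- c(model$eta, 1 - model$eta)
    g <- model$g; delta <- model$delta
  } else if (!is.null(model$R_grid) && !is.null(model$weights)) {
    R <- model$R_grid; w <- model$weights
    g <- model$g %||% 0; delta <- model$delta %||% 2
  } else {
    abort("`model` must be a mixture_model or have `R_grid` and `weights`")
  }
  if (sum(w) <= 0) abort("component weights sum to zero")
  w <- w / sum(w)
  comp <- sample.int(length(R), n_cells, replace = TRUE, prob = w)
  shape <- (3 + g) / delta
  b <- rdc_b(R[comp], g, delta)
  r <- rgamma(n_cells, shape = shape)^(1 / delta) / b
  if (noise > 0) r <- pmax(r + rnorm(n_cells, sd = noise), 0)
  tibble::tibble(pair_id = pair_id, distance_um = r)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random loop-anchor set
#'
#' Uniformly samples `n_loops` distinct non-adjacent anchor pairs on a chain
#' of `N` loci, each spanning at least `min_span` monomers.
#'
#' @param N Chain length.
#' @param n_loops Number of loops (0 gives a plain Rouse chain).
#' @param min_span Minimum anchor separation (> 1).
#' @param seed Optional integer seed.
#' @return A [loop_set()].
#' @export
sample_loopset <- function(N, n_loops, min_span = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (min_span <= 1) abort("`min_span` must be > 1")
  if (n_loops == 0) return(loop_set())
  anchors <- matrix(NA_integer_, 0, 2)
  guard <- 0
  while (nrow(anchors) < n_loops) {
    p <- sample.int(N - min_span, 1)
    q <- sample(seq(p + min_span, N), 1)
    anchors <- unique(rbind(anchors, c(p, q)))
    guard <- guard + 1
    if (guard > 1000 * n_loops) abort("could not place requested loops")
  }
  loop_set(anchors)
}

#' Pseudo-Hi-C contact counts
#'
#' Draws per-pair contact counts as `Poisson(depth * P_i)`, the sampling
#' model under which relative contact frequencies are recoverable from
#' counts as the read depth grows.
#'
#' @param true_probs Vector of per-pair contact probabilities.
#' @param depth Expected total count scale (reads per unit probability).
#' @param seed Optional integer seed.
#' @param pair_id Optional labels (default `pair_1`, `pair_2`, ...).
#' @return A tibble with `pair_id`, `contact_count`.
#' @export
sample_hic_counts <- function(true_probs, depth, seed = NULL, pair_id = NULL) {
  if (any(true_probs < 0)) abort("`true_probs` must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pair_id)) pair_id <- paste0("pair_", seq_along(true_probs))
  tibble::tibble(pair_id = pair_id,
                 contact_count = rpois(length(true_probs), depth * true_probs))
}
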