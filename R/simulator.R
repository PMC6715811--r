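#' Loop-anchor set for the chromosome chain
#'
#' A set of monomer index pairs `{p, q}` (1-based, `|p - q| > 1`) to be
#' cross-linked by harmonic loop bonds, modelling CTCF/cohesin-mediated
#' loops. Pairs are stored unordered-unique with `p < q`.
#'
#' @param anchors A two-column matrix or data frame of monomer indices, or
#'   `NULL` for a plain Rouse chain.
#' @return An object of class `loop_set` (integer matrix, columns `p`, `q`).
#' @examples
#' loop_set(cbind(c(5, 20), c(40, 60)))
#' @export
loop_set <- function(anchors = NULL) {
  if (is.null(anchors) || NROW(anchors) == 0) {
    m <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("p", "q")))
    return(structure(m, class = c("loop_set", class(m))))
  }
  m <- as.matrix(anchors)[, 1:2, drop = FALSE]
  storage.mode(m) <- "integer"
  if (any(!is.finite(m)) || any(m < 1)) abort("anchor indices must be >= 1")
  p <- pmin(m[, 1], m[, 2]); q <- pmax(m[, 1], m[, 2])
  if (any(q - p <= 1)) {
    abort("loop anchors must be non-adjacent (|p - q| > 1)")
  }
  m <- unique(cbind(p = p, q = q))
  structure(m, class = c("loop_set", class(m)))
}

#' Generalized Rouse chromosome chain
#'
#' A harmonic bead-spring chain of `N` loci with backbone spring constant
#' `kappa`, extra harmonic cross-links of stiffness `omega` at the loop
#' anchors, friction `xi` and thermal energy `kT`. With
#' `rest_length_mode = "zero"` all springs have zero rest length and the
#' equilibrium ensemble is exactly Gaussian (solvable by normal modes of the
#' connectivity matrix); with `"a"` the bond and loop potentials are
#' `k/2 (|d| - a)^2`, the form used for finite-bond-length simulations.
#'
#' @param N Number of loci (>= 2).
#' @param loops A [loop_set()] (anchor indices must lie in `1..N`).
#' @param a Equilibrium bond length (simulation length unit).
#' @param kappa Backbone spring constant, in `kT / a^2`.
#' @param omega Loop spring constant, in `kT / a^2`.
#' @param xi Friction coefficient (low values accelerate conformational
#'   sampling).
#' @param kT Thermal energy.
#' @param rest_length_mode `"zero"` or `"a"` (see above).
#' @return An object of class `grmc_system`.
#' @examples
#' grmc_system(50, loops = loop_set(cbind(10, 40)))
#' @export
grmc_system <- function(N, loops = loop_set(), a = 1, kappa = 100,
                        omega = 100, xi = 0.1, kT = 1,
                        rest_length_mode = c("zero", "a")) {
  rest_length_mode <- match.arg(rest_length_mode)
  if (N < 2) abort("`N` must be >= 2")
  if (kappa <= 0 || omega < 0 || xi <= 0 || kT < 0 || a <= 0) {
    abort("`kappa`, `xi`, `a` must be > 0; `omega`, `kT` >= 0")
  }
  if (!inherits(loops, "loop_set")) loops <- loop_set(loops)
  if (NROW(loops) && max(loops) > N) {
    abort("loop anchor index exceeds chain length `N`")
  }
  structure(list(N = as.integer(N), loops = loops, a = a, kappa = kappa,
                 omega = omega, xi = xi, kT = kT,
                 rest_length_mode = rest_length_mode),
            class = "grmc_system")
}

#' @export
print.grmc_system <- function(x, ...) {
  cat(sprintf(
    "<grmc_system> N = %d, %d loops, kappa = %g, omega = %g, xi = %g, kT = %g, rest length = %s\n",
    x$N, NROW(x$loops), x$kappa, x$omega, x$xi, x$kT,
    if (x$rest_length_mode == "zero") "0" else "a"))
  invisible(x)
}

#' Connectivity matrix of the loop-anchored chain
#'
#' The `N x N` matrix `A` coupling loci in the Langevin equation
#' `xi dR/dt = A R + F`: off-diagonal `kappa` between chain neighbours,
#' `omega` between loop anchors, and diagonal entries set so every row sums
#' to zero (translation invariance). `A` is symmetric negative semidefinite
#' with a single zero eigenvalue for a connected chain.
#'
#' @param system A [grmc_system()].
#' @return The connectivity matrix.
#' @examples
#' build_connectivity(grmc_system(3, kappa = 2))
#' @export
build_connectivity <- function(system) {
  N <- system$N
  A <- matrix(0, N, N)
  idx <- cbind(1:(N - 1), 2:N)
  A[idx] <- system$kappa
  A[idx[, 2:1, drop = FALSE]] <- system$kappa
  if (NROW(system$loops)) {
    A[system$loops] <- A[system$loops] + system$omega
    A[system$loops[, 2:1, drop = FALSE]] <-
      A[system$loops[, 2:1, drop = FALSE]] + system$omega
  }
  diag(A) <- -rowSums(A)
  A
}

#' Exact pair statistics by normal-mode analysis
#'
#' Diagonalises the connectivity matrix and evaluates, for each requested
#' locus pair, the per-axis standard deviation of the pair vector,
#' `sigma_mn^2 = -sum_p (V_pm - V_pn)^2 kT / lambda_p` over the non-zero
#' modes (the uniform zero mode contributes nothing), together with the
#' implied mean distance `<R_mn> = 2 sqrt(2/pi) sigma_mn`. Exact for
#' `rest_length_mode = "zero"`.
#'
#' @param system A [grmc_system()].
#' @param pairs Optional two-column matrix of locus pairs; default all
#'   `N (N - 1) / 2` pairs.
#' @return A tibble with columns `m`, `n`, `sigma`, `mean_distance`.
#' @export
analytic_pair_sigma <- function(system, pairs = NULL) {
  A <- build_connectivity(system)
  e <- eigen(A, symmetric = TRUE)
  lam <- e$values
  tol <- max(abs(lam)) * 1e-9
  zero <- abs(lam) < tol
  if (sum(zero) != 1L) {
    abort("chain is disconnected: connectivity matrix has multiple zero modes")
  }
  keep <- !zero
  # rows of M are loci; sigma^2_mn = || M[m, ] - M[n, ] ||^2
  M <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(-system$kT / lam[keep]), sum(keep))
  if (is.null(pairs)) {
    pairs <- t(utils::combn(system$N, 2))
  }
  pairs <- as.matrix(pairs)
  d <- M[pairs[, 1], , drop = FALSE] - M[pairs[, 2], , drop = FALSE]
  sig <- sqrt(rowSums(d^2))
  tibble::tibble(m = as.integer(pairs[, 1]), n = as.integer(pairs[, 2]),
                 sigma = sig, mean_distance = mean_from_sigma(sig))
}

default_dt <- function(system) 0.01 / sqrt(system$kappa)

init_positions <- function(system) {
  if (system$rest_length_mode == "zero") {
    matrix(0, system$N, 3)
  } else {
    cbind(seq(0, by = system$a, length.out = system$N), 0, 0)
  }
}

#' Langevin dynamics of the chain
#'
#' Integrates the underdamped Langevin equation for the chain with a BAOAB
#' splitting (unit bead mass), returning saved snapshots. The random-force
#' stream is generated from `seed` alone, so a repeated call reproduces the
#' trajectory bit for bit.
#'
#' @param system A [grmc_system()].
#' @param n_steps Production steps after `burn_in`.
#' @param dt Time step; default `0.01 / sqrt(kappa)` (in units where the
#'   bead mass is 1).
#' @param save_every Snapshot interval in steps.
#' @param seed Integer seed of the thermal-noise stream.
#' @param burn_in Equilibration steps discarded before saving.
#' @param x_init Optional `N x 3` initial coordinates; default all-zero for
#'   zero rest length, a straight line at bond spacing `a` otherwise.
#' @return An object of class `grmc_trajectory`: list with `positions`
#'   (array `N x 3 x T`), `system`, `dt`, `seed`, `save_every` and
#'   `kinetic_temp` (mean per-axis kinetic temperature over saved frames).
#' @examples
#' sys <- grmc_system(10, kappa = 1)
#' tr <- langevin_run(sys, n_steps = 2000, seed = 1)
#' @export
langevin_run <- function(system, n_steps, dt = NULL, save_every = 100,
                         seed = 1, burn_in = 0, x_init = NULL) {
  if (is.null(dt)) dt <- default_dt(system)
  if (n_steps < save_every) abort("`n_steps` must be >= `save_every`")
  if (is.null(x_init)) x_init <- init_positions(system)
  res <- grmc_langevin_cpp(
    N = system$N, kappa = system$kappa, omega = system$omega,
    xi = system$xi, kT = system$kT,
    r0 = if (system$rest_length_mode == "zero") 0 else system$a,
    loops = loop_matrix(system), x_init = x_init, dt = dt,
    n_steps = as.integer(n_steps), burn_in = as.integer(burn_in),
    save_every = as.integer(save_every), seed = as.integer(seed),
    pairs = matrix(integer(0), ncol = 2), rc = 0, save_traj = TRUE)
  structure(list(positions = res$trajectory, system = system, dt = dt,
                 seed = seed, save_every = save_every,
                 kinetic_temp = res$kinetic_temp),
            class = "grmc_trajectory")
}

loop_matrix <- function(system) {
  m <- unclass(system$loops)
  if (!NROW(m)) m <- matrix(integer(0), ncol = 2)
  storage.mode(m) <- "integer"
  m
}

#' @export
print.grmc_trajectory <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf(
    "<grmc_trajectory> N = %d, %d snapshots (every %d steps, dt = %g), kinetic T = %.4g\n",
    d[1], d[3], x$save_every, x$dt, x$kinetic_temp))
  invisible(x)
}

#' Contact probabilities and mean distances from trajectories
#'
#' The simulation estimators: over all saved snapshots of all supplied
#' trajectories, `P_mn` is the fraction of frames with
#' `|r_m - r_n| <= r_c` and `<R_mn>` the average distance.
#'
#' @param trajectory A `grmc_trajectory` or a list of them (independent
#'   replicas are pooled).
#' @param r_c Contact threshold.
#' @param pairs Optional two-column matrix of locus pairs (default: all
#'   pairs).
#' @return A tibble with `m`, `n`, `contact_prob`, `mean_distance`,
#'   `sigma2_hat` (distance second moment / 3, the per-axis variance
#'   estimate) and `n_frames`.
#' @export
estimate_stats <- function(trajectory, r_c, pairs = NULL) {
  trajs <- if (inherits(trajectory, "grmc_trajectory")) list(trajectory)
           else trajectory
  N <- dim(trajs[[1]]$positions)[1]
  if (is.null(pairs)) pairs <- t(utils::combn(N, 2))
  pairs <- as.matrix(pairs)
  np <- nrow(pairs)
  contact <- numeric(np); sum_r <- numeric(np); sum_r2 <- numeric(np)
  frames <- 0L
  for (tr in trajs) {
    pos <- tr$positions
    t_n <- dim(pos)[3]
    frames <- frames + t_n
    for (k in seq_len(np)) {
      dvec <- pos[pairs[k, 1], , , drop = FALSE] -
        pos[pairs[k, 2], , , drop = FALSE]
      d2 <- colSums(matrix(dvec, nrow = 3)^2)
      d <- sqrt(d2)
      contact[k] <- contact[k] + sum(d <= r_c)
      sum_r[k] <- sum_r[k] + sum(d)
      sum_r2[k] <- sum_r2[k] + sum(d2)
    }
  }
  tibble::tibble(m = as.integer(pairs[, 1]), n = as.integer(pairs[, 2]),
                 contact_prob = contact / frames,
                 mean_distance = sum_r / frames,
                 sigma2_hat = sum_r2 / (3 * frames),
                 n_frames = frames)
}

#' Streamed pair statistics from independent Langevin replicas
#'
#' Runs `n_traj` independent trajectories (seeds `seed, seed + 1, ...`) and
#' accumulates the contact and distance estimators inside the integrator
#' without storing snapshots, which keeps long production runs cheap in
#' memory. Per-trajectory estimates are returned alongside the pooled ones
#' so standard errors can be taken across replicas.
#'
#' @inheritParams langevin_run
#' @inheritParams estimate_stats
#' @param n_traj Number of independent trajectories.
#' @return A list with `stats` (pooled tibble as in [estimate_stats()]),
#'   `per_traj` (tibble with per-replica `mean_distance` and `sigma2_hat`),
#'   and `kinetic_temp` (mean over replicas).
#' @export
simulate_pair_stats <- function(system, pairs, r_c, n_traj = 10,
                                n_steps = 1e5, burn_in = 0, dt = NULL,
                                save_every = 100, seed = 1) {
  if (is.null(dt)) dt <- default_dt(system)
  pairs <- as.matrix(pairs)
  storage.mode(pairs) <- "integer"
  np <- nrow(pairs)
  contact <- numeric(np); sum_r <- numeric(np); sum_r2 <- numeric(np)
  frames <- 0
  per <- vector("list", n_traj)
  ktemp <- numeric(n_traj)
  x_init <- init_positions(system)
  for (a in seq_len(n_traj)) {
    res <- grmc_langevin_cpp(
      N = system$N, kappa = system$kappa, omega = system$omega,
      xi = system$xi, kT = system$kT,
      r0 = if (system$rest_length_mode == "zero") 0 else system$a,
      loops = loop_matrix(system), x_init = x_init, dt = dt,
      n_steps = as.integer(n_steps), burn_in = as.integer(burn_in),
      save_every = as.integer(save_every),
      seed = as.integer(seed + a - 1L),
      pairs = pairs, rc = r_c, save_traj = FALSE)
    contact <- contact + res$contact
    sum_r <- sum_r + res$sum_r
    sum_r2 <- sum_r2 + res$sum_r2
    frames <- frames + res$n_saved
    ktemp[a] <- res$kinetic_temp
    per[[a]] <- tibble::tibble(
      traj = a, m = pairs[, 1], n = pairs[, 2],
      contact_prob = res$contact / res$n_saved,
      mean_distance = res$sum_r / res$n_saved,
      sigma2_hat = res$sum_r2 / (3 * res$n_saved))
  }
  stats <- tibble::tibble(m = as.integer(pairs[, 1]),
                          n = as.integer(pairs[, 2]),
                          contact_prob = contact / frames,
                          mean_distance = sum_r / frames,
                          sigma2_hat = sum_r2 / (3 * frames),
                          n_frames = frames)
  list(stats = stats, per_traj = dplyr::bind_rows(per),
       kinetic_temp = mean(ktemp))
}

#' Bin the mean distance against the contact probability
#'
#' Reproduces the simulation-versus-theory summary: pairs are binned by
#' their estimated contact probability and the average of `<R_mn>` is
#' reported per bin, for overlaying on the closed-form curve
#' [theory_curve()]. Bins are log-spaced in `P` by default (`n_bins` per
#' the spanned decades) or linear with width `delta`.
#'
#' @param stats A tibble with `contact_prob` and `mean_distance` columns
#'   (from [estimate_stats()] or [simulate_pair_stats()]).
#' @param n_bins Number of log-spaced bins.
#' @param delta Optional linear bin width in `P`; overrides `n_bins`.
#' @param p_min Discard pairs with estimated `P` below this floor.
#' @return A tibble with `bin_center`, `contact_prob` (mean estimated P in
#'   the bin), `mean_distance` (binned average `E[<R_mn>]`) and `n_pairs`;
#'   empty bins are omitted.
#' @export
binned_P_vs_R <- function(stats, n_bins = 25, delta = NULL, p_min = 0) {
  df <- dplyr::filter(stats, .data$contact_prob > max(p_min, 0))
  if (!nrow(df)) abort("no pairs with contact probability above `p_min`")
  if (is.null(delta)) {
    edges <- exp(seq(log(min(df$contact_prob)) - 1e-9,
                     log(max(df$contact_prob)) + 1e-9,
                     length.out = n_bins + 1))
    centers <- sqrt(edges[-1] * edges[-length(edges)])
  } else {
    lo <- floor(min(df$contact_prob) / delta) * delta
    edges <- seq(lo, max(df$contact_prob) + delta, by = delta)
    centers <- (edges[-1] + edges[-length(edges)]) / 2
  }
  df |>
    dplyr::mutate(bin = cut(.data$contact_prob, edges, labels = FALSE,
                            include.lowest = TRUE)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(contact_prob = mean(.data$contact_prob),
                     mean_distance = mean(.data$mean_distance),
                     n_pairs = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(bin_center = centers[.data$bin]) |>
    dplyr::select("bin_center", "contact_prob", "mean_distance", "n_pairs")
}

#' Plot simulated pair statistics against the closed-form curve
#'
#' @param stats Pair statistics tibble (see [binned_P_vs_R()]).
#' @param r_c Contact threshold used for the statistics.
#' @param binned Overlay binned averages instead of raw pairs when TRUE.
#' @return A ggplot object: `<R>` versus `P` on log-log axes with the
#'   theoretical relation and its small-P asymptote.
#' @export
plot_P_vs_R <- function(stats, r_c, binned = TRUE) {
  pts <- if (binned) binned_P_vs_R(stats) else stats
  pr <- range(pts$contact_prob)
  curve <- theory_curve(exp(seq(log(pr[1]), log(pr[2]), length.out = 100)), r_c)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$contact_prob,
                                    y = .data$mean_distance)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$asymptote),
                       linetype = "dashed", colour = "grey50") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "contact probability P", y = "mean distance <R>") +
    ggplot2::theme_minimal()
}
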