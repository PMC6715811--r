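test_that("connectivity matrix matches the loop-anchored chain definition", {
  k <- 2.5
  A <- build_connectivity(grmc_system(3, kappa = k))
  expect_equal(A, matrix(c(-k, k, 0, k, -2 * k, k, 0, k, -k), 3, 3))
  expect_equal(sort(eigen(A, symmetric = TRUE)$values),
               c(-3 * k, -k, 0), tolerance = 1e-12)

  sys <- grmc_system(6, loops = loop_set(cbind(2, 5)), kappa = 1, omega = 3)
  A <- build_connectivity(sys)
  expect_equal(A, t(A))
  expect_equal(rowSums(A), rep(0, 6), tolerance = 1e-12)
  expect_equal(A[2, 5], 3)
  expect_equal(A[2, 2], -2 * 1 - 1 * 3)  # -2 kappa - |Sigma_2| omega
  ev <- eigen(A, symmetric = TRUE)$values
  expect_true(all(ev < 1e-10))
  expect_identical(sum(abs(ev) < 1e-10), 1L)  # single zero mode

  expect_error(grmc_system(6, loops = loop_set(cbind(2, 10))), "exceeds")
  expect_error(loop_set(cbind(3, 4)), "non-adjacent")
})

test_that("normal-mode pair statistics match hand-solvable cases", {
  # two beads: sigma^2 = kT/kappa from the single (0, -2 kappa) eigenpair
  sys2 <- grmc_system(2, kappa = 4, kT = 1.5)
  st <- analytic_pair_sigma(sys2)
  expect_equal(st$sigma^2, 1.5 / 4, tolerance = 1e-12)
  expect_equal(st$mean_distance, mean_from_sigma(st$sigma))

  # plain Rouse chain: sigma^2_mn = |m - n| kT / kappa
  sysr <- grmc_system(12, kappa = 2, kT = 1)
  str <- analytic_pair_sigma(sysr)
  expect_equal(str$sigma^2, abs(str$m - str$n) / 2, tolerance = 1e-9)

  # adding a loop strictly tightens every pair it spans
  base <- analytic_pair_sigma(grmc_system(30, kappa = 1))
  looped <- analytic_pair_sigma(
    grmc_system(30, loops = loop_set(cbind(5, 25)), kappa = 1, omega = 1))
  expect_true(all(looped$sigma <= base$sigma + 1e-12))
  in_span <- base$m >= 5 & base$n <= 25
  expect_true(all(looped$sigma[in_span] < base$sigma[in_span]))
})

test_that("Langevin dynamics is reproducible and thermally consistent", {
  sys <- grmc_system(15, kappa = 1, xi = 0.1)
  tr1 <- langevin_run(sys, n_steps = 3e4, seed = 99, burn_in = 5e3)
  tr2 <- langevin_run(sys, n_steps = 3e4, seed = 99, burn_in = 5e3)
  expect_identical(tr1$positions, tr2$positions)
  tr3 <- langevin_run(sys, n_steps = 3e4, seed = 100, burn_in = 5e3)
  expect_false(identical(tr1$positions, tr3$positions))
  # equipartition: kinetic temperature within 5% of kT
  expect_equal(tr1$kinetic_temp, 1, tolerance = 0.05)
})

test_that("frozen dynamics at kT = 0 from mechanical equilibrium is static", {
  sys <- grmc_system(8, kappa = 5, kT = 0, rest_length_mode = "a")
  x0 <- cbind(seq(0, by = 1, length.out = 8), 0, 0)
  tr <- langevin_run(sys, n_steps = 1000, save_every = 100, seed = 1,
                     x_init = x0)
  last <- tr$positions[, , dim(tr$positions)[3]]
  expect_equal(last, unname(x0), tolerance = 1e-12)
})

test_that("simulated pair statistics agree with normal-mode analytics", {
  loops <- loop_set(rbind(c(4, 18), c(10, 26)))
  sys <- grmc_system(30, loops = loops, kappa = 1, omega = 1, xi = 0.1)
  pairs <- rbind(c(1, 30), c(4, 18), c(8, 22), c(1, 10), c(15, 16))
  out <- simulate_pair_stats(sys, pairs, r_c = 2, n_traj = 6, n_steps = 1.2e5,
                             burn_in = 3e4, save_every = 50, seed = 17)
  an <- analytic_pair_sigma(sys, pairs)
  per <- out$per_traj |>
    dplyr::group_by(m, n) |>
    dplyr::summarise(s2 = mean(sigma2_hat),
                     se = sd(sigma2_hat) / sqrt(dplyr::n()),
                     R = mean(mean_distance),
                     seR = sd(mean_distance) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::inner_join(an, by = c("m", "n"))
  expect_true(all(abs(per$s2 - per$sigma^2) <= 3 * per$se))
  expect_true(all(abs(per$R - per$mean_distance) <= 3 * per$seR))
  # contact probabilities near the closed-form chi prediction
  joined <- dplyr::inner_join(out$stats, an, by = c("m", "n"))
  expect_equal(joined$contact_prob,
               contact_prob_from_mean(joined$mean_distance.y, 2),
               tolerance = 0.1)
})

test_that("isotropy: per-axis variances agree across x, y, z", {
  sys <- grmc_system(10, kappa = 1, xi = 0.1)
  tr <- langevin_run(sys, n_steps = 1e5, burn_in = 2e4, save_every = 25,
                     seed = 12)
  d <- tr$positions[1, , ] - tr$positions[10, , ]  # 3 x T pair vector
  v <- apply(d, 1, function(axis) mean(axis^2))
  expect_lt(diff(range(v)) / mean(v), 0.35)
  expect_equal(mean(v), 9, tolerance = 0.15)  # sigma^2 = |m-n| kT/kappa = 9
})

test_that("trajectory estimators transcribe the snapshot definitions", {
  # single synthetic snapshot: two beads at distance d
  tr <- structure(list(
    positions = array(c(0, 0.5, 0, 0, 0, 0), dim = c(2, 3, 1)),
    system = grmc_system(2), dt = 0.01, seed = 1, save_every = 1,
    kinetic_temp = 1), class = "grmc_trajectory")
  st_in <- estimate_stats(tr, r_c = 1)
  expect_equal(st_in$contact_prob, 1)
  expect_equal(st_in$mean_distance, 0.5)
  st_out <- estimate_stats(tr, r_c = 0.2)
  expect_equal(st_out$contact_prob, 0)
  # streamed accumulation agrees with stored-trajectory estimation
  sys <- grmc_system(8, kappa = 1)
  tr1 <- langevin_run(sys, n_steps = 2e4, burn_in = 1e3, save_every = 100,
                      seed = 55)
  es <- estimate_stats(tr1, r_c = 1.5)
  stream <- simulate_pair_stats(sys, pairs = cbind(es$m, es$n), r_c = 1.5,
                                n_traj = 1, n_steps = 2e4, burn_in = 1e3,
                                save_every = 100, seed = 55)
  expect_equal(es$contact_prob, stream$stats$contact_prob, tolerance = 1e-12)
  expect_equal(es$mean_distance, stream$stats$mean_distance, tolerance = 1e-9)
})

test_that("binning by contact probability averages the right members", {
  stats <- tibble::tibble(contact_prob = c(0.1, 0.1, 0.1, 0.5, 0.5),
                          mean_distance = c(1, 2, 3, 10, 20))
  b <- binned_P_vs_R(stats, delta = 0.2)
  expect_identical(nrow(b), 2L)
  expect_equal(b$mean_distance, c(2, 15))
  expect_equal(b$n_pairs, c(3L, 2L))
  # all pairs identical: one bin holding the common value
  b1 <- binned_P_vs_R(tibble::tibble(contact_prob = rep(0.3, 4),
                                     mean_distance = rep(1.7, 4)), n_bins = 5)
  expect_equal(sum(b1$n_pairs), 4L)
  expect_equal(b1$mean_distance[1], 1.7)
})

test_that("numerical blow-up is caught with a diagnostic", {
  sys <- grmc_system(5, kappa = 100)
  expect_error(langevin_run(sys, n_steps = 5000, dt = 1, seed = 1),
               "blow-up")
})
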