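---
title: "Methods: models, estimators and numerical choices in fishhic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and numerical choices in fishhic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishhic)
```

# The model

## Generalized Rouse Model for Chromosomes (GRMC)

A chromosome segment is a chain of `N` monomers connected by harmonic
bonds of stiffness `kappa` (in units of `kT/a^2`, with `a` the bond
length scale). Loops — e.g. cohesin-extruded, CTCF-anchored — are extra
harmonic bonds of stiffness `omega` between non-adjacent anchor
monomers. The potential is quadratic, so the Boltzmann distribution of
monomer positions is Gaussian and everything about pair distances is
determined by the connectivity matrix `A`:

- `A[i, i+1] = A[i+1, i] = kappa` for chain neighbours,
- `A[p, q] = A[q, p] = omega` for each loop `(p, q)`,
- diagonal entries make every row sum to zero.

`A` is negative semidefinite with a single zero mode (uniform
translation) whenever the chain is connected; `analytic_pair_sigma()`
checks this and refuses disconnected systems.

## Exact pair statistics

Diagonalising `A = V Λ Vᵀ` and dropping the zero mode, the vector
distance between monomers `m` and `n` is Gaussian per coordinate with

```
sigma^2_mn = sum_{p : lambda_p < 0} (V[m,p] - V[n,p])^2 * kT / (-lambda_p)
```

The scalar distance is then chi-distributed (3 degrees of freedom,
scale `sigma_mn`):

```
f(r) = sqrt(2/pi) r^2 / sigma^3 exp(-r^2 / (2 sigma^2))
<R>  = 2 sqrt(2/pi) sigma
```

and the probability of being within a capture radius `r_c` is the
closed form used throughout the package:

```
P = erf(x) - (2/sqrt(pi)) x exp(-x^2),   x = r_c / (sqrt(2) sigma)
                                           = 2 r_c / (sqrt(pi) <R>)
```

with the small-`P` asymptote `<R> ~ r_c P^(-1/3)`.

## Redner–des Cloizeaux family

For polymers with excluded volume the chi form generalises to

```
f(r) = delta b^(3+g) / Gamma((3+g)/delta) * r^(2+g) exp(-(b r)^delta)
```

with `b` fixed by the mean. `(g, delta) = (0, 2)` reproduces the chi
family exactly (tested to 1e-10); chromatin-appropriate values are
`(g, delta) = (1, 5/4)`; `delta = 1/(1 - nu)` for a Flory exponent
`nu`. The CDF is an incomplete gamma function, so `rdc_cdf()` and
`rdc_quantile()` delegate to `stats::pgamma()`/`qgamma()` rather than
quadrature.

## Two-population mixtures and the paradox

If a fraction `eta` of cells has mean distance `R1` (looped/compact)
and `1 - eta` has `R2` (unlooped/extended), then

```
<R>_mix = eta R1 + (1 - eta) R2
P_mix   = eta P(R1) + (1 - eta) P(R2)
```

`P` is convex and sharply decreasing in the mean, so `P_mix` is
dominated by the compact subpopulation while `<R>_mix` is dominated by
the extended one. `paradox_grid()` + `find_paradox_pairs()` scan a grid
of `(R1, R2)` cells for pairs where both `P` and `<R>` increase
together; at `eta = 0` the scan provably finds none.

# Estimators and fitting

## Mixture fits

`fit_mixture()` minimises the sum of squared differences between the
model mixture CDF and the empirical CDF (`i/n` at the sorted
distances), over `(eta, log R1, log R2)` with `stats::optim()`
(L-BFGS-B). Multistart is deterministic, not random: a grid of `eta`
starts crossed with ECDF-quantile guesses for `R1`/`R2`, plus a
single-population start. Fits are canonicalised to `R1 <= R2` by
swapping and `eta -> 1 - eta`. Goodness of fit is the
Kolmogorov–Smirnov statistic; for raw samples the two-sided sup over
step jumps is used, for supplied CDF curves the plain sup norm.

## Continuous spectra

`deconvolve_spectrum()` solves the Fredholm problem `K w = y` (columns
of `K` are family CDFs at candidate mean distances `R_grid`, `y` is
the empirical CDF) by nonnegative Tikhonov least squares:

```
min_w ||K w - y||^2 + alpha^2 ||w||^2,  w >= 0
```

implemented as `pracma::lsqnonneg()` on the stacked system
`rbind(K, alpha I)`. Weights are normalised to sum to one. Summaries
are the spectrum mean, sd, coefficient of variation, and a peak count
(local maxima at least 5% of the global maximum; plateaus count once).

Defaults: `alpha = 1e-2` (visible smoothing without biasing two-spike
recovery; `scan_alpha()` explores the trade-off), `n_grid = 100`
log-spaced candidate means spanning half the smallest to twice the
largest observed distance, and an identifiability floor requiring at
least `n_grid / 4` data points.

# The simulator

Langevin dynamics `m r'' = -grad U - xi r' + noise` is integrated with
the BAOAB splitting (unit mass), implemented in C++ via Rcpp. The
Ornstein–Uhlenbeck half-step uses `c1 = exp(-xi dt)` and
`c2 = sqrt((1 - c1^2) kT)` with a `std::mt19937_64` generator seeded
explicitly, so trajectories are bit-identical across runs for a given
seed and independent of R's RNG state. Non-finite coordinates abort
with a "blow-up" diagnostic rather than propagating silently.

Choices and defaults:

- `dt = 0.01 / sqrt(kappa)`: the stiffest normal-mode frequency is
  `O(sqrt(kappa))`, so this keeps the fastest mode well resolved.
- `xi = 0.1`, `kT = 1` by default; kinetic temperature is accumulated
  and reported so equipartition can be asserted.
- Rest lengths are zero by default (the pure GRMC); `rest_length_mode
  = "a"` gives finite rest lengths for mechanical-equilibrium tests.
- `simulate_pair_stats()` streams per-pair contact counts, `sum r` and
  `sum r^2` inside the C++ loop at each saved frame, so memory does
  not grow with trajectory length; per-trajectory means give standard
  errors across independent seeds (`seed, seed+1, ...`).

For the desk-scale theory-vs-simulation experiment shipped in the test
suite (`N = 200`, 10 random loops) the package's own simulation units
use `kappa = omega = 1 kT/a^2` and `r_c = 2a`. With stiffness 1 the
pair scales `sigma^2 <= N kT / kappa` span contact probabilities from
order 1 down to below `1e-3` on a 200-monomer chain, which stiffer
chains cannot reach at this size; this is a choice of reduced units,
not a change of model. Burn-in (2e5 steps) is about five relaxation
times of the slowest Rouse mode (`tau ~ xi N^2 / (kappa pi^2)`), and
production (8e5 steps x 10 trajectories) about 20 `tau` each.

# Numerical choices

- **Contact kernel.** `P(x) = erf(x) - (2/sqrt(pi)) x exp(-x^2)`
  suffers catastrophic cancellation for small `x`; below `x = 0.05`
  the alternating series `(2/sqrt(pi)) sum (-1)^(n+1) 2n x^(2n+1) /
  (n! (2n+1))` is used instead, giving full precision down to
  `P ~ 1e-18`. `erf` is computed from `stats::pnorm`.
- **Inversion.** `invert_contact_to_mean()` brackets the root in
  `[1e-3 r_c, 10 r_c P^(-1/3)]` (the asymptote guarantees the upper
  end for small `P`), widens defensively if needed, and calls
  `stats::uniroot()` with `tol = 1e-12`. Monotonicity of `P` in the
  mean makes the root unique.
- **Empirical CDF convention.** Raw samples use `i/n` at sorted
  values; readers also accept pre-tabulated `(r, cdf)` curves, flagged
  internally so the KS statistic uses the right sup norm.
- **Units.** Lengths are unit-agnostic; `distance_um` column names
  follow the FISH convention of micrometres but nothing in the code
  assumes it. Capture radii of 0.01 and 0.02 um both appear in the
  literature for the same data; functions take `r_c` explicitly
  everywhere rather than fixing one.
- **Hi-C comparison.** Counts and model probabilities are compared on
  the scale-free `P_i / mean(P)` (relative contact frequency), since
  sequencing depth and `r_c` set unknown overall scales.

# Assumptions and limitations

- Harmonic (Gaussian) chain: no excluded volume in the simulator;
  excluded-volume statistics enter only through the Redner–des
  Cloizeaux family used for fitting.
- Quenched loops: anchors are fixed within a subpopulation; dynamic
  loop extrusion is modelled only as population heterogeneity.
- The two-population fit is identifiable only when the subpopulations
  are separated; near-degenerate fits are flagged (`degenerate`) and
  canonicalised towards a single population rather than reported as
  spurious splits.
- Deconvolution is a regularised ill-posed inverse: peak counts and
  CVs are stable, individual weights are not; treat `tidy(spectrum)`
  as a smoothed density, not a point estimate.
- Measurement noise in FISH (localisation error, chromatic offsets) is
  available in the generator (`noise` argument) but is not deconvolved
  from real data by the fitters.
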