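# reference computations: explicit scheme, closed forms, conversions,
# fine-grid transient solver

test_that("the explicit scheme handles boundaries and degenerate cases", {
  p0 <- gradient_params(n = 6, J0 = 0, source_on = FALSE)
  expect_equal(explicit_step(numeric(6), p0), numeric(6))
  # constant profile, no degradation, no influx: discrete Laplacian of a
  # constant vanishes and both boundaries are zero-flux
  pk0 <- gradient_params(n = 6, k = 0, J0 = 0, source_on = FALSE)
  expect_equal(explicit_step(rep(7.5, 6), pk0), rep(7.5, 6))
  # D = 0: pure exponential decay per cell
  pD0 <- gradient_params(n = 6, D = 0, J0 = 0, source_on = FALSE)
  s <- c(10, 5, 2, 1, 0.5, 0)
  expect_equal(explicit_step(s, pD0), (1 - pD0$k * pD0$dt) * s)
  # influx and degradation off: total mass is conserved exactly
  set.seed(1)
  s <- runif(6, 0, 100)
  expect_equal(sum(explicit_step(s, pk0)), sum(s))
})

test_that("the phase oracle reproduces hand-computed cycles", {
  w <- structure(list(w_fill = 100, w_move_cost = 676, w_deg_fill = 0,
                      w_deg_cost = 1e5, w_source = 0),
                 class = "scaled_weights")
  r <- phase_oracle_cycle(c(676, 0), w, source_on = FALSE)
  expect_equal(r$trace$alpha, 67600)
  expect_equal(r$trace$beta, 100)
  expect_equal(r$state, c(576, 100))

  z <- phase_oracle_cycle(c(0, 0), w, source_on = FALSE)
  expect_equal(z$state, c(0, 0))
  expect_equal(z$trace$beta, 0)

  expect_warning(phase_oracle_cycle(c(10, 50), w, source_on = FALSE),
                 "non-monotone")
})

test_that("closed-form steady states have the expected shape", {
  p <- gradient_params(J0 = 1)   # Dpp kinetics, unit influx
  mu <- sqrt(p$k / p$D)
  expect_equal(steady_state_infinite(0, p), 1 / sqrt(2.52e-5))
  r <- seq(0, 70, by = 5)
  v <- steady_state_infinite(r, p)
  expect_true(all(diff(v) < 0))
  # value halves every ln(2)/mu ~ 13.8 um
  half <- log(2) / mu
  expect_equal(steady_state_infinite(r + half, p) / v, rep(0.5, length(r)))

  # finite-domain form: larger at the source, zero flux at r = L
  expect_gt(steady_state_finite(0, p), steady_state_infinite(0, p))
  L <- p$n * p$ell
  eps <- 1e-6
  slope <- (steady_state_finite(L + eps, p) -
            steady_state_finite(L - eps, p)) / (2 * eps)
  expect_lt(abs(slope), 1e-6 * mu * steady_state_finite(L, p))
  # as L grows the correction factor tends to 1
  pbig <- gradient_params(n = 400, J0 = 1)
  expect_equal(steady_state_finite(30, pbig), steady_state_infinite(30, pbig),
               tolerance = 1e-12)
  expect_error(steady_state_infinite(0, gradient_params(D = 0, J0 = 1)),
               "requires D > 0")
})

test_that("densities convert to counts by the trapezoid rule", {
  p <- gradient_params(n = 4)
  grid <- seq(0, 4 * 2.6, length.out = 200)
  expect_equal(
    counts_from_density(list(grid = grid, values = rep(100, 200)), p),
    rep(676, 4))
  expect_equal(
    counts_from_density(list(grid = grid, values = numeric(200)), p),
    rep(0, 4))
  # trapezoid is exact on linear densities: N_k = h*a*ell^2*(2k-1)/2
  a <- 3
  expect_equal(
    counts_from_density(list(grid = grid, values = a * grid), p),
    p$h * a * p$ell^2 * (2 * (1:4) - 1) / 2)
  expect_error(
    counts_from_density(list(grid = grid[grid < 8], values = rep(1, sum(grid < 8))), p),
    "does not cover")
})

test_that("the transient solver converges to the closed-form steady state", {
  p <- gradient_params(J0 = 10)
  f0 <- solve_transient(p, 0)
  expect_true(all(f0$values == 0))
  # long integration approaches the finite-domain steady state per cell
  f <- solve_transient(p, 6e4, refine = 3)
  Nt <- counts_from_density(f, p)
  edges <- (0:p$n) * p$ell
  Nss <- counts_from_density(
    list(grid = edges, values = steady_state_finite(edges, p)), p)
  expect_lt(max(abs(Nt - Nss) / Nss) * 100, 0.1)
})

test_that("grid refinement is converged at the default resolution", {
  p <- gradient_params(J0 = 10)
  N16 <- counts_from_density(solve_transient(p, 600, refine = 16), p)
  N32 <- counts_from_density(solve_transient(p, 600, refine = 32), p)
  # scale-relative change; per-cell relative change where the profile is
  # not super-exponentially small (front tail, see vignette)
  expect_lt(max(abs(N32 - N16)) / max(N32) * 100, 0.05)
  keep <- N32 >= 1e-3 * max(N32)
  expect_lt(max(abs(N32[keep] - N16[keep]) / N32[keep]) * 100, 0.05)
})

test_that("the solver matches the analytic half-line transient solution", {
  # C(x,t) for influx at x = 0 with first-order decay on a half line;
  # at these times the front is far from L, so the finite domain and the
  # half line agree to well below the asserted tolerance
  p <- gradient_params(J0 = 10)
  erfc <- function(z) 2 * stats::pnorm(-z * sqrt(2))
  analytic <- function(x, t) {
    mu <- sqrt(p$k / p$D)
    (p$J0 / (2 * sqrt(p$k * p$D))) *
      (exp(-mu * x) * erfc(x / (2 * sqrt(p$D * t)) - sqrt(p$k * t)) -
       exp( mu * x) * erfc(x / (2 * sqrt(p$D * t)) + sqrt(p$k * t)))
  }
  for (t_end in c(600, 2400)) {
    f <- solve_transient(p, t_end, refine = 16)
    for (x in c(0, 2.6, 13, 26, 39)) {
      i <- which.min(abs(f$grid - x))
      expect_equal(f$values[i], analytic(x, t_end), tolerance = 1e-3)
    }
  }
})
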