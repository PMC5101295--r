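#' One explicit finite-difference step of the discretised model
#'
#' Advances the per-cell molecule counts by one time step `dt` of the
#' real-valued explicit scheme obtained by discretising the
#' reaction-diffusion equation on the cell grid:
#' interior `dm_i = (D*dt/ell^2) * (m_{i-1} - 2 m_i + m_{i+1}) - k*dt*m_i`,
#' first cell with influx `J0*h*dt` (when `source_on`), last cell with a
#' zero-flux boundary.
#'
#' @param state numeric vector of `n` cell counts (real-valued).
#' @param params a [gradient_params()] object.
#' @return the counts after one step of length `dt`.
#' @export
explicit_step <- function(state, params) {
  stopifnot(inherits(params, "gradient_params"))
  n <- params$n
  if (length(state) != n) stop("state must have one count per cell")
  a <- params$D * params$dt / params$ell^2
  kdt <- params$k * params$dt
  influx <- if (params$source_on) params$J0 * params$h * params$dt else 0
  new <- state
  new[1] <- state[1] + influx - a * (state[1] - state[2]) - kdt * state[1]
  if (n > 2) {
    i <- 2:(n - 1)
    new[i] <- state[i] + a * (state[i - 1] - 2 * state[i] + state[i + 1]) -
      kdt * state[i]
  }
  new[n] <- state[n] + a * (state[n - 1] - state[n]) - kdt * state[n]
  new
}

#' Phase-faithful integer oracle for one 5-step cycle
#'
#' Replays the net's cycle as a direct integer recurrence: (1) counters
#' `a_i = w_fill * m_i` from the pre-cycle counts and the source adds
#' `w_source` to cell 1; (2) `alpha_i = w_fill * (m_i - m_{i+1})`
#' (clamped at 0 with a warning when the profile is non-monotone, exactly
#' as the net leaves an `x''` residue instead of a negative counter);
#' (3) `beta_i = floor(alpha_i / w_move_cost)` tokens move `i -> i+1`;
#' (4) `rho_i = w_deg_fill * m_i` on the post-transport counts;
#' (5) `delta_i = floor(rho_i / w_deg_cost)` tokens are removed.
#'
#' The cycle-boundary markings of [build_gradient_net()] under the
#' maximally concurrent step semantics coincide exactly with iterates of
#' this recurrence; the equality is the central correctness oracle of the
#' package and is asserted in the test suite.
#'
#' @param state integer vector of `n` cell counts.
#' @param weights a [scaled_weights()] object.
#' @param source_on logical; add `w_source` to cell 1?
#' @return list with `state` (counts after the cycle) and `trace` (list
#'   `alpha`, `beta`, `delta`, `source_in`).
#' @export
phase_oracle_cycle <- function(state, weights, source_on = TRUE) {
  stopifnot(inherits(weights, "scaled_weights"))
  .check_counts(state, "cell counts")
  n <- length(state)
  m <- as.numeric(state)
  diffs <- m[1:(n - 1)] - m[2:n]
  if (any(diffs < 0))
    warning("non-monotone profile: negative counter differences clamped to 0")
  alpha <- weights$w_fill * pmax(diffs, 0)
  source_in <- if (source_on) weights$w_source else 0
  m[1] <- m[1] + source_in
  beta <- pmin(floor(alpha / weights$w_move_cost), m[1:(n - 1)])
  m[1:(n - 1)] <- m[1:(n - 1)] - beta
  m[2:n] <- m[2:n] + beta
  delta <- pmin(floor(weights$w_deg_fill * m / weights$w_deg_cost), m)
  m <- m - delta
  list(state = m,
       trace = list(alpha = alpha, beta = beta, delta = delta,
                    source_in = source_in))
}

#' Closed-form steady state on an infinite domain
#'
#' `C*(r) = J0 / sqrt(k*D) * exp(-mu*r)` with decay rate
#' `mu = sqrt(k/D)`: the balance of influx, diffusion and first-order
#' degradation on a half line.
#'
#' @param r position(s) in um.
#' @param params a [gradient_params()] object with `D > 0`, `k > 0`.
#' @return areal density (molecules/um^2) at `r`.
#' @export
steady_state_infinite <- function(r, params) {
  stopifnot(inherits(params, "gradient_params"))
  if (params$D <= 0 || params$k <= 0)
    stop("the closed-form steady state requires D > 0 and k > 0")
  mu <- sqrt(params$k / params$D)
  params$J0 / sqrt(params$k * params$D) * exp(-mu * r)
}

#' Closed-form steady state on the finite domain
#'
#' The infinite-domain profile times the finite-domain correction
#' `(1 + exp(2*mu*(r - L))) / (1 - exp(-2*mu*L))`, which enforces zero
#' flux at `r = L = n*ell` while keeping the influx condition at `r = 0`.
#'
#' @inheritParams steady_state_infinite
#' @return areal density (molecules/um^2) at `r`.
#' @export
steady_state_finite <- function(r, params) {
  stopifnot(inherits(params, "gradient_params"))
  if (params$D <= 0 || params$k <= 0)
    stop("the closed-form steady state requires D > 0 and k > 0")
  mu <- sqrt(params$k / params$D)
  L <- params$n * params$ell
  steady_state_infinite(r, params) *
    (1 + exp(2 * mu * (r - L))) / (1 - exp(-2 * mu * L))
}

#' Convert an areal density field to per-cell molecule counts
#'
#' `N_i = h * integral over [(i-1)*ell, i*ell] of C(r) dr`, approximated
#' by the basic trapezoidal rule at the cell edges:
#' `N_i ~= ell*h*(C((i-1)*ell) + C(i*ell))/2`.  Edge values are linearly
#' interpolated when the grid does not contain them.
#'
#' @param field a `density_field` (see [solve_transient()]) or a list
#'   with elements `grid` and `values`.
#' @param params a [gradient_params()] object.
#' @return numeric vector of `n` (real-valued) molecule counts.
#' @export
counts_from_density <- function(field, params) {
  stopifnot(inherits(params, "gradient_params"))
  grid <- field$grid; values <- field$values
  if (is.unsorted(grid, strictly = TRUE))
    stop("density grid must be strictly increasing")
  n <- params$n
  edges <- (0:n) * params$ell
  eps <- 1e-9 * params$ell
  if (min(grid) > edges[1] + eps || max(grid) < edges[n + 1] - eps)
    stop("density field does not cover the tissue [0, n*ell]")
  Ce <- stats::approx(grid, values, xout = edges, rule = 2)$y
  params$ell * params$h * (Ce[1:n] + Ce[2:(n + 1)]) / 2
}

#' Fine-grid transient reference solution
#'
#' Solves the reaction-diffusion equation with influx/zero-flux boundary
#' conditions by an explicit finite-difference scheme on a grid `refine`
#' times finer than the cell grid, with second-order ghost-node boundary
#' treatment and a time step at 20% of the diffusive stability limit.
#' Serves as the time-dependent reference that the Petri net's markings
#' are compared against.  At the case-study parameters the solver
#' matches the analytic half-line transient solution and converges to
#' [steady_state_finite()] for large `t_end` (both asserted in the test
#' suite).
#'
#' Convergence note: halving the grid spacing changes the per-cell counts
#' by well under 0.05% of the profile maximum; per-cell *relative* changes
#' are only meaningful where the solution is not super-exponentially
#' small (the advancing front tail), see the package vignette.
#'
#' @param params a [gradient_params()] object.
#' @param t_end end time (s).
#' @param refine grid refinement factor (cells per `ell`), >= 2.
#' @param profile optional initial density function `C(r, 0)`.
#' @return an object of class `density_field`: list with `grid`,
#'   `values`, `time`.
#' @export
solve_transient <- function(params, t_end, refine = 16, profile = NULL) {
  stopifnot(inherits(params, "gradient_params"))
  if (t_end < 0) stop("t_end must be >= 0")
  if (refine < 2 || refine != floor(refine)) stop("refine must be an integer >= 2")
  n <- params$n; D <- params$D; k <- params$k
  J0 <- if (params$source_on) params$J0 else 0
  hf <- params$ell / refine
  N <- n * refine
  grid <- (0:N) * hf
  C <- if (is.function(profile)) pmax(profile(grid), 0) else numeric(N + 1)
  if (t_end > 0) {
    dtf <- min(if (D > 0) 0.2 * hf^2 / D else Inf,
               if (k > 0) 0.1 / k else Inf, t_end)
    nst <- ceiling(t_end / dtf)
    dtf <- t_end / nst
    lam <- D * dtf / hf^2
    if (lam > 0.5) stop("internal stability failure in solve_transient")
    ghostL <- 2 * hf * J0 / max(D, .Machine$double.eps)
    for (s in seq_len(nst)) {
      Cm <- c(C[2] + ghostL, C[1:N])
      Cp <- c(C[2:(N + 1)], C[N])
      C <- C + lam * (Cm - 2 * C + Cp) - k * dtf * C
    }
  }
  structure(list(grid = grid, values = C, time = t_end),
            class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  cat(sprintf("density field on [0, %g] um (%d nodes) at t = %g s\n",
              max(x$grid), length(x$grid), x$time))
  invisible(x)
}

#' Export a density field or cell-state vector to CSV
#'
#' @param x a `density_field` or a numeric vector of cell counts.
#' @param path output path.
#' @param time time stamp column value for a plain vector.
#' @return invisibly, `path`.
#' @export
write_profile <- function(x, path, time = NA_real_) {
  df <- if (inherits(x, "density_field")) {
    data.frame(position = x$grid, value = x$values, time = x$time)
  } else {
    data.frame(cell = seq_along(x), value = as.numeric(x), time = time)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
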