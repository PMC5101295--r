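#' Parameters of the gradient-formation model
#'
#' Collects the constants of the one-dimensional reaction-diffusion model
#' `dC/dt = D d2C/dr2 - k C` on `(0, n*ell)` with constant influx areal
#' density `J0` at `r = 0` and zero flux at `r = n*ell`, together with the
#' discretisation and accuracy constants used to derive integer arc
#' weights for the Petri net.
#'
#' The explicit discretisation is valid when `D*dt/ell^2 < 1` and
#' `k*dt < 1`; the constructor rejects parameter sets violating either
#' bound.
#'
#' Defaults reproduce the Dpp wing-disc case study: 30 cells of
#' 2.6 um x 2.6 um, `D = 0.10` um^2/s, `k = 2.52e-4` 1/s, accuracy
#' scalers `p = 100` and `b = 1e5`, time step 10 s.  The influx scale
#' `J0` only sets the token resolution (all reported deviations are
#' relative); the default 1e4 molecules/(um s) makes single-token
#' quantisation effects smaller than 0.05% at every cell of the
#' steady-state profile.
#'
#' @param n number of cells (>= 2).
#' @param D effective diffusion coefficient (um^2/s).
#' @param k degradation rate (1/s).
#' @param J0 influx areal density (molecules/(um s)); `J0*h*dt` tokens
#'   enter cell 1 per cycle.
#' @param ell cell length (um).
#' @param h cell height (um).
#' @param dt time step per 5-step cycle (s).
#' @param p transport accuracy scaler (natural number >= 1).
#' @param b degradation accuracy scaler (natural number >= 1).
#' @param source_on logical; is the source place `f` marked?
#' @return an object of class `gradient_params`.
#' @examples
#' gradient_params()                        # Dpp defaults
#' gradient_params(D = 0.06, k = 1.53e-4)   # Dpp-rescue
#' @export
gradient_params <- function(n = 30, D = 0.10, k = 2.52e-4, J0 = 1e4,
                            ell = 2.6, h = 2.6, dt = 10, p = 100, b = 1e5,
                            source_on = TRUE) {
  if (n < 2 || n != floor(n)) stop("n must be an integer >= 2")
  if (D < 0 || k < 0 || J0 < 0) stop("D, k and J0 must be non-negative")
  if (ell <= 0 || h <= 0 || dt <= 0) stop("ell, h and dt must be positive")
  if (p < 1 || p != floor(p) || b < 1 || b != floor(b))
    stop("p and b must be natural numbers >= 1")
  if (D * dt / ell^2 >= 1)
    stop("stability violated: D*dt/ell^2 = ", signif(D * dt / ell^2, 4),
         " must be < 1")
  if (k * dt >= 1)
    stop("stability violated: k*dt = ", signif(k * dt, 4), " must be < 1")
  structure(list(n = as.integer(n), D = D, k = k, J0 = J0, ell = ell,
                 h = h, dt = dt, p = p, b = b,
                 source_on = isTRUE(source_on), steps_per_cycle = 5L),
            class = "gradient_params")
}

#' @export
print.gradient_params <- function(x, ...) {
  cat("gradient model parameters\n")
  cat(sprintf("  cells:       n = %d, ell = %g um, h = %g um (L = %g um)\n",
              x$n, x$ell, x$h, x$n * x$ell))
  cat(sprintf("  kinetics:    D = %g um^2/s, k = %g 1/s (decay length %.2f um)\n",
              x$D, x$k, if (x$k > 0 && x$D > 0) sqrt(x$D / x$k) else NA))
  cat(sprintf("  source:      J0 = %g molecules/(um s), %s\n",
              x$J0, if (x$source_on) "on" else "off"))
  cat(sprintf("  discretised: dt = %g s, p = %g, b = %g\n", x$dt, x$p, x$b))
  cat(sprintf("  stability:   D*dt/ell^2 = %.4f, k*dt = %.4g\n",
              x$D * x$dt / x$ell^2, x$k * x$dt))
  invisible(x)
}

#' Integer arc weights derived from the model parameters
#'
#' The five composite quantities that enter the net as arc weights:
#' \describe{
#'   \item{w_fill}{tokens added to each counter place per occurrence of a
#'     fill transition `c_i`: `round(p*D*dt)`.}
#'   \item{w_move_cost}{counter tokens consumed per transport firing:
#'     `round(p*ell^2)`; one morphogen token moves per `w_move_cost`
#'     counter tokens.}
#'   \item{w_deg_fill}{tokens added to the degradation counter `r_i` per
#'     occurrence of `g_i`: `round(b*k*dt)`.}
#'   \item{w_deg_cost}{degradation counter tokens consumed per removed
#'     morphogen token: `b`.}
#'   \item{w_source}{tokens emitted into cell 1 per cycle while the
#'     source is on: `round(J0*h*dt)`.}
#' }
#' The scalers `p` and `b` control how much accuracy survives the
#' rounding to natural numbers; a warning is emitted when rounding
#' collapses a positive rate to zero.
#'
#' @param params a `gradient_params` object.
#' @return an object of class `scaled_weights`.
#' @examples
#' scaled_weights(gradient_params(J0 = 10))
#' @export
scaled_weights <- function(params) {
  stopifnot(inherits(params, "gradient_params"))
  w <- list(
    w_fill = round(params$p * params$D * params$dt),
    w_move_cost = round(params$p * params$ell^2),
    w_deg_fill = round(params$b * params$k * params$dt),
    w_deg_cost = params$b,
    w_source = round(params$J0 * params$h * params$dt))
  if (w$w_fill == 0 && params$D > 0)
    warning("round(p*D*dt) = 0 although D > 0: transport is lost; increase p")
  if (w$w_deg_fill == 0 && params$k > 0)
    warning("round(b*k*dt) = 0 although k > 0: degradation is lost; increase b")
  if (w$w_move_cost < 1)
    stop("round(p*ell^2) must be >= 1")
  structure(w, class = "scaled_weights")
}

#' @export
print.scaled_weights <- function(x, ...) {
  cat("integer arc weights:\n")
  cat(sprintf("  w_fill      = %g   (counter tokens per cell token, p*D*dt)\n",
              x$w_fill))
  cat(sprintf("  w_move_cost = %g   (counter tokens per transported token, p*ell^2)\n",
              x$w_move_cost))
  cat(sprintf("  w_deg_fill  = %g   (degradation counter fill, b*k*dt)\n",
              x$w_deg_fill))
  cat(sprintf("  w_deg_cost  = %g   (counter tokens per degraded token, b)\n",
              x$w_deg_cost))
  cat(sprintf("  w_source    = %g   (tokens per cycle from the source, J0*h*dt)\n",
              x$w_source))
  invisible(x)
}
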