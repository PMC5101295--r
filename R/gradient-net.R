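#' @keywords internal
# identifier scheme of the gradient net; zero-padded so that sorted
# identifier order equals spatial order
.grad_ids <- function(n) {
  wd <- nchar(as.character(n))
  num <- function(prefix, i) sprintf("%s%0*d", prefix, wd, i)
  list(
    x   = num("x", 1:n),            # cells (the only biological places)
    xp  = num("xp", 1:(n - 1)),     # transport counters x'_i
    xpp = num("xpp", 2:n),          # transport counters x''_i
    r   = num("r", 1:n),            # degradation counters
    w   = paste0("w", 1:5),         # phase places
    f   = "f",                      # source switch
    s   = "s",
    cc  = num("c", 1:n),
    ep  = num("ep", 1:(n - 1)),     # e'_i  (clear x'_i residue)
    epp = num("epp", 2:n),          # e''_i (clear x''_i residue)
    d   = num("d", 1:(n - 1)),
    tp  = num("tp", 1:(n - 1)),     # t'_i  (transport)
    g   = num("g", 1:n),
    q   = num("q", 1:n),
    gp  = num("gp", 1:n),           # g'_i  (degradation)
    u   = paste0("u", 1:5))         # phase-ring movers
}

#' Build the gradient-formation PTA-net
#'
#' Constructs the complete net: a chain of cell places `x_1..x_n` holding
#' morphogen tokens, auxiliary counter places (`x'_i`, `x''_i`, `r_i`),
#' a source place `f` feeding transition `s`, and a 5-place control ring
#' `w1..w5` whose single token schedules the phases via activator arcs:
#'
#' 1. counters are filled (`c_i`, auto-concurrency capped at `m(x_i)` by a
#'    self-loop), residues cleared (`e'_i`, `e''_i`), source fires (`s`);
#' 2. `d_i` subtracts neighbouring counters, leaving
#'    `alpha_i = w_fill*(m(x_i) - m(x_{i+1}))` in `x'_i`;
#' 3. `t'_i` transports one token `x_i -> x_{i+1}` per `w_move_cost`
#'    counter tokens, i.e. `floor(alpha_i / w_move_cost)` tokens;
#' 4. `g_i` fills the degradation counter `r_i` with `w_deg_fill` per cell
#'    token, `q_i` clears the residue of the previous cycle;
#' 5. `g'_i` removes one token from `x_i` per `w_deg_cost` tokens in `r_i`.
#'
#' The net is conflict-free by construction: every consuming transition
#' is gated to a single phase and no two transitions of a phase compete
#' for tokens, so the maximally concurrent step is unique at every
#' reachable marking and the token game is fully deterministic.
#'
#' @param params a [gradient_params()] object.
#' @param profile initial cell contents passed to [initial_marking()]:
#'   `NULL` (empty), a density function `C(r)` or a vector of counts.
#' @return an object of class `gradient_net`.
#' @examples
#' gnet <- build_gradient_net(gradient_params(n = 5, J0 = 10))
#' gnet
#' @export
build_gradient_net <- function(params, profile = NULL) {
  stopifnot(inherits(params, "gradient_params"))
  n <- params$n
  w <- scaled_weights(params)
  id <- .grad_ids(n)

  arc <- function(from, to, weight) {
    keep <- weight > 0
    data.frame(from = from[keep], to = to[keep], weight = weight[keep])
  }
  one <- function(k) rep(1, k)
  arcs <- rbind(
    # phase ring: the control token moves w^j -> w^{j+1}
    arc(id$w, id$u, one(5)),
    arc(id$u, id$w[c(2:5, 1)], one(5)),
    # phase 1: counter fill via self-loops, residue clearing, source
    arc(id$x, id$cc, one(n)), arc(id$cc, id$x, one(n)),
    arc(id$cc[1:(n - 1)], id$xp, rep(w$w_fill, n - 1)),
    arc(id$cc[2:n], id$xpp, rep(w$w_fill, n - 1)),
    arc(id$xp, id$ep, one(n - 1)),
    arc(id$xpp, id$epp, one(n - 1)),
    arc(id$f, id$s, 1), arc(id$s, id$f, 1),
    arc(id$s, id$x[1], w$w_source),
    # phase 2: subtract neighbouring counters
    arc(id$xp, id$d, one(n - 1)),
    arc(id$xpp, id$d, one(n - 1)),
    # phase 3: transport
    arc(id$xp, id$tp, rep(w$w_move_cost, n - 1)),
    arc(id$x[1:(n - 1)], id$tp, one(n - 1)),
    arc(id$tp, id$x[2:n], one(n - 1)),
    # phase 4: degradation counter fill + residue clearing
    arc(id$x, id$g, one(n)), arc(id$g, id$x, one(n)),
    arc(id$g, id$r, rep(w$w_deg_fill, n)),
    arc(id$r, id$q, one(n)),
    # phase 5: degradation
    arc(id$r, id$gp, rep(w$w_deg_cost, n)),
    arc(id$x, id$gp, one(n)))

  phase_of <- c(rep(1, n), rep(1, n - 1), rep(1, n - 1), 1,
                rep(2, n - 1), rep(3, n - 1), rep(4, n), rep(4, n), rep(5, n))
  gated <- c(id$cc, id$ep, id$epp, id$s, id$d, id$tp, id$g, id$q, id$gp)
  activators <- data.frame(place = id$w[phase_of], transition = gated)

  m0 <- initial_marking(params, profile)
  net <- pta_net(
    places = c(id$x, id$xp, id$xpp, id$r, id$w, id$f),
    transitions = c(id$s, id$cc, id$ep, id$epp, id$d, id$tp, id$g, id$q,
                    id$gp, id$u),
    arcs = arcs, activators = activators, m0 = m0[m0 > 0])

  structure(list(net = net, params = params, weights = w,
                 cell_places = id$x, phase_places = id$w,
                 source_place = id$f,
                 counter_places = list(xp = id$xp, xpp = id$xpp, r = id$r)),
            class = "gradient_net")
}

#' Initial marking of the gradient net
#'
#' Cell place `x_i` receives `round(ell*h * (C((i-1)*ell) + C(i*ell)) / 2)`
#' tokens when `profile` is a density function (trapezoid conversion of an
#' areal density to molecule counts), or the given counts when `profile`
#' is a vector of `n` non-negative integers.  The control ring starts in
#' phase 1 (`w1 = 1`), the source place `f` is marked iff `source_on`,
#' and all counter places are empty.
#'
#' @param params a [gradient_params()] object.
#' @param profile `NULL` for an empty tissue, a vectorised density
#'   function of `r` on `[0, n*ell]`, or a numeric vector of `n` counts.
#' @return a full named marking vector for the gradient net.
#' @export
initial_marking <- function(params, profile = NULL) {
  stopifnot(inherits(params, "gradient_params"))
  n <- params$n
  id <- .grad_ids(n)
  cells <- numeric(n)
  if (is.function(profile)) {
    edges <- (0:n) * params$ell
    C <- profile(edges)
    if (any(C < 0)) stop("initial density profile takes negative values")
    cells <- round(params$ell * params$h * (C[1:n] + C[2:(n + 1)]) / 2)
  } else if (!is.null(profile)) {
    if (length(profile) != n) stop("profile must have one count per cell")
    if (any(profile < 0)) stop("initial cell counts must be non-negative")
    .check_counts(profile, "initial cell counts")
    cells <- as.numeric(profile)
  }
  m0 <- stats::setNames(
    numeric(4 * n + 4),
    c(id$x, id$xp, id$xpp, id$r, id$w, id$f))
  m0[id$x] <- cells
  m0[id$w[1]] <- 1
  m0[id$f] <- as.numeric(params$source_on)
  m0
}

#' @export
print.gradient_net <- function(x, ...) {
  cat("gradient-formation PTA-net (", x$params$n, "cells )\n")
  print(x$net)
  print(x$weights)
  invisible(x)
}

#' @export
summary.gradient_net <- function(object, ...) {
  m0 <- object$net$m0
  cat("gradient-formation PTA-net\n")
  print(object$params)
  print(object$weights)
  cat("initial cell counts:",
      paste(m0[object$cell_places], collapse = " "), "\n")
  invisible(object)
}
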