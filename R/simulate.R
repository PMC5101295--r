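#' Simulate the gradient net
#'
#' Executes `5 * n_cycles` maximally concurrent steps of the gradient net
#' and records the cell-place counts at every cycle boundary (the
#' marking after phase 5, corresponding to times `t_j = j*dt`).  The net
#' is deterministic: identical parameters give bit-identical
#' trajectories.
#'
#' @param x a `gradient_net` (or a `gradient_params` object, from which a
#'   net is built).
#' @param n_cycles number of 5-step cycles to execute.
#' @param traces record per-cycle phase diagnostics (`alpha_i` counter
#'   differences, `beta_i` transport firings, `delta_i` degradation
#'   firings, `source_in`)?  Slower; intended for inspection and tests.
#' @param until_steady stop as soon as two consecutive cycle-boundary
#'   cell-count vectors are identical; `n_cycles` then acts as a cap.
#' @return an object of class `gradient_trajectory`: list with `cycle`
#'   (1..N), `time` (s), `counts` (N x n matrix), `initial` (cycle-0
#'   counts), `params`, and optionally `traces`.
#' @examples
#' traj <- simulate_gradient(gradient_params(n = 5, J0 = 10), n_cycles = 20)
#' traj
#' @export
simulate_gradient <- function(x, n_cycles, traces = FALSE,
                              until_steady = FALSE) {
  gnet <- if (inherits(x, "gradient_params")) build_gradient_net(x) else x
  stopifnot(inherits(gnet, "gradient_net"))
  if (n_cycles < 0) stop("n_cycles must be >= 0")
  net <- gnet$net
  n <- gnet$params$n
  ci <- match(gnet$cell_places, net$places)
  xpi <- match(gnet$counter_places$xp, net$places)
  tp_idx <- match(.grad_ids(n)$tp, net$transitions)
  gp_idx <- match(.grad_ids(n)$gp, net$transitions)
  s_idx <- match("s", net$transitions)

  m <- net$m0
  counts <- matrix(NA_real_, n_cycles, n)
  tr <- if (traces) vector("list", n_cycles) else NULL
  conflict <- FALSE
  executed <- 0L
  for (j in seq_len(n_cycles)) {
    alpha <- NULL
    beta <- delta <- src <- NULL
    empty <- FALSE
    for (ph in 1:5) {
      st <- .engine_step(net, m)
      if (st$empty) { empty <- TRUE; break }
      conflict <- conflict || st$conflict
      if (traces) {
        if (ph == 1) src <- st$u[s_idx] * gnet$weights$w_source
        if (ph == 2) alpha <- st$m[xpi]
        if (ph == 3) beta <- st$u[tp_idx]
        if (ph == 5) delta <- st$u[gp_idx]
      }
      m <- st$m
    }
    if (empty) break   # nothing enabled: trace ends before this cycle
    counts[j, ] <- m[ci]
    executed <- j
    if (traces)
      tr[[j]] <- list(alpha = alpha, beta = beta, delta = delta,
                      source_in = src)
    if (until_steady) {
      prev <- if (j == 1) net$m0[ci] else counts[j - 1, ]
      if (all(counts[j, ] == prev)) break
    }
  }
  if (conflict)
    stop("conflict flag raised on a gradient net: internal inconsistency")
  counts <- counts[seq_len(executed), , drop = FALSE]
  colnames(counts) <- gnet$cell_places
  structure(list(cycle = seq_len(executed),
                 time = seq_len(executed) * gnet$params$dt,
                 counts = counts,
                 initial = stats::setNames(net$m0[ci], gnet$cell_places),
                 params = gnet$params,
                 traces = if (traces) tr[seq_len(executed)] else NULL),
            class = "gradient_trajectory")
}

#' @rdname simulate_gradient
#' @param object a `gradient_net`.
#' @param nsim number of cycles (as `n_cycles`).
#' @param seed ignored; the net is fully deterministic.
#' @param ... passed on to [simulate_gradient()].
#' @export
simulate.gradient_net <- function(object, nsim = 1, seed = NULL, ...) {
  simulate_gradient(object, n_cycles = nsim, ...)
}

#' @export
print.gradient_trajectory <- function(x, ...) {
  n <- ncol(x$counts)
  cat(sprintf("gradient trajectory: %d cycles (t up to %g s), %d cells\n",
              length(x$cycle), max(c(0, x$time)), n))
  if (length(x$cycle)) {
    last <- x$counts[nrow(x$counts), ]
    cat("final counts:", paste(utils::head(last, 6), collapse = " "),
        if (n > 6) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.gradient_trajectory <- function(x, ...) {
  df <- data.frame(cycle = x$cycle, time_s = x$time)
  counts <- as.data.frame(x$counts)
  names(counts) <- paste0("cell_", seq_len(ncol(counts)))
  cbind(df, counts)
}

#' @export
plot.gradient_trajectory <- function(x, at = NULL, log = "", ...) {
  n <- ncol(x$counts)
  if (is.null(at)) at <- max(x$cycle)
  rows <- match(at, x$cycle)
  if (anyNA(rows)) stop("requested cycle(s) not in trajectory")
  ylim <- range(x$counts[rows, , drop = FALSE])
  if (log == "y") ylim[1] <- max(ylim[1], 0.5)
  graphics::matplot(seq_len(n), t(x$counts[rows, , drop = FALSE]),
                    type = "b", pch = 19, cex = 0.6, lty = 1,
                    xlab = "cell index", ylab = "molecules per cell",
                    log = log, ylim = ylim, ...)
  graphics::legend("topright", legend = paste0("t = ", x$time[rows], " s"),
                   col = seq_along(rows), lty = 1, pch = 19, bty = "n")
  invisible(x)
}

#' Detect the steady state of a trajectory
#'
#' The net has reached its steady state once the marking after two
#' consecutive step cycles is the same; because the net is deterministic
#' the marking then never changes again.  Returns the first cycle index
#' `j` whose cell counts equal those of cycle `j - 1` (cycle 0 being the
#' initial marking), or `NA` if the trajectory contains no such cycle.
#'
#' @param traj a `gradient_trajectory`.
#' @param tolerance non-negative integer: counts may differ by up to this
#'   many tokens per cell and still count as steady (0 = exact equality,
#'   the default; 1 tolerates single-token flicker).
#' @return integer cycle index or `NA`.
#' @export
detect_steady_state <- function(traj, tolerance = 0) {
  stopifnot(inherits(traj, "gradient_trajectory"))
  if (length(traj$cycle) == 0) stop("trajectory is empty")
  prev <- traj$initial
  for (j in seq_along(traj$cycle)) {
    if (max(abs(traj$counts[j, ] - prev)) <= tolerance) return(j)
    prev <- traj$counts[j, ]
  }
  NA_integer_
}

#' Relative deviation statistics between counts and a reference
#'
#' Per-cell relative deviation `|petri_i - ref_i| / ref_i * 100` (in %),
#' with the maximum and mean over all compared cells.  Cells with a zero
#' reference are excluded: silently when the simulated count is also
#' zero (both models agree on an empty cell), with a warning when it is
#' not (the deviation is undefined there).  `min_fraction` optionally
#' restricts the comparison to cells whose reference holds at least that
#' fraction of the reference maximum — the integer net is exactly zero
#' beyond its token front while a continuous reference is positive
#' everywhere, so unrestricted per-cell relative deviations saturate at
#' 100% in the far tail regardless of the token resolution.
#'
#' @param petri numeric vector of simulated cell counts.
#' @param reference numeric vector of reference counts (same length).
#' @param min_fraction keep cells with `reference >= min_fraction *
#'   max(reference)`; default 0 keeps every cell with a positive
#'   reference.
#' @return an object of class `deviation_report`: list with `per_cell`
#'   (NA for excluded cells), `max_dev`, `mean_dev`, `n_compared`,
#'   `excluded` (indices).
#' @examples
#' deviation_metrics(c(101, 50), c(100, 50))
#' @export
deviation_metrics <- function(petri, reference, min_fraction = 0) {
  if (length(petri) != length(reference))
    stop("petri and reference must have equal length")
  per_cell <- rep(NA_real_, length(petri))
  zero_ref <- reference <= 0
  if (any(zero_ref & petri > 0))
    warning(sum(zero_ref & petri > 0),
            " cell(s) with zero reference but non-zero counts excluded")
  keep <- !zero_ref & reference >= min_fraction * max(reference)
  per_cell[keep] <- abs(petri[keep] - reference[keep]) / reference[keep] * 100
  structure(list(per_cell = per_cell,
                 max_dev = if (any(keep)) max(per_cell[keep]) else NA_real_,
                 mean_dev = if (any(keep)) mean(per_cell[keep]) else NA_real_,
                 n_compared = sum(keep),
                 excluded = which(!keep)),
            class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf("relative deviation over %d cells: max %.4g%%, mean %.4g%%\n",
              x$n_compared, x$max_dev, x$mean_dev))
  if (length(x$excluded))
    cat("excluded cells:", paste(x$excluded, collapse = " "), "\n")
  invisible(x)
}
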