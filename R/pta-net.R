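#' Place/Transition nets with activator arcs
#'
#' A PTA-net is a tuple (P, T, W, Act, m0): finite disjoint sets of places
#' and transitions, a weight function on (P x T) u (T x P), a set of
#' activator arcs (place, transition), and an initial marking.  Activator
#' arcs test a place for at least one token *before* a step executes
#' (a-priori testing) without consuming it, in contrast to a self-loop,
#' which claims the token for the duration of the firing.
#'
#' Markings and steps are represented as named numeric vectors of
#' non-negative integers; names absent from a vector are read as zero, so
#' sparse vectors are accepted everywhere.
#'
#' @param places character vector of place identifiers.
#' @param transitions character vector of transition identifiers, disjoint
#'   from `places`.
#' @param arcs data frame with columns `from`, `to`, `weight` (positive
#'   integers).  Each row is a weighted arc; exactly one endpoint must be a
#'   place and the other a transition.  Pairs not listed have weight 0.
#' @param activators optional data frame with columns `place`,
#'   `transition`.
#' @param m0 initial marking: named numeric vector of non-negative
#'   integers over (a subset of) `places`.
#'
#' @return An object of class `pta_net`.
#' @examples
#' net <- pta_net(
#'   places = c("p", "q"), transitions = "t",
#'   arcs = data.frame(from = c("p", "t"), to = c("t", "q"), weight = c(2, 1)),
#'   m0 = c(p = 5)
#' )
#' maximal_step(net, marking(net))
#' @export
pta_net <- function(places, transitions, arcs, activators = NULL, m0 = NULL) {
  places <- as.character(places)
  transitions <- as.character(transitions)
  if (anyDuplicated(places) || anyDuplicated(transitions))
    stop("duplicate place or transition identifiers")
  if (length(intersect(places, transitions)) > 0L)
    stop("places and transitions must be disjoint")
  nP <- length(places); nT <- length(transitions)
  if (nT == 0L) stop("a PTA-net needs at least one transition")

  pre  <- matrix(0, nP, nT, dimnames = list(places, transitions))
  post <- matrix(0, nP, nT, dimnames = list(places, transitions))
  if (!is.null(arcs) && nrow(arcs) > 0L) {
    from <- as.character(arcs$from); to <- as.character(arcs$to)
    w <- as.numeric(arcs$weight)
    if (any(w < 0) || any(w != floor(w)))
      stop("arc weights must be natural numbers")
    for (i in seq_along(from)) {
      if (from[i] %in% places && to[i] %in% transitions) {
        pre[from[i], to[i]] <- pre[from[i], to[i]] + w[i]
      } else if (from[i] %in% transitions && to[i] %in% places) {
        post[to[i], from[i]] <- post[to[i], from[i]] + w[i]
      } else {
        stop("arc ", from[i], " -> ", to[i],
             " does not connect a place with a transition")
      }
    }
  }
  act <- matrix(FALSE, nP, nT, dimnames = list(places, transitions))
  if (!is.null(activators) && nrow(activators) > 0L) {
    ap <- as.character(activators$place); at <- as.character(activators$transition)
    if (!all(ap %in% places) || !all(at %in% transitions))
      stop("activator arc references unknown place or transition")
    act[cbind(ap, at)] <- TRUE
  }
  no_input <- colSums(pre) == 0
  if (any(no_input))
    stop("every transition needs at least one input place; violated by: ",
         paste(transitions[no_input], collapse = ", "))

  marking0 <- stats::setNames(numeric(nP), places)
  if (!is.null(m0)) {
    if (is.null(names(m0)) || !all(names(m0) %in% places))
      stop("initial marking names unknown place(s)")
    .check_counts(m0, "initial marking")
    marking0[names(m0)] <- m0
  }

  net <- structure(
    list(places = places, transitions = transitions,
         pre = pre, post = post, act = act, m0 = marking0),
    class = "pta_net")
  net$engine <- .compile_engine(net)
  net
}

#' @export
print.pta_net <- function(x, ...) {
  cat("PTA-net:", length(x$places), "places,", length(x$transitions),
      "transitions,", sum(x$pre > 0) + sum(x$post > 0), "arcs,",
      sum(x$act), "activator arcs\n")
  cat("initial marking:", sum(x$m0), "tokens in", sum(x$m0 > 0), "places\n")
  invisible(x)
}

#' Initial marking of a net as a full named vector
#' @param net a `pta_net`.
#' @return named numeric vector over all places.
#' @export
marking <- function(net) net$m0

.check_counts <- function(x, what) {
  if (any(is.na(x)) || any(x < 0) || any(x != floor(x)))
    stop(what, " must consist of non-negative integers")
  invisible(x)
}

# expand a sparse named vector to a full vector over `ids` (absent = 0)
.full_vec <- function(x, ids, what) {
  out <- stats::setNames(numeric(length(ids)), ids)
  if (length(x) == 0L) return(out)
  if (is.null(names(x))) {
    if (length(x) != length(ids))
      stop(what, " must be named or of full length")
    names(x) <- ids
  }
  unknown <- setdiff(names(x), ids)
  if (length(unknown) > 0L)
    stop("unknown ", what, " identifier(s): ", paste(unknown, collapse = ", "))
  .check_counts(x, what)
  out[names(x)] <- x
  out
}

# Precompute index tables so that the maximal step of a conflict-free net
# is a handful of vectorised operations.  in_idx/in_w are K x nT (K = max
# number of distinct input places of a transition), padded with index 1 /
# weight 0; a padded entry yields cap Inf and drops out of the pmin.
.compile_engine <- function(net) {
  nT <- length(net$transitions)
  in_list <- lapply(seq_len(nT), function(j) which(net$pre[, j] > 0))
  K <- max(lengths(in_list))
  in_idx <- matrix(1L, K, nT)
  in_w <- matrix(0, K, nT)
  for (j in seq_len(nT)) {
    ii <- in_list[[j]]
    in_idx[seq_along(ii), j] <- ii
    in_w[seq_along(ii), j] <- net$pre[ii, j]
  }
  act_list <- lapply(seq_len(nT), function(j) which(net$act[, j]))
  KA <- max(c(lengths(act_list), 0L))
  act_idx <- NULL
  if (KA > 0L) {
    act_idx <- matrix(NA_integer_, KA, nT)
    for (j in seq_len(nT)) {
      aa <- act_list[[j]]
      act_idx[seq_along(aa), j] <- aa
    }
  }
  # transition order used by the greedy fallback policy
  ord <- order(net$transitions)
  list(in_idx = in_idx, in_w = in_w, pad = in_w == 0, act_idx = act_idx,
       effect = net$post - net$pre, ord = ord)
}

#' Is a step enabled at a marking?
#'
#' A step (multiset of transitions) U is enabled at marking m when every
#' place holds enough tokens for the combined consumption of all
#' occurrences in U, and every place tested by an activator arc of an
#' occurring transition holds at least one token.  Both conditions are
#' evaluated on the pre-step marking only (a-priori semantics); tokens
#' produced by the step itself never help enable it.
#'
#' @param net a `pta_net`.
#' @param m marking (named numeric vector; absent places read as 0).
#' @param u step: named numeric vector of transition multiplicities.
#' @return `TRUE` or `FALSE`.
#' @export
is_enabled <- function(net, m, u) {
  m <- .full_vec(m, net$places, "marking")
  u <- .full_vec(u, net$transitions, "step")
  cons <- as.vector(net$pre %*% u)
  if (any(m < cons)) return(FALSE)
  fired <- u > 0
  if (any(fired) && any(net$act[, fired, drop = FALSE] & m < 1)) return(FALSE)
  TRUE
}

#' Execute an enabled step
#'
#' Applies the accumulated effect of all transition occurrences in `u`:
#' `m'(p) = m(p) + sum_t U(t) * (W(t,p) - W(p,t))`.
#'
#' @inheritParams is_enabled
#' @return the successor marking (full named vector).
#' @export
execute_step <- function(net, m, u) {
  mfull <- .full_vec(m, net$places, "marking")
  ufull <- .full_vec(u, net$transitions, "step")
  if (!is_enabled(net, mfull, ufull))
    stop("step is not enabled at the given marking")
  mfull + as.vector(net$engine$effect %*% ufull)
}

#' Compute a maximally concurrent step
#'
#' Returns an enabled step to which no further transition occurrence can
#' be added while staying enabled.  On conflict-free markings (no two
#' occurrences compete for the same tokens) the maximal step is unique and
#' that step is returned.  Otherwise the engine resolves the competition
#' greedily in sorted transition-identifier order, taking the maximum
#' admissible multiplicity per transition, and flags the conflict via the
#' `conflict` attribute of the result.
#'
#' @param net a `pta_net`.
#' @param m marking.
#' @return named numeric vector of multiplicities over all transitions,
#'   with attribute `conflict` (logical).
#' @export
maximal_step <- function(net, m) {
  m <- .full_vec(m, net$places, "marking")
  eng <- net$engine
  caps <- .solo_caps(eng, m)
  cons <- as.vector(net$pre %*% caps)
  if (all(m - cons >= 0)) {
    u <- stats::setNames(caps, net$transitions)
    attr(u, "conflict") <- FALSE
    return(u)
  }
  .greedy_step(net, m, caps)
}

# per-transition maximum multiplicity w.r.t. a token budget, with
# activator gating evaluated on the true pre-step marking
.solo_caps <- function(eng, avail, m_pre = avail) {
  caps <- floor(avail[eng$in_idx] / eng$in_w)
  caps[eng$pad] <- Inf   # padded entries: no constraint
  dim(caps) <- dim(eng$in_idx)
  caps <- do.call(pmin, lapply(seq_len(nrow(caps)), function(i) caps[i, ]))
  if (!is.null(eng$act_idx)) {
    tested <- m_pre[eng$act_idx] < 1
    tested[is.na(tested)] <- FALSE
    dim(tested) <- dim(eng$act_idx)
    caps[colSums(tested) > 0] <- 0
  }
  caps
}

# sequential greedy policy for conflicting markings
.greedy_step <- function(net, m, solo) {
  eng <- net$engine
  avail <- m
  u <- stats::setNames(numeric(length(net$transitions)), net$transitions)
  for (j in eng$ord) {
    if (solo[j] == 0) next
    ii <- eng$in_idx[eng$in_w[, j] > 0, j]
    ww <- eng$in_w[eng$in_w[, j] > 0, j]
    mult <- min(floor(avail[ii] / ww))
    if (mult > 0) {
      u[j] <- mult
      avail[ii] <- avail[ii] - mult * ww
    }
  }
  # conflict: some transition could fire once more were it alone
  conflict <- FALSE
  for (j in seq_along(u)) {
    if (u[j] >= solo[j]) next
    ii <- eng$in_idx[eng$in_w[, j] > 0, j]
    ww <- eng$in_w[eng$in_w[, j] > 0, j]
    own_left <- m[ii] - u[j] * ww
    if (all(own_left >= ww)) { conflict <- TRUE; break }
  }
  attr(u, "conflict") <- conflict
  u
}

#' Run a sequence of maximally concurrent steps
#'
#' Iterates [maximal_step()] and [execute_step()] from a marking.  The
#' trace ends early when only the empty step is enabled (the formal step
#' sequence consists of non-empty steps).
#'
#' @param net a `pta_net`.
#' @param m starting marking; defaults to the initial marking.
#' @param n_steps maximum number of steps to execute (>= 0).
#' @return an object of class `pta_trace`: list with elements `steps`
#'   (list of named multiplicity vectors) and `markings` (list of named
#'   marking vectors, one per executed step), plus attribute `conflict`.
#' @export
run_steps <- function(net, m = NULL, n_steps) {
  if (n_steps < 0) stop("n_steps must be >= 0")
  m <- if (is.null(m)) net$m0 else .full_vec(m, net$places, "marking")
  steps <- vector("list", n_steps)
  markings <- vector("list", n_steps)
  conflict <- FALSE
  k <- 0L
  while (k < n_steps) {
    u <- maximal_step(net, m)
    if (all(u == 0)) break
    conflict <- conflict || attr(u, "conflict")
    m <- m + as.vector(net$engine$effect %*% u)
    k <- k + 1L
    steps[[k]] <- u
    markings[[k]] <- m
  }
  structure(list(steps = steps[seq_len(k)], markings = markings[seq_len(k)]),
            class = "pta_trace", conflict = conflict)
}

#' @export
print.pta_trace <- function(x, ...) {
  cat("max-enabled step sequence of length", length(x$steps), "\n")
  if (isTRUE(attr(x, "conflict"))) cat("(conflict flag raised)\n")
  invisible(x)
}

#' Write a step/marking trace to CSV
#'
#' Writes two CSV files: `steps_path` with columns
#' `step_index,transition,multiplicity` (one row per non-zero multiplicity)
#' and `markings_path` with one column `step_index` plus one column per
#' place.
#'
#' @param trace a `pta_trace` from [run_steps()].
#' @param steps_path,markings_path output paths.
#' @return invisibly, the two paths.
#' @export
write_trace <- function(trace, steps_path, markings_path) {
  rows <- do.call(rbind, lapply(seq_along(trace$steps), function(i) {
    u <- trace$steps[[i]]
    nz <- which(u > 0)
    data.frame(step_index = i, transition = names(u)[nz],
               multiplicity = unname(u[nz]))
  }))
  if (is.null(rows))
    rows <- data.frame(step_index = integer(), transition = character(),
                       multiplicity = numeric())
  utils::write.csv(rows, steps_path, row.names = FALSE, quote = FALSE)
  mk <- do.call(rbind, trace$markings)
  mk <- cbind(step_index = seq_along(trace$markings), as.data.frame(mk))
  utils::write.csv(mk, markings_path, row.names = FALSE, quote = FALSE)
  invisible(c(steps_path, markings_path))
}

# fast internal runner: no per-step allocation of names/attributes, stops
# early on the empty step; returns final marking + optional recordings
.run_fast <- function(net, m, n_steps, record_at = integer(),
                      record_places = NULL, record_steps_of = NULL) {
  eng <- net$engine
  rec <- if (length(record_at)) matrix(NA_real_, length(record_at),
                                       length(record_places)) else NULL
  recs <- if (!is.null(record_steps_of))
    matrix(NA_real_, length(record_at), length(record_steps_of)) else NULL
  ri <- 1L
  conflict <- FALSE
  pi <- if (!is.null(record_places)) match(record_places, net$places) else NULL
  ti <- if (!is.null(record_steps_of)) match(record_steps_of, net$transitions) else NULL
  executed <- 0L
  for (s in seq_len(n_steps)) {
    caps <- .solo_caps(eng, m)
    if (all(caps == 0)) break
    cons <- as.vector(net$pre %*% caps)
    if (any(m - cons < 0)) {
      u <- .greedy_step(net, m, caps)
      conflict <- conflict || attr(u, "conflict")
      caps <- as.vector(u)
    }
    m <- m + as.vector(eng$effect %*% caps)
    executed <- s
    if (ri <= length(record_at) && s == record_at[ri]) {
      if (!is.null(rec)) rec[ri, ] <- m[pi]
      if (!is.null(recs)) recs[ri, ] <- caps[ti]
      ri <- ri + 1L
    }
  }
  list(m = m, recorded = rec, step_mults = recs, conflict = conflict,
       executed = executed)
}

# one maximally concurrent step; returns new marking, multiplicities and
# whether the step was empty
.engine_step <- function(net, m) {
  eng <- net$engine
  caps <- .solo_caps(eng, m)
  if (all(caps == 0))
    return(list(m = m, u = caps, empty = TRUE, conflict = FALSE))
  cons <- as.vector(net$pre %*% caps)
  conflict <- FALSE
  if (any(m - cons < 0)) {
    u <- .greedy_step(net, m, caps)
    conflict <- attr(u, "conflict")
    caps <- as.vector(u)
  }
  list(m = m + as.vector(eng$effect %*% caps), u = caps, empty = FALSE,
       conflict = conflict)
}
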