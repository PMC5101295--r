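# shared fixtures: small hand-built nets, a random tiny-net generator and
# a brute-force step-semantics oracle (independent of the engine)

# all enabled steps at m, by exhaustive enumeration over bounded
# multiplicities (per-transition bound from each input place separately)
enumerate_enabled_steps <- function(net, m) {
  m <- stats::setNames(as.numeric(m[net$places]), net$places)
  caps <- vapply(net$transitions, function(t) {
    ip <- net$pre[, t] > 0
    min(floor(m[ip] / net$pre[ip, t]))
  }, 0)
  grids <- lapply(caps, function(k) 0:k)
  combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  names(combos) <- net$transitions
  keep <- apply(combos, 1, function(u) is_enabled(net, m, unlist(u)))
  lapply(which(keep), function(i) unlist(combos[i, , drop = FALSE]))
}

# the subset of enabled steps that are maximal (no strict enabled superset)
enumerate_maximal_steps <- function(net, m) {
  steps <- enumerate_enabled_steps(net, m)
  is_max <- vapply(seq_along(steps), function(i) {
    u <- steps[[i]]
    !any(vapply(steps, function(v)
      all(v >= u) && any(v > u), FALSE))
  }, FALSE)
  steps[is_max]
}

# random tiny net: <= 4 transitions, <= 6 tokens, occasional activator arcs
rand_tiny_net <- function(seed) {
  set.seed(seed)
  nP <- sample(2:4, 1)
  nT <- sample(1:4, 1)
  places <- paste0("p", seq_len(nP))
  transitions <- paste0("t", seq_len(nT))
  arcs <- do.call(rbind, lapply(transitions, function(t) {
    ins <- sample(places, sample(1:2, 1))
    outs <- if (stats::runif(1) < 0.8) sample(places, sample(1:2, 1)) else character()
    rbind(
      data.frame(from = ins, to = t, weight = sample(1:2, length(ins), TRUE)),
      if (length(outs))
        data.frame(from = t, to = outs, weight = sample(1:2, length(outs), TRUE))
    )
  }))
  activators <- NULL
  if (stats::runif(1) < 0.4)
    activators <- data.frame(place = sample(places, 1),
                             transition = sample(transitions, 1))
  total <- sample(0:6, 1)
  m0 <- stats::setNames(as.numeric(stats::rmultinom(1, total, rep(1, nP))), places)
  pta_net(places, transitions, arcs, activators, m0 = m0[m0 > 0])
}

# small descending-profile gradient setup used in several tests
small_grad <- function(n = 4, profile = c(500, 300, 100, 0), ...) {
  params <- gradient_params(n = n, J0 = 10, ...)
  build_gradient_net(params, profile = profile)
}
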