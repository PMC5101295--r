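# semantics of the PTA-net engine: enabling, execution, maximal steps

test_that("step enabling follows token demand and tests activators a priori", {
  net <- pta_net(
    places = c("p", "q"), transitions = c("t", "v"),
    arcs = data.frame(from = c("p", "p", "v"), to = c("t", "v", "q"),
                      weight = c(1, 1, 1)),
    activators = data.frame(place = "q", transition = "v"),
    m0 = c(p = 2))
  m <- marking(net)
  expect_true(is_enabled(net, m, c(t = 2)))
  expect_false(is_enabled(net, m, c(t = 3)))
  # v needs a token in q via its activator arc
  expect_false(is_enabled(net, m, c(v = 1)))
  expect_true(is_enabled(net, c(p = 2, q = 1), c(v = 1)))
  # a priori: tokens produced by the step itself never enable it, even
  # though v itself outputs into the tested place q
  expect_false(is_enabled(net, m, c(t = 1, v = 1)))
  expect_error(is_enabled(net, m, c(zz = 1)), "unknown")
  expect_error(is_enabled(net, c(bad = 1), c(t = 1)), "unknown")
})

test_that("executing a step applies the accumulated token effect", {
  net <- pta_net(
    places = c("p", "p2"), transitions = "t",
    arcs = data.frame(from = c("p", "t"), to = c("t", "p2"), weight = c(2, 1)),
    m0 = c(p = 5))
  m2 <- execute_step(net, marking(net), c(t = 2))
  expect_equal(unname(m2[c("p", "p2")]), c(1, 2))
  # the empty step is the identity
  expect_equal(execute_step(net, marking(net), numeric(0)), marking(net))
  expect_error(execute_step(net, marking(net), c(t = 3)), "not enabled")

  loop <- pta_net(
    places = "p", transitions = "t",
    arcs = data.frame(from = c("p", "t"), to = c("t", "p"), weight = c(1, 1)),
    m0 = c(p = 4))
  for (k in 0:4)
    expect_equal(unname(execute_step(loop, marking(loop), c(t = k))["p"]), 4)
})

test_that("maximal steps maximise multiplicities and flag conflicts", {
  single <- pta_net(
    places = "p", transitions = "t",
    arcs = data.frame(from = "p", to = "t", weight = 1), m0 = c(p = 3))
  u <- maximal_step(single, marking(single))
  expect_equal(unname(u["t"]), 3)
  expect_false(attr(u, "conflict"))
  # brute force confirms 3t is the unique maximal step
  mx <- enumerate_maximal_steps(single, marking(single))
  expect_length(mx, 1)
  expect_equal(unname(mx[[1]]["t"]), 3)

  gated <- pta_net(
    places = c("p", "a"), transitions = "t",
    arcs = data.frame(from = "p", to = "t", weight = 1),
    activators = data.frame(place = "a", transition = "t"),
    m0 = c(p = 3))
  expect_true(all(maximal_step(gated, marking(gated)) == 0))

  disjoint <- pta_net(
    places = c("p", "q"), transitions = c("t1", "t2"),
    arcs = data.frame(from = c("p", "q"), to = c("t1", "t2"), weight = c(1, 1)),
    m0 = c(p = 2, q = 3))
  u <- maximal_step(disjoint, marking(disjoint))
  expect_equal(unname(u[c("t1", "t2")]), c(2, 3))
  expect_false(attr(u, "conflict"))

  shared <- pta_net(
    places = "p", transitions = c("t1", "t2"),
    arcs = data.frame(from = c("p", "p"), to = c("t1", "t2"), weight = c(1, 1)),
    m0 = c(p = 1))
  u <- maximal_step(shared, marking(shared))
  expect_true(attr(u, "conflict"))
  # greedy policy: sorted identifier order, so t1 wins the single token
  expect_equal(unname(u[c("t1", "t2")]), c(1, 0))
  expect_length(enumerate_maximal_steps(shared, marking(shared)), 2)
})

test_that("maximal_step agrees with brute-force enumeration on tiny nets", {
  for (seed in 1:40) {
    net <- rand_tiny_net(seed)
    m <- marking(net)
    u <- maximal_step(net, m)
    expect_true(is_enabled(net, m, u), info = paste("seed", seed))
    # maximality: no transition can be added once more
    for (t in net$transitions) {
      u1 <- u; u1[t] <- u1[t] + 1
      expect_false(is_enabled(net, m, u1), info = paste("seed", seed, t))
    }
    # membership in the brute-force maximal set
    mx <- enumerate_maximal_steps(net, m)
    hit <- any(vapply(mx, function(v) all(v == u[names(v)]), FALSE))
    expect_true(hit, info = paste("seed", seed))
    # no conflict flag implies the maximal step is unique
    if (!attr(u, "conflict"))
      expect_length(mx, if (length(mx)) 1 else 0)
  }
})

test_that("a weight-1 self-loop caps auto-concurrency at the place count", {
  for (k in c(0, 1, 5)) {
    net <- pta_net(
      places = c("p", "out"), transitions = "t",
      arcs = data.frame(from = c("p", "t", "t"), to = c("t", "p", "out"),
                        weight = c(1, 1, 1)),
      m0 = c(p = k))
    u <- maximal_step(net, marking(net))
    expect_equal(unname(u["t"]), k)
    m2 <- execute_step(net, marking(net), u)
    expect_equal(unname(m2[c("p", "out")]), c(k, k))
  }
})

test_that("run_steps iterates max-enabled steps and stops at the empty step", {
  pipe <- pta_net(
    places = c("p", "p2"), transitions = "t",
    arcs = data.frame(from = c("p", "t"), to = c("t", "p2"), weight = c(1, 1)),
    m0 = c(p = 4))
  expect_length(run_steps(pipe, n_steps = 0)$steps, 0)
  tr <- run_steps(pipe, n_steps = 2)
  expect_length(tr$steps, 1)
  expect_equal(unname(tr$steps[[1]]["t"]), 4)
  expect_equal(unname(tr$markings[[1]][c("p", "p2")]), c(0, 4))

  dead <- pta_net(
    places = "p", transitions = "t",
    arcs = data.frame(from = "p", to = "t", weight = 1), m0 = NULL)
  expect_length(run_steps(dead, n_steps = 5)$steps, 0)

  # token accounting is exact along every trace
  for (seed in 41:55) {
    net <- rand_tiny_net(seed)
    tr <- run_steps(net, n_steps = 3)
    m <- marking(net)
    for (i in seq_along(tr$steps)) {
      eff <- as.vector((net$post - net$pre) %*% tr$steps[[i]])
      expect_equal(unname(tr$markings[[i]]), unname(m + eff))
      expect_true(all(tr$markings[[i]] >= 0))
      m <- tr$markings[[i]]
    }
  }
})

test_that("step/marking traces export losslessly to CSV", {
  net <- pta_net(
    places = c("p", "p2"), transitions = "t",
    arcs = data.frame(from = c("p", "t"), to = c("t", "p2"), weight = c(2, 1)),
    m0 = c(p = 5))
  tr <- run_steps(net, n_steps = 3)  # 2t fires once, then nothing
  sp <- tempfile(fileext = ".csv"); mp <- tempfile(fileext = ".csv")
  write_trace(tr, sp, mp)
  steps <- read.csv(sp)
  expect_equal(names(steps), c("step_index", "transition", "multiplicity"))
  expect_equal(steps$multiplicity, 2)
  mk <- read.csv(mp)
  expect_equal(names(mk), c("step_index", "p", "p2"))
  expect_equal(nrow(mk), 1)
  expect_equal(c(mk$p, mk$p2), c(1, 2))
})
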