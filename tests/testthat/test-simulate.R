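# trajectory-level behaviour: determinism, steady state, deviations

test_that("with the source off and an empty tissue nothing ever happens", {
  params <- gradient_params(n = 5, J0 = 10, source_on = FALSE)
  traj <- simulate_gradient(params, n_cycles = 10)
  expect_true(all(traj$counts == 0))
  expect_equal(detect_steady_state(traj), 1L)
})

test_that("the net is deterministic: identical runs, identical trajectories", {
  params <- gradient_params(n = 10, J0 = 50)
  t1 <- simulate_gradient(params, n_cycles = 60)
  t2 <- simulate_gradient(params, n_cycles = 60)
  expect_identical(t1$counts, t2$counts)
})

test_that("steady-state detection finds exact fixed points only", {
  params <- gradient_params(n = 10, J0 = 50)
  traj <- simulate_gradient(params, n_cycles = 30)
  expect_true(is.na(detect_steady_state(traj)))   # still growing
  # fast-relaxing parameter set reaches an exact integer fixed point
  fast <- gradient_params(n = 8, D = 0.1, k = 5e-3, J0 = 100, dt = 10)
  gnet <- build_gradient_net(fast)
  traj <- simulate_gradient(gnet, n_cycles = 2000, until_steady = TRUE)
  ss <- detect_steady_state(traj)
  expect_false(is.na(ss))
  # fixed-point persistence: once equal, the marking never changes again
  longer <- simulate_gradient(gnet, n_cycles = ss + 10)
  for (j in ss:(ss + 10))
    expect_identical(longer$counts[j, ], longer$counts[ss, ])
})

test_that("monotone profiles stay monotone at cycle boundaries", {
  traj <- simulate_gradient(do.call(gradient_params, case_study_params("Dpp")),
                            n_cycles = 150)
  for (j in seq_len(nrow(traj$counts)))
    expect_true(all(diff(traj$counts[j, ]) <= 0))
})

test_that("deviation metrics compute per-cell relative deviations", {
  d <- deviation_metrics(c(100, 50), c(100, 50))
  expect_equal(d$max_dev, 0)
  expect_equal(d$mean_dev, 0)
  d <- deviation_metrics(101, 100)
  expect_equal(d$max_dev, 1)
  expect_equal(d$mean_dev, 1)
  d <- deviation_metrics(c(90, 120, 100), c(100, 100, 100))
  expect_equal(d$per_cell, c(10, 20, 0))
  expect_equal(d$max_dev, 20)
  expect_equal(d$mean_dev, 10)
  # zero reference with non-zero counts is excluded with a warning
  expect_warning(d <- deviation_metrics(c(5, 100), c(0, 100)), "excluded")
  expect_equal(d$n_compared, 1)
  expect_equal(d$excluded, 1L)
  expect_true(is.na(d$per_cell[1]))
  # restriction to a fraction of the reference maximum
  d <- deviation_metrics(c(1000, 1), c(1000, 2), min_fraction = 0.01)
  expect_equal(d$n_compared, 1)
  expect_error(deviation_metrics(1:3, 1:2), "equal length")
})

test_that("steady-state deviations are robust to the influx scale", {
  devmax <- vapply(c(1e4, 2e4), function(J0) {
    params <- gradient_params(n = 12, D = 0.1, k = 2e-3, J0 = J0, dt = 10)
    gnet <- build_gradient_net(params)
    traj <- simulate_gradient(gnet, n_cycles = 4000, until_steady = TRUE)
    ss <- detect_steady_state(traj)
    expect_false(is.na(ss))
    edges <- (0:params$n) * params$ell
    ref <- counts_from_density(
      list(grid = edges, values = steady_state_finite(edges, params)), params)
    deviation_metrics(traj$counts[ss, ], ref)$max_dev
  }, 0)
  expect_lt(abs(devmax[1] - devmax[2]), 0.1)
})

test_that("trajectories print, convert and plot", {
  traj <- simulate_gradient(gradient_params(n = 4, J0 = 10), n_cycles = 5)
  df <- as.data.frame(traj)
  expect_equal(names(df), c("cycle", "time_s", paste0("cell_", 1:4)))
  expect_equal(nrow(df), 5)
  expect_output(print(traj), "5 cycles")
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf)
  expect_silent(plot(traj, at = c(1, 5)))
  grDevices::dev.off()
  expect_true(file.exists(tf))
})
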