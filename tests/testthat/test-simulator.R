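test_that("task grid enumerates the full 10x10 difficulty lattice", {
  grid <- build_task_grid()
  expect_equal(nrow(grid), 100)
  expect_true(all(grid$d_a %in% ((1:10) / 10)))
  expect_true(all(grid$d_b %in% ((1:10) / 10)))
  expect_equal(anyDuplicated(grid[, c("d_a", "d_b")]), 0L)
  expect_true(any(grid$d_a == 0.1 & grid$d_b == 0.1))
  expect_true(any(grid$d_a == 1.0 & grid$d_b == 1.0))
  # row-major ordering: d_a outer, d_b inner
  expect_equal(grid$d_a[1:10], rep(0.1, 10))
  expect_equal(grid$d_b[1:10], (1:10) / 10)
})

test_that("admissible capacity cells match brute-force enumeration", {
  cells <- capacity_grid_cells()
  oracle <- enumerate_capacity_cells()
  expect_equal(nrow(cells), 324)
  expect_equal(as.matrix(cells), oracle, ignore_attr = TRUE)
  # per-row counts against the oracle
  for (a in c(1.0, 1.2, 2.0, 3.5)) {
    expect_equal(sum(cells$mean_cap_a == a), sum(oracle[, 1] == a))
  }
  # first row partners: |1.0 - b| < 1/3 in exact arithmetic
  expect_equal(cells$mean_cap_b[cells$mean_cap_a == 1.0], c(1.0, 1.1, 1.2, 1.3))
  # exact-third tie excluded
  expect_false(any(cells$mean_cap_a == 1.2 & cells$mean_cap_b == 1.6))
})

test_that("system generation is model-independent, truncated positive, and pools conserve capability", {
  mult <- build_system_grid("multiplicative", seed = 42)
  flex0 <- build_system_grid("flexible", pool_per_module = 0, seed = 42)
  expect_equal(flex0$cap_a, mult$cap_a)
  expect_equal(flex0$cap_b, mult$cap_b)
  expect_true(all(mult$cap_a > 0) && all(mult$cap_b > 0))

  flex <- build_system_grid("flexible", seed = 42)
  expect_equal(flex$cap_a, mult$cap_a - 0.5)
  expect_equal(flex$cap_b, mult$cap_b - 0.5)
  expect_true(all(flex$pool == 1.0))
  # total capability conserved
  expect_equal(flex$cap_a + flex$cap_b + flex$pool, mult$cap_a + mult$cap_b)
  expect_error(build_system_grid("flexible", pool_per_module = 2, seed = 1),
               "nonpositive")
  expect_error(build_system_grid("additive", pool_per_module = 0.5, seed = 1))
})

test_that("final-capacity rules match the worked examples", {
  expect_equal(final_capacity_additive(2.0, 0.5), 1.5)
  expect_equal(final_capacity_additive(2.7, 1.0), 2.7)
  expect_equal(final_capacity_additive(1.0, 0.1), 0.1)
  expect_equal(final_capacity_additive(0.5, 0.1), 0)   # clamped at zero
  expect_equal(final_capacity_multiplicative(2.0, 0.5), 1.0)
  expect_equal(final_capacity_multiplicative(2.7, 1.0), 2.7)
  expect_equal(final_capacity_multiplicative(3.5, 0.1), 0.35)
})

test_that("shared-pool allocation follows both rules and conserves capacity", {
  # gap larger than pool: weaker module gets everything
  a <- allocate_shared(2.5, 1.0, 1.0)
  expect_equal(c(a$cap_a, a$cap_b), c(2.5, 2.0))
  # gap within pool: equalize
  a <- allocate_shared(1.6, 1.4, 1.0)
  expect_equal(c(a$cap_a, a$cap_b), c(2.0, 2.0))
  # symmetry
  a <- allocate_shared(1.7, 1.7, 0.6)
  expect_equal(c(a$cap_a, a$cap_b), c(2.0, 2.0))
  # conservation over random triples
  set.seed(1)
  for (i in 1:200) {
    ca <- runif(1, 0, 4); cb <- runif(1, 0, 4); p <- runif(1, 0, 2)
    out <- allocate_shared(ca, cb, p)
    expect_equal(out$cap_a + out$cap_b, ca + cb + p, tolerance = 1e-12)
    if (abs(ca - cb) > p) {
      expect_equal(max(out$cap_a - ca, out$cap_b - cb), p)
    } else {
      expect_equal(out$cap_a, out$cap_b)
    }
  }
})

test_that("input ramp and pipelined output follow the stated forms", {
  expect_equal(input_rate(0), 0.5)
  expect_equal(input_rate(100), 3.0)
  expect_equal(input_rate(280), 7.5)     # exceeds every grid capacity
  expect_equal(input_rate(0, n = -10), 0)  # clamped at zero
  expect_equal(step_output(0.8, 1.5, 1.2), 0.8)  # input-limited
  expect_equal(step_output(5.0, 1.5, 1.2), 1.2)  # bottleneck-limited
  expect_equal(step_output(1.0, 0.5, -0.2), 0)   # non-negativity
})

test_that("trial traces interpolate between update points where the output rule holds exactly", {
  sys <- build_system_grid("additive", seed = 3)
  tasks <- build_task_grid()
  tr <- simulate_trial(sys[50, ], tasks[37, ], n_updates = 2, seed = 9)
  expect_length(tr$output, 101)
  up <- tr$updates
  expect_equal(tr$output[c(1, 101)], up$output)
  expect_equal(tr$input[c(1, 101)], up$input)
  # pipelined-minimum rule holds exactly at update points; the midframe is
  # the interpolation of the endpoints
  expect_equal(up$output,
               pmax(0, pmin(up$input, up$cap_a_final, up$cap_b_final)))
  expect_equal(tr$output[51], mean(up$output), tolerance = 1e-12)

  # longer trace: frame count contract
  tr <- simulate_trial(sys[50, ], tasks[37, ], n_updates = 281, seed = 9)
  expect_length(tr$output, 28001)
  expect_error(simulate_trial(sys[50, ], tasks[37, ], n_updates = 1), "n_updates")
  bad <- sys[50, ]; bad$model <- "quadratic"
  expect_error(simulate_trial(bad, tasks[37, ]), "invalid model")
})

test_that("zero-noise traces plateau at the bottleneck and rise monotonically to it", {
  sys <- build_system_grid("multiplicative", seed = 5)
  tasks <- build_task_grid()
  for (i in c(10, 160, 324)) {
    for (j in c(34, 100)) {
      tr <- simulate_trial(sys[i, ], tasks[j, ], noise = FALSE)
      bottleneck <- min(tail(tr$cap_a, 1), tail(tr$cap_b, 1))
      expect_lt(abs(max(tr$output) - bottleneck), 1e-9)
      # non-decreasing to the plateau, constant after
      expect_true(all(diff(tr$output) > -1e-12))
      plateau_frames <- tr$output > bottleneck - 1e-9
      expect_gt(sum(plateau_frames), 1000)
      expect_lt(diff(range(tr$output[plateau_frames])), 1e-9)
    }
  }
})

test_that("flexible allocation never hurts the bottleneck", {
  mult <- build_system_grid("multiplicative", seed = 11)
  flex <- build_system_grid("flexible", pool_per_module = 0, seed = 11)
  flex$pool <- 1.0  # same drawn capacities, plus a free shared pool
  tasks <- build_task_grid()
  for (i in c(1, 77, 200, 324)) {
    for (j in c(5, 55, 100)) {
      tr_m <- simulate_trial(mult[i, ], tasks[j, ], noise = FALSE)
      tr_f <- simulate_trial(flex[i, ], tasks[j, ], noise = FALSE)
      expect_gte(max(tr_f$output), max(tr_m$output) - 1e-12)
    }
  }
})

test_that("sweeps are reproducible and trial substreams are isolated", {
  sys <- build_system_grid("additive", seed = 2)[c(1, 150), ]
  tasks <- build_task_grid()[c(1, 100), ]
  a <- run_experiment("additive", seed = 7, systems = sys, tasks = tasks)
  b <- run_experiment("additive", seed = 7, systems = sys, tasks = tasks)
  expect_equal(a, b)
  expect_equal(nrow(a), 4)
  # a single trial reproduces in isolation via its substream seed
  tr1 <- simulate_trial(sys[1, ], tasks[1, ],
                        seed = pipecap:::trial_seed(7, sys$system_id[1], 1))
  r1 <- steady_state_rate(tr1$input, tr1$output, stride = 50, downsample = 10)
  expect_equal(r1$ssr, a$ssr_hz[1])
})
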