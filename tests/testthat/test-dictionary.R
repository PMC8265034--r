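test_that("geometric grid spacing and truncation follow the construction
           rule", {
  g <- build_grid(300, 3500, 0.05)
  expect_equal(g[1], 300)
  expect_equal(g[-1] / g[-length(g)] - 1, rep(0.05, length(g) - 1))
  expect_true(max(g) >= 3500)               # range covered
  expect_true(max(g) <= 3500 * 1.05)        # overshoot < one step
  # brute-force enumeration oracle for a short grid
  oracle <- c(10)
  while (oracle[length(oracle)] * 1.05 <= 10.4 * 1.05) {
    oracle <- c(oracle, oracle[length(oracle)] * 1.05)
  }
  expect_equal(build_grid(10, 10.4, 0.05), oracle)  # = c(10, 10.5)
  expect_error(build_grid(500, 300), "smaller")
})

test_that("default parameter grid has the protocol B1 axis and 5% steps", {
  grid <- parameter_grid()
  expect_equal(grid$b1_values, seq(0.6, 1.4, by = 0.1))
  expect_length(grid$b1_values, 9L)
  expect_equal(range(grid$t1_values)[1], 300)
  expect_equal(range(grid$t2s_values)[1], 10)
})

test_that("dictionary atoms are unit norm and indexed by the grid product", {
  sched <- default_schedule()
  grid <- parameter_grid(t1_range = c(800, 900), t2s_range = c(40, 60),
                         rel_step = 0.05, b1_values = 1.0)
  dict <- build_dictionary(sched, grid)
  expect_equal(nrow(dict$atoms),
               length(grid$t1_values) * length(grid$t2s_values))
  expect_equal(sqrt(rowSums(dict$atoms^2)), rep(1, nrow(dict$atoms)),
               tolerance = 1e-9)
})

test_that("matching recovers atoms exactly and is scale invariant", {
  dict <- build_dictionary(default_schedule(), coarse_grid())
  i <- seq(1, nrow(dict$atoms), by = 53)
  fp <- dict$atoms[i, , drop = FALSE] * dict$norms[i]  # raw fingerprints
  m <- match_voxel(fp, dict)
  expect_equal(m$t1, dict$t1[i])
  expect_equal(m$t2s, dict$t2s[i])
  expect_equal(m$b1, dict$b1[i])
  expect_equal(m$correlation, rep(1, length(i)), tolerance = 1e-9)
  expect_equal(m$m0, rep(1, length(i)), tolerance = 1e-9)
  m2 <- match_voxel(7.3 * fp, dict)
  expect_equal(m2$t1, m$t1)
  expect_equal(m2$m0, 7.3 * m$m0, tolerance = 1e-9)
})

test_that("accelerated matching equals the brute-force oracle", {
  dict <- build_dictionary(default_schedule(), coarse_grid())
  set.seed(33)
  fp <- matrix(runif(100 * 35, 0, 2), 100, 35)
  m <- match_voxel(fp, dict)
  for (r in 1:100) {
    v <- fp[r, ] / sqrt(sum(fp[r, ]^2))
    cors <- as.numeric(dict$atoms %*% v)
    best <- which.max(cors)
    expect_equal(m$t1[r], dict$t1[best])
    expect_equal(m$t2s[r], dict$t2s[best])
    expect_equal(m$correlation[r], cors[best])
  }
})

test_that("matching attains half-step precision where the schedule encodes
           the parameters", {
  # T2* is encoded by the TE ramp (16-76.5 ms): off-grid draws in a
  # TE-comparable range must match within half a 5% step. T1 is encoded by
  # the inter-frame recovery exp(-TR/T1), informative only for T1
  # comparable to TR; long T1 must match within half a step.
  dict <- build_dictionary(default_schedule(), parameter_grid())
  set.seed(77)
  n <- 300
  t1 <- exp(runif(n, log(1500), log(3400)))
  t2s <- exp(runif(n, log(20), log(300)))
  fp <- simulate_fingerprint(t1, t2s, 1, 1, default_schedule())
  m <- match_voxel(fp, dict)
  expect_lte(max(abs(m$t2s - t2s) / t2s), 0.05)
  expect_lte(max(abs(m$t1 - t1) / t1), 0.05)
})

test_that("all-zero fingerprints are flagged as background", {
  dict <- build_dictionary(default_schedule(), coarse_grid())
  m <- match_voxel(rep(0, 35), dict)
  expect_equal(unlist(m), c(t1 = 0, t2s = 0, b1 = 0, m0 = 0,
                            correlation = 0))
})

test_that("on-grid phantom stacks reconstruct exactly inside the mask", {
  grid <- parameter_grid()
  cfg <- tiny_phantom_config(
    t1_ms = c(nawm = grid$t1_values[22], gm = grid$t1_values[32],
              csf = grid$t1_values[50]),
    t2s_ms = c(nawm = grid$t2s_values[34], gm = grid$t2s_values[36],
               csf = grid$t2s_values[103]),
    n_lesions = 0, prob_sigma = 0, b1_field = "uniform")
  ph <- generate_phantom(cfg, seed = 1)
  st <- simulate_baseline_stack(ph)
  dict <- build_dictionary(st$schedule, grid)
  maps <- reconstruct_maps(st, dict, ph$brain_mask)
  inb <- ph$brain_mask
  expect_equal(maps$t1_ms[inb], ph$t1_map[inb])
  expect_equal(maps$t2s_ms[inb], ph$t2s_map[inb])
  expect_equal(maps$b1_scale[inb], ph$b1_map[inb])
  expect_equal(max(abs(maps$t1_ms[!inb])), 0)
  # empty mask gives all-zero maps
  empty <- reconstruct_maps(st, dict, array(FALSE, dim(ph$t1_map)))
  expect_equal(max(abs(empty$t1_ms)), 0)
})

test_that("reconstruction error does not grow when the grid is refined", {
  cfg <- tiny_phantom_config(n_lesions = 0, b1_field = "uniform",
                             shape = c(32L, 32L, 2L))
  ph <- generate_phantom(cfg, seed = 2)
  st <- simulate_baseline_stack(ph)
  err <- vapply(c(0.20, 0.05), function(step) {
    dict <- build_dictionary(st$schedule,
                             parameter_grid(rel_step = step, b1_values = 1))
    maps <- reconstruct_maps(st, dict, ph$brain_mask)
    mean_relative_deviation(maps$t2s_ms, ph$t2s_map, ph$brain_mask)
  }, numeric(1))
  expect_lte(err[2], err[1])
})

test_that("frame-count mismatches are rejected", {
  dict <- build_dictionary(default_schedule(), coarse_grid())
  expect_error(match_voxel(rep(1, 20), dict), "does not match")
  ph <- tiny_phantom(seed = 1)
  st <- simulate_baseline_stack(ph, default_schedule(n_frames = 21L))
  expect_error(reconstruct_maps(st, dict), "does not match")
})
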