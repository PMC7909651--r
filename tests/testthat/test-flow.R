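test_that("lumen diameter wraps cells into a circle circumference", {
  expect_identical(lumen_diameter(0, 5e-6), 0)
  expect_equal(lumen_diameter(8, 5e-6), 1.2732395e-5, tolerance = 1e-7)
  n <- 1:20
  expect_equal(lumen_diameter(2 * n, 5e-6), 2 * lumen_diameter(n, 5e-6))
})

test_that("segment conductance follows n^4 scaling with a floor at n = 0", {
  expect_identical(segment_conductance(0, 5e-6, 0.0035, 1e-5), 1e-25)
  expect_equal(segment_conductance(8, 5e-6, 0.0035, 1e-5), 1.842945e-14,
               tolerance = 1e-6)
  expect_equal(segment_conductance(2, 5e-6, 0.0035, 1e-5) /
                 segment_conductance(1, 5e-6, 0.0035, 1e-5), 16)
})

test_that("resistance is the exact reciprocal of conductance", {
  expect_equal(segment_resistance(8, 5e-6, 0.0035, 1e-5), 5.4260984e13,
               tolerance = 1e-7)
  n <- 1:20
  expect_equal(segment_resistance(n, 5e-6, 0.0035, 1e-5) *
                 segment_conductance(n, 5e-6, 0.0035, 1e-5), rep(1, 20))
  expect_equal(segment_resistance(10, 5e-6, 0.0035, 1e-5) /
                 segment_resistance(5, 5e-6, 0.0035, 1e-5), 1 / 16)
  expect_error(segment_resistance(0, 5e-6, 0.0035, 1e-5), "infinite")
})

test_that("initial A-branch solve matches the series-parallel hand reduction", {
  net <- ref_net()
  fs <- solve_flow(net)
  h <- hand_initial_flow()
  feed <- branch_segments(net, "feeding")
  prox <- branch_segments(net, "proximal")
  dist <- branch_segments(net, "distal")
  # per-segment pressure-drop magnitudes 6 / 4 / 2 Pa
  expect_equal(abs(fs$dp[feed]), rep(6, 5), tolerance = 1e-9)
  expect_equal(abs(fs$dp[prox]), rep(4, 10), tolerance = 1e-9)
  expect_equal(abs(fs$dp[dist]), rep(2, 20), tolerance = 1e-9)
  expect_equal(fs$q[feed[1]], h$q_in, tolerance = 1e-9)
  expect_equal(fs$q[feed[1]], 1.1057669e-13, tolerance = 1e-7)
  # wall shear: feeding ~1.91 Pa; feeding and proximal in the 1-5 Pa band
  expect_equal(fs$tau[feed[1]], h$tau(8, 6), tolerance = 1e-9)
  expect_equal(fs$tau[feed[1]], 1.909859, tolerance = 1e-6)
  expect_true(all(fs$tau[c(feed, prox)] > 1 & fs$tau[c(feed, prox)] < 5))
  expect_true(all(fs$tau[dist] < fs$tau[prox[1]]))
  # exact 2:1 shear ratio at the convergent bifurcation
  b <- net$convergent_branch_segments
  expect_equal(fs$tau[b[1]] / fs$tau[b[2]], 2, tolerance = 1e-12)
})

test_that("flow balance holds at interior nodes and q = -G dp per segment", {
  net <- ref_net()
  counts <- net$segments$n
  set.seed(11)
  counts[sample(40, 10)] <- sample(0:12, 10, replace = TRUE)
  fs <- solve_flow(with_counts(net, counts))
  expect_equal(fs$q, -fs$G * fs$dp)
  seg <- net$segments
  flow_in <- tapply(c(fs$q, -fs$q),
                    c(seg$downstream_node, seg$upstream_node), sum)
  interior <- setdiff(net$nodes, c(net$inlet_nodes, net$outlet_node))
  expect_lt(max(abs(flow_in[as.character(interior)])),
            1e-10 * max(abs(fs$q)))
})

test_that("no driving pressure gives an all-zero flow state", {
  p <- model_params(p_in = 0, p_out = 0)
  fs <- solve_flow(build_a_branch(p))
  expect_equal(max(abs(fs$q)), 0)
  expect_equal(max(fs$tau), 0)
})

test_that("removing cells from a branch raises its per-segment pressure drop", {
  net <- ref_net()
  b <- net$convergent_branch_segments
  dp0 <- abs(solve_flow(net)$dp[b[2]])
  counts <- net$segments$n
  counts[b[2]] <- 5L
  dp1 <- abs(solve_flow(with_counts(net, counts))$dp[b[2]])
  counts[b[2]] <- 2L
  dp2 <- abs(solve_flow(with_counts(net, counts))$dp[b[2]])
  expect_gt(dp1, dp0)
  expect_gt(dp2, dp1)
  # and tau is linear in n at fixed dp
  expect_equal(segment_wss(6, 5e-6, 1e-5, 2), 2 * segment_wss(3, 5e-6, 1e-5, 2))
})

test_that("prescribed inlet flow reproduces the pressure-driven state", {
  net <- ref_net()
  fsp <- solve_flow(net)
  fsf <- solve_flow(net, bc = flow_bc("inlet_flow", q_in = fsp$q[1],
                                      p_out = 0))
  expect_equal(fsf$p, fsp$p, tolerance = 1e-9)
  expect_equal(fsf$q, fsp$q, tolerance = 1e-9)
  expect_error(flow_bc("inlet_flow"), "q_in")
})

test_that("the long-distal variant has an exact 10:1 shear ratio at the bifurcation", {
  net10 <- build_a_branch(ref_params(), distal_multiplier = 10)
  fs <- solve_flow(net10)
  b <- net10$convergent_branch_segments
  expect_equal(fs$tau[b[1]] / fs$tau[b[2]], 10, tolerance = 1e-12)
})
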