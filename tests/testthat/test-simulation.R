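test_that("deterministic rules give the canonical regressions, bitwise repeatably", {
  net <- ref_net()
  tr1 <- run_simulation(net, rule_spec("BR1"))
  expect_true(tr1$loss$occurred)
  expect_identical(tr1$loss$lost_branch, "distal")
  expect_identical(tr1$loss$onset_step, 1L)   # starved segment empties at once
  tr1b <- run_simulation(net, rule_spec("BR1"))
  expect_identical(tr1$n, tr1b$n)
  tr2 <- run_simulation(net, rule_spec("BR2"))
  expect_true(tr2$loss$occurred)
  expect_identical(tr2$loss$lost_branch, "proximal")
})

test_that("the BR2 distal diameter trace oscillates with a ~30-step period", {
  # the surviving loop is 30 segments long and cells advance one per step,
  # so smoothing transients recur with that period
  net <- build_a_branch(model_params(duration_days = 28))
  tr <- run_simulation(net, rule_spec("BR2"))
  d <- mean_branch_diameter(tr, "distal")
  period <- oscillation_period(d$mean_diameter_m)
  expect_lt(abs(period - 30), 3)
})

test_that("stochastic runs reproduce bitwise from their seed and record time correctly", {
  net <- ref_net()
  rule <- rule_spec("BR5", alpha = 0.45)
  tr <- run_simulation(net, rule, seed = 123)
  tr_b <- run_simulation(net, rule, seed = 123)
  expect_identical(tr$n, tr_b$n)
  expect_identical(tr$probs, tr_b$probs)
  expect_equal(tr$time_hr, (0:43) * 10 / 3)
  # step 0 is the pre-migration initial state
  expect_identical(tr$n[1, ], rep(8L, 40))
  expect_error(run_simulation(net, rule), "seed")
})

test_that("BR5 probability records satisfy the normalisation invariants each step", {
  net <- ref_net()
  tr <- run_simulation(net, rule_spec("BR5", alpha = 0.45), seed = 5)
  pr <- probability_traces(tr)
  ok <- stats::complete.cases(pr)
  expect_true(any(ok))
  expect_equal(pr$P1[ok] + pr$P2[ok], rep(1, sum(ok)), tolerance = 1e-12)
  expect_equal(pr$P_tau1[ok] + pr$P_tau2[ok], rep(1, sum(ok)),
               tolerance = 1e-12)
  expect_equal(pr$P_n1[ok] + pr$P_n2[ok], rep(1, sum(ok)), tolerance = 1e-12)
  expect_equal(pr$P1[ok],
               0.45 * pr$P_tau1[ok] + 0.55 * pr$P_n1[ok], tolerance = 1e-12)
})

test_that("in lost runs the losing branch's probability hits 0 at or before loss", {
  net <- ref_net()
  seeds <- generate_seeds(5)
  for (s in seeds) {
    tr <- run_simulation(net, rule_spec("BR5", alpha = 1), seed = s)
    expect_true(tr$loss$occurred)   # shear-only runs always lose
    pr <- probability_traces(tr)
    upto <- pr[pr$step <= tr$loss$loss_step, ]
    p_lose <- if (tr$loss$lost_branch == "proximal") upto$P1 else upto$P2
    expect_lte(min(p_lose, na.rm = TRUE), 1e-12)
    expect_gte(max((1 - p_lose), na.rm = TRUE), 1 - 1e-12)
  }
})

test_that("loss events record branch, time and day bin consistently", {
  net <- ref_net()
  tr <- run_simulation(net, rule_spec("BR1"))
  le <- tr$loss
  expect_equal(le$loss_time_hr, le$loss_step * 10 / 3)
  expect_identical(le$day_bin, as.integer(ceiling(le$loss_time_hr / 24)))
  expect_lte(le$onset_step, le$loss_step)
  # loss state detection on constructed configurations
  dist <- branch_segments(net, "distal")
  lost_net <- with_counts(net, replace(net$segments$n, dist, 0L))
  det <- detect_bifurcation_loss(lost_net)
  expect_true(det$lost)
  expect_identical(det$lost_branch, "distal")
  # onset without loss: only the bifurcation segment empty
  onset_net <- with_counts(net, replace(net$segments$n,
                                        net$convergent_branch_segments[1], 0L))
  det2 <- detect_bifurcation_loss(onset_net)
  expect_false(det2$lost)
  expect_true(det2$onset)
  expect_identical(det2$onset_branch, "proximal")
  det3 <- detect_bifurcation_loss(net)
  expect_false(det3$lost)
  expect_false(det3$onset)
})

test_that("fixed-probability rules preserve the bifurcation across seeds", {
  net <- ref_net()
  seeds <- generate_seeds(10)
  final_prox <- final_dist <- matrix(NA_real_, length(seeds), 2)
  for (i in seq_along(seeds)) {
    tr3 <- run_simulation(net, rule_spec("BR3"), seed = seeds[i])
    expect_false(tr3$loss$occurred)
    d3p <- mean_branch_diameter(tr3, "proximal")$mean_diameter_m
    d3d <- mean_branch_diameter(tr3, "distal")$mean_diameter_m
    tr4 <- run_simulation(net, rule_spec("BR4"), seed = seeds[i])
    expect_false(tr4$loss$occurred)
    d4p <- mean_branch_diameter(tr4, "proximal")$mean_diameter_m
    d4d <- mean_branch_diameter(tr4, "distal")$mean_diameter_m
    last <- 30:44   # settled portion of the run
    final_prox[i, ] <- c(mean(d3p[last]), mean(d4p[last]))
    final_dist[i, ] <- c(mean(d3d[last]), mean(d4d[last]))
  }
  # BR3: no discernible diameter difference between branches (< 10%)
  expect_lt(abs(mean(final_prox[, 1]) - mean(final_dist[, 1])) /
              mean(final_dist[, 1]), 0.10)
  # BR4: the favoured high-flow proximal branch stabilises larger
  expect_gt(mean(final_prox[, 2]), mean(final_dist[, 2]))
})

test_that("Dirichlet cell conditions shrink the population monotonically", {
  net <- ref_net()
  tr <- run_simulation(net, rule_spec("BR5", alpha = 0.45),
                       bc = cell_bc("dirichlet", 8L), seed = 17)
  expect_true(all(diff(tr$total_cells) <= 0L))
  expect_lt(utils::tail(tr$total_cells, 1), 320L)
  # periodic counterpart conserves exactly
  trp <- run_simulation(net, rule_spec("BR5", alpha = 0.45), seed = 17)
  expect_true(all(trp$total_cells == 320L))
})

test_that("seed lists are uniform on [1, 1e9] and reproducible", {
  s1 <- generate_seeds(1000)
  s2 <- generate_seeds(1000)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 1 & s1 <= 1e9))
  expect_length(generate_seeds(1), 1L)
  expect_false(identical(generate_seeds(10, meta_seed = 1L),
                         generate_seeds(10, meta_seed = 2L)))
})
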