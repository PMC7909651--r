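test_that("mean branch diameter uses matched segment subsets", {
  net <- ref_net()
  tr <- run_simulation(net, rule_spec("BR1"))
  dp <- mean_branch_diameter(tr, "proximal")
  dd <- mean_branch_diameter(tr, "distal")
  # t = 0: both branches at n0 * w / pi
  expect_equal(dp$mean_diameter_m[1], 8 * 5e-6 / pi, tolerance = 1e-12)
  expect_equal(dd$mean_diameter_m[1], 8 * 5e-6 / pi, tolerance = 1e-12)
  # post-regression the dead distal branch reads zero
  expect_equal(utils::tail(dd$mean_diameter_m, 1), 0)
  expect_gt(utils::tail(dp$mean_diameter_m, 1), 0)
  expect_error(mean_branch_diameter(tr, "feeding"), "branch must be one of")
})

test_that("probability traces exist only for BR5", {
  net <- ref_net()
  tr1 <- run_simulation(net, rule_spec("BR1"))
  expect_error(probability_traces(tr1), "BR5")
  tr5 <- run_simulation(net, rule_spec("BR5", alpha = 0.45), seed = 2)
  pr <- probability_traces(tr5)
  expect_identical(nrow(pr), 43L)
})

test_that("cell number and pressure drop at the bifurcation anticorrelate", {
  net <- ref_net()
  # first preserved run from the shared seed list (stable bifurcation)
  seeds <- generate_seeds(30)
  tr <- NULL
  for (s in seeds) {
    cand <- run_simulation(net, rule_spec("BR5", alpha = 0.45), seed = s)
    if (!cand$loss$occurred) { tr <- cand; break }
  }
  expect_false(is.null(tr))
  pc <- pressure_cellnumber_traces(tr, "proximal")
  rho <- stats::cor(diff(pc$n), diff(pc$dp_Pa), method = "spearman")
  expect_lt(rho, 0)
  # constant-n interval implies constant dp: flow is deterministic in n
  runs <- rle(pc$n)
  if (any(runs$lengths >= 3)) {
    i <- which(runs$lengths >= 3)[1]
    idx <- (cumsum(runs$lengths)[i] - runs$lengths[i] + 1):cumsum(runs$lengths)[i]
    expect_lt(diff(range(pc$dp_Pa[idx])) , 1e-9 * max(pc$dp_Pa))
  }
  # shear and cell-number probability components alternate competitively
  pr <- probability_traces(tr)
  rho2 <- stats::cor(diff(pr$P_tau1), diff(pr$P_n1), method = "spearman")
  expect_lt(rho2, 0)
})

test_that("stable runs typically favour the high-flow branch at P1 ~ 0.6-0.7", {
  net <- ref_net()
  p1_means <- c()
  for (s in generate_seeds(60)) {
    tr <- run_simulation(net, rule_spec("BR5", alpha = 0.45), seed = s)
    if (!tr$loss$occurred) {
      pr <- probability_traces(tr)
      expect_gt(mean(pr$P1), mean(pr$P2))
      p1_means <- c(p1_means, mean(pr$P1))
      if (length(p1_means) >= 5L) break
    }
  }
  expect_length(p1_means, 5L)
  expect_gt(mean(p1_means), 0.55)
  expect_lt(mean(p1_means), 0.75)
})

test_that("sweeps produce monotone, well-normalised loss summaries", {
  net <- ref_net()
  sw <- alpha_sweep(net, c(0.2, 0.8), generate_seeds(15))
  expect_identical(nrow(sw), 30L)
  surf <- loss_surface(sw)
  for (a in unique(surf$alpha)) {
    f <- surf$fraction_lost[surf$alpha == a]
    expect_true(all(diff(f) >= 0))
    expect_true(all(f >= 0 & f <= 1))
  }
  ls <- loss_summary(sw)
  lost_rows <- ls[ls$n_lost > 0, ]
  if (nrow(lost_rows) > 0)
    expect_equal(lost_rows$frac_proximal + lost_rows$frac_distal,
                 rep(1, nrow(lost_rows)))
})

test_that("oscillation periods are recovered from synthetic traces", {
  x <- sin(2 * pi * (0:200) / 20)
  expect_equal(oscillation_period(x), 20, tolerance = 0.01)
  expect_true(is.na(oscillation_period(rep(1, 50))))
})

test_that("trajectory and sweep files round-trip through disk", {
  net <- ref_net()
  tr <- run_simulation(net, rule_spec("BR5", alpha = 0.45), seed = 3)
  d <- withr::local_tempdir()
  paths <- write_trajectory(tr, d, prefix = "t")
  expect_true(all(file.exists(paths)))
  long <- utils::read.csv(file.path(d, "t_trajectory.csv"))
  expect_identical(nrow(long), 44L * 40L)
  expect_equal(sum(long$n[long$time_hr == 0]), 320)
  meta <- jsonlite::read_json(file.path(d, "t_meta.json"))
  expect_identical(meta$rule, "BR5")
  sw <- alpha_sweep(net, 0.5, generate_seeds(4))
  sp <- write_sweep(sw, d)
  expect_true(all(file.exists(sp)))
})

test_that("config files build the requested geometry", {
  d <- withr::local_tempdir()
  cfg <- list(n0 = 8L, duration_days = 3,
              geometry = list(type = "a_branch", distal_multiplier = 10))
  jsonlite::write_json(cfg, file.path(d, "c.json"), auto_unbox = TRUE)
  got <- read_config(file.path(d, "c.json"))
  expect_identical(length(branch_segments(got$network, "distal")), 100L)
  expect_equal(got$params$duration_days, 3)
})
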