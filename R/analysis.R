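#' Ensemble sweep over the shear-cue weight alpha
#'
#' Runs the BR5 rule for every combination of `alphas` and `seeds` on
#' (copies of) the supplied network, reusing the identical seed list for
#' every alpha so ensembles are paired. Each run records whether and when
#' the flow-convergent bifurcation was lost and which branch regressed.
#'
#' @param network A `"vessel_network"` initial state.
#' @param alphas Numeric vector of weights in `[0, 1]`.
#' @param seeds Integer vector of RNG seeds (see [generate_seeds()]).
#' @param bc A [cell_bc()].
#' @param flow_conditions A [flow_bc()]; defaults to the network's drive.
#' @param duration_days Simulated days per run.
#' @return An object of class `"sweep_result"`: a data frame with one row
#'   per (alpha, seed): `alpha`, `seed`, `occurred`, `loss_step`,
#'   `loss_time_hr`, `lost_branch`, `day_bin`, `onset_step`, plus
#'   attributes `dt`, `steps`, `branch_names`.
#' @examples
#' \donttest{
#' net <- build_a_branch(model_params())
#' sw <- alpha_sweep(net, c(0, 0.45, 1), generate_seeds(20))
#' loss_summary(sw)
#' }
#' @export
alpha_sweep <- function(network, alphas, seeds, bc = cell_bc("periodic"),
                        flow_conditions = default_bc(network),
                        duration_days = network$params$duration_days) {
  stopifnot(length(alphas) >= 1L, length(seeds) >= 1L,
            all(alphas >= 0), all(alphas <= 1))
  rows <- vector("list", length(alphas) * length(seeds))
  k <- 0L
  dt <- network$params$dt
  steps <- n_steps(network$params, duration_days)
  bn <- NULL
  for (a in alphas) {
    rule <- rule_spec("BR5", alpha = a)
    for (s in seeds) {
      tr <- run_simulation(network, rule, bc = bc,
                           flow_conditions = flow_conditions,
                           duration_days = duration_days, seed = s,
                           record = "loss")
      if (is.null(bn)) bn <- tr$meta$branch_names
      le <- tr$loss
      k <- k + 1L
      rows[[k]] <- data.frame(
        alpha = a, seed = s, occurred = le$occurred,
        loss_step = le$loss_step, loss_time_hr = le$loss_time_hr,
        lost_branch = if (is.na(le$lost_branch)) NA_character_
          else le$lost_branch,
        day_bin = le$day_bin, onset_step = le$onset_step)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "dt") <- dt
  attr(out, "steps") <- steps
  attr(out, "branch_names") <- bn
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Per-alpha loss summary of a sweep
#'
#' @param sweep A `"sweep_result"`.
#' @return Data frame with one row per alpha: ensemble size `m`, `n_lost`,
#'   `fraction_lost`, attribution fractions over lost runs
#'   (`frac_branch1`/`frac_branch2`, with simultaneous losses counted
#'   half-half), and the modal loss day bin.
#' @export
loss_summary <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  bn <- attr(sweep, "branch_names")
  out <- lapply(split(sweep, sweep$alpha), function(d) {
    lost <- d[d$occurred, , drop = FALSE]
    nl <- nrow(lost)
    w1 <- sum(lost$lost_branch == bn[1]) + 0.5 * sum(lost$lost_branch == "both")
    data.frame(alpha = d$alpha[1], m = nrow(d), n_lost = nl,
               fraction_lost = nl / nrow(d),
               frac_branch1 = if (nl > 0) w1 / nl else NA_real_,
               frac_branch2 = if (nl > 0) 1 - w1 / nl else NA_real_,
               modal_day_bin = if (nl > 0)
                 as.integer(names(which.max(table(lost$day_bin))))
                 else NA_integer_)
  })
  out <- do.call(rbind, out)
  names(out)[names(out) == "frac_branch1"] <- paste0("frac_", bn[1])
  names(out)[names(out) == "frac_branch2"] <- paste0("frac_", bn[2])
  rownames(out) <- NULL
  out
}

#' Loss-fraction surface over time
#'
#' Cumulative fraction of runs with bifurcation loss by each time point,
#' per alpha. Non-decreasing in time for every alpha by construction.
#'
#' @param sweep A `"sweep_result"`.
#' @return Data frame: `alpha`, `step`, `time_hr`, `fraction_lost`.
#' @export
loss_surface <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  dt <- attr(sweep, "dt"); steps <- attr(sweep, "steps")
  out <- lapply(split(sweep, sweep$alpha), function(d) {
    frac <- vapply(seq_len(steps), function(t)
      mean(d$occurred & d$loss_step <= t, na.rm = TRUE), numeric(1))
    data.frame(alpha = d$alpha[1], step = seq_len(steps),
               time_hr = seq_len(steps) * dt, fraction_lost = frac)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Mean branch diameter trace
#'
#' Per-step mean lumen diameter over a fixed subset of the branch's
#' segments. The subset size is the same for both convergent branches (the
#' shorter branch's full length); for the longer branch the segments
#' adjacent to the flow-convergent bifurcation are used. In the default
#' A-branch this means all 10 proximal segments and the 10 distal segments
#' nearest the convergent node.
#'
#' @param trajectory A full-record `"ec_trajectory"`.
#' @param branch Branch label (one of the two convergent branches).
#' @return Data frame: `step` (0-based, step 0 = initial state), `time_hr`,
#'   `mean_diameter_m`.
#' @export
mean_branch_diameter <- function(trajectory, branch) {
  stopifnot(inherits(trajectory, "ec_trajectory"))
  if (is.null(trajectory$n))
    stop("trajectory was not recorded in full", call. = FALSE)
  net <- trajectory$network
  bn <- trajectory$meta$branch_names
  if (!branch %in% bn)
    stop("branch must be one of: ", paste(bn, collapse = ", "), call. = FALSE)
  segs1 <- branch_segments(net, bn[1])
  segs2 <- branch_segments(net, bn[2])
  k <- min(length(segs1), length(segs2))
  segs <- branch_segments(net, branch)
  segs <- utils::tail(segs, k)   # the k segments nearest the convergent node
  d <- lumen_diameter(trajectory$n[, segs, drop = FALSE], net$params$w)
  data.frame(step = seq_along(trajectory$time_hr) - 1L,
             time_hr = trajectory$time_hr,
             mean_diameter_m = rowMeans(d))
}

#' BR5 probability traces
#'
#' Per-step branch probabilities and their shear and cell-number
#' components at the flow-convergent bifurcation.
#'
#' @param trajectory An `"ec_trajectory"` produced with rule BR5.
#' @return Data frame: `step`, `time_hr`, `P1`, `P2`, `P_tau1`, `P_tau2`,
#'   `P_n1`, `P_n2`.
#' @export
probability_traces <- function(trajectory) {
  stopifnot(inherits(trajectory, "ec_trajectory"))
  if (is.null(trajectory$probs))
    stop("probability components are defined only for BR5 trajectories",
         call. = FALSE)
  trajectory$probs
}

#' Cell-number and pressure-drop traces at the bifurcation
#'
#' Per-step cell number and pressure-drop magnitude of one branch segment
#' incident to the flow-convergent node. Because segment resistance scales
#' as n^-4, drops in cell number appear as spikes in the pressure drop:
#' the two series are inversely related.
#'
#' @param trajectory A full-record `"ec_trajectory"`.
#' @param branch Branch label (one of the two convergent branches).
#' @return Data frame: `step`, `time_hr`, `n`, `dp_Pa`.
#' @export
pressure_cellnumber_traces <- function(trajectory, branch) {
  stopifnot(inherits(trajectory, "ec_trajectory"))
  if (is.null(trajectory$n))
    stop("trajectory was not recorded in full", call. = FALSE)
  bn <- trajectory$meta$branch_names
  if (!branch %in% bn)
    stop("branch must be one of: ", paste(bn, collapse = ", "), call. = FALSE)
  seg <- trajectory$network$convergent_branch_segments[match(branch, bn)]
  data.frame(step = seq_along(trajectory$time_hr) - 1L,
             time_hr = trajectory$time_hr,
             n = trajectory$n[, seg],
             dp_Pa = abs(trajectory$dp[, seg]))
}

#' Dominant oscillation period of a trace
#'
#' Mean peak-to-peak spacing of local maxima, in sampling steps, over the
#' supplied series (e.g. a mean-diameter trace).
#'
#' @param x Numeric series sampled once per step.
#' @param min_peak_distance Minimum spacing between accepted peaks
#'   (default 5 steps) to suppress single-step jitter.
#' @return Mean spacing between successive peaks, in steps (`NA` if fewer
#'   than two peaks).
#' @export
oscillation_period <- function(x, min_peak_distance = 5) {
  pk <- pracma::findpeaks(as.numeric(x),
                          minpeakdistance = min_peak_distance)
  if (is.null(pk) || nrow(pk) < 2L) return(NA_real_)
  mean(diff(sort(pk[, 2])))
}
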