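#' Run one coupled flow-migration simulation
#'
#' Iterates the flow-migration loop: solve network flow for the current
#' cell configuration, record the state, advance every cell one segment
#' against flow (applying the bifurcation rule and cell boundary
#' condition), then update diameters and repeat in the new flow
#' environment. The number of steps is `floor(duration_days * 24 / dt)`
#' (43 for the default 6 days).
#'
#' Bifurcation loss is monitored after every step: the run records both the
#' regression onset (the first step at which either branch segment incident
#' to the flow-convergent node holds zero cells) and the bifurcation loss
#' proper (the first step at which an entire branch holds zero cells, i.e.
#' the network has collapsed to a single flow path). Once a branch segment
#' at the bifurcation empties, both of its probability components vanish,
#' so no further cells enter and complete drainage of that branch follows;
#' the loss event therefore fires a branch-transit time after onset. The
#' simulation continues after loss.
#'
#' @param network A `"vessel_network"` (its current counts are the initial
#'   condition; the builder seeds `n0` everywhere).
#' @param rule A [rule_spec()].
#' @param bc A [cell_bc()] (default periodic).
#' @param flow_conditions A [flow_bc()]; defaults to the network's recorded
#'   drive.
#' @param duration_days Simulated days (default from the network's params).
#' @param seed Integer seed for the run's RNG stream; required for the
#'   stochastic rules BR3-BR5, ignored by BR1/BR2.
#' @param record `"full"` records per-step per-segment state (n, q, dp,
#'   tau); `"loss"` records only totals, probabilities and loss events
#'   (used by ensemble sweeps).
#' @return An object of class `"ec_trajectory"`: list with `time_hr`,
#'   matrices `n`, `q`, `dp`, `tau` (step 0 = pre-migration initial state,
#'   one row per recorded step), `probs` (per-step BR5 probability
#'   decomposition, else `NULL`), `total_cells`, `loss` (a `"loss_event"`),
#'   `network` (final state) and `meta`.
#' @examples
#' net <- build_a_branch(model_params())
#' tr <- run_simulation(net, rule_spec("BR1"))
#' tr$loss$lost_branch   # "distal"
#' @export
run_simulation <- function(network, rule, bc = cell_bc("periodic"),
                           flow_conditions = default_bc(network),
                           duration_days = network$params$duration_days,
                           seed = NULL, record = c("full", "loss")) {
  stopifnot(inherits(network, "vessel_network"), inherits(rule, "rule_spec"),
            inherits(bc, "cell_bc"), inherits(flow_conditions, "flow_bc"))
  record <- match.arg(record)
  params <- network$params
  stochastic <- rule$rule_id %in% c("BR3", "BR4", "BR5")
  if (stochastic) {
    if (is.null(seed)) stop("stochastic rules need a seed", call. = FALSE)
    set.seed(seed)
  }
  steps <- n_steps(params, duration_days)
  topo <- compile_topology(network)
  n <- as.integer(network$segments$n)
  full <- record == "full"

  if (full) {
    n_mat <- matrix(0L, steps + 1L, topo$n_seg)
    q_mat <- dp_mat <- tau_mat <- matrix(0, steps + 1L, topo$n_seg)
  }
  probs_mat <- if (rule$rule_id == "BR5")
    matrix(NA_real_, steps, 6L,
           dimnames = list(NULL, c("P1", "P2", "P_tau1", "P_tau2",
                                   "P_n1", "P_n2"))) else NULL
  totals <- integer(steps + 1L)
  totals[1L] <- sum(n)

  onset_step <- NA_integer_; onset_branch <- NA_character_
  loss_step <- NA_integer_; lost_branch <- NA_character_

  for (t in seq_len(steps)) {
    G <- segment_conductance(n, params$w, params$mu, params$l_seg)
    fs <- flow_solve_core(topo$up, topo$dn, G, topo$n_node,
                          topo$inlet_nodes, topo$outlet_node,
                          flow_conditions)
    tau <- segment_wss(n, params$w, params$l_seg, fs$dp)
    if (full) {
      n_mat[t, ] <- n; q_mat[t, ] <- fs$q
      dp_mat[t, ] <- fs$dp; tau_mat[t, ] <- tau
    }
    st <- migrate_core(n, topo, fs$q, tau, fs$dp, rule, bc)
    n <- st$n
    totals[t + 1L] <- sum(n)
    if (bc$kind == "periodic" && totals[t + 1L] != totals[1L])
      stop("cell conservation violated under periodic boundary conditions",
           call. = FALSE)
    if (!is.null(probs_mat) && !is.null(st$probs))
      probs_mat[t, ] <- unlist(st$probs[colnames(probs_mat)])
    if (is.na(onset_step) && (n[topo$b1] == 0L || n[topo$b2] == 0L)) {
      onset_step <- t
      onset_branch <- if (n[topo$b1] == 0L && n[topo$b2] == 0L) "both"
        else if (n[topo$b1] == 0L) topo$branch_names[1]
        else topo$branch_names[2]
    }
    if (is.na(loss_step)) {
      z1 <- sum(n[topo$branch1_segs]) == 0L
      z2 <- sum(n[topo$branch2_segs]) == 0L
      if (z1 || z2) {
        loss_step <- t
        lost_branch <- if (z1 && z2) "both"
          else if (z1) topo$branch_names[1] else topo$branch_names[2]
      }
    }
  }
  # final pre-step-like record of the end state
  if (full) {
    G <- segment_conductance(n, params$w, params$mu, params$l_seg)
    fs <- flow_solve_core(topo$up, topo$dn, G, topo$n_node,
                          topo$inlet_nodes, topo$outlet_node, flow_conditions)
    n_mat[steps + 1L, ] <- n; q_mat[steps + 1L, ] <- fs$q
    dp_mat[steps + 1L, ] <- fs$dp
    tau_mat[steps + 1L, ] <- segment_wss(n, params$w, params$l_seg, fs$dp)
  }

  loss <- loss_event(loss_step, lost_branch, onset_step, onset_branch,
                     params$dt)
  network$segments$n <- n
  probs <- if (!is.null(probs_mat))
    data.frame(step = seq_len(steps),
               time_hr = seq_len(steps) * params$dt, probs_mat) else NULL
  structure(list(
    time_hr = (0:steps) * params$dt,
    n = if (full) n_mat else NULL,
    q = if (full) q_mat else NULL,
    dp = if (full) dp_mat else NULL,
    tau = if (full) tau_mat else NULL,
    probs = probs,
    total_cells = totals,
    loss = loss,
    network = network,
    meta = list(rule = rule$rule_id, alpha = rule$alpha,
                fixed_p1 = rule$fixed_p1, seed = seed,
                geometry = network$geometry, cell_bc = bc$kind,
                n_fixed = bc$n_fixed, flow_bc = flow_conditions$kind,
                duration_days = duration_days, dt = params$dt,
                steps = steps, branch_names = topo$branch_names)
  ), class = "ec_trajectory")
}

loss_event <- function(loss_step, lost_branch, onset_step, onset_branch, dt) {
  occurred <- !is.na(loss_step)
  structure(list(
    occurred = occurred,
    loss_step = loss_step,
    loss_time_hr = if (occurred) loss_step * dt else NA_real_,
    lost_branch = lost_branch,
    day_bin = if (occurred) as.integer(ceiling(loss_step * dt / 24))
              else NA_integer_,
    onset_step = onset_step,
    onset_time_hr = if (!is.na(onset_step)) onset_step * dt else NA_real_,
    onset_branch = onset_branch
  ), class = "loss_event")
}

#' @export
print.loss_event <- function(x, ...) {
  if (!x$occurred) cat("bifurcation preserved (no loss event)\n")
  else cat(sprintf("bifurcation lost: %s branch, step %d (%.1f hr, day %d); onset step %s\n",
                   x$lost_branch, x$loss_step, x$loss_time_hr, x$day_bin,
                   ifelse(is.na(x$onset_step), "-", x$onset_step)))
  invisible(x)
}

#' Bifurcation loss test on a network state
#'
#' The bifurcation is lost when the cell number of one of the two branches
#' at the flow-convergent bifurcation has dropped to zero, i.e. when that
#' branch's total cell count over all its segments is zero and the network
#' has collapsed to a single flow path. Also reports the regression onset
#' indicator: whether a branch segment incident to the convergent node is
#' currently empty.
#'
#' @param network A `"vessel_network"`.
#' @return A list: `lost` (logical), `lost_branch` (branch name, `"both"`
#'   if both, `NA` if none), `onset` (logical), `onset_branch`.
#' @export
detect_bifurcation_loss <- function(network) {
  topo <- compile_topology(network)
  n <- network$segments$n
  z1 <- sum(n[topo$branch1_segs]) == 0L
  z2 <- sum(n[topo$branch2_segs]) == 0L
  s1 <- n[topo$b1] == 0L; s2 <- n[topo$b2] == 0L
  list(
    lost = z1 || z2,
    lost_branch = if (z1 && z2) "both" else if (z1) topo$branch_names[1]
      else if (z2) topo$branch_names[2] else NA_character_,
    onset = s1 || s2,
    onset_branch = if (s1 && s2) "both" else if (s1) topo$branch_names[1]
      else if (s2) topo$branch_names[2] else NA_character_
  )
}

#' Generate a reproducible ensemble seed list
#'
#' Draws `m` integers uniformly from 1 to 1e9 using a fixed meta-seed, so
#' the same list can be reused across every rule and alpha value of a
#' sweep. The draw uses (and therefore reseeds) the session RNG.
#'
#' @param m Number of seeds.
#' @param meta_seed Integer meta-seed (default 8191).
#' @return Integer vector of length `m` with values in `[1, 1e9]`.
#' @examples
#' generate_seeds(5)
#' @export
generate_seeds <- function(m, meta_seed = 8191L) {
  stopifnot(m >= 1)
  set.seed(meta_seed)
  sample.int(1e9L, m, replace = TRUE)
}

#' @export
print.ec_trajectory <- function(x, ...) {
  cat(sprintf("<ec_trajectory> %s%s, %d steps (%.1f days), %s cell BC\n",
              x$meta$rule,
              if (!is.null(x$meta$alpha)) sprintf(" (alpha = %g)", x$meta$alpha)
              else "",
              x$meta$steps, x$meta$duration_days, x$meta$cell_bc))
  print(x$loss)
  invisible(x)
}
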