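#' Cell boundary condition
#'
#' Governs what happens to cells that migrate out of the network at an
#' inlet. Under the periodic condition they re-enter at the outlet the same
#' step, so the total cell count is conserved exactly. Under the Dirichlet
#' condition at most `n_fixed` cells enter at the outlet per step (fewer if
#' fewer exited); surplus exiting cells are removed, so the total count can
#' only stay level or decrease.
#'
#' @param kind `"periodic"` or `"dirichlet"`.
#' @param n_fixed Cells admitted at the outlet per step under the Dirichlet
#'   condition (default 8, the initial per-segment seeding).
#' @return An object of class `"cell_bc"`.
#' @export
cell_bc <- function(kind = c("periodic", "dirichlet"), n_fixed = 8L) {
  kind <- match.arg(kind)
  if (n_fixed < 0) stop("n_fixed must be >= 0", call. = FALSE)
  structure(list(kind = kind, n_fixed = as.integer(n_fixed)),
            class = "cell_bc")
}

# threshold below which a segment's flow is treated as zero for migration
Q_ZERO <- 1e-30

# Pre-resolve the network into plain vectors for the simulation hot path.
compile_topology <- function(network) {
  seg <- network$segments
  bif <- c(network$divergent_node, network$convergent_node)
  bif <- bif[!is.na(bif)]
  exempt <- seg$upstream_node %in% bif | seg$downstream_node %in% bif
  labels <- unique(seg$branch_label)
  branch_pair <- seg$branch_label[network$convergent_branch_segments]
  list(up = seg$upstream_node, dn = seg$downstream_node,
       n_seg = nrow(seg), n_node = length(network$nodes),
       inlet_nodes = network$inlet_nodes, outlet_node = network$outlet_node,
       b1 = network$convergent_branch_segments[1],
       b2 = network$convergent_branch_segments[2],
       theta1 = seg$theta[network$convergent_branch_segments[1]],
       theta2 = seg$theta[network$convergent_branch_segments[2]],
       decision = network$decision_segment,
       outlet_segment = network$outlet_segment,
       exempt = exempt,
       branch1_segs = which(seg$branch_label == branch_pair[1]),
       branch2_segs = which(seg$branch_label == branch_pair[2]),
       branch_names = branch_pair)
}

# One synchronous migration step on raw vectors. All destinations are
# computed from the pre-step state, then applied at once. Stochastic draws
# (one uniform per cell deciding at the convergent bifurcation) are taken
# from the caller's RNG stream; intercalation retention consumes no
# randomness because cells are interchangeable counts.
migrate_core <- function(n, topo, q, tau, dp, rule, bc) {
  into_node <- ifelse(q > Q_ZERO, topo$dn, ifelse(q < -Q_ZERO, topo$up, NA))
  exit_node <- ifelse(q > Q_ZERO, topo$up, ifelse(q < -Q_ZERO, topo$dn, NA))

  outgoing <- integer(topo$n_seg)
  incoming <- integer(topo$n_seg)
  dest <- integer(topo$n_seg)          # unique destination; 0 none, -1 exit
  exited <- 0L
  probs <- NULL
  k_b1 <- 0L; k_b2 <- 0L

  for (s in seq_len(topo$n_seg)) {
    if (n[s] == 0L || is.na(exit_node[s])) next
    e <- exit_node[s]
    cand <- which(into_node == e)
    cand <- cand[cand != s]
    if (length(cand) == 0L) {
      if (e %in% topo$inlet_nodes) {
        outgoing[s] <- n[s]; dest[s] <- -1L; exited <- exited + n[s]
      }
      next
    }
    if (length(cand) == 1L) {
      outgoing[s] <- n[s]; dest[s] <- cand
      incoming[cand] <- incoming[cand] + n[s]
      next
    }
    # two upstream paths: the flow-convergent bifurcation decision
    if (!setequal(cand, c(topo$b1, topo$b2)))
      stop("unexpected multi-way migration junction", call. = FALSE)
    k <- n[s]
    dec <- decide_branch(k, n, topo, tau, dp, rule)
    probs <- dec$probs
    k_b1 <- dec$k1; k_b2 <- k - dec$k1
    outgoing[s] <- k
    incoming[topo$b1] <- incoming[topo$b1] + k_b1
    incoming[topo$b2] <- incoming[topo$b2] + k_b2
  }

  # cells exiting at an inlet are routed to the outlet segment
  entered <- if (bc$kind == "periodic") exited else min(exited, bc$n_fixed)
  incoming[topo$outlet_segment] <- incoming[topo$outlet_segment] + entered

  # intercalation smoothing: away from bifurcations, a segment whose efflux
  # exceeds its (positive) influx keeps one cell back this step
  retained <- integer(topo$n_seg)
  for (s in which(!topo$exempt)) {
    if (outgoing[s] > incoming[s] && incoming[s] > 0L) {
      retained[s] <- 1L
      outgoing[s] <- outgoing[s] - 1L
      if (dest[s] > 0L) {
        incoming[dest[s]] <- incoming[dest[s]] - 1L
      } else if (dest[s] == -1L) {
        exited <- exited - 1L
        ent2 <- if (bc$kind == "periodic") exited else min(exited, bc$n_fixed)
        incoming[topo$outlet_segment] <-
          incoming[topo$outlet_segment] - (entered - ent2)
        entered <- ent2
      }
    }
  }

  n_new <- n - outgoing + incoming
  if (any(n_new < 0L))
    stop("negative cell count after migration step", call. = FALSE)
  list(n = n_new, probs = probs, exited = exited, entered = entered,
       retained = retained, branch_counts = c(k_b1, k_b2))
}

# branch assignment for the k cells crossing the convergent bifurcation
decide_branch <- function(k, n, topo, tau, dp, rule) {
  t1 <- tau[topo$b1]; t2 <- tau[topo$b2]
  n1 <- n[topo$b1]; n2 <- n[topo$b2]
  probs <- NULL
  if (rule$rule_id == "BR1") {
    k1 <- if (br1_choice(t1, t2) == 1L) k else 0L
  } else if (rule$rule_id == "BR2") {
    k1 <- if (br2_choice(topo$theta1, topo$theta2) == 1L) k else 0L
  } else {
    if (rule$rule_id == "BR5") {
      ptau <- shear_probability(t1, t2)
      # same ratio through the n*dp decomposition; must agree identically
      wsum <- n1 * abs(dp[topo$b1]) + n2 * abs(dp[topo$b2])
      if (wsum > 0 &&
          abs(ptau[1] - n1 * abs(dp[topo$b1]) / wsum) > 1e-12)
        stop("shear-ratio and n*dp decompositions disagree", call. = FALSE)
      pn <- if (n1 + n2 > 0L) number_probability(n1, n2) else c(0.5, 0.5)
      probs <- combined_probability(ptau, pn, rule$alpha)
      p1 <- probs$P1
    } else {
      p1 <- rule$fixed_p1
    }
    k1 <- if (k > 0L) sum(stats::runif(k) < p1) else 0L
  }
  list(k1 = as.integer(k1), probs = probs)
}

#' Per-segment migration destinations
#'
#' Maps each segment to the segment(s) its cells will move into this step,
#' given the current flow. Cells migrate against flow: a segment's cells
#' exit through the node its flow comes from, into the neighbouring
#' segment(s) whose flow enters that node. At the flow-convergent
#' bifurcation two such segments exist (the decision point); at an inlet
#' none does and cells leave the network (coded `0`); segments with no flow
#' hold their cells (empty vector).
#'
#' @param network A `"vessel_network"`.
#' @param flow A `"flow_state"` for the network's current configuration.
#' @return A list of length `n_seg`; element `s` is an integer vector of
#'   destination segment ids (length 2 at the decision segment), `0L` for
#'   exit at an inlet, or `integer(0)` if the segment's cells hold.
#' @export
migration_directions <- function(network, flow) {
  stopifnot(inherits(network, "vessel_network"), inherits(flow, "flow_state"))
  topo <- compile_topology(network)
  q <- flow$q
  into_node <- ifelse(q > Q_ZERO, topo$dn, ifelse(q < -Q_ZERO, topo$up, NA))
  exit_node <- ifelse(q > Q_ZERO, topo$up, ifelse(q < -Q_ZERO, topo$dn, NA))
  out <- vector("list", topo$n_seg)
  for (s in seq_len(topo$n_seg)) {
    if (is.na(exit_node[s])) { out[[s]] <- integer(0); next }
    cand <- which(into_node == exit_node[s])
    cand <- cand[cand != s]
    out[[s]] <- if (length(cand) == 0L) {
      if (exit_node[s] %in% topo$inlet_nodes) 0L else integer(0)
    } else cand
  }
  out
}

#' Advance all cells one migration step
#'
#' Moves every cell one segment against the local flow direction,
#' synchronously from the pre-step state: ordinary segments pass all their
#' cells to the single upstream neighbour; cells in the segment downstream
#' of the flow-convergent bifurcation each choose a branch according to
#' `rule`; cells of both branches merge into the feeding side at the
#' flow-divergent bifurcation; cells exiting at an inlet are routed by the
#' cell boundary condition. Intercalation smoothing then retains one cell
#' in any segment away from the bifurcations whose efflux exceeds its
#' positive influx.
#'
#' Stochastic rules consume the R session RNG (seed it, e.g. via
#' [run_simulation()], for reproducibility): one uniform draw per deciding
#' cell, in segment order. Retention consumes no randomness since cells are
#' interchangeable.
#'
#' @param network A `"vessel_network"`.
#' @param flow A `"flow_state"` solved for the network's current counts.
#' @param rule A [rule_spec()].
#' @param bc A [cell_bc()] (default periodic).
#' @return A list: `network` (updated counts), `probs` (the step's
#'   [combined_probability()] record for BR5, else `NULL`), `exited`,
#'   `entered`, `retained` (per-segment 0/1), `branch_counts` (cells sent
#'   into branch 1 and branch 2 this step).
#' @examples
#' net <- build_a_branch(model_params())
#' fs <- solve_flow(net)
#' st <- step_migrate(net, fs, rule_spec("BR1"))
#' total_cells(st$network)   # 320, conserved
#' @export
step_migrate <- function(network, flow, rule, bc = cell_bc("periodic")) {
  stopifnot(inherits(network, "vessel_network"), inherits(flow, "flow_state"),
            inherits(rule, "rule_spec"), inherits(bc, "cell_bc"))
  topo <- compile_topology(network)
  res <- migrate_core(network$segments$n, topo, flow$q, flow$tau, flow$dp,
                      rule, bc)
  network$segments$n <- res$n
  res$network <- network
  res[c("network", "probs", "exited", "entered", "retained", "branch_counts")]
}

#' Intercalation retention rule
#'
#' During a migration step a segment keeps one cell back iff the number of
#' cells leaving exceeds the number arriving and the number arriving is
#' positive; this smooths sharp diameter fluctuations. It is not applied to
#' segments incident to a bifurcation node.
#'
#' @param outgoing,incoming Planned per-step counts for one segment.
#' @return `0L` or `1L`.
#' @export
intercalation_retention <- function(outgoing, incoming) {
  stopifnot(outgoing >= 0, incoming >= 0)
  if (outgoing > incoming && incoming > 0) 1L else 0L
}
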