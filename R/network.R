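#' Build the A-branch vessel network
#'
#' Constructs the idealised remodelling geometry: a feeding vessel that
#' splits at a flow-divergent bifurcation into a short proximal branch and a
#' longer distal branch, which rejoin at a flow-convergent bifurcation into
#' a draining vessel. The unequal path lengths create an initial wall-shear
#' difference at the convergent bifurcation, which is where migrating cells
#' must choose between two upstream paths.
#'
#' Segment allocation keeps the feeding and draining vessels at 5 segments
#' and the proximal branch at 10; the distal branch has
#' `10 * distal_multiplier / 2` segments... more precisely the distal branch
#' is `distal_multiplier` times the proximal length, i.e. `10 *
#' distal_multiplier` segments for multipliers beyond the default. For the
#' default `distal_multiplier = 2` this yields the reference 5/10/20/5
#' allocation: 40 segments whose distal round-trip path (feeding + distal +
#' draining) is 30 segments long.
#'
#' Segments are directed along the initial flow direction; "upstream" and
#' "downstream" refer to flow at time zero. Each segment starts with
#' `params$n0` cells. Branch angles are defined only for the two branch
#' segments meeting the convergent node: the proximal branch joins at
#' -pi/2 (a sharp turn for cells arriving from the draining vessel) and the
#' distal branch at 0 (straight ahead).
#'
#' Node bookkeeping: `n_node` reports `n_seg + 1` following the per-vessel
#' chain convention in which the convergent junction that closes the
#' proximal/distal loop is counted at both of its chain ends; the network
#' graph itself has `length(nodes)` distinct junctions (one fewer), and the
#' pressure system is assembled and solved on those.
#'
#' @param params An [model_params()] object.
#' @param distal_multiplier Length of the distal branch relative to the
#'   proximal branch; an integer >= 2. The reference geometry uses 2; the
#'   long-distal variant uses 10.
#' @return An object of class `"vessel_network"`.
#' @examples
#' net <- build_a_branch(model_params())
#' nrow(net$segments)     # 40
#' sum(net$segments$n)    # 320
#' @seealso [build_y_branch()], [branch_segments()], [solve_flow()]
#' @export
build_a_branch <- function(params = model_params(), distal_multiplier = 2L) {
  stopifnot(inherits(params, "ec_params"))
  m <- distal_multiplier
  if (length(m) != 1L || m < 2 || m != round(m))
    stop("distal_multiplier must be an integer >= 2", call. = FALSE)
  m <- as.integer(m)

  n_feed <- 5L; n_prox <- 10L; n_dist <- 10L * m; n_drain <- 5L
  n_seg <- n_feed + n_prox + n_dist + n_drain
  if (m == 2L && n_seg != params$n_seg)
    stop("params$n_seg inconsistent with the 5/10/20/5 allocation",
         call. = FALSE)

  up <- integer(n_seg); dn <- integer(n_seg)
  lab <- character(n_seg)

  # feeding chain: nodes 1..6; node 1 is the inlet, node 6 the divergent node
  for (i in 1:n_feed) { s <- i; up[s] <- i; dn[s] <- i + 1L; lab[s] <- "feeding" }
  div_node <- n_feed + 1L
  conv_node <- div_node + n_prox              # 16 in the default geometry
  for (i in 1:n_prox) {
    s <- n_feed + i
    up[s] <- if (i == 1L) div_node else div_node + i - 1L
    dn[s] <- if (i == n_prox) conv_node else div_node + i
    lab[s] <- "proximal"
  }
  for (i in 1:n_dist) {
    s <- n_feed + n_prox + i
    up[s] <- if (i == 1L) div_node else conv_node + i - 1L
    dn[s] <- if (i == n_dist) conv_node else conv_node + i
    lab[s] <- "distal"
  }
  drain0 <- conv_node + n_dist - 1L           # last distal interior node id
  for (i in 1:n_drain) {
    s <- n_feed + n_prox + n_dist + i
    up[s] <- if (i == 1L) conv_node else drain0 + i - 1L
    dn[s] <- drain0 + i
    lab[s] <- "draining"
  }
  n_distinct <- drain0 + n_drain

  theta <- rep(NA_real_, n_seg)
  b1 <- n_feed + n_prox                        # proximal segment at conv node
  b2 <- n_feed + n_prox + n_dist               # distal segment at conv node
  theta[b1] <- -pi / 2
  theta[b2] <- 0

  segments <- data.frame(
    id = seq_len(n_seg), upstream_node = up, downstream_node = dn,
    branch_label = lab, theta = theta, n = rep(params$n0, n_seg))

  net <- structure(list(
    segments = segments,
    nodes = seq_len(n_distinct),
    n_node = n_seg + 1L,
    inlet_nodes = 1L,
    outlet_node = n_distinct,
    divergent_node = div_node,
    convergent_node = conv_node,
    convergent_branch_segments = c(b1, b2),
    decision_segment = n_feed + n_prox + n_dist + 1L,
    outlet_segment = n_seg,
    geometry = list(type = "a_branch", distal_multiplier = m),
    params = params
  ), class = "vessel_network")
  validate_network(net)
  net
}

#' Build the Y-branch vessel network
#'
#' Constructs a two-inlet, one-outlet wye: a left and a right branch of
#' equal length converge at a single flow-convergent node into a stem that
#' drains to the outlet. Unlike the A-branch, there is no flow-divergent
#' bifurcation, and the initial shear difference at the convergent node is
#' set directly through the boundary conditions rather than through a path
#' length asymmetry.
#'
#' With `inlet_flow_ratio = 1` the network carries equal-pressure inlet
#' boundary conditions (`params$p_in` at both inlets), which gives equal
#' initial wall shear in the two branches. For any other ratio the network
#' records prescribed inlet flows in the ratio `inlet_flow_ratio : 1`
#' (left : right), with the total inflow matched to the equal-pressure
#' solution of the same geometry, so the initial shear ratio between the
#' branches equals the flow ratio.
#'
#' @param params An [model_params()] object.
#' @param inlet_flow_ratio Positive real; ratio of left-branch to
#'   right-branch inlet flow.
#' @param branch_len Segments per branch (default 10).
#' @param stem_len Segments in the draining stem (default 10).
#' @return An object of class `"vessel_network"`.
#' @examples
#' y <- build_y_branch(model_params())
#' y$geometry$type
#' @export
build_y_branch <- function(params = model_params(), inlet_flow_ratio = 1,
                           branch_len = 10L, stem_len = 10L) {
  stopifnot(inherits(params, "ec_params"))
  if (!is.numeric(inlet_flow_ratio) || length(inlet_flow_ratio) != 1L ||
      !(inlet_flow_ratio > 0))
    stop("inlet_flow_ratio must be a single positive number", call. = FALSE)
  nb <- as.integer(branch_len); nstem <- as.integer(stem_len)
  stopifnot(nb >= 1L, nstem >= 1L)
  n_seg <- 2L * nb + nstem

  up <- integer(n_seg); dn <- integer(n_seg); lab <- character(n_seg)
  # left branch: inlet node 1, interior 2..nb, convergent node nb+1
  conv_node <- nb + 1L
  for (i in 1:nb) {
    up[i] <- i; dn[i] <- i + 1L; lab[i] <- "left"
  }
  # right branch: inlet node nb+2, interior nodes nb+3.., ends at conv node
  r0 <- nb + 1L
  for (i in 1:nb) {
    s <- nb + i
    up[s] <- r0 + i
    dn[s] <- if (i == nb) conv_node else r0 + i + 1L
    lab[s] <- "right"
  }
  # stem: conv node -> outlet
  s0 <- r0 + nb
  for (i in 1:nstem) {
    s <- 2L * nb + i
    up[s] <- if (i == 1L) conv_node else s0 + i - 1L
    dn[s] <- s0 + i
    lab[s] <- "stem"
  }
  n_distinct <- s0 + nstem

  theta <- rep(NA_real_, n_seg)
  segments <- data.frame(
    id = seq_len(n_seg), upstream_node = up, downstream_node = dn,
    branch_label = lab, theta = theta, n = rep(params$n0, n_seg))

  net <- structure(list(
    segments = segments,
    nodes = seq_len(n_distinct),
    n_node = n_seg + 1L,
    inlet_nodes = c(1L, nb + 2L),
    outlet_node = n_distinct,
    divergent_node = NA_integer_,
    convergent_node = conv_node,
    convergent_branch_segments = c(nb, 2L * nb),   # (left, right) at the node
    decision_segment = 2L * nb + 1L,
    outlet_segment = n_seg,
    geometry = list(type = "y_branch", inlet_flow_ratio = inlet_flow_ratio,
                    branch_len = nb, stem_len = nstem),
    params = params
  ), class = "vessel_network")
  validate_network(net)
  net
}

validate_network <- function(net) {
  seg <- net$segments
  if (any(seg$n < 0) || any(seg$n != round(seg$n)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  if (any(seg$upstream_node == seg$downstream_node))
    stop("degenerate segment: identical end nodes", call. = FALSE)
  deg <- tabulate(c(seg$upstream_node, seg$downstream_node),
                  nbins = length(net$nodes))
  boundary <- c(net$inlet_nodes, net$outlet_node)
  interior <- setdiff(net$nodes, boundary)
  if (any(deg[interior] < 2L))
    stop("interior node with degree < 2", call. = FALSE)
  bif <- c(net$divergent_node, net$convergent_node)
  bif <- bif[!is.na(bif)]
  if (any(deg[bif] != 3L))
    stop("bifurcation nodes must have degree 3", call. = FALSE)
  invisible(net)
}

#' Segments of one branch, ordered along the initial flow
#'
#' @param network A `"vessel_network"`.
#' @param label A branch label present in the network (`"feeding"`,
#'   `"proximal"`, `"distal"`, `"draining"` for the A-branch; `"left"`,
#'   `"right"`, `"stem"` for the Y-branch).
#' @return Integer vector of segment ids, ordered upstream to downstream
#'   with respect to the flow direction at time zero.
#' @examples
#' branch_segments(build_a_branch(model_params()), "proximal")
#' @export
branch_segments <- function(network, label) {
  stopifnot(inherits(network, "vessel_network"))
  ids <- network$segments$id[network$segments$branch_label == label]
  if (length(ids) == 0L)
    stop("branch label '", label, "' not present in this network",
         call. = FALSE)
  ids   # builders emit segments in upstream-to-downstream order
}

#' Total number of cells in the network
#' @param network A `"vessel_network"`.
#' @return Integer total of per-segment cell counts.
#' @export
total_cells <- function(network) {
  sum(network$segments$n)
}

#' Network edge list
#'
#' @param network A `"vessel_network"`.
#' @return A data frame with one row per segment: `segment_id` (0-based),
#'   `upstream_node`, `downstream_node` (0-based), `branch_label`,
#'   `length_m`, `n_cells`.
#' @export
network_edgelist <- function(network) {
  seg <- network$segments
  data.frame(segment_id = seg$id - 1L,
             upstream_node = seg$upstream_node - 1L,
             downstream_node = seg$downstream_node - 1L,
             branch_label = seg$branch_label,
             length_m = network$params$l_seg,
             n_cells = seg$n)
}

#' @export
print.vessel_network <- function(x, ...) {
  tab <- table(x$segments$branch_label)
  cat(sprintf("<vessel_network: %s> %d segments, %d junction nodes, %d cells\n",
              x$geometry$type, nrow(x$segments), length(x$nodes),
              total_cells(x)))
  cat("  branches:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
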