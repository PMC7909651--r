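#' Lumen diameter from cell number
#'
#' The lumen is approximated in 3D by wrapping the `n` cells of a segment,
#' each of lateral width `w`, into the circumference of a circle, giving a
#' diameter of `n * w / pi`.
#'
#' @param n Cell count (vectorised, non-negative).
#' @param w Lateral cell width in metres.
#' @return Diameter in metres.
#' @examples
#' lumen_diameter(8, 5e-6)   # ~1.27e-5 m
#' @export
lumen_diameter <- function(n, w) {
  stopifnot(all(n >= 0), w > 0)
  n * w / pi
}

#' Segment conductance to flow
#'
#' Hagen-Poiseuille conductance of a cylindrical segment with the wrapped
#' lumen diameter: `G = n^4 w^4 / (128 pi^3 mu l_seg)`. A segment with zero
#' cells has no lumen; its conductance is pinned to the floor value 1e-25
#' m^3/s/Pa so the nodal system stays invertible while carrying negligible
#' flow.
#'
#' @param n Cell count (vectorised, non-negative).
#' @param w Lateral cell width (m).
#' @param mu Dynamic viscosity (Pa s).
#' @param l_seg Segment length (m).
#' @return Conductance in m^3/s/Pa.
#' @examples
#' segment_conductance(8, 5e-6, 0.0035, 1e-5)
#' segment_conductance(0, 5e-6, 0.0035, 1e-5)   # floor, 1e-25
#' @export
segment_conductance <- function(n, w, mu, l_seg) {
  stopifnot(all(n >= 0), w > 0, mu > 0, l_seg > 0)
  g <- n^4 * w^4 / (128 * pi^3 * mu * l_seg)
  g[n == 0] <- 1e-25
  g
}

#' Segment resistance to flow
#'
#' The reciprocal of [segment_conductance()] for segments with at least one
#' cell: `R = 128 pi^3 mu l_seg / (n^4 w^4)`.
#'
#' @inheritParams segment_conductance
#' @return Resistance in Pa s/m^3. Zero-cell segments have no finite
#'   resistance and raise an error; use the conductance floor instead.
#' @export
segment_resistance <- function(n, w, mu, l_seg) {
  if (any(n == 0))
    stop("resistance is infinite for an empty segment; ",
         "use segment_conductance(), which applies the floor", call. = FALSE)
  1 / segment_conductance(n, w, mu, l_seg)
}

#' Wall shear stress on a segment
#'
#' Poiseuille wall shear stress with the wrapped lumen diameter `d = n w /
#' pi`: `tau = d |dp| / (4 l_seg) = n w |dp| / (4 pi l_seg)`. Returned as a
#' magnitude; flow direction is carried by the sign of `q`.
#'
#' @param n Cell count (vectorised).
#' @param w Lateral cell width (m).
#' @param l_seg Segment length (m).
#' @param dp Pressure difference across the segment (Pa); sign ignored.
#' @return Wall shear stress magnitude in Pa.
#' @export
segment_wss <- function(n, w, l_seg, dp) {
  stopifnot(all(n >= 0))
  n * w * abs(dp) / (4 * pi * l_seg)
}

#' Flow boundary conditions
#'
#' @param kind `"pressure"` (Dirichlet pressures at every inlet and the
#'   outlet) or `"inlet_flow"` (prescribed volumetric inflow at each inlet,
#'   pressure fixed at the outlet only).
#' @param p_in Inlet pressure(s), Pa; recycled across inlets. Ignored for
#'   `"inlet_flow"`.
#' @param p_out Outlet pressure, Pa.
#' @param q_in Prescribed inlet flow(s), m^3/s, one per inlet node; required
#'   for `"inlet_flow"`.
#' @return An object of class `"flow_bc"`.
#' @export
flow_bc <- function(kind = c("pressure", "inlet_flow"),
                    p_in = 100, p_out = 0, q_in = NULL) {
  kind <- match.arg(kind)
  if (kind == "inlet_flow") {
    if (is.null(q_in) || !all(is.finite(q_in)))
      stop("inlet_flow boundary conditions need finite q_in", call. = FALSE)
  }
  structure(list(kind = kind, p_in = p_in, p_out = p_out, q_in = q_in),
            class = "flow_bc")
}

# default boundary conditions for a network: pressure-driven from params,
# except the Y-branch with unequal inlet flows, which prescribes flows in
# the recorded ratio with total inflow matched to the equal-pressure case.
default_bc <- function(network) {
  params <- network$params
  geo <- network$geometry
  if (geo$type == "y_branch" && !isTRUE(all.equal(geo$inlet_flow_ratio, 1))) {
    eq <- build_y_branch(params, inlet_flow_ratio = 1,
                         branch_len = geo$branch_len, stem_len = geo$stem_len)
    fs <- solve_flow(eq, bc = flow_bc("pressure", params$p_in, params$p_out))
    q_tot <- sum(abs(fs$q[eq$segments$branch_label == "stem"][1]))
    r <- geo$inlet_flow_ratio
    q_in <- q_tot * c(r, 1) / (r + 1)
    flow_bc("inlet_flow", p_out = params$p_out, q_in = q_in)
  } else {
    flow_bc("pressure", p_in = params$p_in, p_out = params$p_out)
  }
}

#' Solve the network flow problem
#'
#' Assembles the nodal flow-balance system (conservation of mass at every
#' junction, flow related to pressure through each segment's conductance)
#' and solves it for the unknown nodal pressures. Per-segment flow is then
#' `q = -G * dp` with `dp = p_downstream - p_upstream`, so `q > 0` means
#' flow along the segment's stored orientation, and wall shear stress
#' follows from the lumen diameter.
#'
#' Pressure boundary conditions are imposed exactly by row substitution;
#' the inlet-flow variant replaces each inlet node's balance row with a
#' prescribed-source row while keeping the outlet pressure row. The system
#' is dense and small (tens of nodes) and is solved directly. Conservation
#' at interior nodes is asserted post hoc to 1e-10 relative.
#'
#' @param network A `"vessel_network"`; its current per-segment cell counts
#'   set the conductances.
#' @param bc A [flow_bc()]; defaults to the network's pressure drive (or its
#'   recorded inlet-flow ratio for the Y-branch variant).
#' @return An object of class `"flow_state"`: list with per-node `p` (Pa)
#'   and per-segment `q` (m^3/s), `dp` (Pa, downstream minus upstream),
#'   `tau` (Pa, magnitude) and `G` (m^3/s/Pa).
#' @examples
#' net <- build_a_branch(model_params())
#' fs <- solve_flow(net)
#' range(fs$tau)
#' @export
solve_flow <- function(network, bc = default_bc(network)) {
  stopifnot(inherits(network, "vessel_network"), inherits(bc, "flow_bc"))
  params <- network$params
  seg <- network$segments
  G <- segment_conductance(seg$n, params$w, params$mu, params$l_seg)
  fs <- flow_solve_core(seg$upstream_node, seg$downstream_node, G,
                        length(network$nodes), network$inlet_nodes,
                        network$outlet_node, bc)
  tau <- segment_wss(seg$n, params$w, params$l_seg, fs$dp)
  structure(list(p = fs$p, q = fs$q, dp = fs$dp, tau = tau, G = G, bc = bc),
            class = "flow_state")
}

# dense nodal solve on raw topology vectors (hot path, also used by the
# simulation engine). Conductances are normalised by their maximum so that
# substituted boundary rows are of comparable scale.
flow_solve_core <- function(up, dn, G, n_node, inlet_nodes, outlet_node, bc) {
  gmax <- max(G)
  Gs <- G / gmax
  L <- matrix(0, n_node, n_node)
  for (s in seq_along(G)) {
    i <- up[s]; j <- dn[s]
    L[i, i] <- L[i, i] + Gs[s]; L[j, j] <- L[j, j] + Gs[s]
    L[i, j] <- L[i, j] - Gs[s]; L[j, i] <- L[j, i] - Gs[s]
  }
  b <- numeric(n_node)
  if (bc$kind == "pressure") {
    p_in <- rep_len(bc$p_in, length(inlet_nodes))
    for (k in seq_along(inlet_nodes)) {
      i <- inlet_nodes[k]
      L[i, ] <- 0; L[i, i] <- 1; b[i] <- p_in[k]
    }
  } else {
    q_in <- rep_len(bc$q_in, length(inlet_nodes))
    # balance row kept, source term = prescribed inflow (scaled like L)
    b[inlet_nodes] <- q_in / gmax
  }
  L[outlet_node, ] <- 0; L[outlet_node, outlet_node] <- 1
  b[outlet_node] <- bc$p_out
  p <- solve(L, b)
  dp <- p[dn] - p[up]
  q <- -G * dp
  # post-hoc conservation assert at interior nodes
  bnd <- c(inlet_nodes, outlet_node)
  net_flow <- numeric(n_node)
  for (s in seq_along(G)) {
    net_flow[up[s]] <- net_flow[up[s]] - q[s]
    net_flow[dn[s]] <- net_flow[dn[s]] + q[s]
  }
  qscale <- max(abs(q), 1e-300)
  if (any(abs(net_flow[-bnd]) > 1e-10 * qscale))
    stop("flow balance violated beyond tolerance", call. = FALSE)
  list(p = p, q = q, dp = dp)
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf("<flow_state> %d nodes, %d segments\n", length(x$p),
              length(x$q)))
  cat(sprintf("  pressure range: %.4g .. %.4g Pa\n", min(x$p), max(x$p)))
  cat(sprintf("  |q| max: %.4g m^3/s, tau range: %.4g .. %.4g Pa\n",
              max(abs(x$q)), min(x$tau), max(x$tau)))
  invisible(x)
}
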