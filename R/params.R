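#' Model parameters
#'
#' Bundles the geometric, cellular, fluid and temporal constants of the
#' flow-migration model. The defaults are the reference configuration used
#' throughout: a 40-segment network of 10 um segments, 8 cells per segment,
#' cells 5 um wide migrating at 3 um/hr, blood treated as a Newtonian fluid
#' of viscosity 0.0035 Pa s, and a 100 Pa / 0 Pa pressure drive chosen so
#' that initial wall shear stress falls in the 1-5 Pa range reported for
#' remodelling capillary plexuses.
#'
#' The time step is tied to the discretisation: a cell must traverse exactly
#' one segment per step, so `v * dt == l_seg` is enforced. With the defaults,
#' 3 um/hr x 10/3 hr = 10 um.
#'
#' @param n_seg Number of vessel segments (default 40).
#' @param n_node Number of grid nodes, `n_seg + 1` by the per-vessel chain
#'   convention in which the loop-closure junction of the A-branch is counted
#'   at both of its chain ends; the number of distinct junctions in the
#'   assembled network can be smaller (see [build_a_branch()]).
#' @param l_seg Segment length in metres (default 10e-6).
#' @param n0 Initial number of cells per segment (default 8).
#' @param v Cell migration speed in metres per hour (default 3e-6).
#' @param w Lateral cell width in metres (default 5e-6).
#' @param dt Time step in hours (default 10/3).
#' @param p_in Inlet pressure in Pa (default 100).
#' @param p_out Outlet pressure in Pa (default 0).
#' @param mu Dynamic viscosity in Pa s (default 0.0035).
#' @param duration_days Simulated duration in days (default 6).
#'
#' @return An object of class `"ec_params"`: a named list of the validated
#'   parameters.
#' @examples
#' p <- model_params()
#' p$v * p$dt == p$l_seg   # one segment per step
#' @export
model_params <- function(n_seg = 40L, n_node = n_seg + 1L,
                         l_seg = 10e-6, n0 = 8L, v = 3e-6, w = 5e-6,
                         dt = 10 / 3, p_in = 100, p_out = 0,
                         mu = 0.0035, duration_days = 6) {
  p <- list(n_seg = as.integer(n_seg), n_node = as.integer(n_node),
            l_seg = l_seg, n0 = as.integer(n0), v = v, w = w, dt = dt,
            p_in = p_in, p_out = p_out, mu = mu,
            duration_days = duration_days)
  validate_params(p)
  class(p) <- "ec_params"
  p
}

validate_params <- function(p) {
  pos <- c("n_seg", "n_node", "l_seg", "v", "w", "dt", "mu", "duration_days")
  for (f in pos) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !(p[[f]] > 0))
      stop("parameter '", f, "' must be a single positive number",
           call. = FALSE)
  }
  if (p$n0 < 1L) stop("n0 must be at least 1", call. = FALSE)
  if (p$n_node != p$n_seg + 1L)
    stop("n_node must equal n_seg + 1", call. = FALSE)
  if (abs(p$v * p$dt - p$l_seg) > 1e-9 * p$l_seg)
    stop("v * dt must equal l_seg: cells traverse exactly one segment ",
         "per time step", call. = FALSE)
  invisible(p)
}

#' @export
print.ec_params <- function(x, ...) {
  cat("Flow-migration model parameters\n")
  cat(sprintf("  segments: %d (l_seg = %.3g m), cells/segment: %d (w = %.3g m)\n",
              x$n_seg, x$l_seg, x$n0, x$w))
  cat(sprintf("  v = %.3g m/hr, dt = %.4g hr, duration = %g days (%d steps)\n",
              x$v, x$dt, x$duration_days, n_steps(x)))
  cat(sprintf("  p_in = %g Pa, p_out = %g Pa, mu = %g Pa s\n",
              x$p_in, x$p_out, x$mu))
  invisible(x)
}

# number of migration steps in the configured duration
n_steps <- function(params, duration_days = params$duration_days) {
  as.integer(floor(duration_days * 24 / params$dt))
}
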