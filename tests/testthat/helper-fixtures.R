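# shared fixtures: the reference configuration and small helpers

ref_params <- function(...) model_params(...)

ref_net <- function() build_a_branch(ref_params())

# hand series-parallel reduction of the initial A-branch: all 40 segments
# carry equal resistance R_seg, so R_total = (5 + 10*20/(10+20) + 5) R_seg
# and the inlet flow is (p_in - p_out) / R_total.
hand_initial_flow <- function(params = ref_params()) {
  g_seg <- segment_conductance(params$n0, params$w, params$mu, params$l_seg)
  r_seg <- 1 / g_seg
  r_tot <- (5 + 10 * 20 / 30 + 5) * r_seg
  q_in <- (params$p_in - params$p_out) / r_tot
  dp_feed <- q_in * r_seg
  list(q_in = q_in, dp_feed = dp_feed,
       dp_prox = dp_feed * 2 / 3, dp_dist = dp_feed / 3,
       tau = function(n, dp) n * params$w * dp / (4 * pi * params$l_seg))
}

# set per-segment counts on a copy of a network
with_counts <- function(net, counts) {
  stopifnot(length(counts) == nrow(net$segments))
  net$segments$n <- as.integer(counts)
  net
}
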