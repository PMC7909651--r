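#' Bifurcation rule specification
#'
#' Selects the decision policy cells apply at the flow-convergent
#' bifurcation, where two upstream migration paths exist:
#'
#' * `BR1` — deterministic shear preference: take the branch with the larger
#'   wall shear stress.
#' * `BR2` — deterministic angle preference: take the branch requiring the
#'   smallest change of migration direction.
#' * `BR3` — fixed equal probabilities (`P1 = 0.5`).
#' * `BR4` — fixed unequal probabilities favouring the high-flow branch
#'   (`P1 = 0.7` by default).
#' * `BR5` — mechanistic stochastic rule: each branch's entry probability is
#'   the weighted average `P_i = alpha * P_tau_i + (1 - alpha) * P_n_i` of
#'   its share of the wall-shear-stress ratio and its share of the
#'   cell-number ratio at the bifurcation, recomputed every step from the
#'   current flow state.
#'
#' @param rule One of `"BR1"` to `"BR5"`.
#' @param fixed_p1 Branch-1 entry probability for `BR3`/`BR4` (defaults 0.5
#'   and 0.7).
#' @param alpha Shear-cue weight in `[0, 1]` for `BR5`.
#' @return An object of class `"rule_spec"`.
#' @examples
#' rule_spec("BR5", alpha = 0.45)
#' @export
rule_spec <- function(rule = c("BR1", "BR2", "BR3", "BR4", "BR5"),
                      fixed_p1 = NULL, alpha = NULL) {
  rule <- match.arg(rule)
  if (rule %in% c("BR3", "BR4")) {
    if (is.null(fixed_p1)) fixed_p1 <- if (rule == "BR3") 0.5 else 0.7
    if (fixed_p1 < 0 || fixed_p1 > 1)
      stop("fixed_p1 must lie in [0, 1]", call. = FALSE)
  } else fixed_p1 <- NULL
  if (rule == "BR5") {
    if (is.null(alpha))
      stop("BR5 requires alpha in [0, 1]", call. = FALSE)
    if (alpha < 0 || alpha > 1)
      stop("alpha must lie in [0, 1]", call. = FALSE)
  } else alpha <- NULL
  structure(list(rule_id = rule, fixed_p1 = fixed_p1, alpha = alpha),
            class = "rule_spec")
}

#' Deterministic shear-preference choice (BR1)
#'
#' Branch 1 iff its wall shear stress strictly exceeds branch 2's; ties fall
#' to branch 2 through the rule's else-clause.
#'
#' @param tau1,tau2 Wall shear stress (Pa, non-negative) of branches 1 and 2.
#' @return `1L` or `2L`.
#' @export
br1_choice <- function(tau1, tau2) {
  stopifnot(tau1 >= 0, tau2 >= 0)
  if (tau1 > tau2) 1L else 2L
}

#' Deterministic angle-preference choice (BR2)
#'
#' Cells take the branch requiring the least change of migration direction,
#' i.e. the smaller angle magnitude relative to the parent segment; ties
#' fall to branch 2. In the A-branch geometry the proximal branch joins at
#' -pi/2 and the distal branch at 0, so BR2 always selects the distal
#' branch.
#'
#' @param theta1,theta2 Branch angles (radians) relative to the parent
#'   segment; must be defined (non-missing).
#' @return `1L` or `2L`.
#' @export
br2_choice <- function(theta1, theta2) {
  if (is.na(theta1) || is.na(theta2))
    stop("branch angles are undefined for this bifurcation", call. = FALSE)
  if (abs(theta1) < abs(theta2)) 1L else 2L
}

#' Fixed-probability choice (BR3/BR4)
#'
#' @param p1 Probability of entering branch 1, in `[0, 1]`.
#' @param r Uniform draw in `[0, 1)`.
#' @return `1L` if `r < p1`, else `2L`.
#' @export
br_fixed_choice <- function(p1, r) {
  stopifnot(p1 >= 0, p1 <= 1, r >= 0, r < 1)
  if (r < p1) 1L else 2L
}

#' Shear-stress probability components
#'
#' Each branch's probability share due to shear is its contribution to the
#' wall-shear-stress ratio at the bifurcation: `P_tau_i = tau_i / (tau_1 +
#' tau_2)`. Because `tau_i` is proportional to `n_i * dp_i`, this equals the
#' ratio of the multiplicative combination of cell number and pressure drop
#' over the two branch segments. If both shears vanish (no flow) the cue is
#' uninformative and the components fall back to (0.5, 0.5).
#'
#' @param tau1,tau2 Wall shear stress (Pa, non-negative).
#' @return Numeric vector `c(P_tau1, P_tau2)` summing to 1.
#' @export
shear_probability <- function(tau1, tau2) {
  stopifnot(tau1 >= 0, tau2 >= 0)
  tot <- tau1 + tau2
  if (tot == 0) return(c(0.5, 0.5))
  c(tau1, tau2) / tot
}

#' Cell-number probability components
#'
#' Each branch's probability share due to collective attraction is its
#' contribution to the cell-number ratio of the two branch segments at the
#' bifurcation: `P_n_i = n_i / (n_1 + n_2)`.
#'
#' @param n1,n2 Cell counts (non-negative) of the two branch segments.
#' @return Numeric vector `c(P_n1, P_n2)` summing to 1.
#' @export
number_probability <- function(n1, n2) {
  stopifnot(n1 >= 0, n2 >= 0)
  tot <- n1 + n2
  if (tot == 0)
    stop("both branch segments are empty: the bifurcation is already lost",
         call. = FALSE)
  c(n1, n2) / tot
}

#' Combined branch-entry probabilities (BR5)
#'
#' Weighted average of the shear and cell-number components:
#' `P_i = alpha * P_tau_i + (1 - alpha) * P_n_i`. `alpha = 1` reduces to the
#' pure shear cue, `alpha = 0` to the pure collective cue.
#'
#' @param ptau Length-2 vector from [shear_probability()].
#' @param pn Length-2 vector from [number_probability()].
#' @param alpha Shear-cue weight in `[0, 1]`.
#' @return An object of class `"branch_probabilities"`: list with `P1`,
#'   `P2`, `P_tau1`, `P_tau2`, `P_n1`, `P_n2`, `alpha`.
#' @export
combined_probability <- function(ptau, pn, alpha) {
  stopifnot(length(ptau) == 2L, length(pn) == 2L,
            alpha >= 0, alpha <= 1,
            all(ptau >= 0), all(ptau <= 1), all(pn >= 0), all(pn <= 1),
            abs(sum(ptau) - 1) <= 1e-12, abs(sum(pn) - 1) <= 1e-12)
  p <- alpha * ptau + (1 - alpha) * pn
  structure(list(P1 = p[1], P2 = p[2],
                 P_tau1 = ptau[1], P_tau2 = ptau[2],
                 P_n1 = pn[1], P_n2 = pn[2], alpha = alpha),
            class = "branch_probabilities")
}

#' Stochastic branch choice under BR5
#'
#' Each cell reaching the bifurcation draws its own uniform number and
#' enters branch 1 iff `r < P1`.
#'
#' @param probs A `"branch_probabilities"` object.
#' @param r Uniform draw in `[0, 1)`.
#' @return `1L` or `2L`.
#' @export
br5_choice <- function(probs, r) {
  stopifnot(inherits(probs, "branch_probabilities"), r >= 0, r < 1)
  if (r < probs$P1) 1L else 2L
}

#' @export
print.branch_probabilities <- function(x, ...) {
  cat(sprintf("P1 = %.4f (tau %.4f, n %.4f), P2 = %.4f (tau %.4f, n %.4f), alpha = %.2f\n",
              x$P1, x$P_tau1, x$P_n1, x$P2, x$P_tau2, x$P_n2, x$alpha))
  invisible(x)
}
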