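# Limiting disjunctive power and the information / sample-size search.

#' Limiting disjunctive power of the single-stage test
#'
#' Probability that the selected arm's efficacy score statistic clears `u_E`
#' under efficacy effects `theta_E` in the limit where every arm's safety
#' effect grows without bound (all arms eligible, safety margin cleared
#' almost surely). The default `theta_E` is the sizing configuration: `K - 1`
#' arms at the minimum clinically important effect `delta0` and one arm at
#' the desirable effect `delta`. With `theta_E = 0` the value reduces to the
#' efficacy FWER criterion.
#'
#' @inheritParams limiting_efficacy_rejection
#' @param u_E Efficacy boundary on the score-statistic scale.
#' @param info_E Efficacy information per comparison.
#' @param theta_E Efficacy effect vector of length `K`.
#' @return An `rb_prob` (see [limiting_efficacy_rejection()]).
#' @examples
#' des <- rb_design()
#' limiting_power(14.466, des, info_E = 47.148)$value  # ~ 0.90
#' @export
limiting_power <- function(u_E, design, info_E,
                           theta_E = c(rep(design$delta0, design$K - 1), design$delta),
                           method = c("integration", "monte_carlo"),
                           reps = 1e5, seed = NULL) {
  stopifnot(inherits(design, "rb_design"), info_E > 0,
            length(theta_E) == design$K)
  method <- match.arg(method)
  if (method == "integration") {
    rb_prob(sum(eff_tail_by_arm(u_E, design, info_E, theta_E)), 0, method)
  } else {
    std <- draw_std_arms(design$K, design$rho, reps, seed)
    p <- mc_eff_tail(u_E, design, info_E, theta_E, std)
    rb_prob(p, sqrt(p * (1 - p) / reps), method)
  }
}

#' Solve the single-stage design: information level and sample size
#'
#' One-dimensional search for the common per-arm information level `I1*` at
#' which the limiting disjunctive power equals the design's target, with
#' stopping boundaries re-solved at every candidate information level so that
#' the FWER remains controlled throughout the search. The per-arm sample size
#' is then rounded up to a whole patient,
#' `n* = ceiling(2 max(sigma_E^2, sigma_S^2) I1*)`, and boundaries are
#' recomputed at the attained information `I_E = n*/(2 sigma_E^2)`,
#' `I_S = n*/(2 sigma_S^2)`; because power is increasing in information this
#' rounding is conservative.
#'
#' @param design An [rb_design()].
#' @param theta_E Efficacy configuration used for sizing; defaults to
#'   `(delta0, ..., delta0, delta)`.
#' @param power_tol Tolerance on the power scale for the information search.
#' @return An `"rb_design_solution"` list: `I_star` (common information
#'   solving the power equation), `n_unrounded` (`2 max(sigma^2) I_star`),
#'   `n_star` (rounded-up integer), `boundaries_at_I_star`, `boundaries`
#'   (at the rounded sample size), and `attained_power` (integration route,
#'   at the rounded sample size).
#' @examples
#' \donttest{
#' sol <- solve_information(rb_design())
#' sol  # I1* ~ 47.14, n ~ 94.3, u_E = u_S ~ 14.46
#' }
#' @export
solve_information <- function(design,
                              theta_E = c(rep(design$delta0, design$K - 1), design$delta),
                              power_tol = 1e-6) {
  stopifnot(inherits(design, "rb_design"), length(theta_E) == design$K)
  target <- 1 - design$beta
  # classical one-arm fixed-sample information as a bracket anchor
  I0 <- ((stats::qnorm(1 - design$alpha) + stats::qnorm(target)) /
           max(design$delta, 1e-8))^2
  # the power criterion involves only the efficacy boundary, so the safety
  # search is deferred until the information level is fixed
  theta0 <- rep(0, design$K)
  pw <- function(I) {
    u_E <- root_expand(function(u) sum(eff_tail_by_arm(u, design, I, theta0)) -
                         design$alpha,
                       lo = -sqrt(I), hi = 3 * sqrt(I), max_hi = 300 * sqrt(I),
                       tol = 1e-8)
    sum(eff_tail_by_arm(u_E, design, I, theta_E)) - target
  }
  lo <- I0 / 2; hi <- I0 * 2
  while (pw(hi) < 0 && hi < 1e4 * I0) hi <- hi * 2
  while (pw(lo) > 0 && lo > 1e-4 * I0) lo <- lo / 2
  if (pw(hi) < 0 || pw(lo) > 0)
    stop("target power unreachable within information bracket", call. = FALSE)
  I_star <- stats::uniroot(pw, c(lo, hi), tol = power_tol)$root
  b_star <- solve_boundaries(design, info_E = I_star, info_S = I_star)
  smax2 <- max(design$sigma_E^2, design$sigma_S^2)
  n_unrounded <- 2 * smax2 * I_star
  n_star <- ceiling(n_unrounded)
  info_E <- info_from_n(n_star, design$sigma_E)
  info_S <- info_from_n(n_star, design$sigma_S)
  b_final <- solve_boundaries(design, info_E = info_E, info_S = info_S)
  structure(
    list(design = design, theta_E = theta_E,
         I_star = I_star, n_unrounded = n_unrounded, n_star = n_star,
         boundaries_at_I_star = b_star, boundaries = b_final,
         attained_power = sum(eff_tail_by_arm(b_final$u_E, design,
                                              info_E, theta_E))),
    class = "rb_design_solution"
  )
}

#' @export
print.rb_design_solution <- function(x, ...) {
  cat("Single-stage risk-benefit MAMS design\n")
  cat(sprintf("  information per arm I1* = %.4f  (n unrounded = %.4f)\n",
              x$I_star, x$n_unrounded))
  cat(sprintf("  boundaries at I1*: u_E = %.4f, u_S = %.4f\n",
              x$boundaries_at_I_star$u_E, x$boundaries_at_I_star$u_S))
  cat(sprintf("  rounded n* = %d per arm -> u_E = %.4f, u_S = %.4f\n",
              x$n_star, x$boundaries$u_E, x$boundaries$u_S))
  cat(sprintf("  attained limiting power at n*: %.4f\n", x$attained_power))
  invisible(x)
}

#' Empirical power under finite safety effects
#'
#' The limiting power calculation assumes arbitrarily safe treatments; this
#' function estimates power by simulation when safety effects are finite, so
#' the gate and the safety rejection margin genuinely bind. Arms `1..j_eff`
#' carry the desirable efficacy effect `delta` and the remaining arms the
#' minimum clinically important effect `delta0`; all arms share the safety
#' effect `gamma_S`.
#'
#' @param design An [rb_design()].
#' @param solution An `rb_design_solution` from [solve_information()].
#' @param gamma_S Common safety effect (may be `design$gamma_surrogate` to
#'   approximate the limit).
#' @param j_eff Number of arms at `delta` (1..K).
#' @param reps,seed Replication and seed.
#' @return A one-row data frame with the empirical power, its binomial
#'   standard error, and the configuration.
#' @export
power_with_finite_safety <- function(design, solution, gamma_S,
                                     j_eff = 1, reps = 1e4, seed = 1) {
  stopifnot(inherits(solution, "rb_design_solution"),
            j_eff >= 1, j_eff <= design$K)
  theta_E <- c(rep(design$delta, j_eff), rep(design$delta0, design$K - j_eff))
  oc <- oc_single(design, theta_E = theta_E,
                  theta_S = rep(gamma_S, design$K),
                  boundaries = solution$boundaries, reps = reps, seed = seed)
  data.frame(gamma_S = gamma_S, j_eff = j_eff,
             power = oc["p_reject"], se = sqrt(oc["p_reject"] *
                                                 (1 - oc["p_reject"]) / reps),
             reps = reps, seed = seed, row.names = NULL)
}
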