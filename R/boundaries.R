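# Single-stage boundary criteria and solver.

rb_prob <- function(value, se, method) {
  structure(list(value = value, standard_error = se, method = method),
            class = "rb_prob")
}

#' @export
print.rb_prob <- function(x, ...) {
  cat(sprintf("limiting probability %.6f (%s", x$value, x$method))
  if (x$standard_error > 0) cat(sprintf(", MC s.e. %.2g", x$standard_error))
  cat(")\n")
  invisible(x)
}

#' Limiting rejection probabilities of the single-stage test
#'
#' `limiting_efficacy_rejection()` evaluates the efficacy calibration
#' criterion: the probability that the selected arm's efficacy score
#' statistic exceeds `u_E` in the limit where all safety effects grow without
#' bound (every arm eligible almost surely) and all efficacy effects are
#' null. `limiting_safety_rejection()` evaluates the safety criterion: the
#' conditional probability, given at least one eligible arm, that the
#' selected arm's safety score statistic exceeds `u_S` in the limit where all
#' efficacy effects grow without bound and all safety effects are null.
#' Boundaries making the first equal `alpha` and the second equal
#' `alpha / P(N_S >= 1; theta_S = 0)` control the FWER at `alpha` in the
#' strong sense.
#'
#' Two routes are available: `"integration"` (Gauss-Legendre quadrature of
#' the limiting post-selection distributions; exact to well below 1e-6) and
#' `"monte_carlo"` (simulation of selection among `K` arms with the large
#' surrogate effect `gamma_surrogate` standing in for infinity), which serves
#' as an independent oracle for the quadrature.
#'
#' @param u_E,u_S Candidate boundary on the score-statistic scale.
#' @param design An [rb_design()].
#' @param info_E,info_S Information per comparison for the endpoint.
#' @param method `"integration"` or `"monte_carlo"`.
#' @param reps,seed Monte-Carlo replication and seed (MC route only).
#' @return An `rb_prob`: list with `value`, `standard_error` (0 for the
#'   integration route) and `method`.
#' @examples
#' des <- rb_design()
#' limiting_efficacy_rejection(14.466, des, info_E = 47.148)$value  # ~ 0.05
#' @export
limiting_efficacy_rejection <- function(u_E, design, info_E,
                                        info_S = info_E * design$sigma_E^2 / design$sigma_S^2,
                                        method = c("integration", "monte_carlo"),
                                        reps = 1e5, seed = NULL) {
  stopifnot(inherits(design, "rb_design"), info_E > 0)
  method <- match.arg(method)
  theta0 <- rep(0, design$K)
  if (method == "integration") {
    rb_prob(sum(eff_tail_by_arm(u_E, design, info_E, theta0)), 0, method)
  } else {
    std <- draw_std_arms(design$K, design$rho, reps, seed)
    p <- mc_eff_tail(u_E, design, info_E, theta0, std)
    rb_prob(p, sqrt(p * (1 - p) / reps), method)
  }
}

#' @rdname limiting_efficacy_rejection
#' @export
limiting_safety_rejection <- function(u_S, design, info_S,
                                      method = c("integration", "monte_carlo"),
                                      reps = 1e5, seed = NULL) {
  stopifnot(inherits(design, "rb_design"), info_S > 0)
  method <- match.arg(method)
  p_ns <- prob_any_safe(design, info_S)
  if (method == "integration") {
    rb_prob(safety_joint_tail(u_S, design, info_S) / p_ns, 0, method)
  } else {
    std <- draw_std_arms(design$K, design$rho, reps, seed)
    tails <- mc_safety_tail(u_S, design, info_S, std)
    p <- unname(tails["joint"] / tails["p_ns"])
    rb_prob(p, sqrt(p * (1 - p) / (reps * tails["p_ns"])), method)
  }
}

# expand a bracket for uniroot until f changes sign (f decreasing in u)
root_expand <- function(f, lo, hi, max_hi, tol = 1e-10) {
  while (f(hi) > 0 && hi < max_hi) hi <- hi * 2
  if (f(hi) > 0) stop("boundary search bracket exhausted", call. = FALSE)
  while (f(lo) < 0 && lo > -max_hi) lo <- if (lo < 0) lo * 2 else lo - abs(hi)
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

#' Solve single-stage stopping boundaries at given information levels
#'
#' Root-finds `u_E` so the limiting efficacy rejection probability equals
#' `alpha`, and `u_S` so the limiting conditional safety rejection
#' probability equals `alpha / P(N_S >= 1; theta_S = 0)` — equivalently so
#' the joint safety tail equals `alpha`. The two searches are uncoupled. With
#' equal weights and equal variances the two boundaries coincide.
#'
#' @inheritParams limiting_efficacy_rejection
#' @param tol Root tolerance on the score scale (integration route).
#' @return An `"rb_boundaries"` list: `u_E`, `u_S`, `info_E`, `info_S`, and
#'   the achieved criterion residuals.
#' @examples
#' \donttest{
#' solve_boundaries(rb_design(), info_E = 47.148)  # u_E = u_S = 14.466
#' }
#' @export
solve_boundaries <- function(design, info_E,
                             info_S = info_E * design$sigma_E^2 / design$sigma_S^2,
                             method = c("integration", "monte_carlo"),
                             reps = 1e5, seed = NULL, tol = 1e-6) {
  stopifnot(inherits(design, "rb_design"), info_E > 0, info_S > 0)
  method <- match.arg(method)
  alpha <- design$alpha
  hi0 <- stats::qnorm(1 - alpha / (2 * design$K)) * sqrt(max(info_E, info_S)) + 5
  if (method == "integration") {
    f_E <- function(u) sum(eff_tail_by_arm(u, design, info_E,
                                           rep(0, design$K))) - alpha
    setup <- safety_quad_setup(design, info_S)
    f_S <- function(u) safety_joint_tail(u, design, info_S, setup) - alpha
  } else {
    std <- draw_std_arms(design$K, design$rho, reps, seed)
    f_E <- function(u) mc_eff_tail(u, design, info_E, rep(0, design$K), std) - alpha
    f_S <- function(u) mc_safety_tail(u, design, info_S, std)["joint"] - alpha
  }
  u_E <- root_expand(f_E, -sqrt(info_E), hi0, 100 * hi0, tol)
  u_S <- root_expand(f_S, max(design$c, -3 * sqrt(info_S)), hi0, 100 * hi0, tol)
  structure(
    list(u_E = u_E, u_S = u_S, info_E = info_E, info_S = info_S,
         residual_E = f_E(u_E), residual_S = f_S(u_S), method = method),
    class = "rb_boundaries"
  )
}

#' @export
print.rb_boundaries <- function(x, ...) {
  cat(sprintf("stopping boundaries (score scale): u_E = %.4f, u_S = %.4f\n",
              x$u_E, x$u_S))
  cat(sprintf("  at information I_E = %.4f, I_S = %.4f (%s route)\n",
              x$info_E, x$info_S, x$method))
  invisible(x)
}
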